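#experiment: my lifespan experiment
#control: N2
#temperature_c: 20
#researchers: AB, CD
condition,day,alive,died,censored
N2,0,60,0,0
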