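---
title: "Lifespan assay analysis with wormspan: models, conventions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lifespan assay analysis with wormspan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormspan)
```

## From scoring sheets to event records

A lifespan assay is recorded as daily counts: per condition and observation
day, the number of worms alive after scoring, newly dead, and newly censored
(missing, bagged, or exploded animals). `wormspan`'s canonical file is a
long-format CSV with header `condition,day,alive,died,censored` preceded by
`#key: value` metadata lines (`#control:`, `#temperature_c:`,
`#researchers:`, `#color:<condition>=<hex>`); the same five columns are read
from the first sheet of an Excel workbook. Validation enforces the
bookkeeping identity `alive[k] = alive[k-1] - died[k] - censored[k]`,
strictly increasing days per condition, and a control label present among
the conditions, and reports the offending condition and day on failure.

`convert_counts()` flattens counts to one record per worm. Two conventions
matter and are deliberate:

* **Event timing.** A death scored on day *d* is assigned time *d*, not an
  interval midpoint. This matches how worm researchers report lifespans
  from daily scoring; users who prefer midpoint timing can shift the `time`
  column of the event table before analysis.
* **End-of-assay survivors.** Worms still alive at a condition's last
  observation are emitted as `CENSORED` on that day, so every condition's
  records always sum to its initial worm count (a conservation property the
  test suite checks on randomized sheets).

Deaths and censoring recorded *at* day 0 are rejected: event times must be
positive, and a scoring sheet's first row is the baseline census.

## Survival estimation

`km_estimate()` computes the product-limit estimate via
`survival::survfit()`: at each distinct death time $t_k$ with $d_k$ deaths
among $r_k$ at risk, $S(t) = \prod_{t_k \le t}(1 - d_k/r_k)$. Worms censored
at $t_k$ remain at risk for deaths at $t_k$ (deaths-before-censoring, the
standard tie convention). With no censoring the estimate reduces to the
empirical survival function — the test suite asserts this against a direct
counting oracle rather than against another library.

Summaries follow worm-lab conventions:

* **Mean lifespan** is the arithmetic mean of observed death days with
  censored animals excluded — *not* the restricted mean survival time. A
  condition with zero deaths has an undefined mean and its legend entry
  shows n only.
* **Median lifespan** is the smallest death time at which the estimated
  survival is at or below 0.5 (inclusive crossing), undefined when the
  curve never reaches 0.5.

No confidence bands are drawn or computed; the plots carry per-condition
test results instead, which is how these figures are conventionally read.

## Two-sample testing

Lifespan conditions are compared with the control by Gehan's generalized
Wilcoxon rank-sum test, the pair-score form. On the pooled two-group sample
each record receives
$h_i = \#\{j: i \text{ definitively outlives } j\} - \#\{j: j \text{
definitively outlives } i\}$, where a pair is decidable only when the
earlier of the two times belongs to a death; ties in time and
censored-before-death pairs contribute zero. The statistic is
$W = \sum_{i \in \text{treatment}} h_i$ with permutation variance
$\mathrm{Var}(W) = \frac{n_t\, n_c}{N(N-1)} \sum_i h_i^2$, and
$z = W/\sqrt{\mathrm{Var}(W)}$ is referred to the standard normal,
two-sided. No continuity correction is applied. When all pooled scores are
zero (fully tied data) the p-value is reported as 1. Under no censoring the
scores are a monotone function of the ranks, so the test coincides with the
classic Wilcoxon rank-sum test — the reason a censoring-aware
generalization is the right reading of "rank-sum test" for survival data.

`permutation_pvalue()` provides the exact reference distribution: the pooled
scores are label-free, so each relabeling simply re-sums $n_t$ of them.
All $\binom{N}{n_t}$ assignments are enumerated up to a configurable pooled
size (default 12); beyond that a seeded Monte-Carlo with the observed
assignment counted in numerator and denominator. The normal approximation
is accurate for group sizes in the dozens (the suite checks agreement
within 0.05 at $n \ge 20$ per group and a type-I error rate within
[0.035, 0.065] at $\alpha = 0.05$ over 2000 null replicates), but at pooled
sizes below ~10 the permutation null is a coarse atomic distribution and
the normal tail can sit several tenths from the exact atom — for such
experiments use `permutation_pvalue()`. Each condition is tested against
the control independently and raw p-values are reported; no
multiple-testing adjustment is applied, matching field practice for
per-condition legend annotation.

## Annotation rules

* **Gene italicization.** Tokens matching `[a-z]{3,4}-[0-9]+(\.[0-9]+)?` as
  a whole word are marked italic, per *C. elegans* nomenclature
  (`daf-2`, `rsks-1`, isoforms like `ceh-20.1`). Lowercase hyphen-number
  strings that are not genes (some drug codes) will false-positive; the
  splitter is guaranteed lossless (segments always concatenate back to the
  input), so a mislabeled token costs only styling.
* **Stars.** `***`, `**`, `*` at p < 0.001, 0.01, 0.05, strict
  inequalities (p = 0.05 earns no star). The caption always carries the
  key (`* p<0.05, ** p<0.01, *** p<0.001 vs control`) plus temperature and
  researcher initials when the sheet records them.
* **Legend.** `<label> (mean <m> d, n=<n>, p=<p><stars>)`, control first
  with mean and n only; p is shown to 3 significant digits, `<0.001` below
  that. The wording is this package's choice; the content (mean, n, p vs
  control) is the fixed contract, and the summary CSV reports exactly the
  same numbers as the legend.

## SVG rendering

Plots are written as SVG 1.1 by a purpose-built renderer whose goal is
hand-editability in a vector editor: each condition is a single `<path>`
with `id="curve-<condition>"` and a `data-condition` attribute; every
legend entry, the title, the caption, and the axis labels are separate
`<text>` elements (italic gene names are `font-style="italic"` tspans); only
a generic `sans-serif` family is referenced so no fonts are embedded.
Curves are drawn as right-continuous steps (horizontal to each death time,
then a vertical drop) starting at 100% at day 0, on a y axis in percent
survival and an x axis in days. The default canvas is 800×600 px with ~10%
margins and a fixed 8-color colorblind-safe palette (Okabe-Ito) assigned in
plotting order, control first; explicit `#color:` entries or user color
maps override the palette without disturbing other assignments, and a
condition keeps its main-plot color in its individual comparison subplot.
All coordinates are formatted with fixed precision, making renders
byte-deterministic — the suite asserts byte-identical output across runs.
Censoring tick marks and risk tables are intentionally not drawn.

## Workflow conventions

`autoplot_lifespan()` titles the plot after the experiment directory's base
name, pools multiple sheets in one directory into a single experiment
(each sheet is flattened on its own, then events are concatenated;
disagreeing `#control:` lines are an error), writes the main SVG, and
writes an individual control-vs-condition SVG for every condition with
p < α (default α = 0.05, configurable). `return_data = TRUE` returns the
full analysis without touching the disk; `write_data = TRUE` additionally
writes the KM step data, the per-condition summary, and the flattened
events as CSV. `batch_autoplot()` maps this over daughter directories,
catching and logging per-directory failures so one corrupt sheet never
aborts a batch, and always returns one record per attempted daughter.
Configuration precedence is: function/CLI arguments, then in-sheet metadata
lines, then built-in defaults. Logging goes to standard error with
timestamps; `quiet = TRUE` silences info lines but not failure lines.

## The synthetic-experiment generator

`simulate_experiment()` emulates manual scoring of arms with known
lifetime distributions: per worm a true death time is drawn (exponential or
Weibull; worm cohorts are commonly Weibull-like with shape 3–5, so the
shipped examples use shape 4 with scales 12–26 days), deaths are recorded
at the next observation at or after the true time, each surviving worm is
independently censored at each observation with a per-observation
probability (a deliberately simple surrogate for missing/bagged/exploded
animals), and survivors at the final day are censored there. Identical
seeds give identical sheets. The `make_example_suite()` layouts (RNAi,
genotype, drug) use 60 worms per arm at 1% per-day censoring, sizes typical
of a single-plate worm experiment.

What the generator does *not* emulate: correlated censoring (a dropped
plate), scoring error and resurrections, heaping on non-scoring days,
batch/plate effects, and non-proportional crossing hazards. Green tests on
synthetic data therefore certify the bookkeeping, the estimator, the test,
and the rendering pipeline — not robustness to those real-world artifacts.

Note one discretization effect relevant to validation: binning deaths to
the next whole day shifts the recorded mean upward by about half the
scoring interval (for exponential lifetimes with rate 0.1/day the binned
mean is exactly $1/(1-e^{-0.1}) \approx 10.51$ days against a true 10.0),
and places the binned median on the integer grid. Recovery checks against
continuous-truth values must therefore either use raw draws or compare
against the binned distribution's own moments; the test suite does both
explicitly.

## Numerical and degenerate-input choices

* Problem sizes in the suite are desk-scale by design: recovery at
  n = 5000, null calibration with 2000 replicates of 50 + 50, power with
  200 replicates of 100 + 100 — a full run takes well under a minute.
* Zero-variance test configurations (identical or fully tied groups)
  return p = 1 rather than NaN.
* Days are non-negative reals (twice-daily scoring works); only strict
  monotonicity per condition is required.
* An empty condition, a group smaller than 2 in `gehan_test()`, x-limits
  that exclude every event, and mismatched curve/legend condition sets are
  argument errors, not silent output.
* Status tokens are exactly `DEATH` and `CENSORED`; a single censored
  status is recorded — censor *reasons* (missing vs bagged vs exploded) are
  out of scope.

## Known limitations

ODS input requires the optional readODS package and is otherwise reported
as unsupported. Only the long-format sheet dialect is read (no wide
per-plate layouts). There are no log-rank/Tarone-Ware variants, no
maximum-lifespan statistics, and no confidence bands — the Gehan test and
the annotated KM plot are deliberately the whole surface.
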