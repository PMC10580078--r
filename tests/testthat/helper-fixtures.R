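# Shared fixtures and independent brute-force oracles.

# canonical two-condition demo sheet (hand-constructed, satisfies bookkeeping)
demo_sheet <- function() {
  count_sheet(
    data.frame(
      condition = c(rep("N2", 3), rep("daf-2 RNAi", 3)),
      day = c(0, 5, 10, 0, 8, 14),
      alive = c(10, 6, 0, 8, 6, 0),
      died = c(0, 4, 5, 0, 2, 5),
      censored = c(0, 0, 1, 0, 0, 1)
    ),
    control = "N2",
    experiment_name = "demo",
    temperature_c = 20,
    researchers = c("AB", "CD"),
    colors = c("daf-2 RNAi" = "#D55E00")
  )
}

demo_sheet_lines <- function() {
  c("#experiment: demo",
    "#control: N2",
    "#temperature_c: 20",
    "#researchers: AB, CD",
    "#color:daf-2 RNAi=#D55E00",
    "condition,day,alive,died,censored",
    "N2,0,10,0,0",
    "N2,5,6,4,0",
    "N2,10,0,5,1",
    "daf-2 RNAi,0,8,0,0",
    "daf-2 RNAi,8,6,2,0",
    "daf-2 RNAi,14,0,5,1")
}

write_demo_csv <- function(path = withr::local_tempfile(fileext = ".csv",
                                                        .local_envir = parent.frame())) {
  writeLines(demo_sheet_lines(), path)
  path
}

# a seeded random valid sheet via the generator
random_sheet <- function(seed, n = 20, censor_prob = 0.05) {
  simulate_experiment(sim_spec(
    list(
      condition_spec("ctrl", "weibull", shape = 3, scale = 12, n = n,
                     censor_prob = censor_prob),
      condition_spec("trt", "weibull", shape = 3, scale = 16, n = n,
                     censor_prob = censor_prob)
    ),
    max_day = 40, seed = seed, control = "ctrl"
  ))
}

death_records <- function(times) {
  tibble::tibble(time = times, status = "DEATH")
}

# ---- independent oracles ----

# empirical survival fraction alive after time t (no censoring)
empirical_survival <- function(death_times, t) {
  mean(death_times > t)
}

# O(n^2) pairwise Gehan scores straight from the definition
gehan_scores_brute <- function(records) {
  n <- nrow(records)
  h <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      # i definitively outlives j: j died strictly earlier
      if (records$time[j] < records$time[i] && records$status[j] == "DEATH") {
        h[i] <- h[i] + 1L
      }
      # j definitively outlives i: i died strictly earlier
      if (records$time[i] < records$time[j] && records$status[i] == "DEATH") {
        h[i] <- h[i] - 1L
      }
    }
  }
  h
}

# full-enumeration permutation p-value recomputing W from scratch per labeling
perm_p_brute <- function(control, treatment) {
  pooled <- rbind(control[c("time", "status")], treatment[c("time", "status")])
  n <- nrow(pooled)
  n_t <- nrow(treatment)
  h <- gehan_scores_brute(pooled)
  w_obs <- sum(h[(nrow(control) + 1):n])
  sets <- utils::combn(n, n_t)
  w_all <- apply(sets, 2, function(idx) sum(gehan_scores_brute(pooled)[idx]))
  mean(abs(w_all) >= abs(w_obs))
}

# random censored two-group samples for the permutation battery
random_small_groups <- function(seed) {
  withr::with_seed(seed, {
    n_c <- sample(2:4, 1)
    n_t <- sample(2:4, 1)
    make <- function(n) {
      tibble::tibble(
        time = sample(1:6, n, replace = TRUE),
        status = sample(c("DEATH", "CENSORED"), n, replace = TRUE,
                        prob = c(0.75, 0.25))
      )
    }
    list(control = make(n_c), treatment = make(n_t))
  })
}

# build an xlsx copy of the demo sheet with the pre-installed python/openpyxl
write_demo_xlsx <- function(path) {
  csv <- tempfile(fileext = ".csv")
  writeLines(demo_sheet_lines(), csv)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys",
    "from openpyxl import Workbook",
    "wb = Workbook(); ws = wb.active",
    "for line in open(sys.argv[1]):",
    "    line = line.rstrip('\\n')",
    "    if line.startswith('#'):",
    "        ws.append([line])",
    "    else:",
    "        cells = line.split(',')",
    "        ws.append([c if i == 0 else (float(c) if c not in ('day','alive','died','censored') else c) for i, c in enumerate(cells)])",
    "wb.save(sys.argv[2])"
  ), script)
  status <- system2("python", c(script, csv, path), stdout = TRUE, stderr = TRUE)
  path
}
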