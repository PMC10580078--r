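#' Gehan pairwise scores for a pooled censored sample
#'
#' For each record i in the pooled sample, the Gehan score is
#' `h_i = (# records i definitively outlives) - (# records that definitively
#' outlive i)`. A pair is decidable only when the earlier of the two times
#' belongs to a death: a death at time s is definitively outlived by any
#' record (death or censored) at a strictly later time, whereas nothing can
#' be said about a pair tied in time or about times after a censoring.
#' Undecidable pairs contribute 0. With no censoring the scores are a
#' monotone function of the ranks of the death times, which is why the test
#' built on them reduces to the classic Wilcoxon rank-sum test.
#'
#' @param pooled Data frame of event records (`time`, `status`) from both
#'   groups combined, or an [event_table()].
#' @return Integer vector of scores, one per record, in input row order.
#'   The scores always sum to zero.
#' @export
#' @examples
#' gehan_scores(data.frame(time = 1:4, status = "DEATH"))  # -3 -1 1 3
gehan_scores <- function(pooled) {
  pooled <- as_event_records(pooled)
  tm <- pooled$time
  death <- pooled$status == "DEATH"
  # h_i = #{j : t_j < t_i, j died}  -  I(i died) * #{j : t_j > t_i}
  ut <- sort(unique(tm))
  death_counts <- vapply(ut, function(u) sum(death & tm == u), integer(1))
  le_counts <- vapply(ut, function(u) sum(tm <= u), integer(1))
  idx <- match(tm, ut)
  cum_before <- c(0L, cumsum(death_counts))[idx]
  n_after <- length(tm) - le_counts[idx]
  as.integer(cum_before - as.integer(death) * n_after)
}

#' Gehan generalized Wilcoxon test of a condition against the control
#'
#' Two-sample censoring-aware rank test: Gehan scores are computed on the
#' pooled sample and summed over the comparison (treatment) group to give the
#' statistic W. Under the permutation null, `Var(W) = n_t * n_c / (N (N-1)) *
#' sum(h^2)` and `z = W / sqrt(Var(W))` is referred to the standard normal
#' for a two-sided p-value. A positive W means the treatment group tends to
#' outlive the control. When every pooled score is zero (e.g. identical
#' groups with full ties) the p-value is 1. No continuity correction and no
#' multiple-testing adjustment are applied; each condition is compared to the
#' control independently.
#'
#' @param control,treatment Data frames of event records (`time`, `status`),
#'   each with at least 2 records.
#' @return An object of class `gehan_test` (also `htest`-like): a list with
#'   `statistic` (W), `variance`, `z`, `p.value`, `n_control`,
#'   `n_treatment`, `method`.
#' @seealso [permutation_pvalue()] for the exact small-sample version.
#' @export
#' @examples
#' ctl <- data.frame(time = c(1, 2), status = "DEATH")
#' trt <- data.frame(time = c(3, 4), status = "DEATH")
#' gehan_test(ctl, trt)  # W = 4, Var = 20/3, p ~= 0.121
gehan_test <- function(control, treatment) {
  control <- as_event_records(control)
  treatment <- as_event_records(treatment)
  if (nrow(control) < 2 || nrow(treatment) < 2) {
    ws_error("gehan_test() needs at least 2 records per group",
             "wormspan_argument_error")
  }
  n_c <- nrow(control)
  n_t <- nrow(treatment)
  pooled <- dplyr::bind_rows(
    control[c("time", "status")],
    treatment[c("time", "status")]
  )
  h <- gehan_scores(pooled)
  is_trt <- c(rep(FALSE, n_c), rep(TRUE, n_t))
  w <- sum(h[is_trt])
  n <- n_c + n_t
  variance <- n_t * n_c / (n * (n - 1)) * sum(h^2)
  if (variance == 0) {
    z <- 0
    p <- 1
  } else {
    z <- w / sqrt(variance)
    p <- 2 * pnorm(-abs(z))
  }
  new_gehan_test(w, variance, z, p, n_c, n_t, method = "normal_approx")
}

#' Permutation p-value for the Gehan statistic
#'
#' Exact or Monte-Carlo permutation reference for [gehan_test()]. The pooled
#' Gehan scores are fixed (they do not depend on group labels); each
#' relabeling assigns `n_treatment` of the pooled records to the treatment
#' group and recomputes `W* = sum of their scores`. The p-value is the
#' proportion of relabelings with `|W*| >= |W_observed|`. When the pooled
#' sample size is at most `max_exact_n` all `choose(N, n_t)` assignments are
#' enumerated; otherwise `n_perm` random assignments are drawn with the given
#' seed and the observed assignment is included in both numerator and
#' denominator.
#'
#' @inheritParams gehan_test
#' @param max_exact_n Largest pooled size for full enumeration.
#' @param n_perm Number of Monte-Carlo relabelings beyond `max_exact_n`.
#' @param seed Integer seed for the Monte-Carlo draw.
#' @return A `gehan_test` object with `method = "exact_permutation"` or
#'   `"monte_carlo_permutation"`.
#' @export
#' @examples
#' ctl <- data.frame(time = c(1, 2), status = "DEATH")
#' trt <- data.frame(time = c(3, 4), status = "DEATH")
#' permutation_pvalue(ctl, trt)$p.value  # 1/3
permutation_pvalue <- function(control, treatment, max_exact_n = 12,
                               n_perm = 2000, seed = 1L) {
  control <- as_event_records(control)
  treatment <- as_event_records(treatment)
  if (nrow(control) < 1 || nrow(treatment) < 1) {
    ws_error("permutation_pvalue() needs non-empty groups",
             "wormspan_argument_error")
  }
  n_c <- nrow(control)
  n_t <- nrow(treatment)
  n <- n_c + n_t
  pooled <- dplyr::bind_rows(
    control[c("time", "status")],
    treatment[c("time", "status")]
  )
  h <- gehan_scores(pooled)
  w_obs <- sum(h[(n_c + 1):n])
  variance <- n_t * n_c / (n * (n - 1)) * sum(h^2)
  z <- if (variance > 0) w_obs / sqrt(variance) else 0
  if (n <= max_exact_n) {
    assignments <- combn(n, n_t)
    w_star <- colSums(matrix(h[assignments], nrow = n_t))
    p <- mean(abs(w_star) >= abs(w_obs))
    method <- "exact_permutation"
  } else {
    w_star <- withr::with_seed(seed, {
      vapply(seq_len(n_perm),
             function(i) sum(h[sample.int(n, n_t)]),
             numeric(1))
    })
    p <- (1 + sum(abs(w_star) >= abs(w_obs))) / (1 + n_perm)
    method <- "monte_carlo_permutation"
  }
  new_gehan_test(w_obs, variance, z, p, n_c, n_t, method = method)
}

new_gehan_test <- function(w, variance, z, p, n_c, n_t, method) {
  structure(
    list(
      statistic = c(W = w),
      variance = variance,
      z = z,
      p.value = p,
      n_control = n_c,
      n_treatment = n_t,
      method = method
    ),
    class = "gehan_test"
  )
}

#' @export
print.gehan_test <- function(x, ...) {
  cat("Gehan generalized Wilcoxon test (", x$method, ")\n", sep = "")
  cat(sprintf("  W = %g, Var(W) = %.4g, z = %.3f, p = %.4g\n",
              unname(x$statistic), x$variance, x$z, x$p.value))
  cat(sprintf("  n_control = %d, n_treatment = %d\n",
              x$n_control, x$n_treatment))
  invisible(x)
}

#' Tidy a Gehan test result
#'
#' @param x A `gehan_test`.
#' @param ... Unused.
#' @return One-row tibble: `statistic`, `variance`, `z`, `p.value`,
#'   `n_control`, `n_treatment`, `method`.
#' @method tidy gehan_test
#' @export
tidy.gehan_test <- function(x, ...) {
  tibble::tibble(
    statistic = unname(x$statistic),
    variance = x$variance,
    z = x$z,
    p.value = x$p.value,
    n_control = x$n_control,
    n_treatment = x$n_treatment,
    method = x$method
  )
}

#' @rdname tidy.gehan_test
#' @method glance gehan_test
#' @export
glance.gehan_test <- function(x, ...) tidy(x, ...)
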