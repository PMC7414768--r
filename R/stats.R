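# Paired statistical comparisons and cohort reporting.

#' Matched-pair Student's t-test with effect size
#'
#' Two-sided paired t-test on per-subject condition pairs, reporting the
#' standardised effect size `dz = mean(diff) / sd(diff)`. A degenerate
#' (zero-variance) difference yields `p = 1` with a warning.
#'
#' @param a,b numeric vectors of per-subject values under conditions A and
#'   B, matched by position (length >= 2)
#' @param labels optional condition labels
#' @return list of class `paired_comparison`: `t`, `df`, `p`, `dz`,
#'   `mean_diff`, `sd_diff`, `n`
#' @export
#' @examples
#' paired_t_test(c(2, 3, 4), c(1, 1, 1)) # diffs 1, 2, 3
paired_t_test <- function(a, b, labels = c("A", "B")) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  n <- length(d)
  sd_d <- sd(d)
  if (sd_d == 0) {
    warning("zero variance of paired differences; p set to 1")
    t_stat <- 0
    p <- 1
    dz <- 0
  } else {
    t_stat <- mean(d) / (sd_d / sqrt(n))
    p <- 2 * pt(-abs(t_stat), n - 1)
    dz <- mean(d) / sd_d
  }
  structure(list(t = t_stat, df = n - 1, p = p, dz = dz,
                 mean_diff = mean(d), sd_diff = sd_d, n = n,
                 labels = labels),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("Paired t-test (%s vs %s, n = %d): t(%d) = %.3f, p = %.4g, dz = %.3f\n",
              x$labels[1], x$labels[2], x$n, x$df, x$t, x$p, x$dz))
  invisible(x)
}

#' Two one-sided tests (TOST) of equivalence for paired data
#'
#' Tests whether the paired mean difference lies within equivalence bounds
#' expressed as standardised effect sizes (`dz`); the raw bounds are
#' `+/- bound * sd(diff)`. The TOST p-value is the larger of the two
#' one-sided p-values and equivalence is declared when `p_tost < alpha`.
#' Following the gatekeeping convention of the analysis pipeline,
#' equivalence testing is meant to be invoked only when the paired t-test
#' fails to reject equality (`p > alpha`); the returned `gate_ok` flag
#' records whether that held.
#'
#' @param a,b per-subject values under the two conditions
#' @param bound equivalence bound as an effect size dz (default 0.05)
#' @param alpha significance level for both one-sided tests
#' @return list of class `tost_result`: `p_tost`, `equivalent`, `p_lower`,
#'   `p_upper`, `bound_raw`, `dz`, `gate_ok`
#' @export
#' @examples
#' tost_equivalence(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.9), bound = 2)
tost_equivalence <- function(a, b, bound = 0.05, alpha = 0.05) {
  stopifnot(length(a) == length(b), length(a) >= 2, bound > 0)
  d <- a - b
  n <- length(d)
  sd_d <- sd(d)
  if (sd_d == 0) stop("zero variance of paired differences")
  se <- sd_d / sqrt(n)
  delta <- bound * sd_d
  t_lower <- (mean(d) + delta) / se   # H0: mean <= -delta
  t_upper <- (mean(d) - delta) / se   # H0: mean >= +delta
  p_lower <- 1 - pt(t_lower, n - 1)
  p_upper <- pt(t_upper, n - 1)
  p_tost <- max(p_lower, p_upper)
  nhst <- paired_t_test(a, b)
  structure(list(p_tost = p_tost, equivalent = p_tost < alpha,
                 p_lower = p_lower, p_upper = p_upper,
                 bound_raw = delta, dz = nhst$dz,
                 gate_ok = nhst$p > alpha, p_nhst = nhst$p, n = n),
            class = "tost_result")
}

#' @export
print.tost_result <- function(x, ...) {
  cat(sprintf("TOST equivalence (n = %d): p_tost = %.4g -> %s\n",
              x$n, x$p_tost,
              if (x$equivalent) "equivalent" else "not equivalent"))
  if (!x$gate_ok)
    cat(sprintf("  note: NHST already rejected equality (p = %.3g); TOST not indicated\n",
                x$p_nhst))
  invisible(x)
}

#' Cohort summary of failure probabilities
#'
#' Per-subject failure probabilities at a snapshot age and at the end of
#' the simulated horizon, with cohort mean/SD and counts of subjects above
#' probability cutoffs.
#'
#' @param curves list of per-subject [failure_curve()] objects sharing a
#'   time grid
#' @param snapshot_age years (must lie on the simulated age range)
#' @param cutoffs probability cutoffs for exceedance counts at the
#'   snapshot age
#' @param use_repair report the with-repair curve (default) or the
#'   no-repair curve
#' @return list of class `cohort_report`: `subjects` (data frame with
#'   `subject`, `p_snapshot`, `p_end`), `mean_snapshot`, `sd_snapshot`,
#'   `mean_end`, `sd_end`, `exceedance` (named counts), `snapshot_age`
#' @export
cohort_report <- function(curves, snapshot_age = 55, cutoffs = c(0.2),
                          use_repair = TRUE) {
  stopifnot(length(curves) >= 1,
            all(vapply(curves, inherits, TRUE, "failure_curve")))
  ages <- lapply(curves, function(x) range(x$age))
  if (length(unique(vapply(curves, function(x) length(x$time), 1L))) != 1)
    stop("curves must share a time grid")
  if (snapshot_age < ages[[1]][1] || snapshot_age > ages[[1]][2])
    stop("snapshot age outside the simulated grid")
  field <- if (use_repair) "p_fail_repair" else "p_fail"
  p_snap <- vapply(curves, function(x)
    approx(x$age, x[[field]], snapshot_age)$y, 1)
  p_end <- vapply(curves, function(x) x[[field]][length(x$time)], 1)
  counts <- vapply(cutoffs, function(cc) sum(p_snap >= cc), 1L)
  names(counts) <- paste0(">=", format(cutoffs))
  structure(list(
    subjects = data.frame(subject = seq_along(curves),
                          p_snapshot = p_snap, p_end = p_end),
    mean_snapshot = mean(p_snap), sd_snapshot = sd(p_snap),
    mean_end = mean(p_end), sd_end = sd(p_end),
    exceedance = counts, snapshot_age = snapshot_age,
    use_repair = use_repair),
    class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  lab <- if (x$use_repair) "with repair" else "without repair"
  cat(sprintf("Cohort failure probabilities (%s), n = %d\n",
              lab, nrow(x$subjects)))
  cat(sprintf("  at age %.0f: %.3f +/- %.3f\n",
              x$snapshot_age, x$mean_snapshot, x$sd_snapshot))
  cat(sprintf("  at horizon end: %.3f +/- %.3f\n", x$mean_end, x$sd_end))
  for (i in seq_along(x$exceedance))
    cat(sprintf("  subjects %s at age %.0f: %d\n",
                names(x$exceedance)[i], x$snapshot_age, x$exceedance[i]))
  invisible(x)
}
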