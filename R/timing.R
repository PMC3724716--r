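# Activation-signal timing statistics: subphase integrals and percentage
# contributions, correlations of contributions between conditions, and on/off
# interval detection.

check_cycle_series <- function(x, nonneg = TRUE) {
  x <- as.numeric(x)
  if (length(x) != GC_POINTS) {
    stop(sprintf("a gait-cycle series must have %d points (0..100%% GC)",
                 GC_POINTS))
  }
  if (any(!is.finite(x))) stop("gait-cycle series contains non-finite values")
  if (nonneg && any(x < 0)) stop("gait-cycle series must be nonnegative")
  x
}

#' Subphase integrals and percentage contributions of a gait-cycle signal
#'
#' Integrates the signal amplitude (trapezoidal rule on the percent-gait-cycle
#' axis) over each of the seven gait subphases and expresses each integral as
#' a percentage of the total activity. For a constant signal the percentages
#' equal the phase widths (10, 20, 20, 10, 13, 14, 13).
#'
#' @param signal Nonnegative numeric vector of length 101 (0..100% GC).
#' @param phases Phase table, see [gait_phases()].
#' @return A `subphase_contribution`: list with `integrals` (7 nonnegative
#'   values, %GC x signal units) and `percents` (7 values summing to 100, or
#'   all `NA` for an all-zero signal).
#' @export
subphase_integrals <- function(signal, phases = gait_phases()) {
  x <- check_cycle_series(signal)
  pct <- gc_axis()
  integrals <- vapply(seq_len(nrow(phases)), function(p) {
    idx <- which(pct >= phases$lo[p] & pct <= phases$hi[p])
    pracma::trapz(pct[idx], x[idx])
  }, numeric(1))
  names(integrals) <- phases$name
  total <- sum(integrals)
  percents <- if (total > 0) 100 * integrals / total else
    stats::setNames(rep(NA_real_, nrow(phases)), phases$name)
  structure(list(integrals = integrals, percents = percents),
            class = "subphase_contribution")
}

#' Pearson correlation of subphase contributions between two conditions
#'
#' Standard product-moment correlation over the seven paired subphase
#' integrals, used to test whether the timing of an activation signal is
#' maintained between, e.g., treadmill and robotic-guided walking at the same
#' speed. A two-sided p-value from the t transform is reported alongside.
#'
#' @param a,b `subphase_contribution` objects (or plain numeric vectors of 7
#'   integrals).
#' @param use `"integrals"` (default) or `"percents"`.
#' @return List with `r` (Pearson correlation) and `p_value`.
#' @export
correlate_contributions <- function(a, b, use = c("integrals", "percents")) {
  use <- match.arg(use)
  va <- if (inherits(a, "subphase_contribution")) a[[use]] else as.numeric(a)
  vb <- if (inherits(b, "subphase_contribution")) b[[use]] else as.numeric(b)
  if (length(va) != length(vb)) stop("contribution vectors differ in length")
  if (any(!is.finite(va)) || any(!is.finite(vb))) {
    stop("contributions must be finite")
  }
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stop("zero variance in a contribution vector; correlation is undefined")
  }
  ct <- stats::cor.test(va, vb, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Detect on/off intervals of an activation signal
#'
#' Estimates a rest baseline from the lowest-decile samples of the cycle and
#' marks the signal ON wherever it exceeds `baseline + k x SD` of those
#' samples (default the triple-SD range). Runs shorter than `min_duration`
#' %GC are discarded; a run that wraps across 100% -> 0% (the cycle is
#' periodic) is merged and reported split at the cycle boundary.
#'
#' @param activation Nonnegative numeric vector of length 101.
#' @param k SD multiplier (default 3).
#' @param min_duration Minimum ON-run duration in %GC (default 5).
#' @return An `on_off_pattern`: list with `intervals` (two-column matrix of
#'   `%GC` start/end, possibly empty), `threshold_used` and `baseline`.
#' @export
detect_on_off <- function(activation, k = 3, min_duration = 5) {
  x <- check_cycle_series(activation)
  n_base <- ceiling(length(x) / 10)
  base_samples <- sort(x)[seq_len(n_base)]
  baseline <- mean(base_samples)
  threshold <- baseline + k * stats::sd(base_samples)

  on <- x > threshold
  empty <- matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (!any(on)) {
    return(structure(list(intervals = empty, threshold_used = threshold,
                          baseline = baseline),
                     class = "on_off_pattern"))
  }

  # runs on the circular axis: samples 1 and 101 both represent 0% GC
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  wrapped <- FALSE
  if (nrow(runs) >= 2L && runs[1L, 1L] == 1L &&
      runs[nrow(runs), 2L] == length(x)) {
    # merge the wrap-around run for duration accounting
    wrap_len <- (runs[1L, 2L] - runs[1L, 1L]) +
      (runs[nrow(runs), 2L] - runs[nrow(runs), 1L])
    wrapped <- TRUE
  }

  dur <- (runs[, 2L] - runs[, 1L]) # %GC, 1 sample = 1%
  keep <- dur >= min_duration
  if (wrapped) {
    k_wrap <- wrap_len >= min_duration
    keep[1L] <- k_wrap
    keep[nrow(runs)] <- k_wrap
  }
  runs <- runs[keep, , drop = FALSE]
  intervals <- cbind(start = runs[, 1L] - 1, end = runs[, 2L] - 1)
  structure(list(intervals = intervals, threshold_used = threshold,
                 baseline = baseline),
            class = "on_off_pattern")
}

#' @export
print.on_off_pattern <- function(x, ...) {
  if (nrow(x$intervals) == 0L) {
    cat("no ON intervals (threshold", format(x$threshold_used), ")\n")
  } else {
    cat(sprintf("ON intervals (threshold %.4g):\n", x$threshold_used))
    for (i in seq_len(nrow(x$intervals))) {
      cat(sprintf("  %g%% - %g%% GC\n", x$intervals[i, 1], x$intervals[i, 2]))
    }
  }
  invisible(x)
}
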