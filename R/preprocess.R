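#' Raw multi-channel EMG container
#'
#' @param samples Numeric matrix, channels x samples, arbitrary amplitude
#'   units.
#' @param fs Sampling rate in Hz.
#' @param channel_names Unique channel labels, one per row; defaults to the
#'   rownames of `samples`.
#' @return A `raw_emg` object (list with `samples`, `fs`, `channel_names`).
#' @export
raw_emg <- function(samples, fs, channel_names = rownames(samples)) {
  samples <- as.matrix(samples)
  stopifnot(is.numeric(samples), is.numeric(fs), length(fs) == 1L, fs > 0)
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(nrow(samples)))
  }
  if (anyDuplicated(channel_names)) stop("channel names must be unique")
  if (length(channel_names) != nrow(samples)) {
    stop("one channel name per row is required")
  }
  if (ncol(samples) <= fs) stop("need more than 1 s of signal (N > fs)")
  rownames(samples) <- channel_names
  structure(list(samples = samples, fs = fs, channel_names = channel_names),
            class = "raw_emg")
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a 3rd-order Butterworth band-pass (default 20-400 Hz) to each
#' channel, forward and backward (`signal::filtfilt`) so the envelope timing
#' is not shifted by filter phase lag. Attenuates DC offset, motion artifacts
#' and high-frequency noise.
#'
#' @param raw A [raw_emg()] object.
#' @param low,high Band edges in Hz (`0 < low < high < fs/2`).
#' @param order Butterworth order (default 3).
#' @return A `raw_emg` of identical dimensions.
#' @export
bandpass_filter <- function(raw, low = 20, high = 400, order = 3L) {
  stopifnot(inherits(raw, "raw_emg"))
  if (low <= 0 || low >= high) stop("need 0 < `low` < `high`")
  if (high >= raw$fs / 2) {
    stop(sprintf("`high` (%g Hz) must be below the Nyquist frequency %g Hz",
                 high, raw$fs / 2))
  }
  bf <- signal::butter(order, c(low, high) / (raw$fs / 2), type = "pass")
  out <- raw$samples
  for (i in seq_len(nrow(out))) {
    out[i, ] <- signal::filtfilt(bf, raw$samples[i, ])
  }
  raw_emg(out, raw$fs, raw$channel_names)
}

# Centered moving RMS with shrunken windows at the edges, O(N) via cumsum.
moving_rms <- function(x, window) {
  n <- length(x)
  h_left <- (window - 1L) %/% 2L
  h_right <- window %/% 2L
  cs <- c(0, cumsum(x^2))
  t <- seq_len(n)
  lo <- pmax(1L, t - h_left)
  hi <- pmin(n, t + h_right)
  sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

#' Rectify and RMS-smooth filtered EMG
#'
#' Per channel: absolute value, then a centered moving root-mean-square with
#' the given window (default 50 samples = 50 ms at 1 kHz). Edge samples use
#' the shrunken window that fits inside the signal. Output is nonnegative and
#' the same length as the input.
#'
#' @param filtered A [raw_emg()] object (typically band-pass filtered).
#' @param window RMS window length in samples (1 <= window < N).
#' @return A `raw_emg` holding the per-channel envelopes.
#' @export
rectify_and_smooth <- function(filtered, window = 50L) {
  stopifnot(inherits(filtered, "raw_emg"))
  window <- as.integer(window)
  n <- ncol(filtered$samples)
  if (window < 1L) stop("`window` must be >= 1 sample")
  if (window >= n) stop("`window` must be shorter than the signal")
  out <- filtered$samples
  for (i in seq_len(nrow(out))) {
    out[i, ] <- moving_rms(abs(filtered$samples[i, ]), window)
  }
  raw_emg(out, filtered$fs, filtered$channel_names)
}

#' Segment envelopes into gait cycles and time-normalize to 101 points
#'
#' Cycles run from one heel strike to the next (half-open `[HS_i, HS_(i+1))`)
#' and each is linearly resampled to 101 points spanning 0% to 100% of the
#' gait cycle inclusive. The ten central cycles by stride index are retained
#' (for an odd surplus, one more trailing than leading cycle is dropped).
#'
#' @param envelope A [raw_emg()] holding per-channel envelopes.
#' @param heel_strikes Strictly increasing 1-based sample indices of heel
#'   strikes; at least 11 are required for the default ten-central rule.
#' @param keep `"ten central"` (default) or `"all"`.
#' @return A `stride_envelopes` object: list with `cycles` (array muscles x
#'   101 x n_kept), `stride_ids` (original cycle indices kept) and
#'   `channel_names`.
#' @export
segment_and_normalize <- function(envelope, heel_strikes,
                                  keep = c("ten central", "all")) {
  stopifnot(inherits(envelope, "raw_emg"))
  keep <- match.arg(keep)
  hs <- as.numeric(heel_strikes)
  n <- ncol(envelope$samples)
  if (any(diff(hs) <= 0)) stop("heel strikes must be strictly increasing")
  if (hs[1] < 1 || hs[length(hs)] > n) {
    stop("heel strikes must lie within the signal")
  }
  n_cycles <- length(hs) - 1L
  if (keep == "ten central") {
    if (length(hs) < 11L) {
      stop("at least 11 heel strikes (10 gait cycles) are required")
    }
    surplus <- n_cycles - 10L
    first <- 1L + surplus %/% 2L
    ids <- seq(first, first + 9L)
  } else {
    if (n_cycles < 1L) stop("need at least 2 heel strikes")
    ids <- seq_len(n_cycles)
  }

  m <- nrow(envelope$samples)
  t_idx <- seq_len(n)
  cycles <- array(0, dim = c(m, GC_POINTS, length(ids)),
                  dimnames = list(envelope$channel_names, gc_axis(), NULL))
  for (k in seq_along(ids)) {
    i <- ids[k]
    pos <- hs[i] + (hs[i + 1L] - hs[i]) * (0:(GC_POINTS - 1L)) / (GC_POINTS - 1L)
    for (ch in seq_len(m)) {
      cycles[ch, , k] <- stats::approx(t_idx, envelope$samples[ch, ],
                                       xout = pos)$y
    }
  }
  structure(list(cycles = cycles, stride_ids = ids,
                 channel_names = envelope$channel_names),
            class = "stride_envelopes")
}

#' Average stride cycles and amplitude-normalize across conditions
#'
#' For each condition, the retained cycles are averaged into one muscles x
#' 101 matrix; each muscle is then divided by its maximum over *all* of the
#' subject's conditions, so every muscle attains 1.0 in at least one
#' condition. This cross-condition normalization preserves between-condition
#' amplitude differences within each muscle.
#'
#' @param strides_by_condition Named list of `stride_envelopes` (one per
#'   condition), all sharing the same channel ordering. Each element may
#'   carry a `"condition"` attribute which is propagated.
#' @return Named list of muscles x 101 matrices (the normalized envelope
#'   matrices), each with attributes `"normalization_maxima"` (the
#'   per-muscle scaling used) and, when available, `"condition"`.
#' @export
average_and_scale <- function(strides_by_condition) {
  stopifnot(is.list(strides_by_condition), length(strides_by_condition) >= 1L)
  ok <- vapply(strides_by_condition, inherits, logical(1), "stride_envelopes")
  if (!all(ok)) stop("every element must be a `stride_envelopes` object")
  ch <- strides_by_condition[[1L]]$channel_names
  same <- vapply(strides_by_condition,
                 function(s) identical(s$channel_names, ch), logical(1))
  if (!all(same)) stop("all conditions must share the muscle ordering")

  means <- lapply(strides_by_condition, function(s) {
    apply(s$cycles, c(1, 2), mean)
  })
  maxima <- apply(do.call(cbind, lapply(means, function(mm) {
    apply(mm, 1, max)
  })), 1, max)
  if (any(maxima <= 0)) {
    stop(sprintf(
      "muscle(s) %s are identically zero across all conditions; amplitude normalization is undefined",
      paste(ch[maxima <= 0], collapse = ", ")
    ))
  }
  out <- lapply(seq_along(means), function(i) {
    v <- sweep(means[[i]], 1, maxima, "/")
    dimnames(v) <- list(ch, gc_axis())
    attr(v, "normalization_maxima") <- maxima
    cond <- attr(strides_by_condition[[i]], "condition")
    if (!is.null(cond)) attr(v, "condition") <- cond
    v
  })
  names(out) <- names(strides_by_condition)
  out
}

#' Average normalized envelope matrices across subjects
#'
#' @param subject_envelopes List (one element per subject) of named lists of
#'   normalized envelope matrices as produced by [average_and_scale()]; all
#'   subjects must share the same condition names.
#' @return Named list of group-average muscles x 101 matrices.
#' @export
group_average_envelopes <- function(subject_envelopes) {
  stopifnot(is.list(subject_envelopes), length(subject_envelopes) >= 1L)
  conds <- names(subject_envelopes[[1L]])
  same <- vapply(subject_envelopes,
                 function(s) identical(names(s), conds), logical(1))
  if (!all(same)) stop("all subjects must share the same condition set")
  out <- lapply(conds, function(cn) {
    Reduce(`+`, lapply(subject_envelopes, `[[`, cn)) /
      length(subject_envelopes)
  })
  names(out) <- conds
  out
}

#' Run the full preprocessing chain on one raw trial
#'
#' Band-pass filter, rectify and RMS-smooth, then segment into time-normalized
#' gait cycles. Convenience wrapper used by the pipeline.
#'
#' @param trial A `raw_trial` (e.g. from [synthesize_raw_trial()]) or a
#'   [raw_emg()] plus `heel_strikes`.
#' @param heel_strikes Heel-strike sample indices (taken from the trial if
#'   omitted).
#' @param low,high,order Band-pass parameters, see [bandpass_filter()].
#' @param window RMS window in samples, see [rectify_and_smooth()].
#' @param keep Stride-selection rule, see [segment_and_normalize()].
#' @return A `stride_envelopes` object with the trial's condition attached as
#'   attribute `"condition"` when present.
#' @export
preprocess_trial <- function(trial, heel_strikes = NULL, low = 20, high = 400,
                             order = 3L, window = 50L,
                             keep = c("ten central", "all")) {
  keep <- match.arg(keep)
  if (inherits(trial, "raw_trial")) {
    raw <- raw_emg(trial$emg, trial$fs, trial$channel_names)
    heel_strikes <- heel_strikes %||% trial$heel_strikes
    cond <- trial$condition
  } else {
    raw <- trial
    cond <- NULL
  }
  if (is.null(heel_strikes)) stop("`heel_strikes` is required")
  env <- rectify_and_smooth(bandpass_filter(raw, low, high, order), window)
  out <- segment_and_normalize(env, heel_strikes, keep)
  if (!is.null(cond)) attr(out, "condition") <- cond
  out
}
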