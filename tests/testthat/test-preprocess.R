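make_test_raw <- function(x, fs = 1000) {
  raw_emg(matrix(x, nrow = 1, dimnames = list("ch1", NULL)), fs)
}

test_that("band-pass filter passes the band and rejects DC", {
  fs <- 1000
  n <- 4000
  t <- (seq_len(n) - 1) / fs

  zero <- bandpass_filter(make_test_raw(rep(0, n)))
  expect_true(all(zero$samples == 0))

  dc <- bandpass_filter(make_test_raw(rep(1, n)))
  mid <- 1000:3000
  expect_lt(max(abs(dc$samples[1, mid])), 1e-3)

  # 100 Hz sits inside 20-400 Hz: steady-state amplitude (quadrature
  # projection over the middle of the signal) within 2% of unity
  sine <- bandpass_filter(make_test_raw(sin(2 * pi * 100 * t)))
  y <- sine$samples[1, mid]
  amp <- 2 * sqrt(mean(y * sin(2 * pi * 100 * t[mid]))^2 +
                    mean(y * cos(2 * pi * 100 * t[mid]))^2)
  expect_lt(abs(amp - 1), 0.02)
  # ... and agrees with the transfer-function oracle |H(100 Hz)|^2 evaluated
  # directly from the filter coefficients (zero-phase = two passes)
  bf <- signal::butter(3, c(20, 400) / (fs / 2), type = "pass")
  z <- exp(-1i * 2 * pi * 100 / fs)
  h100 <- abs(sum(bf$b * z^(seq_along(bf$b) - 1)) /
                sum(bf$a * z^(seq_along(bf$a) - 1)))
  expect_equal(amp, h100^2, tolerance = 0.01)

  expect_error(bandpass_filter(make_test_raw(rep(0, n)), high = 600),
               "Nyquist")
  expect_error(bandpass_filter(make_test_raw(rep(0, n)), low = 0))
})

test_that("rectify-and-smooth is a rectification-symmetric moving RMS", {
  n <- 2000
  const <- rectify_and_smooth(make_test_raw(rep(3.5, n)), window = 50)
  expect_equal(unname(const$samples[1, ]), rep(3.5, n), tolerance = 1e-12)

  neg <- rectify_and_smooth(make_test_raw(rep(-3.5, n)), window = 50)
  expect_equal(neg$samples, const$samples)

  square <- rectify_and_smooth(make_test_raw(rep(c(1, -1), n / 2)),
                               window = 50)
  expect_equal(unname(square$samples[1, ]), rep(1, n), tolerance = 1e-12)

  expect_error(rectify_and_smooth(make_test_raw(rep(1, 2000)), window = 2000),
               "shorter than the signal")

  # hand-computed moving RMS on a short ramp, shrunken edge windows
  x <- as.numeric(1:8)
  sm <- synergait:::moving_rms(x, 3)
  manual <- sapply(1:8, function(i) {
    idx <- max(1, i - 1):min(8, i + 1)
    sqrt(mean(x[idx]^2))
  })
  expect_equal(sm, manual)
})

test_that("segmentation keeps the ten central cycles and preserves ramps", {
  fs <- 1000
  n <- 13000
  ramp <- make_test_raw(seq(0, 1, length.out = n), fs)
  hs <- seq(1, 13001, by = 1000)[1:12] # 12 strikes -> 11 cycles

  st <- segment_and_normalize(ramp, hs)
  expect_equal(dim(st$cycles), c(1L, 101L, 10L))
  expect_equal(st$stride_ids, 1:10) # odd surplus drops the trailing cycle

  # a linear ramp resamples to the same ramp on 101 points
  cyc1 <- st$cycles[1, , 1]
  expect_equal(cyc1, seq(cyc1[1], cyc1[101], length.out = 101),
               tolerance = 1e-12, ignore_attr = TRUE)

  # strictly positive input stays strictly positive
  pos <- make_test_raw(runif(n, 0.1, 1), fs)
  stp <- segment_and_normalize(pos, hs)
  expect_true(all(stp$cycles > 0))

  expect_error(segment_and_normalize(ramp, hs[1:10]), "at least 11")
  expect_error(segment_and_normalize(ramp, c(1, 3, 2)), "strictly increasing")
  # keep = "all" retains every cycle
  expect_equal(dim(segment_and_normalize(ramp, hs, keep = "all")$cycles)[3],
               11L)
})

test_that("averaging and cross-condition scaling follow the normalization rule", {
  mk_strides <- function(cycles_list) {
    arr <- array(unlist(cycles_list), dim = c(2, 101, length(cycles_list)),
                 dimnames = list(c("RF", "VL"), NULL, NULL))
    structure(list(cycles = arr, stride_ids = seq_along(cycles_list),
                   channel_names = c("RF", "VL")),
              class = "stride_envelopes")
  }
  base <- rbind(RF = 3.7 * exp(-((0:100) - 30)^2 / 200),
                VL = 1.2 * exp(-((0:100) - 60)^2 / 200))

  # single condition: every muscle self-normalizes to peak 1
  one <- average_and_scale(list(c1 = mk_strides(list(base, base))))
  expect_equal(max(one$c1["RF", ]), 1)
  expect_equal(max(one$c1["VL", ]), 1)
  # two identical cycles average to either cycle (before scaling: ratio check)
  expect_equal(one$c1["RF", ] * attr(one$c1, "normalization_maxima")["RF"],
               base["RF", ], ignore_attr = TRUE)

  # cross-condition: the weaker condition must NOT reach 1
  two <- average_and_scale(list(a = mk_strides(list(base)),
                                b = mk_strides(list(0.5 * base))))
  expect_equal(max(two$a["RF", ]), 1)
  expect_equal(max(two$b["RF", ]), 0.5)

  # brute-force mean oracle over 10 distinct cycles
  set.seed(8)
  cycles <- lapply(1:10, function(i) base * runif(1, 0.5, 1.5))
  st10 <- mk_strides(cycles)
  avg <- average_and_scale(list(x = st10))$x
  manual <- Reduce(`+`, cycles) / 10
  manual <- sweep(manual, 1, apply(manual, 1, max), "/")
  expect_equal(unname(avg), unname(manual), ignore_attr = TRUE)

  # identically zero muscle is rejected
  z <- base
  z["VL", ] <- 0
  expect_error(average_and_scale(list(c1 = mk_strides(list(z)))),
               "identically zero")
})

test_that("permuting channels permutes envelope rows with no leakage", {
  gt <- make_ground_truth(4, seed = 1)
  cond <- condition_spec("treadmill", 2.0)
  trial <- synthesize_raw_trial(gt, cond, seed = 3)
  raw <- raw_emg(trial$emg, trial$fs, trial$channel_names)
  perm <- c(3, 1, 7, 2, 6, 4, 5)
  raw_p <- raw_emg(trial$emg[perm, ], trial$fs, trial$channel_names[perm])

  env <- rectify_and_smooth(bandpass_filter(raw))
  env_p <- rectify_and_smooth(bandpass_filter(raw_p))
  expect_equal(env_p$samples, env$samples[perm, ])

  st <- segment_and_normalize(env, trial$heel_strikes)
  st_p <- segment_and_normalize(env_p, trial$heel_strikes)
  expect_equal(st_p$cycles[, , 1], st$cycles[perm, , 1])
})
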