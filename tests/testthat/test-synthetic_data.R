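test_that("ground truth honours the muscle groupings and constructor contract", {
  gt <- make_ground_truth(4, seed = 1)
  expect_equal(dim(gt$W_true), c(7L, 4L))
  expect_equal(ncol(gt$A_true), 101L)
  expect_true(all(gt$W_true >= 0))
  expect_true(all(gt$A_true >= 0))
  expect_equal(unname(apply(gt$W_true, 2, max)), rep(1, 4))
  # plantarflexor module: largest two weights on GM and GL
  top2 <- rownames(gt$W_true)[order(gt$W_true[, 3], decreasing = TRUE)[1:2]]
  expect_setequal(top2, c("GM", "GL"))
  # quadriceps module dominated by RF/VL, hamstring module by ST/BF, TA module by TA
  expect_setequal(rownames(gt$W_true)[order(gt$W_true[, 1], decreasing = TRUE)[1:2]],
                  c("RF", "VL"))
  expect_setequal(rownames(gt$W_true)[order(gt$W_true[, 2], decreasing = TRUE)[1:2]],
                  c("ST", "BF"))
  expect_equal(which.max(gt$W_true[, 4]), c(TA = 7L))

  # seeded determinism
  expect_identical(make_ground_truth(4, seed = 1), gt)

  gt2 <- make_ground_truth(2, seed = 7)
  expect_equal(ncol(gt2$W_true), 2L)
  expect_true(all(gt2$W_true >= 0))
  expect_equal(unname(apply(gt2$W_true, 2, max)), rep(1, 2))

  expect_error(make_ground_truth(1, seed = 1), "between 2 and 5")
  expect_error(make_ground_truth(6, seed = 1), "between 2 and 5")
})

test_that("synthesized envelopes are the exact modular product when noiseless", {
  gt <- make_ground_truth(4, seed = 1)
  ref <- condition_spec("treadmill", 2.0) # neutral reference condition
  env <- synthesize_envelopes(gt, ref, noise_sd = 0)
  expect_equal(unname(env), unname(gt$W_true %*% gt$A_true),
               tolerance = 1e-12, ignore_attr = TRUE)

  # any condition scaling is diagonal, so noiseless rank stays <= n_modules
  for (cond in list(condition_spec("robotic", 1.5, guidance_force = 20),
                    condition_spec("robotic", 2.5, guidance_force = 100),
                    condition_spec("treadmill", 1.5))) {
    e <- synthesize_envelopes(gt, cond, noise_sd = 0)
    expect_true(all(e >= 0))
    expect_lte(num_rank(e), 4L)
  }
})

test_that("envelope noise has the requested standard deviation", {
  gt <- make_ground_truth(4, seed = 1)
  ref <- condition_spec("treadmill", 2.0)
  clean <- synthesize_envelopes(gt, ref, noise_sd = 0)
  noisy <- synthesize_envelopes(gt, ref, noise_sd = 0.05, seed = 42)
  nominal <- 0.05 * max(clean)
  measured <- sd(noisy - clean) # includes the clip-at-zero of the generator
  expect_lt(abs(measured - nominal), 0.2 * nominal)
})

test_that("raw trials have the stated stride structure and determinism", {
  gt <- make_ground_truth(4, seed = 1)
  cond <- condition_spec("robotic", 2.0, guidance_force = 70)
  trial <- synthesize_raw_trial(gt, cond, n_strides = 12, seed = 5)
  expect_length(trial$heel_strikes, 13L)
  expect_true(all(diff(trial$heel_strikes) > 0))
  expect_lte(max(trial$heel_strikes), ncol(trial$emg))
  expect_identical(synthesize_raw_trial(gt, cond, n_strides = 12, seed = 5),
                   trial)
  expect_error(synthesize_raw_trial(gt, cond, n_strides = 11, seed = 5),
               "ten central")

  # stride duration scales inversely with speed (2.4 s at 1.5 km/h)
  tr15 <- synthesize_raw_trial(gt, condition_spec("treadmill", 1.5), seed = 1)
  expect_equal(diff(tr15$heel_strikes)[1], 2400L)

  # zero-amplitude ground truth modulates the carrier to exactly zero
  gt0 <- gt
  gt0$A_true[] <- 0
  tr0 <- synthesize_raw_trial(gt0, cond, n_strides = 12, seed = 5)
  expect_true(all(tr0$emg == 0))
})

test_that("the preprocessing chain recovers the generating envelope", {
  gt <- make_ground_truth(4, seed = 1)
  cond <- condition_spec("treadmill", 2.0)
  clean <- synthesize_envelopes(gt, cond, noise_sd = 0)
  trial <- synthesize_raw_trial(gt, cond, n_strides = 12, seed = 3)
  strides <- preprocess_trial(trial)
  recovered <- apply(strides$cycles, c(1, 2), mean)
  for (i in seq_len(nrow(clean))) {
    expect_gte(cor(recovered[i, ], clean[i, ]), 0.9)
  }
})

test_that("joint traces attain requested extrema exactly where requested", {
  # published hip kinematics row as the requested extrema
  tr <- synthesize_cycle_trace(-16.47, 23.49, t_min = 41, t_max = 80)
  expect_identical(min(tr), -16.47)
  expect_identical(max(tr), 23.49)

  tr2 <- synthesize_cycle_trace(0, 1, t_min = 25, t_max = 75)
  expect_equal(which.min(tr2), 26L) # sample at 25% GC
  expect_equal(which.max(tr2), 76L) # sample at 75% GC

  expect_error(synthesize_cycle_trace(1, 0), "`min` must be <")

  cond <- condition_spec("robotic", 1.5, guidance_force = 20)
  kin <- synthesize_joint_traces(cond)
  expect_named(kin, c("pct_gait_cycle", "hip_angle_deg", "knee_angle_deg",
                      "hip_force", "knee_force"))
  expect_equal(nrow(kin), 101L)

  bad <- data.frame(joint = "hip", signal = "angle", min = 5, max = 5,
                    t_min = 10, t_max = 60)
  expect_error(synthesize_joint_traces(cond, extrema = bad), "min")

  # generator-oracle closure: ROM of a requested trace is max - min of the request
  set.seed(99)
  for (k in 1:5) {
    a <- runif(1, -40, 0)
    b <- runif(1, 5, 60)
    tr <- synthesize_cycle_trace(a, b, t_min = sample(0:40, 1),
                                 t_max = sample(55:95, 1))
    expect_equal(range_of_motion(tr)$range, b - a)
  }
})
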