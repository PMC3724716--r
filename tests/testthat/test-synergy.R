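test_that("NNMF reconstructs exact low-rank inputs and saturated models", {
  lr <- make_exact_lowrank(m = 7, n = 4, t = 101)
  fac <- extract_modules(lr$V, 4, restarts = 10, seed = 1)
  expect_gte(compute_vaf(lr$V, fac$W %*% fac$A), 0.999)

  # n = m reconstructs any nonnegative matrix of rank <= m
  fac_full <- extract_modules(lr$V, 7, restarts = 5, seed = 1)
  expect_gte(compute_vaf(lr$V, fac_full$W %*% fac_full$A), 0.999)

  expect_error(extract_modules(-lr$V, 2), "nonnegative")
  expect_error(extract_modules(lr$V, 8), "1 <= n")
})

test_that("factorizations satisfy the canonical-form contract", {
  gt <- make_ground_truth(4, seed = 1)
  env <- synthesize_envelopes(gt, condition_spec("treadmill", 2.0),
                              noise_sd = 0.05, seed = 2)
  fac <- extract_modules(env, 4, restarts = 5, seed = 1)

  expect_true(all(fac$W >= 0))
  expect_true(all(fac$A >= 0))
  expect_equal(unname(apply(fac$W, 2, max)), rep(1, 4))
  # modules ordered by %GC of activation peak
  peaks <- apply(fac$A, 1, which.max)
  expect_true(all(diff(peaks) >= 0))
  # objective matches the reconstruction it reports
  expect_equal(fac$objective, sum((env - fac$W %*% fac$A)^2),
               tolerance = 1e-8)
  # the per-run objective never increases across iterations
  expect_true(all(diff(fac$objective_trace) <= 1e-10))
})

test_that("VAF matches hand-computed oracles and masks partition the cycle", {
  V <- matrix(c(1, 0, 2, 1), 2, 2)       # [[1,2],[0,1]] row-wise
  R <- matrix(c(1, 0, 1, 1), 2, 2)       # [[1,1],[0,1]]
  expect_equal(compute_vaf(V, R), 1 - 1 / 6)
  expect_equal(compute_vaf(V, V), 1)
  expect_equal(compute_vaf(V, 0 * V), 0)
  expect_error(compute_vaf(V, R[, 1, drop = FALSE]), "shapes differ")
  expect_error(compute_vaf(0 * V, 0 * V), "identically zero")

  idx <- lapply(1:7, phase_sample_idx)
  expect_equal(sort(unlist(idx)), 1:101)          # partition: covers all
  expect_equal(sum(lengths(idx)), 101L)           # ... with no overlap
  # boundaries follow the published subphase bounds (lower-inclusive)
  expect_equal(idx[[1]][1], 1L)                   # 0% GC
  expect_equal(idx[[3]][1], 31L)                  # 30% GC
  expect_equal(idx[[7]], 88:101)                  # 87..100% GC inclusive

  # per-phase masked VAF of a perfect reconstruction is 1 everywhere
  M <- matrix(runif(7 * 101, 0.1, 1), 7, 101)
  for (p in 1:7) expect_equal(compute_vaf(M, M, phase = p), 1)
})

test_that("the VAF selection rule finds the generative module count", {
  gt4 <- make_ground_truth(4, seed = 1)
  env4 <- synthesize_envelopes(gt4, condition_spec("treadmill", 2.0),
                               noise_sd = 0)
  sel4 <- select_module_count(env4, candidates = 2:5, restarts = 5, seed = 1)
  expect_equal(sel4$n_selected, 4L)
  expect_true(sel4$qualifies)

  gt2 <- make_ground_truth(2, seed = 7)
  env2 <- synthesize_envelopes(gt2, condition_spec("treadmill", 2.0),
                               noise_sd = 0)
  sel2 <- select_module_count(env2, candidates = 2:5, restarts = 5, seed = 1)
  expect_equal(sel2$n_selected, 2L)

  # warm-started chain keeps the best-of-restarts VAF non-decreasing in n
  overall <- vapply(sel4$reports, `[[`, numeric(1), "vaf_overall")
  expect_true(all(diff(overall) >= -1e-9))

  # a single qualifying candidate is returned as-is
  sel1 <- select_module_count(env4, candidates = 5, restarts = 5, seed = 1)
  expect_equal(sel1$n_selected, 5L)
  expect_error(select_module_count(env4, candidates = integer(0)), "nonempty")
})

test_that("fixed-module re-fit solves per-column NNLS exactly", {
  lr <- make_exact_lowrank(m = 7, n = 4, t = 50)
  # compatible input: the generating activations are recovered
  A_hat <- fixed_module_activations(lr$V, lr$W)
  expect_lt(max(abs(A_hat - lr$A)), 1e-6)

  # zero target gives zero activations
  A0 <- fixed_module_activations(matrix(0, 7, 10) + 0, abs(lr$W))
  expect_true(all(A0 == 0))

  expect_error(fixed_module_activations(lr$V, cbind(lr$W[, 1:3], 0)),
               "zero column")
  expect_error(fixed_module_activations(lr$V, lr$W[1:5, ]), "one row per")

  # incompatible random target: per-column objective matches the exhaustive
  # support-enumeration oracle
  set.seed(21)
  V <- matrix(runif(7 * 30), 7, 30)
  A_fit <- fixed_module_activations(V, lr$W)
  for (j in seq_len(ncol(V))) {
    oracle <- nnls_exhaustive(lr$W, V[, j])
    got <- sum((V[, j] - lr$W %*% A_fit[, j])^2)
    expect_lt(abs(got - oracle$objective), 1e-6)
  }
})

test_that("module matching inverts permutations and is exhaustive-optimal", {
  lr <- make_exact_lowrank(m = 7, n = 4, t = 20)
  ref <- list(W = lr$W)

  # spec permutation (2,0,1,3) zero-based = columns (3,1,2,4)
  p <- c(3L, 1L, 2L, 4L)
  mm <- match_modules(ref, list(W = lr$W[, p]))
  expect_equal(p[mm$permutation], 1:4)       # recovered mapping inverts it
  expect_equal(unname(mm$similarities), rep(1, 4))

  mm_id <- match_modules(ref, ref)
  expect_equal(mm_id$permutation, 1:4)

  # optimal over all 24 permutations of a random pair
  other <- list(W = matrix(runif(28), 7, 4))
  mm_r <- match_modules(ref, other)
  rmat <- cor(ref$W, other$W)
  perms <- pracma::perms(1:4)
  totals <- apply(perms, 1, function(q) sum(rmat[cbind(1:4, q)]))
  expect_gte(mm_r$total + 1e-12, max(totals))

  expect_error(match_modules(ref, list(W = lr$W[, 1:3])), "module count")
})

test_that("unit-max rescaling of W leaves the reconstruction invariant", {
  lr <- make_exact_lowrank(m = 7, n = 3, t = 40)
  scales <- c(0.2, 5, 1.7)
  W2 <- sweep(lr$W, 2, scales, "*")
  A2 <- sweep(lr$A, 1, scales, "/")
  fac <- synergait:::canonicalize_factors(W2, A2)
  expect_equal(fac$W %*% fac$A, lr$W %*% lr$A, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unname(apply(fac$W, 2, max)), rep(1, 3))
})
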