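# Non-negative matrix factorization of EMG envelope matrices into motor
# modules (muscle weightings, columns of W) and activation signals (rows of
# A), with squared-error objective  sum((EMG0 - W A)^2)  minimized by
# Lee-Seung multiplicative updates.

EPS_NMF <- 1e-12

# One multiplicative-update run from a given nonnegative initialization.
nmf_mu <- function(V, W, A, tol = 1e-6, max_iter = 2000L) {
  obj <- sum((V - W %*% A)^2)
  trace <- numeric(max_iter + 1L)
  trace[1L] <- obj
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    A <- A * (crossprod(W, V) / pmax(crossprod(W) %*% A, EPS_NMF))
    W <- W * (V %*% t(A) / pmax(W %*% tcrossprod(A), EPS_NMF))
    obj_new <- sum((V - W %*% A)^2)
    trace[iter + 1L] <- obj_new
    converged <- obj - obj_new <= tol * max(obj, EPS_NMF)
    obj <- obj_new
    if (converged) break
  }
  list(W = W, A = A, objective = obj, iterations = iter,
       objective_trace = trace[seq_len(iter + 1L)])
}

as_envelope_values <- function(emg0) {
  v <- as.matrix(emg0)
  if (!is.numeric(v)) stop("`emg0` must be a numeric matrix")
  if (any(v < 0)) stop("`emg0` must be nonnegative")
  v
}

# Push scale into A (unit-max columns of W) and sort modules by the %GC of
# their activation peak; peak-time ties broken by the muscle index of the
# module's largest weight.  Reconstruction W A is unchanged.
canonicalize_factors <- function(W, A) {
  cmax <- apply(W, 2, max)
  cmax[cmax == 0] <- 1
  W <- sweep(W, 2, cmax, "/")
  A <- sweep(A, 1, cmax, "*")
  peak <- apply(A, 1, which.max) - 1L
  tie <- apply(W, 2, which.max)
  ord <- order(peak, tie)
  W <- W[, ord, drop = FALSE]
  A <- A[ord, , drop = FALSE]
  mod_names <- paste0("module_", seq_len(ncol(W)))
  colnames(W) <- mod_names
  rownames(A) <- mod_names
  if (ncol(A) == GC_POINTS) colnames(A) <- gc_axis()
  list(W = W, A = A)
}

#' Extract motor modules by non-negative matrix factorization
#'
#' Factorizes a nonnegative envelope matrix `EMG0` (muscles x time) into
#' `W %*% A` with `W` (muscles x n) the motor modules and `A` (n x time) the
#' activation signals, minimizing the squared Frobenius reconstruction error
#' by Lee-Seung multiplicative updates. The best of `restarts` random
#' nonnegative initializations is retained. Columns of `W` are rescaled to
#' unit maximum (the scale moves into `A`, leaving the reconstruction
#' unchanged) and modules are ordered by the gait-cycle position of their
#' activation peak.
#'
#' @param emg0 Nonnegative muscles x time matrix (typically 7 x 101).
#' @param n Number of modules, `1 <= n <= nrow(emg0)`.
#' @param restarts Number of random initializations (default 20).
#' @param tol Relative objective-change convergence tolerance (default 1e-6).
#' @param max_iter Iteration cap per run (default 2000).
#' @param seed Integer seed for the initializations.
#' @param extra_inits Optional list of additional initializations, each a
#'   list with nonnegative `W` and `A`; used e.g. to warm-start from a
#'   lower-dimensional solution.
#' @return A `factorization` object: list with `W`, `A`, `objective` (the
#'   squared error), `n`, `restarts_used`, `seed`, `iterations`.
#' @export
extract_modules <- function(emg0, n, restarts = 20L, tol = 1e-6,
                            max_iter = 2000L, seed = 1L, extra_inits = NULL) {
  V <- as_envelope_values(emg0)
  m <- nrow(V)
  t <- ncol(V)
  n <- as.integer(n)
  if (n < 1L || n > m) stop("`n` must satisfy 1 <= n <= nrow(emg0)")
  if (restarts < 1L && is.null(extra_inits)) {
    stop("need at least one initialization")
  }

  set.seed(seed)
  scale0 <- sqrt(max(mean(V), EPS_NMF) / n)
  inits <- lapply(seq_len(restarts), function(r) {
    list(W = matrix(stats::runif(m * n), m, n) * scale0,
         A = matrix(stats::runif(n * t), n, t) * scale0)
  })
  inits <- c(inits, extra_inits)

  best <- NULL
  for (init in inits) {
    stopifnot(all(init$W >= 0), all(init$A >= 0),
              nrow(init$W) == m, ncol(init$W) == n,
              nrow(init$A) == n, ncol(init$A) == t)
    fit <- nmf_mu(V, pmax(init$W, EPS_NMF), pmax(init$A, EPS_NMF),
                  tol = tol, max_iter = max_iter)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }

  fac <- canonicalize_factors(best$W, best$A)
  rownames(fac$W) <- rownames(V) %||% paste0("m", seq_len(m))
  structure(
    list(W = fac$W, A = fac$A, objective = best$objective, n = n,
         restarts_used = length(inits), seed = as.integer(seed),
         iterations = best$iterations,
         objective_trace = best$objective_trace),
    class = "factorization"
  )
}

#' @export
print.factorization <- function(x, ...) {
  cat(sprintf("NNMF factorization: %d modules, objective %.4g (%d iterations, best of %d starts)\n",
              x$n, x$objective, x$iterations, x$restarts_used))
  invisible(x)
}

#' Variance accounted for by a reconstruction
#'
#' `VAF = 1 - SSE / SSQ` where `SSE` is the sum of squared differences
#' between `emg0` and `recon` and `SSQ` the *uncentered* sum of squares of
#' `emg0`, optionally restricted to a subset of muscles and/or one gait
#' subphase.
#'
#' @param emg0 Nonnegative muscles x time matrix.
#' @param recon Reconstruction of the same shape (e.g. `W %*% A`).
#' @param muscles Optional muscle subset: indices or rownames.
#' @param phase Optional gait-subphase index 1..7 (column mask per
#'   [phase_sample_idx()]); requires a 101-point time axis.
#' @param phases Phase table, see [gait_phases()].
#' @return VAF as a fraction (<= 1; can be negative for reconstructions worse
#'   than zero).
#' @export
compute_vaf <- function(emg0, recon, muscles = NULL, phase = NULL,
                        phases = gait_phases()) {
  V <- as.matrix(emg0)
  R <- as.matrix(recon)
  if (!all(dim(V) == dim(R))) stop("`emg0` and `recon` shapes differ")
  rows <- seq_len(nrow(V))
  if (!is.null(muscles)) {
    rows <- if (is.character(muscles)) match(muscles, rownames(V)) else muscles
    if (anyNA(rows) || length(rows) == 0L) stop("unknown muscle selection")
  }
  cols <- seq_len(ncol(V))
  if (!is.null(phase)) {
    if (ncol(V) != GC_POINTS) {
      stop("phase masking requires the 101-point gait-cycle axis")
    }
    cols <- phase_sample_idx(phase, phases)
  }
  v <- V[rows, cols, drop = FALSE]
  r <- R[rows, cols, drop = FALSE]
  ssq <- sum(v^2)
  if (ssq == 0) stop("masked EMG0 is identically zero; VAF is undefined")
  1 - sum((v - r)^2) / ssq
}

#' Full VAF report for one factorization
#'
#' @param emg0 Nonnegative muscles x 101 matrix.
#' @param fac A `factorization` (or any list with `W` and `A`).
#' @param phases Phase table, see [gait_phases()].
#' @return A `vaf_report`: list with `vaf_overall`, `vaf_per_muscle` (named),
#'   `vaf_per_phase` (named), `phase_bounds` and `n`.
#' @export
vaf_report <- function(emg0, fac, phases = gait_phases()) {
  V <- as.matrix(emg0)
  R <- fac$W %*% fac$A
  per_muscle <- vapply(seq_len(nrow(V)),
                       function(i) compute_vaf(V, R, muscles = i), numeric(1))
  names(per_muscle) <- rownames(V) %||% paste0("m", seq_len(nrow(V)))
  per_phase <- vapply(phases$phase,
                      function(p) compute_vaf(V, R, phase = p, phases = phases),
                      numeric(1))
  names(per_phase) <- phases$name
  structure(
    list(vaf_overall = compute_vaf(V, R), vaf_per_muscle = per_muscle,
         vaf_per_phase = per_phase, phase_bounds = phases,
         n = ncol(fac$W)),
    class = "vaf_report"
  )
}

#' @export
print.vaf_report <- function(x, ...) {
  cat(sprintf("VAF report (%d modules): overall %.3f, min muscle %.3f, min phase %.3f\n",
              x$n, x$vaf_overall, min(x$vaf_per_muscle), min(x$vaf_per_phase)))
  invisible(x)
}

vaf_qualifies <- function(report, phase_threshold, overall_threshold) {
  all(report$vaf_per_phase >= phase_threshold) &&
    all(report$vaf_per_muscle >= phase_threshold) &&
    report$vaf_overall >= overall_threshold
}

#' Select the number of motor modules by the VAF rule
#'
#' Fits each candidate module count and returns the smallest one whose
#' factorization reaches VAF >= `phase_threshold` in every gait subphase and
#' every muscle and VAF >= `overall_threshold` overall. Candidates are fitted
#' in increasing order; each count additionally seeds one initialization from
#' the previous count's solution plus one random module, which makes the
#' best-of-restarts VAF curve non-decreasing in `n`.
#'
#' @param emg0 Nonnegative muscles x 101 matrix.
#' @param candidates Candidate module counts (default 2:5).
#' @param phase_threshold Minimum per-phase and per-muscle VAF (default 0.80).
#' @param overall_threshold Minimum overall VAF (default 0.90).
#' @param restarts,tol,max_iter,seed Passed to [extract_modules()].
#' @param phases Phase table, see [gait_phases()].
#' @return A `module_selection`: list with `n_selected`, `qualifies`
#'   (FALSE when no candidate met the rule and the largest was returned),
#'   `reports` (named list of `vaf_report` per candidate), `factorizations`.
#' @export
select_module_count <- function(emg0, candidates = 2:5,
                                phase_threshold = 0.80,
                                overall_threshold = 0.90,
                                restarts = 20L, tol = 1e-6, max_iter = 2000L,
                                seed = 1L, phases = gait_phases()) {
  V <- as_envelope_values(emg0)
  if (length(candidates) == 0L) stop("`candidates` must be nonempty")
  candidates <- sort(unique(as.integer(candidates)))
  if (any(candidates < 1L) || any(candidates > nrow(V))) {
    stop("candidates must lie in 1..nrow(emg0)")
  }

  reports <- list()
  facs <- list()
  prev <- NULL
  for (i in seq_along(candidates)) {
    n <- candidates[i]
    extra <- NULL
    if (!is.null(prev) && prev$n < n) {
      set.seed(seed + 1000L + n)
      growW <- matrix(stats::runif(nrow(V) * (n - prev$n)), nrow(V))
      growA <- matrix(stats::runif((n - prev$n) * ncol(V)) *
                        max(mean(V), EPS_NMF), ncol = ncol(V))
      extra <- list(list(W = cbind(prev$W, growW), A = rbind(prev$A, growA)))
    }
    fac <- extract_modules(V, n, restarts = restarts, tol = tol,
                           max_iter = max_iter, seed = seed,
                           extra_inits = extra)
    key <- as.character(n)
    facs[[key]] <- fac
    reports[[key]] <- vaf_report(V, fac, phases)
    prev <- fac
  }

  qualify <- vapply(reports, vaf_qualifies, logical(1),
                    phase_threshold = phase_threshold,
                    overall_threshold = overall_threshold)
  if (any(qualify)) {
    n_selected <- candidates[which(qualify)[1L]]
    qualifies <- TRUE
  } else {
    n_selected <- max(candidates)
    qualifies <- FALSE
  }
  structure(
    list(n_selected = n_selected, qualifies = qualifies, reports = reports,
         factorizations = facs, candidates = candidates,
         phase_threshold = phase_threshold,
         overall_threshold = overall_threshold),
    class = "module_selection"
  )
}

#' @export
print.module_selection <- function(x, ...) {
  cat(sprintf("Selected %d modules (%s)\n", x$n_selected,
              if (x$qualifies) "meets the VAF rule" else "no candidate met the VAF rule"))
  for (key in names(x$reports)) print(x$reports[[key]])
  invisible(x)
}

#' Re-fit activation signals under a fixed module basis
#'
#' Solves for the nonnegative activation signals `A` that minimize the
#' squared reconstruction error with the module matrix `W` frozen — used to
#' compare activation timing across conditions under a shared modular basis
#' (e.g. the modules from treadmill walking at 2.5 km/h). Each time sample is
#' an independent nonnegative least-squares problem, solved exactly by
#' Lawson-Hanson NNLS (`pracma::lsqnonneg`).
#'
#' @param emg0 Nonnegative muscles x time matrix.
#' @param W_fixed Nonnegative muscles x n module matrix with no zero column.
#' @return Nonnegative n x time activation matrix with attribute
#'   `"objective"` (total squared error).
#' @export
fixed_module_activations <- function(emg0, W_fixed) {
  V <- as_envelope_values(emg0)
  W <- as.matrix(W_fixed)
  if (any(W < 0)) stop("`W_fixed` must be nonnegative")
  if (nrow(W) != nrow(V)) stop("`W_fixed` must have one row per muscle")
  if (any(apply(W, 2, max) == 0)) {
    stop("`W_fixed` has a zero column; its activation is unidentifiable")
  }
  n <- ncol(W)
  A <- matrix(0, n, ncol(V))
  for (j in seq_len(ncol(V))) {
    A[, j] <- pracma::lsqnonneg(W, V[, j])$x
  }
  dimnames(A) <- list(colnames(W) %||% paste0("module_", seq_len(n)),
                      colnames(V))
  attr(A, "objective") <- sum((V - W %*% A)^2)
  A
}

#' Match modules between two factorizations
#'
#' Finds the bijective assignment of `other`'s modules to `reference`'s
#' modules that maximizes the total Pearson correlation between matched
#' module weight vectors (exhaustive over all permutations).
#'
#' @param reference,other `factorization` objects (or lists with `W`) with
#'   the same number of muscles and modules.
#' @return A `module_match`: list with `permutation` (`permutation[k]` is the
#'   column of `other$W` matched to reference module `k`), `similarities`
#'   (Pearson r per matched pair) and `total`.
#' @export
match_modules <- function(reference, other) {
  Wr <- as.matrix(if (is.list(reference)) reference$W else reference)
  Wo <- as.matrix(if (is.list(other)) other$W else other)
  if (nrow(Wr) != nrow(Wo)) stop("factorizations differ in muscle count")
  if (ncol(Wr) != ncol(Wo)) stop("factorizations differ in module count")
  n <- ncol(Wr)
  rmat <- suppressWarnings(stats::cor(Wr, Wo))
  rmat[!is.finite(rmat)] <- 0
  perms <- pracma::perms(seq_len(n))
  totals <- apply(perms, 1, function(p) sum(rmat[cbind(seq_len(n), p)]))
  best <- perms[which.max(totals), ]
  structure(
    list(permutation = as.integer(best),
         similarities = rmat[cbind(seq_len(n), best)],
         total = max(totals)),
    class = "module_match"
  )
}
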