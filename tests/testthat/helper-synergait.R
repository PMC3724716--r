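# Shared fixtures and independent oracles for the test suite.

# Independent brute-force nonnegative least squares: enumerate every support
# set, solve the unconstrained least-squares problem on it, keep feasible
# (nonnegative) candidates and return the best.  The global NNLS optimum is
# feasible on its own support, so it is always among the candidates.
nnls_exhaustive <- function(W, v) {
  n <- ncol(W)
  best <- list(objective = sum(v^2), x = rep(0, n)) # empty support
  for (mask in seq_len(2^n - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    Ws <- W[, S, drop = FALSE]
    coef <- tryCatch(qr.coef(qr(Ws), v), error = function(e) NULL)
    if (is.null(coef) || anyNA(coef) || any(coef < 0)) next
    x <- rep(0, n)
    x[S] <- coef
    obj <- sum((v - W %*% x)^2)
    if (obj < best$objective) best <- list(objective = obj, x = x)
  }
  best
}

# A small strictly positive envelope-like matrix of known rank.
make_exact_lowrank <- function(m = 7, n = 4, t = 101, seed = 11) {
  set.seed(seed)
  W <- matrix(runif(m * n, 0.05, 1), m, n)
  A <- matrix(runif(n * t, 0.05, 1), n, t)
  list(W = W, A = A, V = W %*% A)
}

# Numerical matrix rank via singular values.
num_rank <- function(M, tol = 1e-8) {
  s <- svd(M, nu = 0, nv = 0)$d
  sum(s > tol * max(s))
}

# Phase widths in %GC of the seven gait subphases.
phase_widths <- function() {
  ph <- synergait::gait_phases()
  ph$hi - ph$lo
}
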