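#' Walking-condition specification
#'
#' A condition is one cell of the study grid: treadmill walking at a given
#' speed, or robotic-guided walking at a given speed and guidance-force (GF)
#' level. Guidance force is the percentage of assistance torque provided by
#' the exoskeleton and is only defined for robotic walking.
#'
#' @param mode `"treadmill"` or `"robotic"`.
#' @param speed Walking speed in km/h (> 0; the study used 1.5, 2.0, 2.5).
#' @param guidance_force Guidance force in percent (robotic mode only; the
#'   study used 20, 40, 70, 100).
#' @param subject_id Label for the subject (default `"S1"`).
#' @return A `condition_spec` object (list with the four fields above).
#' @examples
#' condition_spec("robotic", 1.5, guidance_force = 20)
#' condition_spec("treadmill", 2.5)
#' @export
condition_spec <- function(mode = c("treadmill", "robotic"), speed,
                           guidance_force = NULL, subject_id = "S1") {
  mode <- match.arg(mode)
  stopifnot(is.numeric(speed), length(speed) == 1L)
  if (speed <= 0) stop("`speed` must be > 0 km/h")
  if (mode == "robotic") {
    if (is.null(guidance_force)) {
      stop("robotic mode requires `guidance_force` (% assistance)")
    }
    stopifnot(is.numeric(guidance_force), length(guidance_force) == 1L)
    if (guidance_force <= 0 || guidance_force > 100) {
      stop("`guidance_force` must be in (0, 100]")
    }
  } else if (!is.null(guidance_force)) {
    stop("`guidance_force` is only defined for robotic mode")
  }
  structure(
    list(mode = mode, speed = speed, guidance_force = guidance_force,
         subject_id = subject_id),
    class = "condition_spec"
  )
}

#' @export
format.condition_spec <- function(x, ...) {
  gf <- if (is.null(x$guidance_force)) "" else sprintf(" %g%%GF", x$guidance_force)
  sprintf("%s %.1fkm/h%s [%s]", x$mode, x$speed, gf, x$subject_id)
}

#' @export
print.condition_spec <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' A short file-system-safe label for a condition
#' @param condition A [condition_spec()].
#' @return Character scalar, e.g. `"robotic_gf020_sp1.5"`.
#' @export
condition_label <- function(condition) {
  stopifnot(inherits(condition, "condition_spec"))
  if (condition$mode == "treadmill") {
    sprintf("treadmill_sp%.1f", condition$speed)
  } else {
    sprintf("robotic_gf%03d_sp%.1f", as.integer(condition$guidance_force),
            condition$speed)
  }
}

#' The full study condition grid
#'
#' All combinations of the study's walking conditions: treadmill walking plus
#' robotic-guided walking at each guidance-force level, crossed with each
#' speed (default 3 speeds x (treadmill + 4 GF levels) = 15 conditions).
#'
#' @param speeds Speeds in km/h.
#' @param guidance_forces GF levels in percent for the robotic conditions.
#' @param subject_id Subject label applied to every condition.
#' @return Named list of [condition_spec()] objects.
#' @export
condition_grid <- function(speeds = c(1.5, 2.0, 2.5),
                           guidance_forces = c(20, 40, 70, 100),
                           subject_id = "S1") {
  out <- list()
  for (sp in speeds) {
    out[[length(out) + 1L]] <- condition_spec("treadmill", sp,
                                              subject_id = subject_id)
    for (gf in guidance_forces) {
      out[[length(out) + 1L]] <- condition_spec("robotic", sp,
                                                guidance_force = gf,
                                                subject_id = subject_id)
    }
  }
  names(out) <- vapply(out, condition_label, character(1))
  out
}

# Burst placements (center %GC, width %GC, relative amplitude) per module
# count.  The 4-module set follows the canonical functional roles: module 1
# knee/hip extensors in midstance, module 2 hamstrings in terminal swing with
# a secondary midstance burst, module 3 plantarflexors in late stance,
# module 4 tibialis anterior in midstance and through swing.
module_burst_table <- function(n_modules) {
  b <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    colnames(m) <- c("center", "width", "amp")
    m
  }
  switch(as.character(n_modules),
    "2" = list(
      b(20, 10, 1),
      b(70, 12, 1, 93, 6, 0.7)
    ),
    "3" = list(
      b(15, 8, 1),
      b(45, 7, 1),
      b(75, 12, 1, 93, 6, 0.7)
    ),
    "4" = list(
      b(15, 8, 1, 25, 9, 0.5),
      b(93, 6, 1, 18, 9, 0.6),
      b(45, 7, 1),
      b(12, 8, 0.7, 67, 12, 1)
    ),
    "5" = list(
      b(15, 8, 1, 25, 9, 0.5),
      b(93, 6, 1, 18, 9, 0.6),
      b(45, 7, 1),
      b(12, 8, 0.7, 67, 12, 1),
      b(55, 6, 1)
    ),
    stop("`n_modules` must be between 2 and 5")
  )
}

# Dominant-muscle assignment per module (indices into gait_muscles()).
module_muscle_groups <- function(n_modules) {
  switch(as.character(n_modules),
    "2" = list(c(1, 2, 5, 6), c(3, 4, 7)),
    "3" = list(c(1, 2), c(5, 6), c(3, 4, 7)),
    "4" = list(c(1, 2), c(3, 4), c(5, 6), 7),
    "5" = list(c(1, 2), c(3, 4), c(5, 6), 7, c(1, 5)),
    stop("`n_modules` must be between 2 and 5")
  )
}

# Gaussian burst on the periodic 0-100% gait-cycle axis (period 100).
circular_gaussian <- function(pct, center, width) {
  d <- abs(pct - center)
  d <- pmin(d, 100 - d)
  exp(-0.5 * (d / width)^2)
}

#' Generate a modular ground truth for synthetic gait EMG
#'
#' Builds a known pair of factors: a nonnegative muscle-weighting matrix
#' `W_true` (7 muscles x `n_modules`, unit-max columns) and nonnegative
#' activation signals `A_true` (`n_modules` x 101 on the percent-gait-cycle
#' axis). Activation signals are Gaussian bursts (with circular wrap-around,
#' since the gait cycle is periodic) centred at phase-appropriate times; for
#' the default 4 modules: module 1 midstance (RF, VL), module 2 terminal
#' swing plus midstance (ST, BF), module 3 late stance (GM, GL), module 4
#' midstance and swing (TA). Dominant muscles get weights near 1, the
#' remaining muscles small seeded cross-talk weights.
#'
#' @param n_modules Number of modules, 2..5 (default 4).
#' @param seed Integer seed; generation is deterministic given the seed.
#' @param noise_sd Default additive-noise level stored with the ground truth,
#'   as a fraction of the peak envelope (default 0.05).
#' @return A `ground_truth_set`: list with `W_true`, `A_true`, `noise_sd`,
#'   `seed`, `n_modules`, `muscles`.
#' @examples
#' gt <- make_ground_truth(4, seed = 1)
#' dim(gt$W_true) # 7 x 4
#' @export
make_ground_truth <- function(n_modules = 4L, seed = 1L, noise_sd = 0.05) {
  stopifnot(length(n_modules) == 1L, n_modules == round(n_modules))
  if (n_modules < 2 || n_modules > 5) {
    stop("`n_modules` must be between 2 and 5")
  }
  n_modules <- as.integer(n_modules)
  muscles <- gait_muscles()
  m <- length(muscles)
  pct <- gc_axis()

  bursts <- module_burst_table(n_modules)
  A <- t(vapply(bursts, function(tab) {
    rowSums(vapply(seq_len(nrow(tab)), function(i) {
      tab[i, "amp"] * circular_gaussian(pct, tab[i, "center"], tab[i, "width"])
    }, numeric(length(pct))))
  }, numeric(length(pct))))
  rownames(A) <- paste0("module_", seq_len(n_modules))
  colnames(A) <- pct

  groups <- module_muscle_groups(n_modules)
  rng <- local({
    set.seed(seed)
    list(dom = matrix(stats::runif(m * n_modules, 0.85, 1.0), m, n_modules),
         cross = matrix(stats::runif(m * n_modules, 0.02, 0.20), m, n_modules))
  })
  W <- rng$cross
  for (k in seq_len(n_modules)) W[groups[[k]], k] <- rng$dom[groups[[k]], k]
  # unit-max columns: overall scale lives in the activation signals
  W <- sweep(W, 2, apply(W, 2, max), "/")
  dimnames(W) <- list(muscles, rownames(A))

  structure(
    list(W_true = W, A_true = A, noise_sd = noise_sd, seed = as.integer(seed),
         n_modules = n_modules, muscles = muscles),
    class = "ground_truth_set"
  )
}

# Per-muscle gain profile for a walking condition.  Speed scales all
# amplitudes linearly (reference 2.0 km/h = gain 1).  Robotic guidance
# increases quadriceps demand -- more so at low guidance force, where the
# subject must contribute actively -- and slightly reduces plantarflexor and
# tibialis activity (the foot lifters assist dorsiflexion).
condition_gains <- function(condition) {
  stopifnot(inherits(condition, "condition_spec"))
  g <- rep(1, length(gait_muscles()))
  names(g) <- gait_muscles()
  if (condition$mode == "robotic") {
    gf <- condition$guidance_force
    g[c("RF", "VL")] <- 1.15 + 0.35 * (1 - gf / 100)
    g[c("GM", "GL", "TA")] <- 0.85
  }
  list(muscle = g, speed = condition$speed / 2.0)
}

#' Synthesize a noisy EMG envelope matrix from a ground truth
#'
#' Forms the noiseless envelope `W_true %*% A_true`, applies condition
#' scaling (speed multiplies all amplitudes; robotic guidance redistributes
#' quadriceps versus plantarflexor gain), adds Gaussian noise with standard
#' deviation `noise_sd` times the peak of the scaled envelope, and clips at
#' zero. Treadmill walking at 2.0 km/h is the neutral reference condition
#' (all gains 1).
#'
#' @param gt A `ground_truth_set` from [make_ground_truth()].
#' @param condition A [condition_spec()].
#' @param noise_sd Noise level as a fraction of the peak envelope (>= 0);
#'   defaults to the level stored in `gt`.
#' @param seed Optional integer seed for the noise draw.
#' @return A 7 x 101 nonnegative matrix with muscle rownames and the
#'   condition attached as attribute `"condition"`.
#' @export
synthesize_envelopes <- function(gt, condition, noise_sd = gt$noise_sd,
                                 seed = NULL) {
  stopifnot(inherits(gt, "ground_truth_set"),
            inherits(condition, "condition_spec"))
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (length(gt$muscles) != nrow(gt$W_true)) {
    stop("ground truth muscle list does not match W_true rows")
  }
  gains <- condition_gains(condition)
  env <- gt$W_true %*% gt$A_true
  env <- gains$speed * (gains$muscle * env) # row-wise muscle gains
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    sd_abs <- noise_sd * max(env)
    env <- env + matrix(stats::rnorm(length(env), 0, sd_abs),
                        nrow(env), ncol(env))
    env <- pmax(env, 0)
  }
  dimnames(env) <- list(gt$muscles, gc_axis())
  attr(env, "condition") <- condition
  env
}

#' Synthesize a raw multi-channel EMG trial with heel-strike events
#'
#' Emulates a 1 kHz surface-EMG recording of repeated strides: the
#' condition's noiseless envelope, resampled to the stride duration and
#' multiplied by per-stride multiplicative jitter, amplitude-modulates a
#' zero-mean broadband carrier band-limited to 20-400 Hz. Stride duration is
#' 2.4 s at 1.5 km/h and scales inversely with speed. Heel strikes are placed
#' at stride boundaries.
#'
#' @param gt A `ground_truth_set`.
#' @param condition A [condition_spec()].
#' @param n_strides Number of strides (>= 12 so ten central cycles exist).
#' @param fs Sampling rate in Hz (>= 1000).
#' @param seed Integer seed; the trial is deterministic given the seed.
#' @param stride_jitter_sd Standard deviation of the per-stride, per-muscle
#'   multiplicative amplitude jitter (default 0.05).
#' @return A `raw_trial`: list with `emg` (muscles x samples), `fs`,
#'   `heel_strikes` (1-based sample indices, strictly increasing),
#'   `channel_names` and `condition`.
#' @export
synthesize_raw_trial <- function(gt, condition, n_strides = 12L, fs = 1000,
                                 seed = 1L, stride_jitter_sd = 0.05) {
  stopifnot(inherits(gt, "ground_truth_set"),
            inherits(condition, "condition_spec"))
  if (n_strides < 12) {
    stop("`n_strides` must be >= 12 so that ten central gait cycles exist")
  }
  if (fs < 1000) stop("`fs` must be >= 1000 Hz")
  n_strides <- as.integer(n_strides)

  env <- synthesize_envelopes(gt, condition, noise_sd = 0)
  m <- nrow(env)
  stride_s <- 2.4 * 1.5 / condition$speed
  spp <- as.integer(round(stride_s * fs)) # samples per stride
  n <- n_strides * spp + 1L
  heel_strikes <- 1L + (0:n_strides) * spp

  set.seed(seed)
  jitter <- matrix(pmax(stats::rnorm(m * n_strides, 1, stride_jitter_sd), 0),
                   m, n_strides)

  # per-sample envelope track: stride-resampled envelope x stride jitter
  track <- matrix(0, m, n)
  pct <- gc_axis()
  for (s in seq_len(n_strides)) {
    idx <- heel_strikes[s]:(heel_strikes[s + 1L] - 1L)
    frac <- (idx - heel_strikes[s]) / spp * 100
    for (i in seq_len(m)) {
      track[i, idx] <- jitter[i, s] *
        stats::approx(pct, env[i, ], xout = frac)$y
    }
  }
  track[, n] <- env[, 1L] # close the final cycle at 0% GC

  if (max(env) == 0) {
    emg <- matrix(0, m, n)
  } else {
    carrier <- matrix(stats::rnorm(m * n), m, n)
    bf <- signal::butter(3, c(20, 400) / (fs / 2), type = "pass")
    for (i in seq_len(m)) {
      ci <- signal::filtfilt(bf, carrier[i, ])
      carrier[i, ] <- ci / stats::sd(ci)
    }
    emg <- track * carrier
  }
  dimnames(emg) <- list(gt$muscles, NULL)

  structure(
    list(emg = emg, fs = fs, heel_strikes = heel_strikes,
         channel_names = gt$muscles, condition = condition),
    class = "raw_trial"
  )
}

# Smooth periodic shape on the 101-point axis whose grid minimum sits at
# t_min and maximum at t_max (percent gait cycle), built from two circular
# Gaussian bumps and mapped affinely so the requested extrema are attained
# exactly.
cycle_shape <- function(t_min, t_max, width = 10) {
  pct <- gc_axis()
  # keep the bumps narrow enough that their overlap cannot shift the grid
  # extrema off the requested samples
  d <- abs(t_max - t_min)
  d <- min(d, 100 - d)
  width <- min(width, d / 3)
  s <- circular_gaussian(pct, t_max, width) -
    circular_gaussian(pct, t_min, width)
  (s - min(s)) / (max(s) - min(s))
}

#' Synthesize one smooth gait-cycle trace with exact extrema
#'
#' @param min,max Requested minimum and maximum values (`min < max`).
#' @param t_min,t_max Percent of gait cycle (integers 0..100) where the
#'   minimum / maximum are attained.
#' @param width Width (%GC) of the underlying Gaussian bumps.
#' @return Numeric vector of length 101 whose minimum is exactly `min` (at
#'   `t_min`) and maximum exactly `max` (at `t_max`).
#' @export
synthesize_cycle_trace <- function(min, max, t_min = 40L, t_max = 80L,
                                   width = 10) {
  if (min >= max) stop("`min` must be < `max`")
  t_min <- as.integer(round(t_min)); t_max <- as.integer(round(t_max))
  stopifnot(t_min %in% gc_axis(), t_max %in% gc_axis(), t_min != t_max)
  s <- cycle_shape(t_min, t_max, width)
  tr <- min + (max - min) * s
  # pin the extrema exactly (the affine map can lose the last ulp)
  tr[t_min + 1L] <- min
  tr[t_max + 1L] <- max
  stopifnot(which.min(tr) == t_min + 1L, which.max(tr) == t_max + 1L)
  tr
}

#' Synthesize joint angle and force traces for one condition
#'
#' Builds smooth 101-point hip/knee angle and machine-interaction force
#' cycles achieving requested extrema exactly at requested gait-cycle
#' locations — fixtures for the kinematic/kinetic summary functions.
#'
#' @param condition A [condition_spec()].
#' @param extrema A data.frame with columns `joint` (`"hip"`/`"knee"`),
#'   `signal` (`"angle"`/`"force"`), `min`, `max`, `t_min`, `t_max`. Defaults
#'   to a physiological robotic-walking set.
#' @param seed Unused placeholder for future stochastic variants; traces are
#'   deterministic.
#' @return A data.frame in the pipeline's kinematics layout:
#'   `pct_gait_cycle`, `hip_angle_deg`, `knee_angle_deg`, `hip_force`,
#'   `knee_force`.
#' @export
synthesize_joint_traces <- function(condition, extrema = NULL, seed = NULL) {
  stopifnot(inherits(condition, "condition_spec"))
  if (is.null(extrema)) {
    extrema <- data.frame(
      joint = c("hip", "knee", "hip", "knee"),
      signal = c("angle", "angle", "force", "force"),
      min = c(-16.47, 12.40, -349, -232),
      max = c(23.49, 51.02, 244, 135),
      t_min = c(41, 0, 80, 65),
      t_max = c(80, 70, 55, 97)
    )
  }
  stopifnot(all(c("joint", "signal", "min", "max", "t_min", "t_max") %in%
                  names(extrema)))
  if (any(extrema$min >= extrema$max)) {
    stop("every requested `min` must be < its `max`")
  }
  get_trace <- function(joint, sig) {
    row <- extrema[extrema$joint == joint & extrema$signal == sig, , drop = FALSE]
    if (nrow(row) != 1L) {
      stop(sprintf("extrema must contain exactly one row for %s %s", joint, sig))
    }
    synthesize_cycle_trace(row$min, row$max, row$t_min, row$t_max)
  }
  out <- data.frame(
    pct_gait_cycle = gc_axis(),
    hip_angle_deg = get_trace("hip", "angle"),
    knee_angle_deg = get_trace("knee", "angle"),
    hip_force = get_trace("hip", "force"),
    knee_force = get_trace("knee", "force")
  )
  attr(out, "condition") <- condition
  out
}
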