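# Kinematic and kinetic cycle summaries: range of motion (ROM) of joint
# angles and range of forces (ROF) of the machine-interaction forces, overall
# and per gait subphase.

#' Range of motion of a joint-angle cycle
#'
#' Minimum, maximum and their difference (ROM = max - min) over one
#' time-normalized gait cycle, plus the percent of gait cycle at which each
#' extremum is first attained.
#'
#' @param angle Numeric vector of length 101 (degrees, 0..100% GC); finite
#'   values required, negative values allowed.
#' @return A `joint_summary`: list with `min`, `max`, `range`, `t_min`,
#'   `t_max` (%GC of first attainment).
#' @export
range_of_motion <- function(angle) {
  x <- check_cycle_series(angle, nonneg = FALSE)
  i_min <- which.min(x)
  i_max <- which.max(x)
  structure(
    list(min = x[i_min], max = x[i_max], range = x[i_max] - x[i_min],
         t_min = gc_axis()[i_min], t_max = gc_axis()[i_max]),
    class = "joint_summary"
  )
}

#' Range of forces of a joint-force cycle, overall and per gait subphase
#'
#' Per-phase minima and maxima of the machine-interaction force over the
#' seven gait subphases (samples assigned lower-inclusive / upper-exclusive,
#' final phase closed), and the overall range of forces
#' `ROF = max(phase maxima) - min(phase minima)`, which equals the global
#' max - min of the cycle since the phases partition it.
#'
#' @param force Numeric vector of length 101 (machine units, 0..100% GC).
#' @param phases Phase table, see [gait_phases()].
#' @return A `joint_summary` with `min`, `max`, `range` (the ROF), `t_min`,
#'   `t_max`, and `per_phase_extrema` (7 x 2 matrix of per-phase min/max).
#' @export
range_of_forces <- function(force, phases = gait_phases()) {
  x <- check_cycle_series(force, nonneg = FALSE)
  per_phase <- t(vapply(phases$phase, function(p) {
    v <- x[phase_sample_idx(p, phases)]
    c(min = min(v), max = max(v))
  }, numeric(2)))
  rownames(per_phase) <- phases$name
  out <- range_of_motion(x)
  out$range <- max(per_phase[, "max"]) - min(per_phase[, "min"])
  out$per_phase_extrema <- per_phase
  out
}

#' Overall range of forces from per-phase extrema
#'
#' Closure used to summarize published per-phase force tables:
#' `ROF = max(maxima) - min(minima)`.
#'
#' @param mins,maxs Numeric vectors of per-phase minima and maxima (same
#'   length, typically 7).
#' @return The overall ROF.
#' @export
rof_from_phase_extrema <- function(mins, maxs) {
  stopifnot(length(mins) == length(maxs), all(is.finite(c(mins, maxs))),
            all(mins <= maxs))
  max(maxs) - min(mins)
}

#' @export
print.joint_summary <- function(x, ...) {
  cat(sprintf("min %.2f @ %g%%GC, max %.2f @ %g%%GC, range %.2f\n",
              x$min, x$t_min, x$max, x$t_max, x$range))
  if (!is.null(x$per_phase_extrema)) {
    print(round(x$per_phase_extrema, 2))
  }
  invisible(x)
}

#' Summarize a kinematics/force table for one condition
#'
#' Applies [range_of_motion()] to the angle columns and [range_of_forces()]
#' to the force columns of a kinematics data.frame in the pipeline layout.
#'
#' @param kinematics Data.frame with columns `pct_gait_cycle`,
#'   `hip_angle_deg`, `knee_angle_deg`, `hip_force`, `knee_force`.
#' @param phases Phase table, see [gait_phases()].
#' @return Named list of `joint_summary` objects: `hip_angle`, `knee_angle`,
#'   `hip_force`, `knee_force`.
#' @export
summarize_joints <- function(kinematics, phases = gait_phases()) {
  need <- c("pct_gait_cycle", "hip_angle_deg", "knee_angle_deg",
            "hip_force", "knee_force")
  if (!all(need %in% names(kinematics))) {
    stop("kinematics table must have columns: ", paste(need, collapse = ", "))
  }
  list(
    hip_angle = range_of_motion(kinematics$hip_angle_deg),
    knee_angle = range_of_motion(kinematics$knee_angle_deg),
    hip_force = range_of_forces(kinematics$hip_force, phases),
    knee_force = range_of_forces(kinematics$knee_force, phases)
  )
}
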