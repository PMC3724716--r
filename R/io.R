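# CSV readers and writers for all pipeline artifacts.  Every file written by
# the pipeline carries '#'-prefixed provenance comment lines (package
# version, seed, config hash); readers skip them.

write_csv_provenance <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# synergait %s",
                     as.character(utils::packageVersion("synergait"))), con)
  if (!is.null(provenance)) {
    for (key in names(provenance)) {
      writeLines(sprintf("# %s=%s", key, provenance[[key]]), con)
    }
  }
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_csv_skip_comments <- function(path) {
  utils::read.csv(path, comment.char = "#", check.names = FALSE)
}

#' Read a raw EMG recording from CSV
#'
#' Expected layout: first column `time_s`, then one column per muscle
#' (`RF,VL,ST,BF,GM,GL,TA` for the standard montage). The sampling rate is
#' inferred from the time column.
#'
#' @param path CSV file path.
#' @return A [raw_emg()] object.
#' @export
read_emg_csv <- function(path) {
  df <- read_csv_skip_comments(path)
  if (names(df)[1L] != "time_s") stop("first column must be `time_s`")
  dt <- diff(df$time_s)
  if (any(dt <= 0)) stop("`time_s` must be strictly increasing")
  fs <- 1 / stats::median(dt)
  samples <- t(as.matrix(df[, -1L, drop = FALSE]))
  raw_emg(samples, fs, colnames(df)[-1L])
}

#' Write a raw EMG trial (and its heel-strike events) to CSV
#'
#' @param trial A `raw_trial` (see [synthesize_raw_trial()]).
#' @param emg_path Output path for the EMG CSV (`time_s` + muscle columns).
#' @param events_path Optional output path for the events CSV (single column
#'   `heel_strike_s`).
#' @param provenance Optional named list written as comment-header fields.
#' @return `emg_path`, invisibly.
#' @export
write_emg_csv <- function(trial, emg_path, events_path = NULL,
                          provenance = NULL) {
  stopifnot(inherits(trial, "raw_trial"))
  df <- data.frame(time_s = (seq_len(ncol(trial$emg)) - 1) / trial$fs)
  for (i in seq_along(trial$channel_names)) {
    df[[trial$channel_names[i]]] <- trial$emg[i, ]
  }
  write_csv_provenance(df, emg_path, provenance)
  if (!is.null(events_path)) {
    ev <- data.frame(heel_strike_s = (trial$heel_strikes - 1) / trial$fs)
    write_csv_provenance(ev, events_path, provenance)
  }
  invisible(emg_path)
}

#' Read heel-strike events from CSV
#'
#' @param path CSV with a single column `heel_strike_s` (seconds).
#' @param fs Sampling rate used to convert to 1-based sample indices.
#' @return Integer vector of heel-strike sample indices.
#' @export
read_events_csv <- function(path, fs) {
  df <- read_csv_skip_comments(path)
  if (!"heel_strike_s" %in% names(df)) {
    stop("events CSV must have a `heel_strike_s` column")
  }
  as.integer(round(df$heel_strike_s * fs)) + 1L
}

#' Write / read a normalized envelope matrix (EMG0)
#'
#' Layout: `pct_gait_cycle` (0..100) plus one column per muscle.
#'
#' @param emg0 Muscles x 101 matrix with muscle rownames.
#' @param path CSV file path.
#' @param provenance Optional named list of comment-header fields.
#' @return `path` (writer) or the matrix (reader).
#' @export
write_emg0_csv <- function(emg0, path, provenance = NULL) {
  df <- data.frame(pct_gait_cycle = gc_axis())
  for (i in seq_len(nrow(emg0))) df[[rownames(emg0)[i]]] <- emg0[i, ]
  write_csv_provenance(df, path, provenance)
}

#' @rdname write_emg0_csv
#' @export
read_emg0_csv <- function(path) {
  df <- read_csv_skip_comments(path)
  if (names(df)[1L] != "pct_gait_cycle") {
    stop("first column must be `pct_gait_cycle`")
  }
  m <- t(as.matrix(df[, -1L, drop = FALSE]))
  colnames(m) <- df$pct_gait_cycle
  m
}

#' Write a factorization (modules, activations, VAF report) to CSV
#'
#' Writes `W` as rows = muscles / columns = modules, `A` as
#' `pct_gait_cycle` + module columns, and a tidy VAF table.
#'
#' @param fac A `factorization`.
#' @param report Optional `vaf_report` for the same factorization.
#' @param dir Output directory.
#' @param prefix File-name prefix (e.g. the condition label).
#' @param provenance Optional named list of comment-header fields.
#' @return Character vector of the files written, invisibly.
#' @export
write_factorization_csv <- function(fac, report = NULL, dir, prefix,
                                    provenance = NULL) {
  wdf <- data.frame(muscle = rownames(fac$W), as.data.frame(fac$W))
  adf <- data.frame(pct_gait_cycle = gc_axis(), as.data.frame(t(fac$A)))
  paths <- c(
    file.path(dir, paste0(prefix, "_modules.csv")),
    file.path(dir, paste0(prefix, "_activations.csv"))
  )
  write_csv_provenance(wdf, paths[1L], provenance)
  write_csv_provenance(adf, paths[2L], provenance)
  if (!is.null(report)) {
    vdf <- rbind(
      data.frame(scope = "overall", name = "all", vaf = report$vaf_overall),
      data.frame(scope = "muscle", name = names(report$vaf_per_muscle),
                 vaf = unname(report$vaf_per_muscle)),
      data.frame(scope = "phase", name = names(report$vaf_per_phase),
                 vaf = unname(report$vaf_per_phase))
    )
    p <- file.path(dir, paste0(prefix, "_vaf.csv"))
    write_csv_provenance(vdf, p, provenance)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a kinematics table from CSV
#'
#' @param path CSV with columns `pct_gait_cycle`, `hip_angle_deg`,
#'   `knee_angle_deg`, `hip_force`, `knee_force`.
#' @return The data.frame.
#' @export
read_kinematics_csv <- function(path) {
  df <- read_csv_skip_comments(path)
  need <- c("pct_gait_cycle", "hip_angle_deg", "knee_angle_deg",
            "hip_force", "knee_force")
  if (!all(need %in% names(df))) {
    stop("kinematics CSV must have columns: ", paste(need, collapse = ", "))
  }
  df
}
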