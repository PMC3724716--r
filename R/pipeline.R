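# End-to-end orchestration: simulate -> preprocess -> factorize -> timing /
# biomech -> write artifacts, as one configured, seeded, reproducible run.

#' Build a validated pipeline run configuration
#'
#' Collects every tunable of the pipeline with the study defaults: 20-400 Hz
#' 3rd-order zero-phase band-pass, 50-sample RMS window, ten-central stride
#' selection, NNMF with 20 restarts, VAF thresholds 0.80 (per phase / per
#' muscle) and 0.90 (overall), the seven-subphase bounds, triple-SD on/off
#' rule, and the 15-condition grid (3 speeds x (treadmill + 4 GF levels)).
#'
#' Exactly one of `n` (fixed module count) or `select` (candidate counts for
#' the VAF selection rule) must be given.
#'
#' @param out_dir Output directory for CSV artifacts; `NULL` writes nothing.
#' @param seed Master seed; every stochastic stage derives its seed from it.
#' @param source `"raw"` simulates raw trials and runs the full preprocessing
#'   chain; `"envelopes"` simulates envelope matrices directly.
#' @param gt_modules Ground-truth module count for simulation (2..5).
#' @param noise_sd Envelope noise level (fraction of peak; `"envelopes"`
#'   source).
#' @param n_strides,fs Raw-trial simulation parameters.
#' @param speeds,guidance_forces,subject_id Condition grid.
#' @param low,high,order,rms_window Preprocessing parameters.
#' @param n Fixed module count (mutually exclusive with `select`).
#' @param select Candidate module counts for VAF-rule selection.
#' @param restarts,tol,max_iter NNMF parameters.
#' @param phase_threshold,overall_threshold VAF selection thresholds.
#' @param k_sd,min_duration On/off detection parameters.
#' @param fixed_reference Condition label whose modules are frozen for the
#'   fixed-module activation re-fit (default treadmill at 2.5 km/h), or
#'   `NULL` to skip the re-fit.
#' @param kinematics Logical: also simulate and summarize joint traces.
#' @return A validated `run_config` (list).
#' @export
run_config <- function(out_dir = NULL, seed = 1L,
                       source = c("raw", "envelopes"),
                       gt_modules = 4L, noise_sd = 0.05,
                       n_strides = 12L, fs = 1000,
                       speeds = c(1.5, 2.0, 2.5),
                       guidance_forces = c(20, 40, 70, 100),
                       subject_id = "S1",
                       low = 20, high = 400, order = 3L, rms_window = 50L,
                       n = NULL, select = NULL,
                       restarts = 20L, tol = 1e-6, max_iter = 2000L,
                       phase_threshold = 0.80, overall_threshold = 0.90,
                       k_sd = 3, min_duration = 5,
                       fixed_reference = "treadmill_sp2.5",
                       kinematics = TRUE) {
  source <- match.arg(source)
  if (!is.null(n) && !is.null(select)) {
    stop("give either `n` (fixed module count) or `select` (candidates), not both")
  }
  if (is.null(n) && is.null(select)) select <- 2:5
  stopifnot(phase_threshold > 0, phase_threshold <= 1,
            overall_threshold > 0, overall_threshold <= 1,
            tol > 0, restarts >= 1, max_iter >= 1, noise_sd >= 0)
  cfg <- list(
    out_dir = out_dir, seed = as.integer(seed), source = source,
    gt_modules = as.integer(gt_modules), noise_sd = noise_sd,
    n_strides = as.integer(n_strides), fs = fs,
    speeds = speeds, guidance_forces = guidance_forces,
    subject_id = subject_id,
    low = low, high = high, order = as.integer(order),
    rms_window = as.integer(rms_window),
    n = if (is.null(n)) NULL else as.integer(n),
    select = if (is.null(select)) NULL else as.integer(select),
    restarts = as.integer(restarts), tol = tol,
    max_iter = as.integer(max_iter),
    phase_threshold = phase_threshold,
    overall_threshold = overall_threshold,
    k_sd = k_sd, min_duration = min_duration,
    fixed_reference = fixed_reference, kinematics = isTRUE(kinematics)
  )
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys are [run_config()] arguments.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  keys <- yaml::read_yaml(path)
  # YAML 1.1 parses a bare `n` key as boolean FALSE; map it back
  names(keys)[names(keys) == "FALSE"] <- "n"
  do.call(run_config, keys)
}

#' Hash of a run configuration (provenance stamp)
#' @param config A `run_config`.
#' @return MD5 hex string of the configuration's YAML serialization.
#' @export
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL # the hash identifies the computation, not its location
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(cfg), tmp)
  unname(tools::md5sum(tmp))
}

# Cross-condition per-muscle amplitude normalization of a list of envelope
# matrices (the "envelopes" source path; the "raw" path normalizes inside
# average_and_scale()).
normalize_envelope_set <- function(mats) {
  maxima <- apply(do.call(cbind, lapply(mats, function(m) apply(m, 1, max))),
                  1, max)
  if (any(maxima <= 0)) {
    stop("a muscle is identically zero across all conditions")
  }
  lapply(mats, function(m) {
    out <- sweep(m, 1, maxima, "/")
    attr(out, "normalization_maxima") <- maxima
    attr(out, "condition") <- attr(m, "condition")
    out
  })
}

#' Run the full analysis pipeline
#'
#' Executes, in order: simulation of the condition grid (raw trials or
#' envelope matrices), preprocessing to normalized EMG0 matrices, NNMF
#' extraction (fixed `n` or VAF-rule selection), fixed-module activation
#' re-fitting against the reference condition, activation-timing statistics
#' (subphase integrals / percentages, on/off intervals), and joint ROM/ROF
#' summaries. All stages are deterministic given `config$seed`. When
#' `config$out_dir` is set, every artifact is written as CSV with a
#' provenance comment header (package version, seed, config hash) plus a
#' stage-by-stage run log.
#'
#' @param config A [run_config()].
#' @return A `run_report`: list with `envelopes`, `factorizations`,
#'   `vaf_reports`, `selection` (when selecting), `fixed_activations`,
#'   `contributions`, `on_off`, `joints`, `conditions`, `ground_truth` and
#'   `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  log_lines <- character(0)
  note <- function(fmt, ...) {
    line <- sprintf("[%7.2fs] %s", proc.time()[["elapsed"]] - t0,
                    sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
    message(line)
  }

  provenance <- list(seed = config$seed, config_hash = config_hash(config))
  conditions <- condition_grid(config$speeds, config$guidance_forces,
                               config$subject_id)
  gt <- make_ground_truth(config$gt_modules, seed = config$seed,
                          noise_sd = config$noise_sd)
  note("simulate: %d conditions, %d ground-truth modules (source=%s)",
       length(conditions), config$gt_modules, config$source)

  # --- simulate + preprocess -> normalized EMG0 per condition -------------
  if (config$source == "raw") {
    strides <- lapply(seq_along(conditions), function(i) {
      trial <- synthesize_raw_trial(gt, conditions[[i]],
                                    n_strides = config$n_strides,
                                    fs = config$fs,
                                    seed = config$seed + i)
      preprocess_trial(trial, low = config$low, high = config$high,
                       order = config$order, window = config$rms_window)
    })
    names(strides) <- names(conditions)
    envelopes <- average_and_scale(strides)
    note("preprocess: filtered, smoothed and segmented %d trials",
         length(strides))
  } else {
    raw_envs <- lapply(seq_along(conditions), function(i) {
      synthesize_envelopes(gt, conditions[[i]], noise_sd = config$noise_sd,
                           seed = config$seed + i)
    })
    names(raw_envs) <- names(conditions)
    envelopes <- normalize_envelope_set(raw_envs)
    note("simulate: generated %d envelope matrices", length(envelopes))
  }

  # --- factorization ------------------------------------------------------
  selection <- NULL
  if (!is.null(config$n)) {
    factorizations <- lapply(envelopes, extract_modules, n = config$n,
                             restarts = config$restarts, tol = config$tol,
                             max_iter = config$max_iter, seed = config$seed)
    vaf_reports <- Map(vaf_report, envelopes, factorizations)
    note("extract: %d-module NNMF per condition", config$n)
  } else {
    selection <- lapply(envelopes, select_module_count,
                        candidates = config$select,
                        phase_threshold = config$phase_threshold,
                        overall_threshold = config$overall_threshold,
                        restarts = config$restarts, tol = config$tol,
                        max_iter = config$max_iter, seed = config$seed)
    factorizations <- lapply(selection, function(s) {
      s$factorizations[[as.character(s$n_selected)]]
    })
    vaf_reports <- lapply(selection, function(s) {
      s$reports[[as.character(s$n_selected)]]
    })
    note("extract: VAF-rule selection over {%s}; selected counts: %s",
         paste(config$select, collapse = ","),
         paste(vapply(selection, `[[`, numeric(1), "n_selected"),
               collapse = ","))
  }

  # --- fixed-module activation re-fit ------------------------------------
  fixed_activations <- NULL
  if (!is.null(config$fixed_reference)) {
    if (!config$fixed_reference %in% names(factorizations)) {
      stop(sprintf("fixed_reference '%s' is not in the condition grid",
                   config$fixed_reference))
    }
    W_ref <- factorizations[[config$fixed_reference]]$W
    fixed_activations <- lapply(envelopes, fixed_module_activations,
                                W_fixed = W_ref)
    note("refit: activations under fixed '%s' modules",
         config$fixed_reference)
  }

  # --- timing -------------------------------------------------------------
  act_source <- fixed_activations %||% lapply(factorizations, `[[`, "A")
  contributions <- lapply(act_source, function(A) {
    apply(A, 1, subphase_integrals, simplify = FALSE)
  })
  on_off <- lapply(act_source, function(A) {
    apply(A, 1, detect_on_off, k = config$k_sd,
          min_duration = config$min_duration, simplify = FALSE)
  })
  note("timing: subphase contributions and on/off patterns")

  # --- biomech ------------------------------------------------------------
  joints <- NULL
  if (config$kinematics) {
    joints <- lapply(conditions, function(cond) {
      summarize_joints(synthesize_joint_traces(cond))
    })
    note("biomech: ROM/ROF summaries for %d conditions", length(joints))
  }

  report <- structure(
    list(envelopes = envelopes, factorizations = factorizations,
         vaf_reports = vaf_reports, selection = selection,
         fixed_activations = fixed_activations,
         contributions = contributions, on_off = on_off, joints = joints,
         conditions = conditions, ground_truth = gt,
         provenance = c(provenance,
                        list(version = as.character(
                          utils::packageVersion("synergait")))),
         config = config),
    class = "run_report"
  )

  if (!is.null(config$out_dir)) {
    write_run_report(report, config$out_dir, log_lines)
    note("write: artifacts under %s", config$out_dir)
  }
  report
}

# Serialize every artifact of a run to CSV under `dir`.
write_run_report <- function(report, dir, log_lines = character(0)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prov <- report$provenance[c("seed", "config_hash")]
  for (cn in names(report$envelopes)) {
    write_emg0_csv(report$envelopes[[cn]],
                   file.path(dir, paste0(cn, "_emg0.csv")), prov)
    write_factorization_csv(report$factorizations[[cn]],
                            report$vaf_reports[[cn]], dir, cn, prov)
  }

  if (!is.null(report$selection)) {
    rows <- do.call(rbind, lapply(names(report$selection), function(cn) {
      s <- report$selection[[cn]]
      do.call(rbind, lapply(names(s$reports), function(k) {
        r <- s$reports[[k]]
        data.frame(condition = cn, n = as.integer(k),
                   vaf_overall = r$vaf_overall,
                   vaf_min_muscle = min(r$vaf_per_muscle),
                   vaf_min_phase = min(r$vaf_per_phase),
                   selected = as.integer(k) == s$n_selected)
      }))
    }))
    write_csv_provenance(rows, file.path(dir, "vaf_vs_n.csv"), prov)
  }

  contrib_rows <- do.call(rbind, lapply(names(report$contributions), function(cn) {
    mods <- report$contributions[[cn]]
    do.call(rbind, lapply(names(mods), function(mk) {
      sc <- mods[[mk]]
      data.frame(condition = cn, module = mk,
                 phase = names(sc$integrals),
                 integral = unname(sc$integrals),
                 percent = unname(sc$percents))
    }))
  }))
  write_csv_provenance(contrib_rows, file.path(dir, "contributions.csv"), prov)

  onoff_rows <- do.call(rbind, lapply(names(report$on_off), function(cn) {
    mods <- report$on_off[[cn]]
    do.call(rbind, lapply(names(mods), function(mk) {
      iv <- mods[[mk]]$intervals
      if (nrow(iv) == 0L) return(NULL)
      data.frame(condition = cn, module = mk,
                 start_pct = iv[, "start"], end_pct = iv[, "end"],
                 threshold = mods[[mk]]$threshold_used)
    }))
  }))
  if (!is.null(onoff_rows)) {
    write_csv_provenance(onoff_rows, file.path(dir, "on_off.csv"), prov)
  }

  if (!is.null(report$joints)) {
    joint_rows <- do.call(rbind, lapply(names(report$joints), function(cn) {
      js <- report$joints[[cn]]
      do.call(rbind, lapply(names(js), function(jk) {
        j <- js[[jk]]
        data.frame(condition = cn, signal = jk, min = j$min, max = j$max,
                   range = j$range, t_min = j$t_min, t_max = j$t_max)
      }))
    }))
    write_csv_provenance(joint_rows, file.path(dir, "joint_summaries.csv"),
                         prov)
  }

  cfg <- unclass(report$config)
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  yaml::write_yaml(cfg, file.path(dir, "run_config.yaml"))
  writeLines(log_lines, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("synergait run: %d conditions, seed %d, config %s\n",
              length(x$conditions), x$provenance$seed,
              substr(x$provenance$config_hash, 1, 8)))
  ns <- vapply(x$factorizations, `[[`, numeric(1), "n")
  cat(sprintf("module counts: %s\n",
              paste(sprintf("%s=%d", names(ns), ns), collapse = " ")))
  invisible(x)
}
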