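#' Configuration for a full simulated study
#'
#' Bundles the stimulus specifications of the exposure groups, cochlear
#' geometry, lesion model, sampling design and cohort design, together
#' with a master seed from which all stage seeds are derived.
#'
#' @param exposures Named list of [stimulus_spec()] per exposed group.
#'   Default: the three exposure paradigms (105 dB 2-20 kHz, 120 dB
#'   2-20 kHz, 105 dB 9-13 kHz), as 10 s sweeps repeated for 30 min.
#' @param params A [cochlea_params()].
#' @param lesion A [lesion_model()].
#' @param design A [sampling_design()].
#' @param cohort A [cohort_design()].
#' @param place_map A [place_frequency_map()].
#' @param wav_seconds Seconds of each stimulus to render to WAV (a short
#'   excerpt; the full 30 min exposure is described by the spec itself).
#' @param seed Master seed.
#' @return A `run_config` object.
#' @export
run_config <- function(exposures = default_exposures(),
                       params = cochlea_params(),
                       lesion = lesion_model(),
                       design = sampling_design(),
                       cohort = cohort_design(),
                       place_map = place_frequency_map(),
                       wav_seconds = 2, seed = 1) {
  stopifnot(all(vapply(exposures, inherits, logical(1), "stimulus_spec")))
  structure(list(exposures = exposures, params = params, lesion = lesion,
                 design = design, cohort = cohort, place_map = place_map,
                 wav_seconds = wav_seconds, seed = as.integer(seed)),
            class = "run_config")
}

#' The study's default exposure stimuli
#'
#' @return Named list of [stimulus_spec()]: `vs105_2_20`, `vs120_2_20`,
#'   `vs105_9_13` (10 s linear sweeps repeated over 30 min at the stated
#'   levels and bands).
#' @export
default_exposures <- function() {
  list(
    vs105_2_20 = stimulus_spec("violet_sweep", 2, 20, 105,
                               sweep_duration = 10, total_duration = 1800),
    vs120_2_20 = stimulus_spec("violet_sweep", 2, 20, 120,
                               sweep_duration = 10, total_duration = 1800),
    vs105_9_13 = stimulus_spec("violet_sweep", 9, 13, 105,
                               sweep_duration = 10, total_duration = 1800))
}

#' Run the full simulation pipeline
#'
#' Stages, each with its own derived seed: (1) synthesize and verify a
#' WAV excerpt of each exposure stimulus; (2) build control hair-cell
#' maps and apply each group's lesion; (3) estimate per-sector densities
#' and CE into cochleograms, with percent loss versus control; (4)
#' simulate the ABR/DPOAE cohort and audiogram summary; (5) correlate
#' day-28 threshold shifts with OHC loss for the narrow-band group.
#' All CSV outputs are byte-identical across reruns with the same config.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (d in c("stimuli", "maps", "cochleograms", "audiology", "correlation"))
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  seeds <- derive_seeds(config$seed, 4 + length(config$exposures))
  names(seeds) <- c("stimulus", "map", "cochleogram", "cohort",
                    paste0("lesion_", names(config$exposures)))
  manifest <- list(package_version = as.character(
    utils::packageVersion("cochleostat")),
    master_seed = config$seed, stage_seeds = as.list(seeds))

  # stage 1: stimuli ---------------------------------------------------
  reports <- list()
  for (nm in names(config$exposures)) {
    spec <- config$exposures[[nm]]
    if (spec$kind == "violet_sweep") {
      # one full sweep period is the natural excerpt for verification
      excerpt <- stimulus_spec(spec$kind, spec$f_low, spec$f_high, spec$level,
                               sweep_duration = spec$sweep_duration,
                               total_duration = spec$sweep_duration,
                               sample_rate = spec$sample_rate)
      w <- synth_violet_sweep(excerpt)
    } else {
      excerpt <- stimulus_spec(spec$kind, spec$f_low, spec$f_high, spec$level,
                               total_duration = min(config$wav_seconds,
                                                    spec$total_duration),
                               sample_rate = spec$sample_rate)
      w <- synth_violet_noise(excerpt, seed = seeds[["stimulus"]])
    }
    write_wav(w, file.path(out_dir, "stimuli", paste0(nm, ".wav")))
    rep <- verify_stimulus(w, excerpt)
    jsonlite::write_json(rep, file.path(out_dir, "stimuli",
                                        paste0(nm, "_verify.json")),
                         auto_unbox = TRUE, digits = 10)
    reports[[nm]] <- rep
  }

  # stage 2: maps -------------------------------------------------------
  control <- build_control_map(config$params, seed = seeds[["map"]])
  write_map_csv(control, file.path(out_dir, "maps", "control.csv"))
  maps <- list(control = control)
  for (nm in names(config$exposures)) {
    maps[[nm]] <- apply_lesion(control, config$exposures[[nm]],
                               config$lesion,
                               seed = seeds[[paste0("lesion_", nm)]],
                               place_map = config$place_map)
    write_map_csv(maps[[nm]], file.path(out_dir, "maps", paste0(nm, ".csv")))
  }

  # stage 3: cochleograms ----------------------------------------------
  cgs <- lapply(maps, estimate_cochleogram, design = config$design,
                params = config$params, place_map = config$place_map,
                seed = seeds[["cochleogram"]])
  losses <- list()
  for (nm in names(cgs)) {
    write_cochleogram_csv(cgs[[nm]],
                          file.path(out_dir, "cochleograms",
                                    paste0(nm, ".csv")))
    if (nm != "control") {
      losses[[nm]] <- percent_loss(cgs[[nm]], cgs$control)
      utils::write.csv(losses[[nm]],
                       file.path(out_dir, "cochleograms",
                                 paste0(nm, "_loss.csv")),
                       row.names = FALSE)
    }
  }

  # stage 4: audiology ---------------------------------------------------
  cohort <- config$cohort
  cohort$seed <- seeds[["cohort"]]
  records <- simulate_cohort(cohort)
  utils::write.csv(records, file.path(out_dir, "audiology", "records.csv"),
                   row.names = FALSE)
  summary <- audiogram_table(records)
  utils::write.csv(summary, file.path(out_dir, "audiology", "audiogram.csv"),
                   row.names = FALSE)

  # stage 5: structure-function correlation -----------------------------
  corr <- NULL
  if ("vs105_9_13" %in% names(losses) &&
      "vs105_9_13" %in% names(cohort$group_sizes)) {
    corr <- structure_function_correlation(records, losses$vs105_9_13,
                                           "vs105_9_13", day = 28,
                                           place_map = config$place_map)
    jsonlite::write_json(list(rho = corr$rho, n = corr$n, pairs = corr$pairs),
                         file.path(out_dir, "correlation",
                                   "vs105_9_13_day28.json"),
                         auto_unbox = TRUE, digits = 10, dataframe = "rows")
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(stimulus_reports = reports, maps = maps,
                 cochleograms = cgs, losses = losses, records = records,
                 audiogram = summary, correlation = corr,
                 manifest = manifest))
}
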