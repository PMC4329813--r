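#' Default calibration table for simulated cohorts
#'
#' True-threshold distributions (mean, sd in dB SPL) per group, test,
#' stimulus and timepoint. Baselines are normal-hearing (mean 15, sd 4 dB
#' for ABR; 40 dB for DPOAE); exposed-group trajectories follow the
#' characteristic patterns of the four exposure paradigms: a ~50 dB click
#' shift at day 2 in every exposed group; progressive worsening and no
#' recovery after 120 dB SPL; partial recovery after 105 dB SPL; and for
#' the 9-13 kHz narrow-band group a persistent audiogram notch at
#' 8-10 kHz with extra test frequencies at 4 and 10 kHz. Treatment arms
#' (saline, P17, P144) share the 105 dB 2-20 kHz distributions -- a null
#' treatment effect.
#'
#' @return data.frame: `group`, `test` (`abr`/`dpoae`), `stimulus`
#'   (`"click"` or frequency in kHz as character), `day` (0, 2, 14, 28),
#'   `mean`, `sd`.
#' @export
default_calibration <- function() {
  rows <- list()
  add <- function(group, test, stimulus, day, mean, sd) {
    rows[[length(rows) + 1L]] <<- data.frame(
      group = group, test = test, stimulus = as.character(stimulus),
      day = day, mean = mean, sd = sd, stringsAsFactors = FALSE)
  }
  days <- c(0, 2, 14, 28)
  tones <- c(8, 16, 20, 28, 40)
  tones913 <- c(4, 8, 10, 16, 20, 28, 40)
  dpF <- c(8, 10, 14, 18, 22)

  for (d in days) {
    add("control", "abr", "click", d, 15, 4)
    for (f in tones) add("control", "abr", f, d, 15, 4)
    for (f in dpF) add("control", "dpoae", f, d, 40, 4)
  }

  exposed <- function(group, click, tone_tab, tone_freqs) {
    add(group, "abr", "click", 0, 15, 4)
    for (f in tone_freqs) add(group, "abr", f, 0, 15, 4)
    for (f in dpF) add(group, "dpoae", f, 0, 40, 4)
    for (i in seq_along(c(2, 14, 28))) {
      d <- c(2, 14, 28)[i]
      add(group, "abr", "click", d, click[i], 5)
      for (j in seq_along(tone_freqs))
        add(group, "abr", tone_freqs[j], d, tone_tab[i, j], 5)
      for (f in dpF) add(group, "dpoae", f, d, 65, 5)
    }
  }

  t105 <- rbind(c(60, 65, 65, 65, 65),
                c(50, 55, 55, 57, 57),
                c(45, 50, 52, 53, 55))
  t120 <- rbind(c(70, 75, 78, 80, 80),
                c(78, 82, 84, 85, 85),
                c(80, 83, 85, 86, 86))
  t913 <- rbind(c(45, 70, 75, 65, 68, 68, 68),
                c(35, 58, 68, 52, 55, 57, 58),
                c(28, 45, 62, 48, 47, 50, 54))

  exposed("vs105_2_20", c(67, 55, 50), t105, tones)
  exposed("vs120_2_20", c(70, 80, 82), t120, tones)
  exposed("vs105_9_13", c(67, 50, 45), t913, tones913)
  for (arm in c("saline", "p17", "p144"))
    exposed(arm, c(67, 55, 50), t105, tones)

  do.call(rbind, rows)
}

#' Design of a simulated ABR/DPOAE cohort
#'
#' @param group_sizes Named integer vector of subjects per group; defaults
#'   to the study's four main groups (12/12/8/12).
#' @param calibration Calibration table as from [default_calibration()].
#' @param noise_sd Amplitude noise SD of the simulated level series
#'   (response units; saturation is 1). Default 0.05.
#' @param criterion_k Detection criterion multiplier (default 2).
#' @param seed Integer master seed.
#' @return A `cohort_design` object.
#' @export
cohort_design <- function(group_sizes = c(control = 12, vs105_2_20 = 12,
                                          vs120_2_20 = 8, vs105_9_13 = 12),
                          calibration = default_calibration(),
                          noise_sd = 0.05, criterion_k = 2, seed = 1) {
  if (any(group_sizes < 1)) stop_input("group sizes must be >= 1")
  if (any(calibration$sd <= 0)) stop_input("calibration sds must be positive")
  unknown <- setdiff(names(group_sizes), unique(calibration$group))
  if (length(unknown) > 0)
    stop_input("no calibration for group(s): ", paste(unknown, collapse = ", "))
  structure(list(group_sizes = group_sizes, calibration = calibration,
                 noise_sd = noise_sd, criterion_k = criterion_k,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

#' Simulate an ABR/DPOAE cohort
#'
#' For every subject, test, stimulus and timepoint in the design, a true
#' threshold is drawn from the calibrated distribution, a level series is
#' simulated on the appropriate grid, and the threshold is detected with
#' the criterion rule. Output is fully determined by the design's seed.
#'
#' @param design A [cohort_design()].
#' @return data.frame (one row per measurement): `subject`, `group`,
#'   `day`, `test`, `stimulus`, `true_threshold`, `threshold`, `flag`.
#' @export
simulate_cohort <- function(design) {
  cal <- design$calibration
  cal <- cal[cal$group %in% names(design$group_sizes), ]
  subjects <- unlist(lapply(names(design$group_sizes), function(g)
    paste0(g, "_", seq_len(design$group_sizes[[g]]))), use.names = FALSE)
  sub_group <- sub("_[0-9]+$", "", subjects)
  grid_abr <- level_grid("abr")
  grid_dp <- level_grid("dpoae")

  withr::with_seed(design$seed, {
    out <- lapply(seq_along(subjects), function(i) {
      g <- sub_group[i]
      rows <- cal[cal$group == g, ]
      truth <- stats::rnorm(nrow(rows), rows$mean, rows$sd)
      det <- lapply(seq_len(nrow(rows)), function(j) {
        grid <- if (rows$test[j] == "abr") grid_abr else grid_dp
        series <- simulate_level_series(
          truth[j], grid, noise_sd = design$noise_sd,
          seed = sample.int(.Machine$integer.max - 1L, 1))
        detect_threshold(series, criterion_k = design$criterion_k,
                         noise_floor = design$noise_sd)
      })
      data.frame(subject = subjects[i], group = g, day = rows$day,
                 test = rows$test, stimulus = rows$stimulus,
                 true_threshold = truth,
                 threshold = vapply(det, `[[`, numeric(1), "threshold"),
                 flag = vapply(det, `[[`, character(1), "flag"),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Group-level audiogram summary
#'
#' Mean and SEM of detected thresholds by group, timepoint, test and
#' stimulus. Flagged detections (`above_ceiling`, `at_floor`) are
#' excluded, with their count reported; a single usable record yields an
#' `NA` SEM.
#'
#' @param records Output of [simulate_cohort()].
#' @return data.frame: `group`, `day`, `test`, `stimulus`, `n`,
#'   `mean_threshold`, `sem`, `n_flagged`.
#' @export
audiogram_table <- function(records) {
  if (nrow(records) == 0) stop_input("no records to summarize")
  keys <- unique(records[c("group", "day", "test", "stimulus")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    sub <- records[records$group == k$group & records$day == k$day &
                     records$test == k$test & records$stimulus == k$stimulus, ]
    ok <- sub$flag == "ok"
    x <- sub$threshold[ok]
    data.frame(k, n = length(x),
               mean_threshold = if (length(x) > 0) mean(x) else NA_real_,
               sem = if (length(x) > 1) stats::sd(x) / sqrt(length(x))
                     else NA_real_,
               n_flagged = sum(!ok), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mean paired threshold shift for one group and stimulus
#'
#' @param records Output of [simulate_cohort()].
#' @param group Group label.
#' @param stimulus Stimulus label (default `"click"`).
#' @param day Post-exposure day (default 2).
#' @param test `"abr"` or `"dpoae"`.
#' @return Mean over subjects of (post - baseline) detected thresholds, dB.
#' @export
mean_threshold_shift <- function(records, group, stimulus = "click",
                                 day = 2, test = "abr") {
  sel <- records$group == group & records$test == test &
    records$stimulus == as.character(stimulus) & records$flag == "ok"
  base <- records[sel & records$day == 0, c("subject", "threshold")]
  post <- records[sel & records$day == day, c("subject", "threshold")]
  m <- merge(base, post, by = "subject", suffixes = c("_base", "_post"))
  if (nrow(m) == 0) stop_input("no paired records for group ", group)
  mean(m$threshold_post - m$threshold_base)
}

#' Correlate functional threshold shifts with structural hair-cell loss
#'
#' Each tone frequency is mapped through the place map to its 5% sector
#' (the half-open bin containing its place); the per-frequency mean
#' threshold shift at the chosen day is paired with the sector's OHC
#' percent loss, and the Spearman rank correlation of the pairs is
#' returned. Frequencies outside the place map's range (below the apical
#' characteristic frequency) are dropped.
#'
#' @param records Output of [simulate_cohort()] for the group of interest.
#' @param loss Per-sector loss table from [percent_loss()].
#' @param group Group label in `records`.
#' @param day Post-exposure day for the shift (default 28).
#' @param place_map A [place_frequency_map()].
#' @return A list: `pairs` (data.frame `stimulus_khz`, `sector`,
#'   `threshold_shift`, `ohc_percent_loss`), `rho`, `n`.
#' @export
structure_function_correlation <- function(records, loss, group, day = 28,
                                           place_map = place_frequency_map()) {
  tones <- records[records$group == group & records$test == "abr" &
                     records$stimulus != "click", ]
  freqs <- sort(unique(as.numeric(tones$stimulus)))
  rng <- percent_to_frequency(c(0, 100), place_map)
  freqs <- freqs[freqs >= rng[1] & freqs <= rng[2]]
  ohc <- loss[loss$class == "OHC" & !loss$control_zero, ]
  pairs <- do.call(rbind, lapply(freqs, function(f) {
    d <- frequency_to_percent(f, place_map)
    sector <- 5 * ceiling(d / 5)
    if (!sector %in% ohc$sector) return(NULL)
    ts <- mean_threshold_shift(records, group, stimulus = f, day = day)
    data.frame(stimulus_khz = f, sector = sector, threshold_shift = ts,
               ohc_percent_loss = ohc$percent_loss[ohc$sector == sector])
  }))
  if (is.null(pairs) || nrow(pairs) < 3)
    stop_input("no overlapping sectors between audiogram and cochleogram")
  rho <- stats::cor(pairs$threshold_shift, pairs$ohc_percent_loss,
                    method = "spearman")
  list(pairs = pairs, rho = rho, n = nrow(pairs))
}

#' Plot a group audiogram
#'
#' Tone-evoked thresholds against stimulus frequency by timepoint.
#'
#' @param summary Output of [audiogram_table()], ABR tones only.
#' @return A ggplot object.
#' @export
plot_audiogram <- function(summary) {
  df <- summary[summary$test == "abr" & summary$stimulus != "click", ]
  df$freq <- as.numeric(df$stimulus)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq, y = .data$mean_threshold,
                                   colour = factor(.data$day))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~group) +
    ggplot2::scale_x_log10(breaks = c(4, 8, 10, 16, 20, 28, 40)) +
    ggplot2::labs(x = "frequency (kHz)", y = "ABR threshold (dB SPL)",
                  colour = "day")
}
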