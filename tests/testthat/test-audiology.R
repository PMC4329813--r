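test_that("DPOAE primaries follow the stated multipliers", {
  p <- dpoae_primaries(8)
  expect_equal(p$f1, 7.272)
  expect_equal(p$f2, 8.72)
  expect_equal(p$f_dp, 5.824)
  all_F <- dpoae_primaries(c(8, 10, 14, 18, 22))
  expect_equal(all_F$f2 / all_F$f1, rep(1.09 / 0.909, 5))
  expect_equal(all_F$f2 / all_F$f1, rep(1.2, 5), tolerance = 0.001)
  expect_true(all(all_F$f1 < all_F$F & all_F$F < all_F$f2))
  expect_error(dpoae_primaries(0), "positive")
})

test_that("level series are zero below threshold and saturate above it", {
  s <- simulate_level_series(42, noise_sd = 0)
  expect_equal(s$amplitude[s$level < 42], rep(0, sum(s$level < 42)))
  expect_equal(s$amplitude[s$level == 90], 1)  # far above threshold
  expect_true(all(diff(s$amplitude) <= 0))     # descending levels
  s2 <- simulate_level_series(42, noise_sd = 0.1, seed = 3)
  expect_identical(s2, simulate_level_series(42, noise_sd = 0.1, seed = 3))
  expect_error(simulate_level_series(42, grid = c(30, 20)), "degenerate")
  expect_error(simulate_level_series(42, grid = c(30, 40, 50)),
               "strictly decreasing")
})

test_that("threshold detection snaps to the grid ceiling and flags extremes", {
  s <- simulate_level_series(42, noise_sd = 0)
  d <- detect_threshold(s)
  expect_equal(d$threshold, 45)
  expect_equal(d$flag, "ok")
  # noise-free detected threshold is always >= the true threshold
  for (thr in c(12, 27, 43, 68, 88)) {
    det <- detect_threshold(simulate_level_series(thr, noise_sd = 0))
    expect_gte(det$threshold, thr)
    expect_equal(det$threshold, 5 * ceiling(thr / 5))
  }
  # pure noise: no response anywhere
  grid <- level_grid("abr")
  flat <- data.frame(level = grid, amplitude = rep(0, length(grid)))
  d0 <- detect_threshold(flat)
  expect_equal(d0$flag, "above_ceiling")
  expect_equal(d0$threshold, 95)
  # responses down to the floor level
  low <- detect_threshold(simulate_level_series(5, noise_sd = 0))
  expect_equal(low$flag, "at_floor")
  expect_equal(low$threshold, 10)
})

test_that("threshold shift is the post-baseline difference with flag propagation", {
  # strain-selection data: baseline 17, day-3 69 -> 52 dB shift
  expect_equal(threshold_shift(17, 69)$shift, 52)
  expect_equal(threshold_shift(50, 50)$shift, 0)
  expect_equal(threshold_shift(60, 45)$shift, -15)  # recovery below baseline
  # antisymmetry
  expect_equal(threshold_shift(17, 69)$shift, -threshold_shift(69, 17)$shift)
  flagged <- list(threshold = 95, flag = "above_ceiling")
  expect_equal(threshold_shift(17, flagged)$flag, "flagged")
})

test_that("simulated cohorts reproduce the group trajectories", {
  rec <- simulate_cohort(cohort_design(seed = 5))
  expect_identical(rec, simulate_cohort(cohort_design(seed = 5)))
  tab <- audiogram_table(rec)
  # control click thresholds stay at baseline throughout (|TS| < 5 dB)
  ctrl <- tab[tab$group == "control" & tab$stimulus == "click", ]
  expect_true(all(abs(ctrl$mean_threshold - ctrl$mean_threshold[ctrl$day == 0])
                  < 5))
  # every exposed group shifts by tens of dB at day 2
  for (g in c("vs105_2_20", "vs120_2_20", "vs105_9_13"))
    expect_gt(mean_threshold_shift(rec, g, day = 2), 30)
  # the narrow-band group's day-2 audiogram peaks at 8-10 kHz
  ts <- vapply(c(4, 8, 10, 16), function(f)
    mean_threshold_shift(rec, "vs105_9_13", stimulus = f, day = 2), numeric(1))
  expect_true(which.max(ts) %in% c(2, 3))
  # DPOAE thresholds rise in all exposed groups at day 28
  dp <- tab[tab$test == "dpoae" & tab$day == 28, ]
  expect_gt(min(dp$mean_threshold[dp$group != "control"]), 55)
  expect_lt(max(dp$mean_threshold[dp$group == "control"]), 50)
})

test_that("audiogram_table aggregates like a brute-force oracle", {
  rec <- simulate_cohort(cohort_design(
    group_sizes = c(control = 4, vs105_2_20 = 3), seed = 2))
  tab <- audiogram_table(rec)
  i <- which(tab$group == "vs105_2_20" & tab$day == 2 &
               tab$stimulus == "click")
  sub <- rec[rec$group == "vs105_2_20" & rec$day == 2 &
               rec$stimulus == "click" & rec$flag == "ok", ]
  expect_equal(tab$mean_threshold[i], mean(sub$threshold))
  expect_equal(tab$sem[i], stats::sd(sub$threshold) / sqrt(nrow(sub)))
  expect_error(audiogram_table(rec[0, ]), "no records")
  # single usable record: mean defined, SEM flagged undefined
  one <- rec[rec$subject == rec$subject[1] & rec$day == 0 &
               rec$stimulus == "click", ]
  t1 <- audiogram_table(one)
  expect_equal(t1$mean_threshold, one$threshold)
  expect_true(is.na(t1$sem))
})

test_that("cohort design validates its inputs", {
  expect_error(cohort_design(group_sizes = c(control = 0)), ">= 1")
  expect_error(cohort_design(group_sizes = c(nosuch = 3)), "nosuch")
  cal <- default_calibration()
  cal$sd[1] <- 0
  expect_error(cohort_design(calibration = cal), "sds")
})

test_that("structure-function correlation behaves on constructed pairs", {
  freqs <- c(8, 10, 16, 20, 28, 40)
  sectors <- vapply(freqs, function(f) 5 * ceiling(frequency_to_percent(f) / 5),
                    numeric(1))
  mk_records <- function(shifts) {
    base <- data.frame(subject = "s1", group = "g", day = 0, test = "abr",
                       stimulus = as.character(freqs), true_threshold = 15,
                       threshold = 15, flag = "ok", stringsAsFactors = FALSE)
    post <- base
    post$day <- 28
    post$threshold <- 15 + shifts
    rbind(base, post)
  }
  loss <- data.frame(sector = sectors, class = "OHC",
                     percent_loss = c(10, 20, 30, 40, 50, 60),
                     control_zero = FALSE)
  # shifts monotone in structural loss: perfect rank agreement
  r1 <- structure_function_correlation(mk_records(c(5, 10, 15, 20, 25, 30)),
                                       loss, "g")
  expect_equal(r1$rho, 1)
  expect_equal(r1$n, 6)
  # shuffled pairings average out to no correlation
  rhos <- withr::with_seed(31, replicate(1000, {
    stats::cor(sample(c(5, 10, 15, 20, 25, 30)), c(10, 20, 30, 40, 50, 60),
               method = "spearman")
  }))
  expect_lt(abs(mean(rhos)), 0.1)
  # frequencies below the apical characteristic frequency are dropped
  r2 <- structure_function_correlation(mk_records(c(5, 10, 15, 20, 25, 30)),
                                       rbind(loss, data.frame(
                                         sector = 5, class = "OHC",
                                         percent_loss = 0,
                                         control_zero = FALSE)), "g")
  expect_false(4 %in% r2$pairs$stimulus_khz)
  expect_error(structure_function_correlation(
    mk_records(rep(5, 6)), loss[1:2, ], "g"), "overlapping")
})

test_that("the narrow-band simulation yields a positive structure-function rho", {
  spec <- vs_spec(9, 13, 105)
  rhos <- vapply(1:5, function(s) {
    ctrl <- build_control_map(seed = s)
    les <- apply_lesion(ctrl, spec, seed = s + 300)
    loss <- percent_loss(estimate_cochleogram(les, seed = s + 600),
                         estimate_cochleogram(ctrl, seed = s + 600))
    rec <- simulate_cohort(cohort_design(group_sizes = c(vs105_9_13 = 12),
                                         seed = s))
    structure_function_correlation(rec, loss, "vs105_9_13")$rho
  }, numeric(1))
  expect_true(all(rhos > 0))
})
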