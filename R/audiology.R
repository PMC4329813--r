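#' DPOAE primary tones from a central frequency
#'
#' `f1 = 0.909 * F`, `f2 = 1.09 * F`, distortion product at `2*f1 - f2`;
#' the primary ratio `f2/f1` is approximately 1.2.
#'
#' @param F Central frequency in kHz (vectorized, positive).
#' @return data.frame: `F`, `f1`, `f2`, `f_dp` (kHz).
#' @export
dpoae_primaries <- function(F) {
  if (any(F <= 0)) stop_input("central frequency must be positive")
  f1 <- 0.909 * F
  f2 <- 1.09 * F
  data.frame(F = F, f1 = f1, f2 = f2, f_dp = 2 * f1 - f2)
}

#' Presentation level grids
#'
#' ABR levels descend from 90 dB SPL in 5 dB steps; the floor extends to
#' 10 dB SPL so that normal baselines near 15 dB remain representable.
#' DPOAE levels descend from 80 to 30 dB SPL.
#'
#' @param kind `"abr"` or `"dpoae"`.
#' @return Numeric vector of levels, strictly decreasing.
#' @export
level_grid <- function(kind = c("abr", "dpoae")) {
  kind <- match.arg(kind)
  if (kind == "abr") seq(90, 10, by = -5) else seq(80, 30, by = -5)
}

#' Simulate an evoked-response level series
#'
#' Response amplitude is zero (plus noise) below the true threshold and
#' grows linearly with level above it, saturating at `a_sat`:
#' `a_sat * min(1, (level - threshold + step) / ramp)`. With
#' `noise_sd = 0` the series is exactly 0 below threshold and exactly
#' `a_sat` far above it.
#'
#' @param true_threshold True threshold in dB SPL.
#' @param grid Presentation levels (strictly decreasing), dB SPL.
#' @param noise_sd SD of additive amplitude noise (response units).
#' @param seed Integer seed.
#' @param a_sat Saturation amplitude (default 1).
#' @param step Growth offset so the threshold level itself responds
#'   (default 5 dB).
#' @param ramp Dynamic range to saturation (default 40 dB).
#' @return data.frame: `level`, `amplitude`.
#' @export
simulate_level_series <- function(true_threshold, grid = level_grid("abr"),
                                  noise_sd = 0, seed = 1, a_sat = 1,
                                  step = 5, ramp = 40) {
  if (length(grid) < 3) stop_input("degenerate level grid")
  if (any(diff(grid) >= 0))
    stop_input("levels must be strictly decreasing during presentation")
  growth <- ifelse(grid >= true_threshold,
                   a_sat * pmin(1, (grid - true_threshold + step) / ramp), 0)
  noise <- if (noise_sd > 0)
    withr::with_seed(as.integer(seed), stats::rnorm(length(grid), 0, noise_sd))
  else 0
  data.frame(level = grid, amplitude = growth + noise)
}

#' Detect the response threshold from a level series
#'
#' The threshold is the lowest presented level whose amplitude exceeds
#' `criterion_k` times the noise-floor estimate, with every higher level
#' also responding. A series with no response anywhere is flagged
#' `"above_ceiling"` and recorded as the ceiling plus one step; a series
#' responding at the lowest presented level is flagged `"at_floor"`.
#'
#' @param series data.frame `level`, `amplitude` (levels descending).
#' @param criterion_k Multiplier on the noise floor (default 2).
#' @param noise_floor Noise-floor scale; when 0 any positive amplitude
#'   counts as a response.
#' @return A list: `threshold` (dB SPL), `flag` (`"ok"`,
#'   `"above_ceiling"` or `"at_floor"`).
#' @export
detect_threshold <- function(series, criterion_k = 2, noise_floor = 0) {
  if (nrow(series) < 3) stop_input("need at least 3 levels")
  crit <- criterion_k * noise_floor
  responding <- series$amplitude > crit
  if (!any(responding))
    return(list(threshold = max(series$level) +
                  abs(diff(series$level[1:2])), flag = "above_ceiling"))
  # lowest level from which all higher levels respond
  ord <- order(series$level, decreasing = TRUE)
  resp <- responding[ord]
  run <- cumprod(resp) == 1
  if (!any(run))
    return(list(threshold = max(series$level) +
                  abs(diff(series$level[1:2])), flag = "above_ceiling"))
  thr <- min(series$level[ord][run])
  flag <- if (thr == min(series$level)) "at_floor" else "ok"
  list(threshold = thr, flag = flag)
}

#' Threshold shift
#'
#' Post-exposure threshold minus baseline, in dB. Negative shifts
#' (recovery below baseline) are allowed. Detection flags propagate: a
#' shift computed from a flagged threshold is itself flagged.
#'
#' @param baseline,post Thresholds in dB SPL, or the lists returned by
#'   [detect_threshold()].
#' @return A list: `shift` (dB), `flag`.
#' @export
threshold_shift <- function(baseline, post) {
  get <- function(x) if (is.list(x)) x else list(threshold = x, flag = "ok")
  b <- get(baseline); p <- get(post)
  flag <- if (b$flag != "ok" || p$flag != "ok") "flagged" else "ok"
  list(shift = p$threshold - b$threshold, flag = flag)
}
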