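#' Parametric description of a violet exposure stimulus
#'
#' Two stimulus kinds are supported, mirroring the exposure paradigm the
#' package models: `"violet_noise"` (white noise reshaped so that amplitude
#' gain grows linearly with frequency inside the band, i.e. a +6 dB/octave
#' power slope) and `"violet_sweep"` (a linear swept sine whose amplitude
#' envelope is proportional to its instantaneous frequency, repeated
#' back-to-back for the total exposure duration).
#'
#' @param kind `"violet_noise"` or `"violet_sweep"`.
#' @param f_low,f_high Band edges in kHz; `0 < f_low < f_high`.
#' @param level Nominal presentation level in dB SPL (applied by
#'   [scale_to_level()], not during synthesis).
#' @param sweep_duration Duration of one sweep in seconds (sweeps only;
#'   default 10 s).
#' @param total_duration Total stimulus duration in seconds.
#' @param sample_rate Sampling rate in Hz; must exceed twice `f_high`
#'   (in Hz). Default 96 kHz, which covers 20 kHz content with margin.
#' @return A `stimulus_spec` object.
#' @examples
#' vs <- stimulus_spec("violet_sweep", f_low = 2, f_high = 20,
#'                     level = 105, sweep_duration = 10, total_duration = 30)
#' @export
stimulus_spec <- function(kind = c("violet_noise", "violet_sweep"),
                          f_low, f_high, level = 105,
                          sweep_duration = if (kind == "violet_sweep") 10 else NULL,
                          total_duration, sample_rate = 96000) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(f_low), is.numeric(f_high), is.numeric(total_duration))
  if (!(f_low > 0 && f_high > f_low))
    stop_input("need 0 < f_low < f_high (kHz)")
  if (sample_rate <= 2 * f_high * 1000)
    stop_input("sample_rate violates Nyquist for f_high = ", f_high, " kHz")
  if (total_duration <= 0)
    stop_input("total_duration must be positive")
  if (kind == "violet_sweep") {
    if (is.null(sweep_duration) || sweep_duration <= 0)
      stop_input("sweep_duration must be positive for violet_sweep")
    if (total_duration < sweep_duration)
      stop_input("total_duration must be >= sweep_duration")
  }
  structure(
    list(kind = kind, f_low = f_low, f_high = f_high, level = level,
         sweep_duration = if (kind == "violet_sweep") sweep_duration else NULL,
         total_duration = total_duration, sample_rate = sample_rate),
    class = "stimulus_spec")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf("<stimulus_spec> %s %g-%g kHz, %g dB SPL, %g s @ %g Hz\n",
              x$kind, x$f_low, x$f_high, x$level, x$total_duration,
              x$sample_rate))
  if (!is.null(x$sweep_duration))
    cat(sprintf("  sweep: %g s per repeat (%d complete repeats)\n",
                x$sweep_duration, n_sweep_repeats(x)))
  invisible(x)
}

new_waveform <- function(samples, sample_rate) {
  stopifnot(all(is.finite(samples)))
  structure(list(samples = samples, sample_rate = sample_rate),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples @ %g Hz (%.3f s), RMS %.4g\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate, waveform_rms(x)))
  invisible(x)
}

#' Root-mean-square pressure of a waveform
#' @param w A `waveform`.
#' @return RMS of the sample vector.
#' @export
waveform_rms <- function(w) sqrt(mean(w$samples^2))

#' Number of complete sweep repeats in a swept-sine stimulus
#' @param spec A `violet_sweep` [stimulus_spec()].
#' @return Integer count of complete repeats fitting in `total_duration`.
#' @export
n_sweep_repeats <- function(spec) {
  stopifnot(spec$kind == "violet_sweep")
  as.integer(floor(spec$total_duration / spec$sweep_duration))
}

# Frequency-domain violet gain: |G(f)| proportional to f inside the band,
# raised-cosine tapers of width 5% of the band at both edges, zero outside.
violet_gain <- function(f_khz, f_low, f_high, taper_frac = 0.05) {
  w <- taper_frac * (f_high - f_low)
  g <- f_khz / f_high
  g[f_khz < f_low | f_khz > f_high] <- 0
  lo <- f_khz >= f_low & f_khz < f_low + w
  g[lo] <- g[lo] * 0.5 * (1 - cos(pi * (f_khz[lo] - f_low) / w))
  hi <- f_khz > f_high - w & f_khz <= f_high
  g[hi] <- g[hi] * 0.5 * (1 - cos(pi * (f_high - f_khz[hi]) / w))
  g
}

#' Synthesize violet noise
#'
#' Gaussian white noise is reshaped in the frequency domain: the amplitude
#' spectrum is multiplied by a gain proportional to frequency inside
#' `[f_low, f_high]` (raised-cosine tapers over 5% of the band at each
#' edge, zero outside), which yields the +6 dB/octave "violet" power slope.
#' Output is normalized to unit RMS; use [scale_to_level()] to set SPL.
#'
#' @param spec A `violet_noise` [stimulus_spec()].
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return A `waveform`.
#' @export
synth_violet_noise <- function(spec, seed) {
  stopifnot(inherits(spec, "stimulus_spec"))
  if (spec$kind != "violet_noise")
    stop_input("spec$kind must be 'violet_noise'")
  fs <- spec$sample_rate
  n <- round(spec$total_duration * fs)
  x <- withr::with_seed(as.integer(seed), stats::rnorm(n))
  f_khz <- (seq_len(n) - 1) / n * fs / 1000
  f_khz <- pmin(f_khz, fs / 1000 - f_khz)  # fold to physical frequency
  g <- violet_gain(f_khz, spec$f_low, spec$f_high)
  y <- Re(stats::fft(stats::fft(x) * g, inverse = TRUE)) / n
  y <- y / sqrt(mean(y^2))
  new_waveform(y, fs)
}

#' Instantaneous frequency of a violet swept sine
#'
#' The sweep is linear: frequency rises from `f_low` at the start of each
#' repeat to `f_high` at its end, then restarts.
#'
#' @param spec A `violet_sweep` [stimulus_spec()].
#' @param t Time in seconds (vectorized).
#' @return Frequency in kHz at each `t`.
#' @export
sweep_instantaneous_frequency <- function(spec, t) {
  stopifnot(spec$kind == "violet_sweep")
  Td <- spec$sweep_duration
  tau <- t %% Td
  # the exact end of a repeat belongs to that repeat, not the next
  tau[t > 0 & tau == 0] <- Td
  spec$f_low + (spec$f_high - spec$f_low) * tau / Td
}

#' Synthesize a violet swept-sine stimulus
#'
#' One sweep has phase `2*pi*(f_low*t + (f_high - f_low)*t^2/(2*T))` (Hz
#' scale) and amplitude envelope proportional to instantaneous frequency
#' (linear-with-frequency gain). Sweeps are tiled back-to-back until
#' `total_duration`, truncating the final repeat. Output is normalized to
#' unit RMS. Synthesis is deterministic.
#'
#' @param spec A `violet_sweep` [stimulus_spec()].
#' @return A `waveform`.
#' @export
synth_violet_sweep <- function(spec) {
  stopifnot(inherits(spec, "stimulus_spec"))
  if (spec$kind != "violet_sweep")
    stop_input("spec$kind must be 'violet_sweep'")
  fs <- spec$sample_rate
  Td <- spec$sweep_duration
  n1 <- round(Td * fs)
  t <- (seq_len(n1) - 1) / fs
  f0 <- spec$f_low * 1000
  f1 <- spec$f_high * 1000
  phase <- 2 * pi * (f0 * t + (f1 - f0) * t^2 / (2 * Td))
  env <- (f0 + (f1 - f0) * t / Td) / f1
  one <- env * sin(phase)
  n_tot <- round(spec$total_duration * fs)
  y <- rep_len(one, n_tot)
  y <- y / sqrt(mean(y^2))
  new_waveform(y, fs)
}

#' Scale a waveform to a target sound pressure level
#'
#' SPL is defined on the digital waveform against a reference pressure:
#' the output RMS equals `p_ref * 10^(level/20)`. Scaling is a scalar
#' multiplication (shape unchanged) and is idempotent.
#'
#' @param w A `waveform` with nonzero RMS.
#' @param level Target level, dB SPL.
#' @param p_ref Reference pressure in Pa (default 20 micro-Pa).
#' @return The scaled `waveform`.
#' @export
scale_to_level <- function(w, level, p_ref = 20e-6) {
  stopifnot(inherits(w, "waveform"))
  r <- waveform_rms(w)
  if (r == 0) stop_input("cannot scale a zero-RMS waveform")
  target <- p_ref * 10^(level / 20)
  new_waveform(w$samples * target / r, w$sample_rate)
}
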