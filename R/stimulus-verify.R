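# Spectral verification of synthesized stimuli: Welch PSD, slope fits,
# band power containment and spectrogram ridge linearity.

# Welch-averaged power spectral density. Returns data.frame(freq_khz, power).
welch_psd <- function(w, nfft = 4096, overlap = 0.5) {
  x <- w$samples
  fs <- w$sample_rate
  if (length(x) < nfft) stop_input("waveform too short for PSD averaging")
  step <- max(1L, floor(nfft * (1 - overlap)))
  starts <- seq(1L, length(x) - nfft + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nfft) - 1) / (nfft - 1))  # Hann
  acc <- numeric(nfft %/% 2)
  for (s in starts) {
    seg <- x[s:(s + nfft - 1L)] * win
    p <- Mod(stats::fft(seg))^2
    acc <- acc + p[2:(nfft %/% 2 + 1L)]
  }
  data.frame(freq_khz = (seq_len(nfft %/% 2)) * fs / nfft / 1000,
             power = acc / length(starts))
}

#' Estimate the power spectral slope of a waveform in dB per octave
#'
#' Fits a line to the Welch-averaged power spectrum (in dB) against
#' log2(frequency) over the requested band. Violet-shaped noise measures
#' close to +6.02 dB/octave; white noise close to 0. Band edges should sit
#' inside any synthesis tapers, since tapered edges do not follow the
#' in-band slope.
#'
#' @param w A `waveform` of at least 1 s.
#' @param band Numeric length-2, band `(kHz, kHz)` over which to fit.
#' @param nfft FFT length for the Welch segments.
#' @return Slope in dB/octave.
#' @export
estimate_psd_slope <- function(w, band, nfft = 4096) {
  stopifnot(inherits(w, "waveform"), length(band) == 2)
  if (band[1] >= band[2]) stop_input("empty band")
  if (band[2] * 1000 > w$sample_rate / 2) stop_input("band exceeds Nyquist")
  if (length(w$samples) / w$sample_rate < 1)
    stop_input("waveform shorter than 1 s; slope estimate unreliable")
  psd <- welch_psd(w, nfft = nfft)
  sel <- psd$freq_khz >= band[1] & psd$freq_khz <= band[2] & psd$power > 0
  if (sum(sel) < 10) stop_input("too few spectral points in band")
  fit <- stats::lm(y ~ x, data = data.frame(x = log2(psd$freq_khz[sel]),
                                            y = 10 * log10(psd$power[sel])))
  unname(stats::coef(fit)[2])
}

#' Fraction of total power inside a frequency band
#'
#' @param w A `waveform`.
#' @param band Numeric length-2, band in kHz.
#' @return Fraction in `[0, 1]` of Welch-PSD power falling inside `band`.
#' @export
band_power_fraction <- function(w, band) {
  stopifnot(length(band) == 2, band[1] < band[2])
  psd <- welch_psd(w)
  sel <- psd$freq_khz >= band[1] & psd$freq_khz <= band[2]
  sum(psd$power[sel]) / sum(psd$power)
}

#' Extract the spectrogram ridge of a swept-sine waveform
#'
#' Computes a short-time Fourier transform and takes the peak-frequency
#' bin per frame; for a linear sweep the ridge frequency is linear in time.
#' Frames within 2% of either end are dropped (window edge effects).
#'
#' @param w A `waveform` holding one sweep period (see [synth_violet_sweep()]
#'   with `total_duration = sweep_duration`).
#' @param window STFT window length in samples.
#' @return A list with `time` (s), `freq_khz`, the linear-fit `slope`
#'   (kHz/s), `intercept` (kHz) and `r_squared`.
#' @export
spectrogram_ridge <- function(w, window = 1024) {
  sg <- signal::specgram(w$samples, n = window, Fs = w$sample_rate,
                         overlap = window / 2)
  pow <- Mod(sg$S)^2
  ridge <- sg$f[apply(pow, 2, which.max)] / 1000
  tt <- sg$t
  dur <- length(w$samples) / w$sample_rate
  keep <- tt > 0.02 * dur & tt < 0.98 * dur
  fit <- stats::lm(ridge[keep] ~ tt[keep])
  list(time = tt[keep], freq_khz = ridge[keep],
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared)
}

#' Verify a stimulus waveform against its specification
#'
#' Computes the PSD slope over the band interior, the fraction of power
#' outside the 10%-widened band, and (for sweeps) the spectrogram ridge
#' linearity, returning a report that can be serialized to JSON.
#'
#' @param w A `waveform`.
#' @param spec The [stimulus_spec()] it was synthesized from.
#' @return A list: `psd_slope_db_per_octave`, `band_power_fraction`,
#'   `out_of_band_fraction`, and for sweeps `ridge_r_squared`,
#'   `ridge_slope_khz_per_s`.
#' @export
verify_stimulus <- function(w, spec) {
  taper <- 0.05 * (spec$f_high - spec$f_low)
  interior <- c(spec$f_low + 2 * taper, spec$f_high - 2 * taper)
  inband <- band_power_fraction(w, c(spec$f_low * 0.9, spec$f_high * 1.1))
  rep <- list(
    kind = spec$kind,
    psd_slope_db_per_octave = estimate_psd_slope(w, interior),
    band_power_fraction = inband,
    out_of_band_fraction = 1 - inband)
  if (spec$kind == "violet_sweep") {
    one <- stimulus_spec("violet_sweep", spec$f_low, spec$f_high, spec$level,
                         sweep_duration = spec$sweep_duration,
                         total_duration = spec$sweep_duration,
                         sample_rate = spec$sample_rate)
    ridge <- spectrogram_ridge(synth_violet_sweep(one))
    rep$ridge_r_squared <- ridge$r_squared
    rep$ridge_slope_khz_per_s <- ridge$slope
  }
  rep
}
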