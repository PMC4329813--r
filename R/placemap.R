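#' Cochlear place-frequency map
#'
#' Log-linear place-frequency relation for the mouse basilar membrane,
#' `f = 10^((A - d_base)/B)` kHz with `d_base` the percent distance from
#' the base. The package measures position as percent distance from the
#' apex (`d_apex = 100 - d_base`), matching cochleogram axes. Defaults are
#' the Mueller mouse-map constants (A = 156.5, B = 82.5), giving about
#' 4.8 kHz at the apex and 79 kHz at the basal extreme; alternative maps
#' (e.g. the Ou anatomical map) can be used by supplying their constants.
#'
#' @param A Intercept constant.
#' @param B Slope constant per log10(kHz); must be positive.
#' @param name Label for reports.
#' @return A `place_frequency_map` object.
#' @export
place_frequency_map <- function(A = 156.5, B = 82.5, name = "muller") {
  if (B <= 0) stop_input("B must be positive (monotone map)")
  structure(list(A = A, B = B, name = name), class = "place_frequency_map")
}

#' Convert percent distance from apex to characteristic frequency
#'
#' @param d_apex Percent distance from the apex, in `[0, 100]` (vectorized).
#' @param map A [place_frequency_map()].
#' @return Characteristic frequency in kHz.
#' @export
percent_to_frequency <- function(d_apex, map = place_frequency_map()) {
  if (any(d_apex < 0 | d_apex > 100))
    stop_input("d_apex must lie in [0, 100]")
  10^((map$A - (100 - d_apex)) / map$B)
}

#' Convert frequency to percent distance from apex
#'
#' Exact inverse of [percent_to_frequency()]; round-trips to within 1e-9
#' relative error.
#'
#' @param f Frequency in kHz (vectorized); must lie within the map's range.
#' @param map A [place_frequency_map()].
#' @return Percent distance from the apex.
#' @export
frequency_to_percent <- function(f, map = place_frequency_map()) {
  if (any(f <= 0)) stop_input("frequency must be positive")
  rng <- percent_to_frequency(c(0, 100), map)
  if (any(f < rng[1] | f > rng[2]))
    stop_input("frequency outside the map range [",
               signif(rng[1], 3), ", ", signif(rng[2], 3), "] kHz")
  100 - map$A + map$B * log10(f)
}
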