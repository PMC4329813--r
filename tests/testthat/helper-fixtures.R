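# Shared fixtures: exposure specs at the study's levels/bands, and a small
# deterministic sampling setup.

vs_spec <- function(f_low = 2, f_high = 20, level = 105) {
  stimulus_spec("violet_sweep", f_low, f_high, level,
                sweep_duration = 10, total_duration = 1800)
}

# A long idealized sector (big cochlea) for high-frame-count experiments.
big_params <- function() cochlea_params(bm_length = 60)

empty_substrate <- function(length_um = 256.5, fringe = 28) {
  structure(list(sector = 5, length_um = length_um, fringe_width = fringe,
                 points = data.frame(x_um = numeric(0), y_um = numeric(0),
                                     row = character(0), class = character(0),
                                     stringsAsFactors = FALSE)),
            class = "sampling_substrate")
}

substrate_with_points <- function(x, y, class = "OHC",
                                  length_um = 256.5, fringe = 28) {
  structure(list(sector = 5, length_um = length_um, fringe_width = fringe,
                 points = data.frame(x_um = x, y_um = y,
                                     row = ifelse(class == "IHC", "IHC", "OHC1"),
                                     class = class, stringsAsFactors = FALSE)),
            class = "sampling_substrate")
}
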