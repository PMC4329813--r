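#' Geometry and intensity parameters of a synthetic cochlea
#'
#' Describes the flattened organ-of-Corti preparation the stereology
#' samples: basilar-membrane length, the apical fraction that survives
#' dissection, the width of the stereociliary fringe (the reference space
#' bounding the hair-bundle rows), and per-row Poisson intensities of
#' hair bundles along the length.
#'
#' The three OHC rows and the single IHC row sit at fixed lateral offsets
#' inside the fringe, chosen so that a default 25 um counting frame placed
#' on the fringe midline always spans all four rows.
#'
#' @param bm_length Basilar membrane length in mm (default 5.13).
#' @param coverage_percent Percent of the length dissected from the apex;
#'   valid 70-85 (the basal "hook" is lost to dissection).
#' @param fringe_width Width of the stereociliary fringe in um.
#' @param ohc_rows Number of OHC rows (fixed at 3).
#' @param ohc_intensity Bundles per um per OHC row (default 1/9).
#' @param ihc_intensity Bundles per um in the IHC row (default 1/8).
#' @return A `cochlea_params` object.
#' @export
cochlea_params <- function(bm_length = 5.13, coverage_percent = 80,
                           fringe_width = 28, ohc_rows = 3,
                           ohc_intensity = 1 / 9, ihc_intensity = 1 / 8) {
  if (!(coverage_percent >= 70 && coverage_percent <= 85))
    stop_input("coverage_percent must lie in [70, 85]")
  if (bm_length <= 0) stop_input("bm_length must be positive")
  if (fringe_width <= 0) stop_input("fringe_width must be positive")
  if (ohc_intensity <= 0 || ihc_intensity <= 0)
    stop_input("intensities must be positive")
  if (ohc_rows != 3) stop_input("the organ of Corti has 3 OHC rows")
  structure(
    list(bm_length = bm_length, coverage_percent = coverage_percent,
         fringe_width = fringe_width, ohc_rows = ohc_rows,
         ohc_intensity = ohc_intensity, ihc_intensity = ihc_intensity),
    class = "cochlea_params")
}

#' Expected hair-cell densities of a control map
#'
#' Closed-form expectation of bundle density over the fringe reference
#' area: `rows * intensity / fringe_width * 1000` per 1000 um^2.
#'
#' @param params A [cochlea_params()].
#' @return Named vector `c(OHC=, IHC=)` in bundles per 1000 um^2.
#' @export
expected_densities <- function(params = cochlea_params()) {
  c(OHC = params$ohc_rows * params$ohc_intensity / params$fringe_width * 1000,
    IHC = params$ihc_intensity / params$fringe_width * 1000)
}

#' Generate a control (unexposed) hair-cell map
#'
#' Longitudinal bundle positions are drawn from independent homogeneous
#' Poisson processes per row over the dissected extent; all bundles are
#' present. Poisson placement (rather than the near-regular lattice of a
#' real epithelium) is deliberate: it produces Poisson frame-count
#' variance, the regime in which the empirical coefficients of error
#' reported for this design arise. Lateral positions are drawn uniformly
#' across the stereociliary fringe (row identity is kept as a label):
#' a uniform lateral marginal is what makes the midline-jittered counting
#' frame, which is narrower than the fringe, sample every cell class with
#' inclusion probability `frame_height / fringe_width` and hence leaves
#' the corner-count ratio estimator exactly unbiased for fringe-areal
#' density.
#'
#' @param params A [cochlea_params()].
#' @param seed Integer seed.
#' @return A `hair_cell_map`: data.frame with columns `position_percent`
#'   (distance from apex), `row` (IHC/OHC1/OHC2/OHC3), `lateral_um`,
#'   `present`; attributes carry `params` and lesion state.
#' @export
build_control_map <- function(params = cochlea_params(), seed = 1) {
  length_um <- params$bm_length * 1000
  covered_um <- params$coverage_percent / 100 * length_um
  rates <- c(IHC = params$ihc_intensity,
             OHC1 = params$ohc_intensity,
             OHC2 = params$ohc_intensity,
             OHC3 = params$ohc_intensity)
  map <- withr::with_seed(as.integer(seed), {
    pieces <- lapply(names(rates), function(rw) {
      n <- stats::rpois(1, rates[[rw]] * covered_um)
      data.frame(position_percent = stats::runif(n, 0, params$coverage_percent),
                 row = rw,
                 lateral_um = stats::runif(n, 0, params$fringe_width),
                 present = TRUE,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, pieces)
  })
  map <- map[order(map$position_percent), , drop = FALSE]
  rownames(map) <- NULL
  structure(map, params = params, lesioned = FALSE, seed = as.integer(seed),
            class = c("hair_cell_map", "data.frame"))
}

#' Cell class (IHC/OHC) from row identity
#' @param row Character vector of row labels.
#' @return `"IHC"` or `"OHC"` per element.
#' @export
row_class <- function(row) ifelse(row == "IHC", "IHC", "OHC")

#' Extract one sector of a map as a sampling substrate
#'
#' Converts percent positions of the present bundles in one 5% sector to
#' local um coordinates inside the sector's fringe rectangle
#' (`0.05 * bm_length * 1000` um long by `fringe_width` um wide). Sectors
#' are half-open `(k-5, k]` percent intervals labeled by their basal
#' edge `k`.
#'
#' @param map A `hair_cell_map`.
#' @param sector_label Sector label (5, 10, ..., up to the coverage).
#' @param params A [cochlea_params()]; defaults to the map's own.
#' @return A `sampling_substrate`: list with `sector`, `length_um`,
#'   `fringe_width`, and `points` (data.frame `x_um`, `y_um`, `row`,
#'   `class`).
#' @export
render_sector_substrate <- function(map, sector_label,
                                    params = attr(map, "params")) {
  bins <- sector_bins(params$coverage_percent)
  if (!sector_label %in% bins)
    stop_input("sector ", sector_label, " outside coverage (",
               params$coverage_percent, "%)")
  length_um <- params$bm_length * 1000
  sector_um <- 0.05 * length_um
  in_sector <- map$present &
    map$position_percent > (sector_label - 5) &
    map$position_percent <= sector_label
  pts <- map[in_sector, , drop = FALSE]
  x_um <- (pts$position_percent - (sector_label - 5)) / 100 * length_um
  structure(
    list(sector = sector_label, length_um = sector_um,
         fringe_width = params$fringe_width,
         points = data.frame(x_um = x_um, y_um = pts$lateral_um,
                             row = pts$row, class = row_class(pts$row),
                             stringsAsFactors = FALSE)),
    class = "sampling_substrate")
}

#' Write / read hair-cell maps as CSV
#'
#' @param map A `hair_cell_map`.
#' @param path CSV path.
#' @return `path` (write) or the `hair_cell_map` (read).
#' @export
write_map_csv <- function(map, path) {
  utils::write.csv(as.data.frame(map), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_map_csv
#' @param params A [cochlea_params()] to attach on read.
#' @export
read_map_csv <- function(path, params = cochlea_params()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("position_percent", "row", "lateral_um", "present")
  if (!all(need %in% names(df)))
    stop_input("map CSV must have columns: ", paste(need, collapse = ", "))
  structure(df, params = params, lesioned = NA, class = c("hair_cell_map", "data.frame"))
}
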