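#' Sector labels for a percentage cochleogram
#'
#' The dissected length is divided into half-open 5% bins from the apex,
#' `(k-5, k]`, labeled by their basal edge `k`.
#'
#' @param coverage_percent Dissected coverage; 70-85 for real
#'   preparations, 100 for an idealized full cochlea.
#' @return Integer vector of sector labels (5, 10, ...).
#' @export
sector_bins <- function(coverage_percent) {
  if (!(coverage_percent >= 70 && coverage_percent <= 85) &&
      coverage_percent != 100)
    stop_input("coverage_percent must lie in [70, 85] (or be 100)")
  if (coverage_percent %% 5 != 0) {
    warning("coverage ", coverage_percent,
            "% is not a multiple of 5; rounding down")
    coverage_percent <- 5 * floor(coverage_percent / 5)
  }
  seq.int(5L, as.integer(coverage_percent), by = 5L)
}

#' Estimate a full cytocochleogram from a hair-cell map
#'
#' Runs the frame-sampling estimator over every 5% sector of the map and
#' assembles the per-sector densities and coefficients of error into a
#' `cochleogram`, attaching a frequency axis (characteristic frequency of
#' each sector midpoint under the place map).
#'
#' @param map A `hair_cell_map`.
#' @param design A [sampling_design()].
#' @param params A [cochlea_params()]; defaults to the map's own.
#' @param place_map A [place_frequency_map()].
#' @param seed Master seed for frame placement; one child seed is derived
#'   per sector.
#' @return A `cochleogram`: data.frame `sector`, `class`, `sum_q`,
#'   `sum_a_um2`, `n_a_per_1000um2`, `ce`, `freq_khz`, with the coverage
#'   and place map as attributes.
#' @export
estimate_cochleogram <- function(map, design = sampling_design(),
                                 params = attr(map, "params"),
                                 place_map = place_frequency_map(),
                                 seed = design$seed) {
  bins <- sector_bins(params$coverage_percent)
  seeds <- derive_seeds(seed, length(bins))
  rows <- lapply(seq_along(bins), function(i) {
    sub <- render_sector_substrate(map, bins[i], params)
    estimate_sector(sub, design, seed = seeds[i])
  })
  cg <- do.call(rbind, rows)
  cg$freq_khz <- percent_to_frequency(cg$sector - 2.5, place_map)
  structure(cg, coverage_percent = params$coverage_percent,
            place_map = place_map,
            class = c("cochleogram", "data.frame"))
}

#' Mean densities over the apical, middle and basal regions
#'
#' Sectors are grouped into the three standard regions (apical 5-25%,
#' middle 30-55%, basal 60-80%). The pooled CE per region is the
#' root-mean-square of the sector CEs weighted by their counts.
#'
#' @param cochleogram A `cochleogram` containing sectors 5-80.
#' @return data.frame: `region`, `class`, `mean_n_a`, `pooled_ce`,
#'   `n_sectors`.
#' @export
region_means <- function(cochleogram) {
  regions <- list(apical = seq(5, 25, 5), middle = seq(30, 55, 5),
                  basal = seq(60, 80, 5))
  need <- unlist(regions)
  missing <- setdiff(need, unique(cochleogram$sector))
  if (length(missing) > 0)
    stop_input("cochleogram is missing sectors: ",
               paste(missing, collapse = ", "))
  out <- list()
  for (rg in names(regions)) {
    for (cls in unique(cochleogram$class)) {
      sub <- cochleogram[cochleogram$sector %in% regions[[rg]] &
                           cochleogram$class == cls, ]
      ok <- !is.na(sub$ce) & sub$sum_q > 0
      pooled <- if (any(ok))
        sqrt(stats::weighted.mean(sub$ce[ok]^2, sub$sum_q[ok]))
      else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        region = rg, class = cls, mean_n_a = mean(sub$n_a_per_1000um2),
        pooled_ce = pooled, n_sectors = nrow(sub), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Per-sector percent loss relative to a control cochleogram
#'
#' `100 * (1 - n_a / n_a_control)`, clipped to `[0, 100]`. Sectors whose
#' control density is zero are returned as `NA` and flagged in the
#' `control_zero` column.
#'
#' @param cochleogram,control `cochleogram`s over the same sector set.
#' @return data.frame: `sector`, `class`, `percent_loss`, `control_zero`.
#' @export
percent_loss <- function(cochleogram, control) {
  key <- function(cg) paste(cg$sector, cg$class)
  if (!setequal(key(cochleogram), key(control)))
    stop_input("sector/class sets of the two cochleograms differ")
  ctrl <- control[match(key(cochleogram), key(control)), ]
  zero <- ctrl$n_a_per_1000um2 == 0
  loss <- 100 * (1 - cochleogram$n_a_per_1000um2 / ctrl$n_a_per_1000um2)
  loss <- pmin(pmax(loss, 0), 100)
  loss[zero] <- NA_real_
  data.frame(sector = cochleogram$sector, class = cochleogram$class,
             percent_loss = loss, control_zero = zero,
             stringsAsFactors = FALSE)
}

#' Write / read a cochleogram as CSV
#' @param cochleogram A `cochleogram`.
#' @param path CSV path.
#' @return `path` (write) or a `cochleogram` (read).
#' @export
write_cochleogram_csv <- function(cochleogram, path) {
  utils::write.csv(as.data.frame(cochleogram), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cochleogram_csv
#' @export
read_cochleogram_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(df, class = c("cochleogram", "data.frame"))
}

#' Plot a cytocochleogram
#'
#' Per-class density against percent distance from the apex, one panel
#' per class, in the style of a percentage cytocochleogram figure.
#'
#' @param cochleogram A `cochleogram` (or several row-bound together with
#'   a `group` column).
#' @return A ggplot object.
#' @export
plot_cochleogram <- function(cochleogram) {
  df <- as.data.frame(cochleogram)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$sector,
                                        y = .data$n_a_per_1000um2))
  if ("group" %in% names(df))
    p <- p + ggplot2::aes(colour = .data$group)
  p +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~class, scales = "free_y") +
    ggplot2::labs(x = "distance from apex (%)",
                  y = expression(N[A] ~ "(bundles / 1000" ~ mu * m^2 * ")"))
}
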