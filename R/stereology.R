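#' Frame-sampling design for stereological counting
#'
#' Unbiased counting frames are placed on the stereociliary fringe by
#' systematic-uniform-random sampling: the sector length is split into
#' `frames_per_sector` equal subintervals, one frame per subinterval at a
#' common random offset; laterally each frame is jittered uniformly about
#' the fringe midline. Frames never overlap.
#'
#' @param frame_width,frame_height Frame dimensions in um (default 25x25).
#' @param frames_per_sector Frames per 5% sector; at least 2 (the
#'   coefficient of error needs replicate frames). Default 5.
#' @param ce_correction Logical; if `TRUE` (default) the coefficient of
#'   error carries Cochran's `n/(n-1)` finite-sample factor (the ratio
#'   estimator's textbook form). `FALSE` gives the bare quadratic form.
#' @param seed Integer seed used when placing frames.
#' @return A `sampling_design` object.
#' @export
sampling_design <- function(frame_width = 25, frame_height = 25,
                            frames_per_sector = 5, ce_correction = TRUE,
                            seed = 1) {
  if (frame_width <= 0 || frame_height <= 0)
    stop_input("frame dimensions must be positive")
  if (frames_per_sector < 2)
    stop_input("frames_per_sector must be >= 2 (CE needs replicates)")
  structure(
    list(frame_width = frame_width, frame_height = frame_height,
         frames_per_sector = frames_per_sector,
         ce_correction = ce_correction, seed = as.integer(seed)),
    class = "sampling_design")
}

#' Place counting frames on a sector substrate
#'
#' @param substrate A `sampling_substrate` from [render_sector_substrate()].
#' @param design A [sampling_design()].
#' @param seed Seed for the placement (defaults to the design's).
#' @return data.frame with one row per frame: `x0`, `y0`, `width`, `height`
#'   (um, frame origin at lower-left).
#' @export
place_frames <- function(substrate, design, seed = design$seed) {
  L <- substrate$length_um
  n <- design$frames_per_sector
  fw <- design$frame_width
  fh <- design$frame_height
  if (L < n * fw)
    stop_input("sector of ", L, " um cannot hold ", n,
               " non-overlapping frames of ", fw, " um")
  if (fh > substrate$fringe_width)
    stop_input("frame height exceeds the fringe width")
  period <- L / n
  half_jitter <- (substrate$fringe_width - fh) / 2
  placement <- withr::with_seed(as.integer(seed), {
    u <- stats::runif(1, 0, period - fw)
    jit <- stats::runif(n, -half_jitter, half_jitter)
    list(u = u, jit = jit)
  })
  x0 <- (seq_len(n) - 1) * period + placement$u
  y0 <- substrate$fringe_width / 2 - fh / 2 + placement$jit
  data.frame(x0 = x0, y0 = y0, width = fw, height = fh)
}

#' Count bundles in one unbiased frame
#'
#' Gundersen edge rule: a bundle point is counted if it lies strictly
#' inside the frame or on the inclusion edges (top and right), and not on
#' the exclusion edges (bottom and left): `x0 < x <= x0+w`,
#' `y0 < y <= y0+h`. `corner_hits` is the number of the four frame
#' corners lying inside the fringe rectangle (closed), the test points of
#' the corner-count reference-area estimator.
#'
#' @param frame One row of [place_frames()] output (list or data.frame row).
#' @param substrate The `sampling_substrate` the frame sits on.
#' @return A list: `q` (named counts per cell class, `OHC` and `IHC`),
#'   `corner_hits` (0-4).
#' @export
count_frame <- function(frame, substrate) {
  pts <- substrate$points
  inside <- pts$x_um > frame$x0 & pts$x_um <= frame$x0 + frame$width &
    pts$y_um > frame$y0 & pts$y_um <= frame$y0 + frame$height
  q <- c(OHC = sum(inside & pts$class == "OHC"),
         IHC = sum(inside & pts$class == "IHC"))
  cx <- c(frame$x0, frame$x0 + frame$width, frame$x0, frame$x0 + frame$width)
  cy <- c(frame$y0, frame$y0, frame$y0 + frame$height, frame$y0 + frame$height)
  hits <- sum(cx >= 0 & cx <= substrate$length_um &
                cy >= 0 & cy <= substrate$fringe_width)
  list(q = q, corner_hits = as.integer(hits))
}

#' Reference area sampled by a set of frames
#'
#' Corner point counting with area-per-point equal to a quarter of the
#' frame area: `sum(corner_hits) * frame_area / 4`.
#'
#' @param counted A data.frame with columns `corner_hits`, `width`,
#'   `height` (one row per frame).
#' @return Sampled area in um^2.
#' @export
sampled_area <- function(counted) {
  if (nrow(counted) < 1) stop_input("need at least one frame")
  sum(counted$corner_hits * counted$width * counted$height / 4)
}

#' Areal density N_A from summed counts and sampled area
#'
#' `N_A = sum_q * 1000 / sum_a`, in bundles per 1000 um^2.
#'
#' @param sum_q Total bundles counted.
#' @param sum_a Total sampled reference area, um^2; must be positive.
#' @return Density in bundles per 1000 um^2.
#' @export
density_na <- function(sum_q, sum_a) {
  if (sum_a <= 0)
    stop_input("sampled area is zero: density undefined for this sector")
  sum_q * 1000 / sum_a
}

#' Cochran ratio-estimator coefficient of error
#'
#' For per-frame counts `q_i` and areas `a_i`, the squared CE is
#' `sum(q^2)/sum(q)^2 + sum(a^2)/sum(a)^2 - 2*sum(q*a)/(sum(q)*sum(a))`,
#' floored at zero before the square root; with `correction = TRUE` it is
#' multiplied by `n/(n-1)`, which makes it identical to the classical
#' ratio-estimator error (sample variances and covariance over `n`) and
#' is the variant whose expectation tracks `1/sqrt(n*m)` for Poisson
#' counts of mean `m`.
#'
#' @param q Per-frame counts for one cell class.
#' @param a Per-frame sampled areas (um^2).
#' @param correction Apply the `n/(n-1)` factor (default `FALSE`: the bare
#'   quadratic form; estimation via [estimate_sector()] uses the design's
#'   `ce_correction`, default `TRUE`).
#' @return The CE, or `NA` (with attribute `reason`) when `sum(q)` or
#'   `sum(a)` is zero, where the ratio estimate has no defined error.
#' @export
coefficient_of_error <- function(q, a, correction = FALSE) {
  if (length(q) < 2 || length(q) != length(a))
    stop_input("need per-frame q and a of equal length >= 2")
  if (sum(q) == 0 || sum(a) == 0)
    return(structure(NA_real_, reason = "zero total count or area"))
  v <- sum(q^2) / sum(q)^2 + sum(a^2) / sum(a)^2 -
    2 * sum(q * a) / (sum(q) * sum(a))
  if (correction) v <- v * length(q) / (length(q) - 1)
  sqrt(max(v, 0))
}

#' Estimate densities and CE for one sector
#'
#' Orchestrates [place_frames()], [count_frame()], [sampled_area()],
#' [density_na()] and [coefficient_of_error()]. The same frames (hence the
#' same reference area) serve both cell classes.
#'
#' @param substrate A `sampling_substrate`.
#' @param design A [sampling_design()].
#' @param seed Placement seed (defaults to the design's).
#' @return data.frame with one row per class (`OHC`, `IHC`): `sector`,
#'   `class`, `sum_q`, `sum_a_um2`, `n_a_per_1000um2`, `ce`.
#' @export
estimate_sector <- function(substrate, design, seed = design$seed) {
  frames <- place_frames(substrate, design, seed)
  counts <- lapply(seq_len(nrow(frames)), function(i)
    count_frame(frames[i, ], substrate))
  frames$corner_hits <- vapply(counts, `[[`, integer(1), "corner_hits")
  q_ohc <- vapply(counts, function(ct) ct$q[["OHC"]], numeric(1))
  q_ihc <- vapply(counts, function(ct) ct$q[["IHC"]], numeric(1))
  a_i <- frames$corner_hits * frames$width * frames$height / 4
  sum_a <- sampled_area(frames)
  one <- function(cls, q) {
    data.frame(
      sector = substrate$sector, class = cls, sum_q = sum(q),
      sum_a_um2 = sum_a,
      n_a_per_1000um2 = if (sum_a > 0) density_na(sum(q), sum_a) else NA_real_,
      ce = as.numeric(coefficient_of_error(q, a_i,
                                           correction = design$ce_correction)),
      stringsAsFactors = FALSE)
  }
  rbind(one("OHC", q_ohc), one("IHC", q_ihc))
}
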