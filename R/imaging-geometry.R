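#' Rotational volume of an axially symmetric cell profile
#'
#' The cell is segmented along its long axis into slices of equal height
#' with one radius per slice boundary interval. Consecutive equal radii
#' contribute a cylinder `pi r^2 h`; a radius change contributes a cylinder
#' of the smaller radius plus the cone completing the difference,
#' `(1/3) pi (r_max^2 - r_min^2) h` (a terminal taper to zero is thus a pure
#' cone). The total is the sum over segments.
#'
#' @param radii Non-negative radii in nm, one per axial slice boundary.
#' @param slice_height Axial slice height in nm.
#' @return Volume in cubic micrometres.
#' @export
rotational_volume <- function(radii, slice_height) {
  if (any(radii < 0)) stop("radii must be non-negative", call. = FALSE)
  stopifnot_scalar(slice_height, "slice_height", positive = TRUE)
  if (length(radii) < 1) stop("need at least one slice", call. = FALSE)
  if (length(radii) == 1) return(pi * radii^2 * slice_height / 1e9)
  v <- 0
  for (k in seq_len(length(radii) - 1L)) {
    r1 <- radii[k]; r2 <- radii[k + 1L]
    rmin <- min(r1, r2); rmax <- max(r1, r2)
    v <- v + pi * rmin^2 * slice_height +
      (1 / 3) * pi * (rmax^2 - rmin^2) * slice_height
  }
  v / 1e9
}

#' Average rotational volume over a tilt series
#'
#' The per-image volumes of a tilt series are averaged to damp manual
#' segmentation error and deviations from rotational symmetry.
#'
#' @param profiles List of radius vectors (nm), one per tilt image.
#' @param slice_height Axial slice height in nm.
#' @return Mean volume in cubic micrometres.
#' @export
tilt_series_volume <- function(profiles, slice_height) {
  mean(vapply(profiles, rotational_volume, 1, slice_height = slice_height))
}

#' Relative locus distance from reference-point measurements
#'
#' Locus-to-locus distances measured against a fixed cellular reference
#' point (e.g. a polar organelle) are converted to distances relative to
#' the closest locus by subtracting its median reference distance; the
#' difference may be negative and is reported as-is.
#'
#' @param median_locus_ref Median locus-to-reference distance, nm (>= 0).
#' @param median_anchor_ref Median anchor-locus-to-reference distance, nm.
#' @return Difference in nm.
#' @export
fish_relative_distance <- function(median_locus_ref, median_anchor_ref) {
  if (any(median_locus_ref < 0) || any(median_anchor_ref < 0)) {
    stop("median distances must be non-negative", call. = FALSE)
  }
  median_locus_ref - median_anchor_ref
}

#' Correlation between model-derived and imaging-derived locus distances
#'
#' @param model_medians,imaging_medians Equal-length numeric vectors of
#'   median distances (>= 3 pairs).
#' @return Pearson correlation coefficient.
#' @export
model_imaging_correlation <- function(model_medians, imaging_medians) {
  if (length(model_medians) != length(imaging_medians) || length(model_medians) < 3) {
    stop("need equal-length vectors of at least 3 medians", call. = FALSE)
  }
  if (stats::sd(model_medians) == 0 || stats::sd(imaging_medians) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  stats::cor(model_medians, imaging_medians)
}
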