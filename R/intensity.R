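#' Percent of pixels carrying signal above a black cutoff
#'
#' Coverage quantification for stain channels: the percentage of pixels
#' whose intensity exceeds the black cutoff, i.e.
#' `100 - 100 * #(pixels <= cutoff) / total`. The cutoff is explicit
#' configuration (the original choice was made visually from a histogram
#' legend).
#'
#' @param raster Numeric matrix.
#' @param black_cutoff Intensity at or below which a pixel counts as black.
#' @return Percentage in `[0, 100]`.
#' @examples
#' coverage_fraction(matrix(c(0, 0, 1, 1), 2), 0)  # 50
#' @export
coverage_fraction <- function(raster, black_cutoff = 0) {
  stopifnot(is.matrix(raster))
  100 - 100 * sum(raster <= black_cutoff) / length(raster)
}

#' Partition pixels into empty / low- / high-intensity bins
#'
#' Heatmap-style binning: empty pixels are exactly index 0 (excluded from
#' the low bin), low are in `(0, split_index]`, high above `split_index`.
#' The split index stands in for the display lookup-table boundary and is
#' explicit configuration. The three bins always sum to the pixel count.
#'
#' @param raster Numeric matrix of intensity indices (0 = empty).
#' @param split_index Upper edge of the low-intensity bin (0 < split < max).
#' @return Tibble `low_px`, `high_px`, `empty_px`, `total_px`.
#' @export
intensity_bins <- function(raster, split_index) {
  stopifnot(is.matrix(raster), split_index > 0)
  empty <- sum(raster == 0)
  low <- sum(raster > 0 & raster <= split_index)
  high <- sum(raster > split_index)
  tibble(low_px = low, high_px = high, empty_px = empty,
         total_px = length(raster))
}

#' Puncta metrics normalized to the control-group mean
#'
#' Thresholds each raster, extracts particles ([extract_components()] with
#' the 0-to-Inf area defaults), and reports per-image punctum count and
#' total punctum area, each divided by the corresponding control-group
#' mean; the normalized control mean is 1 by construction.
#'
#' @param test_rasters,control_rasters Lists of numeric matrices.
#' @param threshold Fixed intensity threshold applied to every raster.
#' @param px_size_um Micrometers per pixel.
#' @return Tibble with one row per image: `group`, `image`, `n_puncta`,
#'   `puncta_area_um2`, `norm_n_puncta`, `norm_area`.
#' @export
puncta_metrics_normalized <- function(test_rasters, control_rasters,
                                      threshold, px_size_um = 1) {
  stopifnot(length(control_rasters) >= 1)
  one <- function(r) {
    comp <- extract_components(r >= threshold, px_size_um)
    c(n = nrow(comp), area = sum(comp$area_um2))
  }
  ctl <- t(vapply(control_rasters, one, c(n = 0, area = 0)))
  tst <- if (length(test_rasters) > 0)
    t(vapply(test_rasters, one, c(n = 0, area = 0)))
  else matrix(numeric(0), 0, 2, dimnames = list(NULL, c("n", "area")))
  mean_n <- mean(ctl[, "n"]); mean_a <- mean(ctl[, "area"])
  if (mean_n == 0 || mean_a == 0)
    abort("control-group mean is zero: normalization undefined")
  mk <- function(m, grp) tibble(
    group = grp, image = seq_len(nrow(m)),
    n_puncta = unname(m[, "n"]), puncta_area_um2 = unname(m[, "area"]),
    norm_n_puncta = unname(m[, "n"]) / mean_n,
    norm_area = unname(m[, "area"]) / mean_a)
  bind_rows(mk(ctl, "control"), mk(tst, "test"))
}
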