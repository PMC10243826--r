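#' Specify a synthetic en face field
#'
#' A `field_spec` bundles every parameter of the synthetic en face generator:
#' field geometry, endothelial cell (EC) tessellation size, HIEL density and
#' diameters, the placement mechanism relative to a signaling hub, and marker
#' punctum occupancies. Defaults emulate a third-order mesenteric artery
#' region of interest: ~50 fully in-view ECs and 9.83 HIEL per EC.
#'
#' @param width_um,height_um Field extent in micrometers.
#' @param px_size_um Raster calibration, micrometers per pixel.
#' @param n_cells Number of ECs tiling the field.
#' @param hiel_per_cell Mean HIEL per EC (dimensionless rate).
#' @param hiel_diam_range_um Length-2 numeric, low/high HIEL diameter in
#'   micrometers. The published work reports diameters only in supplementary
#'   material, so this range is a configuration choice.
#' @param placement_mode One of `"RAND"` (uniform, the complete-spatial-
#'   randomness null), `"PC"` (positive control: every HIEL center within
#'   1 micrometer of the hub mask), `"NC"` (negative control: every center
#'   between 1.5 and 4.5 micrometers of the hub).
#' @param hub_kind Which structure acts as the signaling hub: `"nuclei"`,
#'   `"ER"`, or `"junctions"`.
#' @param marker_occupancy Named numeric vector of marker -> fraction of HIEL
#'   carrying at least one punctum of that marker (e.g.
#'   `c(PS = 0.138, Kir2.1 = 0.05)`).
#' @param pairwise_cooccupancy Optional tibble/data frame with columns
#'   `marker_a`, `marker_b`, `conditional` giving P(B-positive | A-positive)
#'   per HIEL. Marginals in `marker_occupancy` are preserved by compensating
#'   the draw on A-negative HIEL.
#' @param count_model `"fixed"` realizes exactly `round(n_cells *
#'   hiel_per_cell)` HIEL (sharper envelopes); `"poisson"` draws the count.
#' @param pc_band_um,nc_band_um Distance bands (micrometers) for the PC and NC
#'   mechanisms.
#' @param noise_sd Additive Gaussian noise s.d. used by [render_field()].
#' @param background_puncta Extra non-MEJ puncta per marker (count; default 0:
#'   only the MEJ-resident fraction is modeled).
#' @param seed Integer seed making the whole field reproducible.
#'
#' @return An object of class `field_spec` (a named list).
#' @examples
#' spec <- field_spec(n_cells = 10, seed = 1)
#' spec$hiel_per_cell
#' @export
field_spec <- function(width_um = 200,
                       height_um = 200,
                       px_size_um = 0.5,
                       n_cells = 50,
                       hiel_per_cell = 9.83,
                       hiel_diam_range_um = c(0.5, 2.5),
                       placement_mode = c("RAND", "PC", "NC"),
                       hub_kind = c("nuclei", "ER", "junctions"),
                       marker_occupancy = c(PS = 0.138),
                       pairwise_cooccupancy = NULL,
                       count_model = c("fixed", "poisson"),
                       pc_band_um = c(0, 1.0),
                       nc_band_um = c(1.5, 4.5),
                       noise_sd = 0.05,
                       background_puncta = 0,
                       seed = 1L) {
  placement_mode <- match.arg(placement_mode)
  hub_kind <- match.arg(hub_kind)
  count_model <- match.arg(count_model)

  stopifnot(is.numeric(width_um), width_um > 0,
            is.numeric(height_um), height_um > 0,
            is.numeric(px_size_um), px_size_um > 0,
            n_cells >= 1,
            hiel_per_cell >= 0,
            length(hiel_diam_range_um) == 2)
  if (hiel_diam_range_um[1] > hiel_diam_range_um[2])
    abort("hiel_diam_range_um must be ordered low <= high")
  if (any(marker_occupancy < 0 | marker_occupancy > 1))
    abort("marker occupancies must lie in [0, 1]")
  if (is.null(names(marker_occupancy)) && length(marker_occupancy) > 0)
    abort("marker_occupancy must be a named vector")
  if (!is.null(pairwise_cooccupancy)) {
    pairwise_cooccupancy <- tibble::as_tibble(pairwise_cooccupancy)
    stopifnot(all(c("marker_a", "marker_b", "conditional") %in%
                    names(pairwise_cooccupancy)))
    if (any(pairwise_cooccupancy$conditional < 0 |
              pairwise_cooccupancy$conditional > 1))
      abort("conditional co-occupancies must lie in [0, 1]")
  }

  structure(list(
    width_um = width_um, height_um = height_um, px_size_um = px_size_um,
    n_cells = as.integer(n_cells), hiel_per_cell = hiel_per_cell,
    hiel_diam_range_um = as.numeric(hiel_diam_range_um),
    placement_mode = placement_mode, hub_kind = hub_kind,
    marker_occupancy = marker_occupancy,
    pairwise_cooccupancy = pairwise_cooccupancy,
    count_model = count_model,
    pc_band_um = as.numeric(pc_band_um), nc_band_um = as.numeric(nc_band_um),
    noise_sd = noise_sd, background_puncta = background_puncta,
    seed = as.integer(seed)
  ), class = "field_spec")
}

#' @export
print.field_spec <- function(x, ...) {
  cat("<field_spec> ", x$width_um, "x", x$height_um, " um @ ",
      x$px_size_um, " um/px; ", x$n_cells, " cells; ",
      x$hiel_per_cell, " HIEL/cell (", x$placement_mode, " vs ",
      x$hub_kind, "); seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Construct a calibrated multi-channel raster
#'
#' A `field_frame` holds one en face region of interest as a named list of
#' equally shaped intensity matrices plus the micrometer-per-pixel
#' calibration. Pixel (1,1) is the top-left corner; the center of pixel
#' (row i, col j) sits at `x = (j - 0.5) * px_size_um`,
#' `y = (i - 0.5) * px_size_um`.
#'
#' @param channels Named list of numeric matrices, all the same dimension.
#' @param px_size_um Micrometers per pixel (> 0).
#' @return A `field_frame` object.
#' @export
field_frame <- function(channels, px_size_um) {
  stopifnot(is.list(channels), length(channels) > 0,
            !is.null(names(channels)), px_size_um > 0)
  dims <- lapply(channels, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1)
    abort("all channels must share the same dimensions")
  structure(list(channels = channels, px_size_um = px_size_um),
            class = "field_frame")
}

#' @export
print.field_frame <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("<field_frame> ", d[1], "x", d[2], " px @ ", x$px_size_um,
      " um/px; channels: ", paste(names(x$channels), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# pixel-center coordinate helpers (1-based row/col <-> um)
px_center_x <- function(col, px) (col - 0.5) * px
px_center_y <- function(row, px) (row - 0.5) * px
um_to_row <- function(y, px, nr) pmin(pmax(ceiling(y / px), 1L), nr)
um_to_col <- function(x, px, nc) pmin(pmax(ceiling(x / px), 1L), nc)

new_hiel_set <- function(x_um, y_um, diameter_um, provenance) {
  n <- length(x_um)
  tibble(
    id = seq_len(n),
    x_um = as.numeric(x_um), y_um = as.numeric(y_um),
    diameter_um = as.numeric(diameter_um),
    area_um2 = pi * (as.numeric(diameter_um) / 2)^2,
    provenance = rep(provenance, length.out = max(n, 0))
  )
}
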