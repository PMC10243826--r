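#' Assign marker puncta to HIEL by the 0.75 micrometer center rule
#'
#' A punctum belongs to an HIEL when its center lies within `radius_um` of
#' the HIEL center (boundary inclusive). Each punctum is assigned to at most
#' one HIEL: the nearest one, with exact distance ties broken by the lowest
#' `hiel_id`. Deterministic.
#'
#' @param puncta Puncta tibble (`id`, `marker`, `x_um`, `y_um`, ...).
#' @param hiels HIEL tibble (`id`, `x_um`, `y_um`, ...).
#' @param radius_um Assignment radius, default 0.75.
#' @return Tibble `punctum_id`, `marker`, `hiel_id` (NA if unassigned),
#'   `dist_um` (distance to the nearest HIEL).
#' @examples
#' h <- tibble::tibble(id = 1:2, x_um = c(0, 10), y_um = 0)
#' p <- tibble::tibble(id = 1, marker = "PS", x_um = 0.5, y_um = 0)
#' assign_puncta(p, h)
#' @export
assign_puncta <- function(puncta, hiels, radius_um = 0.75) {
  stopifnot(radius_um > 0)
  if (nrow(puncta) == 0)
    return(tibble(punctum_id = integer(), marker = character(),
                  hiel_id = integer(), dist_um = numeric()))
  if (nrow(hiels) == 0)
    return(tibble(punctum_id = puncta$id, marker = puncta$marker,
                  hiel_id = NA_integer_, dist_um = NA_real_))

  ord <- order(hiels$id)              # lowest id wins exact ties
  hx <- hiels$x_um[ord]; hy <- hiels$y_um[ord]; hid <- hiels$id[ord]
  nearest_id <- integer(nrow(puncta))
  nearest_d <- numeric(nrow(puncta))
  for (p in seq_len(nrow(puncta))) {
    d2 <- (hx - puncta$x_um[p])^2 + (hy - puncta$y_um[p])^2
    k <- which.min(d2)                # first (lowest id) minimum
    nearest_id[p] <- hid[k]
    nearest_d[p] <- sqrt(d2[k])
  }
  assigned <- nearest_d <= radius_um
  tibble(punctum_id = puncta$id, marker = puncta$marker,
         hiel_id = ifelse(assigned, nearest_id, NA_integer_),
         dist_um = nearest_d)
}

#' Fraction of HIEL (MEJs) occupied by a marker
#'
#' Percentage of HIEL carrying at least one assigned punctum of `marker`,
#' with the underlying counts (k of N).
#'
#' @param hiels HIEL tibble (non-empty).
#' @param assignments Output of [assign_puncta()].
#' @param marker Marker name.
#' @return Tibble with `marker`, `k`, `n`, `occupancy_pct`.
#' @export
occupancy <- function(hiels, assignments, marker) {
  if (nrow(hiels) == 0)
    abort("occupancy is undefined for an empty HIEL set")
  hit <- unique(assignments$hiel_id[assignments$marker == marker &
                                      !is.na(assignments$hiel_id)])
  k <- sum(hiels$id %in% hit)
  tibble(marker = marker, k = k, n = nrow(hiels),
         occupancy_pct = 100 * k / nrow(hiels))
}

#' Per-EC statistics of marker-positive MEJs
#'
#' Counts marker-positive HIEL per endothelial cell (fully in-view cells
#' only, per the `in_view` flag) and reports the overall mean per EC, the
#' fraction of ECs with at least one, and the conditional mean over those
#' ECs. The identity `overall_mean = conditional_mean * fraction_with_1plus`
#' holds exactly on any dataset.
#'
#' @param tess A `field_tessellation` (cells + label raster).
#' @param hiels HIEL tibble.
#' @param assignments Output of [assign_puncta()].
#' @param marker Marker name.
#' @return Tibble with `marker`, `n_ec`, `mean_per_ec`, `frac_ec_pos`,
#'   `conditional_mean` (NA with a warning when no EC is positive), plus a
#'   `per_ec` attribute carrying the per-cell counts.
#' @export
per_ec_stats <- function(tess, hiels, assignments, marker) {
  cells <- tess$cells[tess$cells$in_view, ]
  if (nrow(cells) == 0) abort("no fully in-view cells")
  pos_hiel <- unique(assignments$hiel_id[assignments$marker == marker &
                                           !is.na(assignments$hiel_id)])
  sub <- hiels[hiels$id %in% pos_hiel, ]
  lab <- tess$labels; px <- tess$px_size_um
  cell <- if (nrow(sub) > 0)
    lab[cbind(um_to_row(sub$y_um, px, nrow(lab)),
              um_to_col(sub$x_um, px, ncol(lab)))] else integer(0)
  counts <- tabulate(cell[cell %in% cells$cell_id],
                     nbins = max(tess$cells$cell_id))
  counts <- counts[cells$cell_id]
  overall <- mean(counts)
  frac <- mean(counts >= 1)
  cond <- if (frac > 0) overall / frac else {
    warn("no EC carries a marker-positive MEJ: conditional mean undefined")
    NA_real_
  }
  out <- tibble(marker = marker, n_ec = nrow(cells),
                mean_per_ec = overall, frac_ec_pos = frac,
                conditional_mean = cond)
  attr(out, "per_ec") <- tibble(cell_id = cells$cell_id, n_pos = counts)
  out
}

#' Pairwise marker co-occupancy at MEJs
#'
#' Of the HIEL positive for `marker_a`, the percentage also positive for
#' `marker_b` (direction matters: A is the conditioning marker).
#'
#' @param hiels HIEL tibble.
#' @param assignments Output of [assign_puncta()].
#' @param marker_a,marker_b Marker names.
#' @return Tibble `marker_a`, `marker_b`, `k` (A-and-B), `n` (A-positive),
#'   `cooccupancy_pct`.
#' @export
cooccupancy <- function(hiels, assignments, marker_a, marker_b) {
  pos <- function(m) unique(assignments$hiel_id[assignments$marker == m &
                                                  !is.na(assignments$hiel_id)])
  a <- intersect(pos(marker_a), hiels$id)
  if (length(a) == 0)
    abort(sprintf("no HIEL positive for %s: co-occupancy undefined",
                  marker_a))
  b <- pos(marker_b)
  k <- length(intersect(a, b))
  tibble(marker_a = marker_a, marker_b = marker_b,
         k = k, n = length(a), cooccupancy_pct = 100 * k / length(a))
}
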