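#' Tessellate a field into endothelial cells and build hub masks
#'
#' Generates a seeded Voronoi tessellation of the field emulating the
#' cobblestone EC monolayer seen en face, and rasterized masks for the three
#' kinds of signaling hub: one nuclear ellipse per cell, a perinuclear
#' endoplasmic-reticulum annulus, and interendothelial junctions (the
#' rasterized cell borders, including the field frame). The tessellation is
#' stored as a label raster; every pixel belongs to exactly one cell, so cell
#' areas sum to the field area exactly.
#'
#' @param spec A [field_spec()].
#' @return A `field_tessellation`: list with `labels` (integer matrix),
#'   `cells` (tibble: `cell_id`, `seed_x_um`, `seed_y_um`, `centroid_x_um`,
#'   `centroid_y_um`, `area_um2`, `in_view`), `masks` (named list of logical
#'   matrices `nuclei`, `ER`, `junctions`), and `px_size_um`.
#' @examples
#' tess <- generate_tessellation(field_spec(n_cells = 5, seed = 2))
#' nrow(tess$cells)
#' @export
generate_tessellation <- function(spec) {
  stopifnot(inherits(spec, "field_spec"))
  px <- spec$px_size_um
  nr <- max(1L, round(spec$height_um / px))
  nc <- max(1L, round(spec$width_um / px))
  if (spec$n_cells > nr * nc)
    abort("field too small to host n_cells cells at this pixel size")

  set.seed(spec$seed)
  sx <- runif(spec$n_cells, 0, spec$width_um)
  sy <- runif(spec$n_cells, 0, spec$height_um)

  xc <- px_center_x(seq_len(nc), px)
  yc <- px_center_y(seq_len(nr), px)
  X <- matrix(rep(xc, each = nr), nr, nc)
  Y <- matrix(rep(yc, times = nc), nr, nc)

  label_of <- function(sx, sy) {
    best <- matrix(Inf, nr, nc)
    lab <- matrix(1L, nr, nc)
    for (k in seq_along(sx)) {
      d2 <- (X - sx[k])^2 + (Y - sy[k])^2
      upd <- d2 < best
      best[upd] <- d2[upd]
      lab[upd] <- k
    }
    lab
  }
  labels <- label_of(sx, sy)
  # re-draw seeds whose cell rasterized to zero pixels (possible only at
  # extreme crowding)
  for (try in 1:100) {
    missing <- setdiff(seq_len(spec$n_cells), unique(as.integer(labels)))
    if (length(missing) == 0) break
    sx[missing] <- runif(length(missing), 0, spec$width_um)
    sy[missing] <- runif(length(missing), 0, spec$height_um)
    labels <- label_of(sx, sy)
  }
  if (length(setdiff(seq_len(spec$n_cells), unique(as.integer(labels)))) > 0)
    abort("field too small to host n_cells non-empty cells")

  areas_px <- tabulate(as.integer(labels), nbins = spec$n_cells)
  centroid_x <- vapply(seq_len(spec$n_cells),
                       function(k) mean(X[labels == k]), 0)
  centroid_y <- vapply(seq_len(spec$n_cells),
                       function(k) mean(Y[labels == k]), 0)

  cells <- tibble(
    cell_id = seq_len(spec$n_cells),
    seed_x_um = sx, seed_y_um = sy,
    centroid_x_um = centroid_x, centroid_y_um = centroid_y,
    area_um2 = areas_px * px^2,
    in_view = TRUE
  )

  masks <- build_hub_masks(labels, cells, px)

  structure(list(labels = labels, cells = cells, masks = masks,
                 px_size_um = px,
                 width_um = spec$width_um, height_um = spec$height_um),
            class = "field_tessellation")
}

# Nuclei: one ellipse per cell at the cell centroid, random orientation,
# clipped to the cell's own pixels. ER: annulus within er_reach_um of the
# nuclear mask, excluding it. Junctions: pixels adjacent to a different
# label or on the field frame (one-polygon fields get the frame only).
build_hub_masks <- function(labels, cells, px,
                            nucleus_ab_um = c(3.5, 2.5),
                            er_reach_um = 2) {
  nr <- nrow(labels); nc <- ncol(labels)
  xc <- px_center_x(seq_len(nc), px)
  yc <- px_center_y(seq_len(nr), px)
  X <- matrix(rep(xc, each = nr), nr, nc)
  Y <- matrix(rep(yc, times = nc), nr, nc)

  theta <- runif(nrow(cells), 0, pi)
  nuclei <- matrix(FALSE, nr, nc)
  a <- nucleus_ab_um[1]; b <- nucleus_ab_um[2]
  for (k in seq_len(nrow(cells))) {
    dx <- X - cells$centroid_x_um[k]
    dy <- Y - cells$centroid_y_um[k]
    u <- dx * cos(theta[k]) + dy * sin(theta[k])
    v <- -dx * sin(theta[k]) + dy * cos(theta[k])
    inside <- ((u / a)^2 + (v / b)^2 <= 1) & (labels == k)
    nuclei <- nuclei | inside
  }

  d_nuc <- mask_edt(nuclei, px)
  er <- d_nuc > 0 & d_nuc <= er_reach_um

  junctions <- matrix(FALSE, nr, nc)
  junctions[1, ] <- TRUE; junctions[nr, ] <- TRUE
  junctions[, 1] <- TRUE; junctions[, nc] <- TRUE
  if (nr > 1) {
    diff_v <- labels[-1, , drop = FALSE] != labels[-nr, , drop = FALSE]
    junctions[-1, ][diff_v] <- TRUE
    junctions[-nr, ][diff_v] <- TRUE
  }
  if (nc > 1) {
    diff_h <- labels[, -1, drop = FALSE] != labels[, -nc, drop = FALSE]
    junctions[, -1][diff_h] <- TRUE
    junctions[, -nc][diff_h] <- TRUE
  }

  list(nuclei = nuclei, ER = er, junctions = junctions)
}

#' Look up the hub mask of a tessellation
#'
#' @param tess A `field_tessellation`.
#' @param kind `"nuclei"`, `"ER"`, or `"junctions"`.
#' @return Logical matrix.
#' @export
hub_mask <- function(tess, kind = c("nuclei", "ER", "junctions")) {
  kind <- match.arg(kind)
  tess$masks[[kind]]
}
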