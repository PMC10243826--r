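#' Place HIEL in a field under a chosen spatial mechanism
#'
#' Realizes HIEL centers and diameters under one of three mechanisms:
#' `RAND` scatters centers uniformly over the field (complete spatial
#' randomness); `PC` places every center within 1 micrometer of the hub mask
#' (positive control); `NC` places every center between 1.5 and 4.5
#' micrometers of the hub (negative control). PC/NC centers are drawn
#' uniformly among the pixel centers whose exact distance to the hub lies in
#' the band, which guarantees the band constraint element-wise. Diameters are
#' uniform over `spec$hiel_diam_range_um`.
#'
#' @param spec A [field_spec()].
#' @param hub_mask Logical matrix; required for PC/NC (defaults to the
#'   tessellation's `spec$hub_kind` mask when `tess` is given).
#' @param tess Optional [generate_tessellation()] output.
#' @return A HIEL tibble: `id`, `x_um`, `y_um`, `diameter_um`, `area_um2`,
#'   `provenance` (= the placement mode).
#' @export
generate_hiel <- function(spec, hub_mask = NULL, tess = NULL) {
  stopifnot(inherits(spec, "field_spec"))
  if (is.null(hub_mask) && !is.null(tess))
    hub_mask <- hub_mask(tess, spec$hub_kind)
  set.seed(spec$seed + 1L)

  lambda <- spec$n_cells * spec$hiel_per_cell
  n <- if (spec$count_model == "fixed") as.integer(round(lambda))
       else rpois(1, lambda)
  if (n == 0) return(new_hiel_set(numeric(), numeric(), numeric(),
                                  character()))

  dr <- spec$hiel_diam_range_um
  diam <- runif(n, dr[1], dr[2])

  if (spec$placement_mode == "RAND") {
    x <- runif(n, 0, spec$width_um)
    y <- runif(n, 0, spec$height_um)
  } else {
    if (is.null(hub_mask) || !any(hub_mask))
      abort("PC/NC placement requires a non-empty hub mask")
    band <- if (spec$placement_mode == "PC") spec$pc_band_um
            else spec$nc_band_um
    px <- spec$px_size_um
    d <- mask_edt(hub_mask, px)
    eligible <- which(d >= band[1] & d <= band[2])
    if (length(eligible) == 0)
      abort(sprintf("no pixel lies in the %s distance band [%g, %g] um",
                    spec$placement_mode, band[1], band[2]))
    pick <- eligible[sample.int(length(eligible), n, replace = TRUE)]
    rc <- arrayInd(pick, dim(hub_mask))
    x <- px_center_x(rc[, 2], px)
    y <- px_center_y(rc[, 1], px)
  }
  new_hiel_set(x, y, diam, spec$placement_mode)
}

#' Place marker puncta on HIEL with set occupancies
#'
#' Each marker occupies each HIEL independently with probability
#' `spec$marker_occupancy[marker]`; a punctum is then placed inside half the
#' assignment radius of its HIEL center so that downstream assignment
#' recovers it. Pairwise co-occupancies (P(B | A) per HIEL) are honored by
#' conditional draws on A-positive HIEL, with the draw on A-negative HIEL
#' compensated so the marginal of B is preserved. Optional background
#' (non-MEJ) puncta are scattered uniformly.
#'
#' @param spec A [field_spec()].
#' @param hiel_true HIEL tibble from [generate_hiel()].
#' @param radius_um Assignment radius (default 0.75 micrometers).
#' @param punctum_diam_um Rendered punctum diameter.
#' @return Puncta tibble: `id`, `marker`, `x_um`, `y_um`, `area_um2`,
#'   `hiel_id` (NA for background puncta).
#' @export
generate_puncta <- function(spec, hiel_true, radius_um = 0.75,
                            punctum_diam_um = 0.4) {
  stopifnot(inherits(spec, "field_spec"))
  set.seed(spec$seed + 2L)
  markers <- names(spec$marker_occupancy)
  n <- nrow(hiel_true)

  presence <- list()
  pairs <- spec$pairwise_cooccupancy
  conditioned <- if (!is.null(pairs)) pairs$marker_b else character()
  if (anyDuplicated(conditioned))
    abort("each marker may appear as marker_b in at most one pair")

  for (m in setdiff(markers, conditioned)) {
    presence[[m]] <- runif(n) < spec$marker_occupancy[[m]]
  }
  if (!is.null(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      a <- pairs$marker_a[r]; b <- pairs$marker_b[r]
      cond <- pairs$conditional[r]
      if (!a %in% names(presence))
        abort(sprintf("marker_a '%s' must have an unconditional occupancy", a))
      occ_a <- spec$marker_occupancy[[a]]
      occ_b <- spec$marker_occupancy[[b]]
      joint <- occ_a * cond
      if (joint > occ_b + 1e-12)
        abort(sprintf(
          "inconsistent co-occupancy: joint %s&%s (%.4f) exceeds marginal %s (%.4f)",
          a, b, joint, b, occ_b))
      p0 <- if (occ_a >= 1) 0 else (occ_b - joint) / (1 - occ_a)
      if (p0 > 1 + 1e-12)
        abort("inconsistent co-occupancy: compensated fraction exceeds 1")
      p0 <- min(max(p0, 0), 1)
      pa <- presence[[a]]
      presence[[b]] <- ifelse(pa, runif(n) < cond, runif(n) < p0)
    }
  }

  out <- list()
  for (m in markers) {
    pos <- which(presence[[m]])
    k <- length(pos)
    if (k > 0) {
      ang <- runif(k, 0, 2 * pi)
      rad <- sqrt(runif(k)) * (radius_um / 2)
      out[[m]] <- tibble(
        marker = m,
        x_um = hiel_true$x_um[pos] + rad * cos(ang),
        y_um = hiel_true$y_um[pos] + rad * sin(ang),
        area_um2 = pi * (punctum_diam_um / 2)^2,
        hiel_id = hiel_true$id[pos]
      )
    }
    if (spec$background_puncta > 0) {
      nb <- spec$background_puncta
      out[[paste0(m, "_bg")]] <- tibble(
        marker = m,
        x_um = runif(nb, 0, spec$width_um),
        y_um = runif(nb, 0, spec$height_um),
        area_um2 = pi * (punctum_diam_um / 2)^2,
        hiel_id = NA_integer_
      )
    }
  }
  res <- if (length(out)) bind_rows(out) else
    tibble(marker = character(), x_um = numeric(), y_um = numeric(),
           area_um2 = numeric(), hiel_id = integer())
  res$id <- seq_len(nrow(res))
  select(res, "id", "marker", "x_um", "y_um", "area_um2", "hiel_id")
}

#' Generate a complete synthetic en face field with ground truth
#'
#' One-call wrapper: tessellation, hub mask of `spec$hub_kind`, HIEL under
#' `spec$placement_mode`, and marker puncta. Fully deterministic for a fixed
#' `spec$seed`.
#'
#' @param spec A [field_spec()].
#' @return An `en_face_field` list: `spec`, `tess`, `hub` (logical matrix),
#'   `hiel`, `puncta`.
#' @examples
#' f <- synthesize_field(field_spec(n_cells = 4, hiel_per_cell = 3, seed = 7))
#' nrow(f$hiel)
#' @export
synthesize_field <- function(spec) {
  tess <- generate_tessellation(spec)
  hub <- hub_mask(tess, spec$hub_kind)
  hiel <- generate_hiel(spec, hub_mask = hub, tess = tess)
  puncta <- generate_puncta(spec, hiel)
  structure(list(spec = spec, tess = tess, hub = hub,
                 hiel = hiel, puncta = puncta),
            class = "en_face_field")
}

#' @export
print.en_face_field <- function(x, ...) {
  cat("<en_face_field> ", nrow(x$hiel), " HIEL (", x$spec$placement_mode,
      " vs ", x$spec$hub_kind, "), ", nrow(x$puncta), " puncta, ",
      x$spec$n_cells, " cells; seed ", x$spec$seed, "\n", sep = "")
  invisible(x)
}

# Add Gaussian blobs of amplitude 1 at (x, y) um into a raster.
add_blobs <- function(img, x_um, y_um, sigma_um, px) {
  nr <- nrow(img); nc <- ncol(img)
  for (k in seq_along(x_um)) {
    s <- sigma_um[k]
    w <- ceiling(3 * s / px)
    i0 <- um_to_row(y_um[k], px, nr); j0 <- um_to_col(x_um[k], px, nc)
    ri <- max(1L, i0 - w):min(nr, i0 + w)
    ci <- max(1L, j0 - w):min(nc, j0 + w)
    dy <- px_center_y(ri, px) - y_um[k]
    dx <- px_center_x(ci, px) - x_um[k]
    g <- exp(-outer(dy^2, dx^2, "+") / (2 * s^2))
    img[ri, ci] <- img[ri, ci] + g
  }
  img
}

#' Render a synthetic field to a multi-channel raster
#'
#' Produces one intensity channel per structure: Gaussian blobs at HIEL
#' centers (sigma tied to HIEL diameter) and at each marker's puncta, plus
#' the hub structure masks at fixed intensity. Additive Gaussian noise at
#' `spec$noise_sd` is applied to every channel. Bit-identical for a fixed
#' seed.
#'
#' @param field An `en_face_field` from [synthesize_field()].
#' @param blob_sigma_floor_um Lower bound on blob sigma so that sub-pixel
#'   structures still render above threshold.
#' @return A [field_frame()].
#' @export
render_field <- function(field, blob_sigma_floor_um = 0.35) {
  spec <- field$spec
  px <- spec$px_size_um
  nr <- nrow(field$tess$labels); nc <- ncol(field$tess$labels)
  set.seed(spec$seed + 3L)

  ch <- list()
  hiel_img <- matrix(0, nr, nc)
  if (nrow(field$hiel) > 0) {
    sig <- pmax(field$hiel$diameter_um / 4, blob_sigma_floor_um)
    hiel_img <- add_blobs(hiel_img, field$hiel$x_um, field$hiel$y_um, sig, px)
  }
  ch$hiel <- hiel_img
  for (m in unique(field$puncta$marker)) {
    pm <- field$puncta[field$puncta$marker == m, ]
    img <- matrix(0, nr, nc)
    if (nrow(pm) > 0)
      img <- add_blobs(img, pm$x_um, pm$y_um,
                       rep(blob_sigma_floor_um, nrow(pm)), px)
    ch[[m]] <- img
  }
  for (hk in names(field$tess$masks))
    ch[[hk]] <- field$tess$masks[[hk]] * 0.8

  if (spec$noise_sd > 0) {
    for (i in seq_along(ch))
      ch[[i]] <- ch[[i]] + matrix(rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
  }
  field_frame(ch, px)
}

#' Write a synthetic field bundle to disk
#'
#' Writes the rendered multi-channel raster as TIFF, the ground-truth HIEL
#' and puncta point tables as CSV, the hub masks as PNG, and an echo of the
#' generating parameters as JSON. Outputs are byte-stable for a fixed spec.
#'
#' @param field An `en_face_field`.
#' @param dir Output directory (created if missing).
#' @param frame Optional pre-rendered [field_frame()]; rendered if omitted.
#' @return Invisibly, the vector of files written.
#' @export
write_field <- function(field, dir, frame = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(frame)) frame <- render_field(field)
  files <- c()

  tif <- file.path(dir, "field.tiff")
  imgs <- lapply(frame$channels, function(m) {
    m <- (m - min(m)) / max(max(m) - min(m), 1e-12)
    t(m)  # writeTIFF expects row-major display orientation
  })
  tiff::writeTIFF(imgs, tif, bits.per.sample = 16L)
  files <- c(files, tif)

  hcsv <- file.path(dir, "hiel.csv")
  readr::write_csv(field$hiel, hcsv)
  pcsv <- file.path(dir, "puncta.csv")
  readr::write_csv(field$puncta, pcsv)
  ccsv <- file.path(dir, "cells.csv")
  readr::write_csv(field$tess$cells, ccsv)
  files <- c(files, hcsv, pcsv, ccsv)

  for (hk in names(field$tess$masks)) {
    p <- file.path(dir, paste0("mask_", hk, ".png"))
    png::writePNG(field$tess$masks[[hk]] * 1, p)
    files <- c(files, p)
  }

  sj <- file.path(dir, "spec.json")
  spec_list <- field$spec
  class(spec_list) <- NULL
  spec_list$pairwise_cooccupancy <-
    if (!is.null(spec_list$pairwise_cooccupancy))
      as.data.frame(spec_list$pairwise_cooccupancy)
  jsonlite::write_json(spec_list, sj, auto_unbox = TRUE, digits = NA,
                       null = "null")
  files <- c(files, sj)
  invisible(files)
}
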