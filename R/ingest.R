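#' Threshold one channel of a field frame
#'
#' Mirrors the per-channel customized thresholding of the original detection
#' stage. Three methods: `fixed` (absolute cutoff), `otsu` (bimodal
#' histogram split), `percentile` (keep the brightest `100 - p` percent of
#' pixels). An optional QC overlay (original intensities with the mask
#' marked) can be written as PNG, mirroring the visual confirmation step.
#'
#' @param frame A [field_frame()].
#' @param channel Channel name.
#' @param method `"fixed"`, `"otsu"`, or `"percentile"`.
#' @param value Cutoff for `fixed`, percentile (0-100) for `percentile`.
#' @param invert Detect dark structures (mask = below threshold), e.g. HIEL
#'   as holes in the hydrazide channel.
#' @param qc_png Optional path for a QC overlay image.
#' @return Logical matrix (the mask).
#' @export
threshold_channel <- function(frame, channel,
                              method = c("fixed", "otsu", "percentile"),
                              value = NULL, invert = FALSE, qc_png = NULL) {
  method <- match.arg(method)
  if (!channel %in% names(frame$channels))
    abort(sprintf("channel '%s' not found", channel))
  img <- frame$channels[[channel]]
  rng <- range(img)

  thr <- switch(method,
    fixed = {
      if (is.null(value)) abort("fixed thresholding needs `value`")
      value
    },
    otsu = {
      if (diff(rng) < .Machine$double.eps)
        abort("flat image: Otsu threshold is degenerate")
      EBImage::otsu(EBImage::Image(img), range = rng, levels = 256L)
    },
    percentile = {
      if (is.null(value)) abort("percentile thresholding needs `value`")
      stats::quantile(img, value / 100, names = FALSE, type = 1)
    })

  mask <- if (invert) img < thr else img >= thr
  if (!is.null(qc_png)) {
    norm <- (img - rng[1]) / max(diff(rng), 1e-12)
    overlay <- array(0, c(nrow(img), ncol(img), 3))
    overlay[, , 1] <- pmin(1, norm + 0.5 * mask)
    overlay[, , 2] <- norm
    overlay[, , 3] <- norm
    png::writePNG(overlay, qc_png)
  }
  mask
}

# union-find merge of diagonally touching 4-connected labels -> 8-connectivity
merge_diagonal <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  if (nr < 2 || nc < 2) return(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc])))   # down-left
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs) == 0) return(lab)
  nmax <- max(lab)
  parent <- seq_len(nmax)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in seq_len(nrow(pairs))) {
    a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(nmax), find, 0L)
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Extract connected components as a particle table
#'
#' Labels the mask (8-connectivity by default, 4 optional), computes per-
#' component centroid (micrometers, pixel-center convention), pixel area, and
#' the equivalent-circle diameter `2 * sqrt(area / pi)`, and filters by an
#' area band (defaults 0 to Inf, i.e. keep everything).
#'
#' @param mask Logical matrix.
#' @param px_size_um Micrometers per pixel.
#' @param min_area_um2,max_area_um2 Area filter in square micrometers.
#' @param connectivity 8 (default) or 4.
#' @param marker Optional marker name attached to each record.
#' @return Tibble: `id`, `marker`, `x_um`, `y_um`, `area_um2`,
#'   `diameter_um`, `n_px`.
#' @examples
#' m <- matrix(FALSE, 8, 8); m[2:3, 2:3] <- TRUE
#' extract_components(m, px_size_um = 1)
#' @export
extract_components <- function(mask, px_size_um,
                               min_area_um2 = 0, max_area_um2 = Inf,
                               connectivity = 8, marker = NA_character_) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  mask <- mask != 0
  empty <- tibble(id = integer(), marker = character(),
                  x_um = numeric(), y_um = numeric(), area_um2 = numeric(),
                  diameter_um = numeric(), n_px = integer())
  if (!any(mask)) return(empty)

  lab <- matrix(as.integer(EBImage::imageData(
    EBImage::bwlabel(EBImage::Image(mask * 1)))), nrow(mask), ncol(mask))
  if (connectivity == 8) lab <- merge_diagonal(lab)

  idx <- which(lab > 0, arr.ind = TRUE)
  l <- lab[lab > 0]
  px <- px_size_um
  npx <- tabulate(l)
  sx <- vapply(split(px_center_x(idx[, 2], px), l), mean, 0)
  sy <- vapply(split(px_center_y(idx[, 1], px), l), mean, 0)
  area <- npx * px^2
  out <- tibble(
    id = seq_along(npx), marker = marker,
    x_um = unname(sx), y_um = unname(sy),
    area_um2 = area, diameter_um = 2 * sqrt(area / pi), n_px = npx
  )
  out <- out[out$area_um2 >= min_area_um2 & out$area_um2 <= max_area_um2, ]
  out$id <- seq_len(nrow(out))
  out
}

#' Read a multi-channel TIFF as a field frame
#'
#' @param path TIFF path (all directory entries read as channels).
#' @param px_size_um Calibration in micrometers per pixel.
#' @param channel_names Optional names; defaults to `ch1`, `ch2`, ...
#' @return A [field_frame()].
#' @export
read_field_tiff <- function(path, px_size_um, channel_names = NULL) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(imgs)) imgs <- list(imgs)
  imgs <- lapply(imgs, function(m) {
    if (length(dim(m)) == 3) m <- m[, , 1]
    t(m)  # undo the display-orientation transpose used on write
  })
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_along(imgs))
  names(imgs) <- channel_names
  field_frame(imgs, px_size_um)
}

#' Write or read a point table (HIEL or puncta records) as CSV
#'
#' The on-disk schema is `id, marker_or_provenance, x_um, y_um, diameter_um,
#' area_um2`; missing columns are filled with NA on write and preserved on
#' read.
#'
#' @param points Tibble of HIEL or puncta records.
#' @param path CSV path.
#' @return `write_point_table` returns `path` invisibly; `read_point_table`
#'   the tibble.
#' @export
write_point_table <- function(points, path) {
  lab <- if ("provenance" %in% names(points)) points$provenance
         else if ("marker" %in% names(points)) points$marker
         else NA_character_
  out <- tibble(
    id = points$id,
    marker_or_provenance = lab,
    x_um = points$x_um, y_um = points$y_um,
    diameter_um = if ("diameter_um" %in% names(points)) points$diameter_um
                  else NA_real_,
    area_um2 = if ("area_um2" %in% names(points)) points$area_um2
               else NA_real_
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_point_table
#' @export
read_point_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
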