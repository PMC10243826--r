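#' Exact Euclidean distance transform of a mask
#'
#' Distance (in micrometers) from every pixel center to the nearest foreground
#' (`TRUE`) pixel center, computed with the exact Euclidean distance transform.
#' Foreground pixels map to 0.
#'
#' @param mask Logical matrix; at least one `TRUE` pixel.
#' @param px_size_um Micrometers per pixel.
#' @return Numeric matrix of distances in micrometers.
#' @export
mask_edt <- function(mask, px_size_um = 1) {
  stopifnot(is.matrix(mask))
  mask <- mask != 0
  if (!any(mask)) return(matrix(Inf, nrow(mask), ncol(mask)))
  if (all(mask)) return(matrix(0, nrow(mask), ncol(mask)))
  # distmap(x) gives, for each non-zero pixel of x, the distance to the
  # nearest zero pixel; feed it the complement so zeros are the hub.
  dm <- EBImage::distmap(EBImage::Image(1 - mask), metric = "euclidean")
  matrix(EBImage::imageData(dm), nrow(mask), ncol(mask)) * px_size_um
}

#' Minimum distance of each HIEL center to a hub mask
#'
#' The core statistic of the spatial-pattern analysis: for every HIEL center
#' (in micrometer coordinates) the exact Euclidean distance to the nearest
#' foreground pixel center of the hub mask. Distances are computed by an exact
#' distance transform followed by a windowed exact scan, so the result equals
#' a brute-force search over every foreground pixel.
#'
#' @param hiels Tibble with columns `id`, `x_um`, `y_um`, and optionally
#'   `provenance` (copied to the `group` column).
#' @param hub_mask Logical matrix, non-empty.
#' @param px_size_um Micrometers per pixel.
#' @param group Optional group label overriding `provenance`.
#' @return Tibble with columns `hiel_id`, `group`, `min_dist_um`.
#' @examples
#' m <- matrix(FALSE, 10, 10); m[1, 1] <- TRUE
#' pts <- tibble::tibble(id = 1, x_um = 3.5, y_um = 4.5)
#' min_distances(pts, m, px_size_um = 1)  # 5 um from pixel center (0.5, 0.5)
#' @export
min_distances <- function(hiels, hub_mask, px_size_um, group = NULL) {
  stopifnot(is.matrix(hub_mask))
  hub_mask <- hub_mask != 0
  if (!any(hub_mask)) abort("hub mask is empty: minimum distance undefined")
  if (nrow(hiels) == 0) {
    return(tibble(hiel_id = integer(), group = character(),
                  min_dist_um = numeric()))
  }
  px <- px_size_um
  nr <- nrow(hub_mask); nc <- ncol(hub_mask)
  edt_px <- mask_edt(hub_mask, 1)

  grp <- if (!is.null(group)) rep(group, nrow(hiels))
         else if ("provenance" %in% names(hiels)) as.character(hiels$provenance)
         else rep("REAL", nrow(hiels))

  xs <- hiels$x_um / px
  ys <- hiels$y_um / px
  out <- numeric(nrow(hiels))
  for (p in seq_len(nrow(hiels))) {
    i <- min(max(ceiling(ys[p]), 1L), nr)
    j <- min(max(ceiling(xs[p]), 1L), nc)
    off <- sqrt((xs[p] - (j - 0.5))^2 + (ys[p] - (i - 0.5))^2)
    if (off < 1e-9) {                 # point at a pixel center: EDT is exact
      out[p] <- edt_px[i, j]
      next
    }
    ub <- edt_px[i, j] + off          # upper bound on the true distance (px)
    w <- ceiling(ub) + 1L
    ri <- max(1L, i - w):min(nr, i + w)
    ci <- max(1L, j - w):min(nc, j + w)
    sub <- hub_mask[ri, ci, drop = FALSE]
    idx <- which(sub, arr.ind = TRUE)
    dyy <- (ri[idx[, 1]] - 0.5) - ys[p]
    dxx <- (ci[idx[, 2]] - 0.5) - xs[p]
    out[p] <- sqrt(min(dxx^2 + dyy^2))
  }
  tibble(hiel_id = hiels$id, group = grp, min_dist_um = out * px)
}
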