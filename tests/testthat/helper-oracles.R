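# Independent brute-force oracles used to validate the fast implementations.

# Exhaustive all-pairs scan: distance from each point (um) to the nearest
# foreground pixel center.
oracle_min_dist <- function(x_um, y_um, mask, px) {
  fg <- which(mask, arr.ind = TRUE)
  fx <- (fg[, 2] - 0.5) * px
  fy <- (fg[, 1] - 0.5) * px
  vapply(seq_along(x_um), function(p)
    sqrt(min((fx - x_um[p])^2 + (fy - y_um[p])^2)), 0)
}

# Breadth-first flood-fill labeling at 4 or 8 connectivity.
oracle_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 8)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  cur <- 0L
  for (s in which(mask)) {
    si <- (s - 1L) %% nr + 1L; sj <- (s - 1L) %/% nr + 1L
    if (lab[si, sj] > 0L) next
    cur <- cur + 1L
    queue <- matrix(c(si, sj), 1)
    lab[si, sj] <- cur
    while (nrow(queue) > 0) {
      q <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (k in seq_len(nrow(nb))) {
        i <- q[1] + nb[k, 1]; j <- q[2] + nb[k, 2]
        if (i >= 1 && i <= nr && j >= 1 && j <= nc &&
            mask[i, j] && lab[i, j] == 0L) {
          lab[i, j] <- cur
          queue <- rbind(queue, c(i, j))
        }
      }
    }
  }
  lab
}

new_hiel_set_for_test <- function() {
  tibble::tibble(id = 1:4, x_um = c(1, 2.5, 7, 9), y_um = c(2, 8, 3, 9),
                 diameter_um = c(1, 1.5, 2, 0.8),
                 area_um2 = pi * (c(1, 1.5, 2, 0.8) / 2)^2,
                 provenance = "observed")
}

# A small field spec used across tests (fast to synthesize).
small_spec <- function(...) {
  args <- list(width_um = 60, height_um = 60, px_size_um = 0.5,
               n_cells = 6, hiel_per_cell = 6)
  over <- list(...)
  args[names(over)] <- over
  do.call(field_spec, args)
}
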