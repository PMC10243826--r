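#' Configuration for placement-envelope simulations
#'
#' Controls the Monte Carlo envelopes run against an observed HIEL set:
#' number of replicates, the PC/NC distance bands, and the seed. Each
#' replicate matches the observed HIEL count. Following the original
#' analysis, PC/NC replicates use the mean observed diameter for every
#' simulated HIEL, while RAND draws diameters uniformly within the observed
#' range.
#'
#' @param n_replicates Replicates per group (default 100).
#' @param pc_band_um,nc_band_um PC and NC distance bands in micrometers.
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_replicates = 100, pc_band_um = c(0, 1.0),
                       nc_band_um = c(1.5, 4.5), seed = 1L) {
  stopifnot(n_replicates >= 1)
  if (pc_band_um[2] > nc_band_um[1])
    abort("PC and NC bands must not overlap")
  structure(list(n_replicates = as.integer(n_replicates),
                 pc_band_um = as.numeric(pc_band_um),
                 nc_band_um = as.numeric(nc_band_um),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate placement-envelope replicates for an observed HIEL set
#'
#' Generates `cfg$n_replicates` simulated HIEL sets of the same size as the
#' observed set under the requested mechanism. `PC` centers lie within the
#' PC band of the hub, `NC` within the NC band (both guaranteed element-wise
#' by sampling pixel centers whose exact hub distance is in band), `RAND`
#' uniformly over the field with diameters uniform over the observed range.
#'
#' @param group `"PC"`, `"NC"`, or `"RAND"`.
#' @param hub_mask Logical matrix (required, non-empty, for PC/NC).
#' @param observed Observed HIEL tibble (supplies count, mean diameter, and
#'   diameter range).
#' @param cfg A [sim_config()].
#' @param px_size_um Micrometers per pixel of `hub_mask`.
#' @param width_um,height_um Field extent; defaults to the mask extent.
#' @return Tibble of simulated HIEL with columns of [generate_hiel()] plus
#'   `replicate`.
#' @export
simulate_hiel <- function(group = c("PC", "NC", "RAND"), hub_mask, observed,
                          cfg = sim_config(), px_size_um,
                          width_um = ncol(hub_mask) * px_size_um,
                          height_um = nrow(hub_mask) * px_size_um) {
  group <- match.arg(group)
  if (nrow(observed) == 0)
    abort("observed HIEL set is empty: nothing to match")
  n <- nrow(observed)
  set.seed(cfg$seed)

  if (group %in% c("PC", "NC")) {
    if (missing(hub_mask) || is.null(hub_mask) || !any(hub_mask != 0))
      abort("PC/NC simulation requires a non-empty hub mask")
    band <- if (group == "PC") cfg$pc_band_um else cfg$nc_band_um
    d <- mask_edt(hub_mask != 0, px_size_um)
    eligible <- which(d >= band[1] & d <= band[2])
    if (length(eligible) == 0)
      abort(sprintf(
        "distance band [%g, %g] um unreachable on this hub mask", band[1],
        band[2]))
    mean_diam <- mean(observed$diameter_um)
    reps <- lapply(seq_len(cfg$n_replicates), function(r) {
      pick <- eligible[sample.int(length(eligible), n, replace = TRUE)]
      rc <- arrayInd(pick, dim(hub_mask))
      h <- new_hiel_set(px_center_x(rc[, 2], px_size_um),
                       px_center_y(rc[, 1], px_size_um),
                       rep(mean_diam, n), group)
      h$replicate <- r
      h
    })
  } else {
    dr <- range(observed$diameter_um)
    reps <- lapply(seq_len(cfg$n_replicates), function(r) {
      h <- new_hiel_set(runif(n, 0, width_um), runif(n, 0, height_um),
                        runif(n, dr[1], dr[2]), "RAND")
      h$replicate <- r
      h
    })
  }
  bind_rows(reps)
}

#' Pooled envelope distances for all three simulation groups
#'
#' Convenience wrapper running [simulate_hiel()] for PC, NC, and RAND and
#' computing hub distances for the observed set and every replicate.
#' Distances from all replicates of a group are pooled into that group's
#' sample, matching single-box-plot-per-group reporting.
#'
#' @inheritParams simulate_hiel
#' @param observed Observed HIEL tibble (group label becomes `REAL`).
#' @return Tibble `hiel_id`, `group` (REAL/PC/NC/RAND), `min_dist_um`.
#' @export
envelope_distances <- function(observed, hub_mask, cfg = sim_config(),
                               px_size_um,
                               width_um = ncol(hub_mask) * px_size_um,
                               height_um = nrow(hub_mask) * px_size_um) {
  real <- min_distances(observed, hub_mask, px_size_um, group = "REAL")
  sims <- lapply(c("PC", "NC", "RAND"), function(g) {
    cfg_g <- cfg
    cfg_g$seed <- cfg$seed + match(g, c("PC", "NC", "RAND"))
    s <- simulate_hiel(g, hub_mask, observed, cfg_g, px_size_um,
                       width_um, height_um)
    min_distances(s, hub_mask, px_size_um, group = g)
  })
  bind_rows(c(list(real), sims))
}
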