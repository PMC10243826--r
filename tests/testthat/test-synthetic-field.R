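test_that("a single-cell tessellation covers the field and its border mask is the frame", {
  spec <- field_spec(width_um = 20, height_um = 20, px_size_um = 1,
                     n_cells = 1, seed = 1)
  tess <- generate_tessellation(spec)
  expect_true(all(tess$labels == 1L))
  expect_equal(tess$cells$area_um2, 400)
  jm <- hub_mask(tess, "junctions")
  frame <- matrix(FALSE, 20, 20)
  frame[1, ] <- frame[20, ] <- frame[, 1] <- frame[, 20] <- TRUE
  expect_identical(jm, frame)
})

test_that("tessellation is deterministic and cell areas sum to the field area", {
  spec <- field_spec(n_cells = 50, seed = 5)
  t1 <- generate_tessellation(spec)
  t2 <- generate_tessellation(spec)
  expect_identical(t1$labels, t2$labels)
  expect_identical(t1$cells, t2$cells)
  # pixel-count oracle over the label raster
  px_counts <- table(factor(t1$labels, levels = 1:50))
  expect_equal(unname(as.numeric(px_counts)) * spec$px_size_um^2,
               t1$cells$area_um2)
  expect_equal(sum(t1$cells$area_um2), spec$width_um * spec$height_um)
})

test_that("tessellation refuses fields too small for the requested cells", {
  expect_error(
    generate_tessellation(field_spec(width_um = 2, height_um = 2,
                                     px_size_um = 1, n_cells = 10)),
    "too small")
})

test_that("PC placement keeps every center within 1 um of the hub", {
  spec <- small_spec(placement_mode = "PC", hub_kind = "nuclei", seed = 2)
  tess <- generate_tessellation(spec)
  hub <- hub_mask(tess, "nuclei")
  h <- generate_hiel(spec, hub)
  d <- min_distances(h, hub, spec$px_size_um)
  expect_true(all(d$min_dist_um <= 1.0))
  expect_equal(unique(h$provenance), "PC")
})

test_that("NC placement keeps every center in the 1.5-4.5 um band", {
  spec <- small_spec(placement_mode = "NC", hub_kind = "nuclei", seed = 3)
  tess <- generate_tessellation(spec)
  hub <- hub_mask(tess, "nuclei")
  d <- min_distances(generate_hiel(spec, hub), hub, spec$px_size_um)
  expect_true(all(d$min_dist_um >= 1.5 & d$min_dist_um <= 4.5))
})

test_that("a zero HIEL rate yields an empty set and PC needs a hub", {
  spec <- small_spec(hiel_per_cell = 0, seed = 1)
  expect_equal(nrow(generate_hiel(spec)), 0)
  spec_pc <- small_spec(placement_mode = "PC", seed = 1)
  expect_error(generate_hiel(spec_pc, hub_mask = matrix(FALSE, 10, 10)),
               "hub mask")
})

test_that("RAND centers are 2-D uniform (chi-square on a 4x4 grid)", {
  spec <- field_spec(n_cells = 50, hiel_per_cell = 200, seed = 17)  # 10,000
  h <- generate_hiel(spec)
  expect_equal(nrow(h), 10000)
  bx <- cut(h$x_um, breaks = seq(0, spec$width_um, length.out = 5))
  by <- cut(h$y_um, breaks = seq(0, spec$height_um, length.out = 5))
  cs <- suppressWarnings(chisq.test(table(bx, by)))
  expect_gt(cs$p.value, 0.01)
  expect_true(all(h$diameter_um >= spec$hiel_diam_range_um[1] &
                    h$diameter_um <= spec$hiel_diam_range_um[2]))
})

test_that("puncta occupancy is recovered within 3 binomial SE at large n", {
  spec <- field_spec(n_cells = 50, hiel_per_cell = 100,   # 5,000 HIEL
                     marker_occupancy = c(PS = 0.138), seed = 23)
  h <- generate_hiel(spec)
  p <- generate_puncta(spec, h)
  occ <- length(unique(p$hiel_id[p$marker == "PS"])) / nrow(h)
  se <- sqrt(0.138 * (1 - 0.138) / nrow(h))
  expect_lt(abs(occ - 0.138), 3 * se)
  # every generated MEJ punctum lies within the assignment radius of its HIEL
  d <- sqrt((p$x_um - h$x_um[p$hiel_id])^2 + (p$y_um - h$y_um[p$hiel_id])^2)
  expect_true(all(d <= 0.75))
})

test_that("zero occupancy gives no puncta; inconsistent joints error", {
  spec <- small_spec(marker_occupancy = c(PS = 0), seed = 4)
  h <- generate_hiel(spec)
  expect_equal(nrow(generate_puncta(spec, h)), 0)
  bad <- small_spec(
    marker_occupancy = c(A = 0.5, B = 0.1),
    pairwise_cooccupancy = data.frame(marker_a = "A", marker_b = "B",
                                      conditional = 0.9),
    seed = 4)
  expect_error(generate_puncta(bad, h), "exceeds marginal")
})

test_that("occupancy estimates tighten as 1/sqrt(n)", {
  occ_err <- function(n_per_cell, seed) {
    spec <- field_spec(n_cells = 50, hiel_per_cell = n_per_cell,
                       marker_occupancy = c(PS = 0.3), seed = seed)
    h <- generate_hiel(spec)
    p <- generate_puncta(spec, h)
    abs(length(unique(p$hiel_id)) / nrow(h) - 0.3)
  }
  e_small <- mean(vapply(1:5, function(s) occ_err(2, s), 0))      # n = 100
  e_large <- mean(vapply(1:5, function(s) occ_err(200, s), 0))    # n = 10^4
  expect_lt(e_large, e_small)  # error shrinks with n
  expect_lt(e_large, 3 * sqrt(0.3 * 0.7 / 10000) * 2)
})

test_that("rendering is bit-identical under a fixed seed and detectable without noise", {
  spec <- field_spec(width_um = 30, height_um = 30, n_cells = 2,
                     hiel_per_cell = 0.5, noise_sd = 0, seed = 6)
  f <- synthesize_field(spec)
  expect_equal(nrow(f$hiel), 1)
  fr1 <- render_field(f)
  fr2 <- render_field(f)
  expect_identical(fr1$channels, fr2$channels)
  m <- threshold_channel(fr1, "hiel", method = "fixed", value = 0.5)
  expect_equal(nrow(extract_components(m, spec$px_size_um)), 1)
})

test_that("detect-after-render recovers at least 95% of 500 HIEL at default SNR", {
  spec <- field_spec(n_cells = 50, hiel_per_cell = 10, seed = 42)
  f <- synthesize_field(spec)
  fr <- render_field(f)
  comp <- extract_components(
    threshold_channel(fr, "hiel", method = "fixed", value = 0.5),
    spec$px_size_um)
  # greedy matching of truth to detections within 0.5 um
  used <- rep(FALSE, nrow(comp))
  matched <- 0
  for (k in seq_len(nrow(f$hiel))) {
    d2 <- (comp$x_um - f$hiel$x_um[k])^2 + (comp$y_um - f$hiel$y_um[k])^2
    d2[used] <- Inf
    j <- which.min(d2)
    if (length(j) == 1 && d2[j] <= 0.25) { matched <- matched + 1; used[j] <- TRUE }
  }
  expect_gte(matched, 475)
})

test_that("a field bundle writes and reads back consistently", {
  dir <- withr::local_tempdir()
  spec <- small_spec(seed = 8)
  f <- synthesize_field(spec)
  write_field(f, dir)
  expect_true(all(file.exists(file.path(
    dir, c("field.tiff", "hiel.csv", "puncta.csv", "cells.csv",
           "mask_nuclei.png", "spec.json")))))
  h <- read_point_table(file.path(dir, "hiel.csv"))
  expect_equal(nrow(h), nrow(f$hiel))
  expect_equal(h$x_um, f$hiel$x_um)
  m <- png::readPNG(file.path(dir, "mask_nuclei.png")) > 0.5
  expect_identical(m, hub_mask(f$tess, "nuclei"))
  fr <- read_field_tiff(file.path(dir, "field.tiff"), spec$px_size_um)
  expect_equal(dim(fr$channels[[1]]), dim(f$tess$labels))
})
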