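test_that("the 0.75 um assignment boundary is inclusive and exact", {
  h <- tibble::tibble(id = 1L, x_um = 0, y_um = 0)
  mk <- function(d) tibble::tibble(id = 1L, marker = "PS", x_um = d, y_um = 0)
  expect_equal(assign_puncta(mk(0), h)$hiel_id, 1L)
  expect_equal(assign_puncta(mk(0.74), h)$hiel_id, 1L)
  expect_equal(assign_puncta(mk(0.75), h)$hiel_id, 1L)   # boundary inclusive
  expect_true(is.na(assign_puncta(mk(0.76), h)$hiel_id))
})

test_that("equidistant puncta go to the lowest HIEL id and assignment is a function", {
  h <- tibble::tibble(id = c(7L, 3L), x_um = c(1, 0), y_um = 0)
  p <- tibble::tibble(id = 1L, marker = "PS", x_um = 0.5, y_um = 0)
  asn <- assign_puncta(p, h, radius_um = 0.75)
  expect_equal(asn$hiel_id, 3L)
  # exhaustive nearest-neighbor check with the tie rule on random sets
  set.seed(3)
  h2 <- tibble::tibble(id = sample(1:50), x_um = runif(50, 0, 20),
                       y_um = runif(50, 0, 20))
  p2 <- tibble::tibble(id = 1:80, marker = "PS", x_um = runif(80, 0, 20),
                       y_um = runif(80, 0, 20))
  asn2 <- assign_puncta(p2, h2)
  expect_equal(nrow(asn2), 80)                # one row per punctum
  for (i in seq_len(80)) {
    d <- sqrt((h2$x_um - p2$x_um[i])^2 + (h2$y_um - p2$y_um[i])^2)
    dm <- min(d)
    want <- if (dm <= 0.75) min(h2$id[d == dm]) else NA_integer_
    expect_identical(asn2$hiel_id[i], want)
  }
})

test_that("occupancy counts are exact fractions with k of N reported", {
  h <- tibble::tibble(id = 1:6, x_um = 10 * (1:6), y_um = 0)
  expect_equal(occupancy(h, tibble::tibble(punctum_id = integer(),
                                           marker = character(),
                                           hiel_id = integer(),
                                           dist_um = numeric()),
                         "PS")$occupancy_pct, 0)
  p <- tibble::tibble(id = 1:5, marker = "PS", x_um = 10 * (1:5), y_um = 0.1)
  asn <- assign_puncta(p, h)
  occ <- occupancy(h, asn, "PS")
  expect_equal(occ$k, 5)
  expect_equal(occ$n, 6)
  expect_equal(occ$occupancy_pct, 500 / 6)    # 83.33%
  expect_error(occupancy(h[0, ], asn, "PS"), "empty")
})

test_that("generator occupancy and co-occupancy are recovered within 3 binomial SE", {
  spec <- field_spec(
    n_cells = 50, hiel_per_cell = 100,        # 5,000 HIEL
    marker_occupancy = c(PS = 0.138, Kir2.1 = 0.05),
    pairwise_cooccupancy = data.frame(marker_a = "Kir2.1", marker_b = "PS",
                                      conditional = 5 / 6),
    seed = 77)
  f <- synthesize_field(spec)
  asn <- assign_puncta(f$puncta, f$hiel)
  occ <- occupancy(f$hiel, asn, "PS")
  se_occ <- 100 * sqrt(0.138 * (1 - 0.138) / nrow(f$hiel))
  expect_lt(abs(occ$occupancy_pct - 13.8), 3 * se_occ)

  co <- cooccupancy(f$hiel, asn, "Kir2.1", "PS")
  se_co <- 100 * sqrt((5 / 6) * (1 / 6) / co$n)
  expect_lt(abs(co$cooccupancy_pct - 100 * 5 / 6), 3 * se_co)
})

test_that("co-occupancy reproduces exact counts and errors without conditioning HIEL", {
  h <- tibble::tibble(id = 1:50, x_um = 10 * (1:50), y_um = 0)
  # 41 Cx40-positive HIEL, 6 of which also carry PS -> 14.63%
  cx <- tibble::tibble(id = 1:41, marker = "Cx40", x_um = 10 * (1:41),
                       y_um = 0.1)
  ps <- tibble::tibble(id = 42:47, marker = "PS", x_um = 10 * (1:6),
                       y_um = -0.1)
  asn <- assign_puncta(dplyr::bind_rows(cx, ps), h)
  co <- cooccupancy(h, asn, "Cx40", "PS")
  expect_equal(co$k, 6)
  expect_equal(co$n, 41)
  expect_equal(co$cooccupancy_pct, 600 / 41, tolerance = 1e-12)  # 14.63
  expect_equal(cooccupancy(h, asn, "PS", "Cx40")$cooccupancy_pct, 100)
  expect_error(cooccupancy(h, asn, "Kir2.1", "PS"), "undefined")
  # marginal occupancy dominates the joint
  expect_gte(occupancy(h, asn, "Cx40")$occupancy_pct,
             co$k / nrow(h) * 100)
})

test_that("per-EC statistics satisfy the conditional-mean identity", {
  spec <- field_spec(width_um = 40, height_um = 40, px_size_um = 1,
                     n_cells = 4, seed = 5)
  tess <- generate_tessellation(spec)
  # place marker-positive HIEL: counts {0, 0, 2, 2} across the 4 cells
  cells34 <- lapply(3:4, function(k) {
    idx <- which(tess$labels == k, arr.ind = TRUE)[1:2, ]
    cbind(idx[, 2] - 0.5, idx[, 1] - 0.5)
  })
  pts <- do.call(rbind, cells34)
  h <- tibble::tibble(id = 1:4, x_um = pts[, 1], y_um = pts[, 2])
  p <- tibble::tibble(id = 1:4, marker = "PS", x_um = pts[, 1],
                      y_um = pts[, 2])
  st <- per_ec_stats(tess, h, assign_puncta(p, h), "PS")
  expect_equal(st$mean_per_ec, 1.0)
  expect_equal(st$frac_ec_pos, 0.5)
  expect_equal(st$conditional_mean, 2.0)

  # identity holds to machine precision on random tables
  set.seed(21)
  for (r in 1:25) {
    counts <- rpois(20, runif(1, 0.2, 3))
    overall <- mean(counts); frac <- mean(counts >= 1)
    if (frac > 0)
      expect_equal(overall, (overall / frac) * frac, tolerance = 1e-15)
  }
})

test_that("every EC occupied gives (1, 100%, 1) and empty markers are flagged", {
  spec <- field_spec(width_um = 30, height_um = 30, px_size_um = 1,
                     n_cells = 3, seed = 6)
  tess <- generate_tessellation(spec)
  pts <- do.call(rbind, lapply(1:3, function(k) {
    idx <- which(tess$labels == k, arr.ind = TRUE)[1, , drop = FALSE]
    cbind(idx[, 2] - 0.5, idx[, 1] - 0.5)
  }))
  h <- tibble::tibble(id = 1:3, x_um = pts[, 1], y_um = pts[, 2])
  p <- tibble::tibble(id = 1:3, marker = "PS", x_um = pts[, 1],
                      y_um = pts[, 2])
  st <- per_ec_stats(tess, h, assign_puncta(p, h), "PS")
  expect_equal(unname(unlist(st[c("mean_per_ec", "frac_ec_pos",
                                  "conditional_mean")])), c(1, 1, 1))
  expect_warning(
    st0 <- per_ec_stats(tess, h, assign_puncta(p[0, ], h), "PS"),
    "undefined")
  expect_true(is.na(st0$conditional_mean))
})
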