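test_that("outlier removal leaves tight clusters alone and catches a gross outlier", {
  expect_length(rout_outliers(c(1.0, 1.1, 0.9, 1.05))$removed, 0)

  set.seed(5)
  x <- c(rnorm(50, 1, 0.05), 50)
  ro <- rout_outliers(x, Q = 1)
  expect_equal(ro$removed, 50)
  expect_equal(sum(!ro$keep), 1)

  # step-by-step oracle of the published procedure on the same data
  n <- length(x); k <- 1
  center <- median(x)
  rsdr <- quantile(abs(x - center), 0.6827, names = FALSE) * n / (n - k)
  p <- 2 * pt(-abs(x - center) / rsdr, df = n - k)
  ord <- order(p)
  below <- p[ord] <= 0.01 * seq_len(n) / n
  keep <- rep(TRUE, n)
  if (any(below)) keep[ord[seq_len(max(which(below)))]] <- FALSE
  expect_identical(ro$keep, keep)
})

test_that("outlier removal defaults to Q = 1 percent and no-ops below 3 samples", {
  expect_equal(formals(rout_outliers)$Q, 1)
  expect_warning(ro <- rout_outliers(c(1, 100)), "fewer than 3")
  expect_length(ro$removed, 0)
})

test_that("Holm-Sidak adjustment matches manual arithmetic", {
  p <- c(0.3, 0.01, 0.04)
  adj <- mejpattern:::holm_sidak(p)
  expect_equal(adj[2], 1 - (1 - 0.01)^3)
  expect_equal(adj[3], max(1 - (1 - 0.04)^2, adj[2]))
  expect_equal(adj[1], max(0.3, adj[3]))
})

test_that("the Brown-Forsythe ANOVA statistic matches hand computation", {
  vals <- c(1, 2, 3, 2, 3, 4, 10, 12, 14)
  grp <- rep(c("a", "b", "c"), each = 3)
  got <- mejpattern:::brown_forsythe_anova(vals, grp)
  # by hand: group means 2, 3, 12; variances 1, 1, 4; N = 9
  gm <- (2 + 3 + 12) / 3
  num <- 3 * ((2 - gm)^2 + (3 - gm)^2 + (12 - gm)^2)
  den <- (1 - 3 / 9) * (1 + 1 + 4)
  expect_equal(got$statistic, num / den)
  w <- (1 - 3 / 9) * c(1, 1, 4) / den
  expect_equal(got$df2, 1 / sum(w^2 / 2))
  expect_equal(got$p.value, pf(num / den, 2, got$df2, lower.tail = FALSE))
})

test_that("identical groups give adjusted p = 1 and an inconclusive label", {
  x <- c(1, 2, 3, 4, 5)
  v <- compare_groups(real = x, pc = x, nc = x, rand = x, rout_q = NULL)
  expect_true(all(v$p_adjusted == 1))
  expect_equal(v$label, "inconclusive")

  # degenerate zero-variance groups: exact ties give p = 1
  z <- rep(2, 5)
  v2 <- compare_groups(real = z, pc = z, nc = z, rand = z, rout_q = NULL)
  expect_true(all(v2$p_adjusted == 1))
})

test_that("a RAND-generated field is labeled random and a PC field hub_associated", {
  run_one <- function(mode, seed) {
    spec <- field_spec(placement_mode = mode, hub_kind = "nuclei",
                       seed = seed)
    f <- synthesize_field(spec)
    d <- envelope_distances(f$hiel, f$hub,
                            sim_config(n_replicates = 10, seed = seed + 1),
                            spec$px_size_um)
    compare_groups(d)$label
  }
  expect_equal(run_one("RAND", 102), "random")
  expect_equal(run_one("PC", 102), "hub_associated")
  expect_equal(run_one("NC", 103), "hub_excluded")
})

test_that("raising all REAL distances cannot turn hub_excluded into hub_associated", {
  set.seed(9)
  pc <- runif(500, 0, 1)
  nc <- runif(500, 1.5, 4.5)
  rand <- runif(500, 0, 10)
  real_nc <- runif(200, 1.5, 4.5)
  v1 <- compare_groups(real = real_nc, pc = pc, nc = nc, rand = rand,
                       rout_q = NULL)
  expect_equal(v1$label, "hub_excluded")
  v2 <- compare_groups(real = real_nc + 5, pc = pc, nc = nc, rand = rand,
                       rout_q = NULL)
  expect_false(v2$label == "hub_associated")
})

test_that("tidy and glance expose the verdict in broom shape", {
  v <- compare_groups(real = rnorm(20, 5), pc = rnorm(20, 0),
                      nc = rnorm(20, 10), rand = rnorm(20, 5),
                      rout_q = NULL)
  td <- tidy(v)
  expect_equal(nrow(td), 3)
  expect_named(td, c("comparison", "p.value", "p.adjusted", "significant"))
  gl <- glance(v)
  expect_equal(gl$label, v$label)
  expect_s3_class(autoplot(v), "ggplot")
})

test_that("per-EC density counts HIEL and recovers the generator rate", {
  # one cell, 5 HIEL inside
  spec1 <- field_spec(width_um = 20, height_um = 20, px_size_um = 1,
                      n_cells = 1, seed = 1)
  tess1 <- generate_tessellation(spec1)
  h5 <- tibble::tibble(id = 1:5, x_um = runif(5, 1, 19),
                       y_um = runif(5, 1, 19))
  dr1 <- density_regression(tess1, h5)
  expect_equal(dr1$mean_per_cell, 5)

  # generator rate 9.83 over many cells: sample mean within 3 SE
  spec <- field_spec(n_cells = 50, seed = 3)
  fs <- lapply(1:4, function(s) synthesize_field(
    field_spec(n_cells = 50, seed = s)))
  means <- vapply(fs, function(f)
    density_regression(f$tess, f$hiel)$mean_per_cell, 0)
  # fixed realized counts: mean per cell is exactly round(50*9.83)/50
  expect_equal(mean(means), round(50 * 9.83) / 50, tolerance = 1e-12)
})

test_that("counts proportional to areas give a positive significant slope", {
  set.seed(13)
  spec <- field_spec(n_cells = 40, seed = 13)
  tess <- generate_tessellation(spec)
  # construct HIEL with count proportional to cell area
  per <- pmax(1, round(tess$cells$area_um2 / 100))
  pts <- do.call(rbind, lapply(seq_len(nrow(tess$cells)), function(k) {
    idx <- which(tess$labels == k, arr.ind = TRUE)
    pick <- idx[sample(nrow(idx), per[k], replace = TRUE), , drop = FALSE]
    cbind((pick[, 2] - 0.5) * spec$px_size_um,
          (pick[, 1] - 0.5) * spec$px_size_um)
  }))
  h <- tibble::tibble(id = seq_len(nrow(pts)), x_um = pts[, 1],
                      y_um = pts[, 2])
  dr <- density_regression(tess, h)
  expect_gt(dr$slope, 0)
  expect_lt(dr$slope_p, 0.01)
  # closed-form OLS oracle on the same per-cell table
  a <- dr$per_cell$area_um2; y <- dr$per_cell$n_hiel
  slope_hand <- sum((a - mean(a)) * (y - mean(y))) / sum((a - mean(a))^2)
  expect_equal(dr$slope, slope_hand)
})

test_that("HIEL outside every polygon are warned about", {
  spec <- field_spec(width_um = 10, height_um = 10, px_size_um = 1,
                     n_cells = 1, seed = 1)
  tess <- generate_tessellation(spec)
  tess$labels[1, 1] <- 0L   # punch a hole in the tessellation
  h <- tibble::tibble(id = 1, x_um = 0.5, y_um = 0.5)
  expect_warning(density_regression(tess, h), "unassigned")
})
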