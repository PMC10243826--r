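#' Robust FDR-based outlier removal (ROUT, constant-location model)
#'
#' Implements the robust-regression-plus-FDR outlier scheme of Motulsky &
#' Brown (2006), adapted to the constant-location model used for a single
#' distance distribution: the robust fit is the sample median, the robust
#' scale (RSDR) is the 68.27th percentile of the absolute residuals inflated
#' by `N / (N - K)` with `K = 1`, each point gets a t-ratio
#' `|residual| / RSDR` with a two-tailed p-value on `N - K` degrees of
#' freedom, and the ordered tail is tested by a Benjamini-Hochberg pass at
#' rate `Q`. Applied to the real-world group only in the pattern pipeline;
#' removed points are returned, not discarded silently.
#'
#' @param x Numeric vector (e.g. `min_dist_um` of the REAL group).
#' @param Q FDR rate in percent (default 1, the published setting).
#' @return List with `kept`, `removed` (values), `keep` (logical index),
#'   `rsdr`, and `center`.
#' @examples
#' rout_outliers(c(rnorm(50, 1, 0.05), 50))$removed
#' @export
rout_outliers <- function(x, Q = 1) {
  stopifnot(Q > 0, Q < 100)
  n <- length(x)
  if (n < 3) {
    warn("fewer than 3 samples: outlier removal skipped")
    return(list(kept = x, removed = numeric(0), keep = rep(TRUE, n),
                rsdr = NA_real_, center = stats::median(x)))
  }
  k_par <- 1
  center <- stats::median(x)
  res <- x - center
  rsdr <- stats::quantile(abs(res), 0.6827, names = FALSE) * n / (n - k_par)
  if (rsdr <= 0) rsdr <- .Machine$double.eps
  tval <- abs(res) / rsdr
  p <- 2 * stats::pt(-tval, df = n - k_par)

  ord <- order(p)                     # most extreme first
  thr <- (Q / 100) * seq_len(n) / n
  below <- p[ord] <= thr
  keep <- rep(TRUE, n)
  if (any(below)) {
    cut <- max(which(below))
    keep[ord[seq_len(cut)]] <- FALSE
  }
  list(kept = x[keep], removed = x[!keep], keep = keep,
       rsdr = rsdr, center = center)
}

# Holm-Sidak step-down adjustment of m p-values.
holm_sidak <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- 1 - (1 - p[ord])^(m - seq_len(m) + 1)
  adj <- cummax(adj)
  out <- numeric(m)
  out[ord] <- pmin(adj, 1)
  out
}

# Brown-Forsythe ANOVA (F* robust to variance heterogeneity) with
# Satterthwaite denominator df.
brown_forsythe_anova <- function(values, groups) {
  groups <- factor(groups)
  ni <- tapply(values, groups, length)
  mi <- tapply(values, groups, mean)
  vi <- tapply(values, groups, stats::var)
  N <- sum(ni)
  gm <- sum(ni * mi) / N
  num <- sum(ni * (mi - gm)^2)
  ci <- (1 - ni / N) * vi
  den <- sum(ci)
  if (den <= 0) return(list(statistic = NA_real_, p.value = 1,
                            df1 = length(ni) - 1, df2 = NA_real_))
  Fstar <- num / den
  w <- ci / den
  df2 <- 1 / sum(w^2 / (ni - 1))
  df1 <- length(ni) - 1
  list(statistic = unname(Fstar), p.value = stats::pf(Fstar, df1, df2,
                                                      lower.tail = FALSE),
       df1 = df1, df2 = unname(df2))
}

# Welch two-sample t-test p-value with exact-tie handling for degenerate
# zero-variance samples.
welch_p <- function(a, b) {
  va <- stats::var(a); vb <- stats::var(b)
  if ((is.na(va) || va == 0) && (is.na(vb) || vb == 0)) {
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  }
  stats::t.test(a, b, var.equal = FALSE)$p.value
}

#' Classify the spatial pattern of HIEL against Monte Carlo envelopes
#'
#' The verdict stage: Welch's ANOVA across the four distance samples (REAL,
#' PC, NC, RAND) with the Brown-Forsythe statistic reported alongside, then
#' pairwise Welch t-tests of REAL against each simulated group, adjusted by
#' Holm-Sidak. The label follows the envelope logic: `random` when REAL is
#' indistinguishable from RAND but differs from both PC and NC;
#' `hub_associated` when REAL matches PC and differs from RAND and NC;
#' `hub_excluded` when REAL matches NC and differs from RAND and PC;
#' `inconclusive` otherwise. (Only the random case is defined by the
#' original analysis; the other two labels are a documented extension.)
#'
#' @param distances Tibble with `group` (REAL/PC/NC/RAND) and `min_dist_um`,
#'   e.g. from [envelope_distances()], or pass the four samples via `real`,
#'   `pc`, `nc`, `rand`.
#' @param real,pc,nc,rand Optional numeric vectors overriding `distances`.
#' @param alpha Significance level (default 0.05).
#' @param rout_q ROUT Q in percent applied to the REAL sample before testing
#'   (default 1); `NULL` disables removal.
#' @return A `pattern_verdict` object; see [tidy.pattern_verdict()].
#' @export
compare_groups <- function(distances = NULL, real = NULL, pc = NULL,
                           nc = NULL, rand = NULL, alpha = 0.05,
                           rout_q = 1) {
  if (!is.null(distances)) {
    pick <- function(g) distances$min_dist_um[distances$group == g]
    real <- pick("REAL"); pc <- pick("PC"); nc <- pick("NC")
    rand <- pick("RAND")
  }
  if (min(length(real), length(pc), length(nc), length(rand)) < 3)
    abort("each group needs at least 3 distance samples")

  n_real_total <- length(real)
  removed <- numeric(0)
  if (!is.null(rout_q)) {
    ro <- rout_outliers(real, Q = rout_q)
    real <- ro$kept
    removed <- ro$removed
  }

  vals <- c(real, pc, nc, rand)
  grp <- rep(c("REAL", "PC", "NC", "RAND"),
             c(length(real), length(pc), length(nc), length(rand)))
  welch <- tryCatch(
    stats::oneway.test(vals ~ factor(grp), var.equal = FALSE),
    error = function(e) list(statistic = NA_real_, p.value = 1))
  bf <- brown_forsythe_anova(vals, grp)

  p_raw <- c(rand = welch_p(real, rand),
             pc = welch_p(real, pc),
             nc = welch_p(real, nc))
  p_adj <- setNames(holm_sidak(p_raw), names(p_raw))

  same_rand <- p_adj[["rand"]] >= alpha
  same_pc <- p_adj[["pc"]] >= alpha
  same_nc <- p_adj[["nc"]] >= alpha
  label <- if (same_rand && !same_pc && !same_nc) "random"
    else if (same_pc && !same_rand && !same_nc) "hub_associated"
    else if (same_nc && !same_rand && !same_pc) "hub_excluded"
    else "inconclusive"

  five_num <- function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    c(lower_whisker = max(min(v), q[1] - 1.5 * iqr), q1 = q[1],
      median = q[2], q3 = q[3],
      upper_whisker = min(max(v), q[3] + 1.5 * iqr))
  }
  desc <- bind_rows(lapply(
    list(REAL = real, PC = pc, NC = nc, RAND = rand),
    function(v) c(n = length(v), mean = mean(v), five_num(v))), .id = "group")

  structure(list(
    label = label, alpha = alpha,
    p_adjusted = p_adj, p_raw = p_raw,
    welch = list(statistic = unname(welch$statistic),
                 p.value = welch$p.value),
    brown_forsythe = bf,
    descriptives = desc,
    n_real_total = n_real_total, n_real_used = length(real),
    removed = removed,
    samples = tibble(group = grp, min_dist_um = vals)
  ), class = "pattern_verdict")
}

#' @export
print.pattern_verdict <- function(x, ...) {
  cat("<pattern_verdict> label:", x$label, " (alpha =", x$alpha, ")\n")
  cat(sprintf("  REAL vs RAND p = %.4g | vs PC p = %.4g | vs NC p = %.4g (Holm-Sidak)\n",
              x$p_adjusted[["rand"]], x$p_adjusted[["pc"]],
              x$p_adjusted[["nc"]]))
  cat(sprintf("  Welch ANOVA p = %.4g; Brown-Forsythe p = %.4g; REAL n = %d (%d after outlier removal)\n",
              x$welch$p.value, x$brown_forsythe$p.value,
              x$n_real_total, x$n_real_used))
  invisible(x)
}

#' Tidy a pattern verdict
#'
#' `tidy()` returns one row per pairwise comparison (raw and Holm-Sidak
#' adjusted p-values); `glance()` one row with the omnibus tests, label, and
#' sample accounting.
#'
#' @param x A `pattern_verdict`.
#' @param ... Unused.
#' @method tidy pattern_verdict
#' @export
tidy.pattern_verdict <- function(x, ...) {
  tibble(
    comparison = c("REAL_vs_RAND", "REAL_vs_PC", "REAL_vs_NC"),
    p.value = unname(x$p_raw[c("rand", "pc", "nc")]),
    p.adjusted = unname(x$p_adjusted[c("rand", "pc", "nc")]),
    significant = unname(x$p_adjusted[c("rand", "pc", "nc")]) < x$alpha
  )
}

#' @rdname tidy.pattern_verdict
#' @method glance pattern_verdict
#' @export
glance.pattern_verdict <- function(x, ...) {
  tibble(
    label = x$label, alpha = x$alpha,
    welch_statistic = x$welch$statistic, welch_p = x$welch$p.value,
    bf_statistic = x$brown_forsythe$statistic,
    bf_p = x$brown_forsythe$p.value,
    n_real = x$n_real_total, n_real_used = x$n_real_used,
    n_outliers_removed = length(x$removed)
  )
}

#' @rdname tidy.pattern_verdict
#' @param object A `pattern_verdict` (autoplot method).
#' @method autoplot pattern_verdict
#' @export
autoplot.pattern_verdict <- function(object, ...) {
  df <- object$samples
  df$group <- factor(df$group, levels = c("REAL", "PC", "RAND", "NC"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group,
                                   y = .data$min_dist_um)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::labs(x = NULL, y = "minimum distance to hub (µm)",
                  title = paste("spatial pattern:", object$label)) +
    ggplot2::theme_minimal()
}

#' Per-EC HIEL counts and the count-versus-area regression
#'
#' Assigns each HIEL center to its containing cell via the tessellation
#' label raster, reports the mean HIEL per EC, and fits ordinary least
#' squares of per-cell count on cell area. HIEL falling outside every cell
#' (impossible for a space-filling tessellation, possible for traced
#' polygon subsets) are counted as unassigned with a warning.
#'
#' @param tess A `field_tessellation` (or list with `labels`, `cells`,
#'   `px_size_um`).
#' @param hiels HIEL tibble.
#' @return A `hiel_density` list: `per_cell` tibble (`cell_id`, `area_um2`,
#'   `n_hiel`), `mean_per_cell`, `fit` (the `lm`), `slope`, `slope_p`,
#'   `n_unassigned`.
#' @export
density_regression <- function(tess, hiels) {
  lab <- tess$labels
  px <- tess$px_size_um
  if (nrow(hiels) > 0) {
    i <- um_to_row(hiels$y_um, px, nrow(lab))
    j <- um_to_col(hiels$x_um, px, ncol(lab))
    cell <- lab[cbind(i, j)]
  } else cell <- integer(0)
  n_unassigned <- sum(is.na(cell) | cell == 0)
  if (n_unassigned > 0)
    warn(sprintf("%d HIEL outside all cells (unassigned)", n_unassigned))
  counts <- tabulate(cell[!is.na(cell) & cell > 0],
                     nbins = nrow(tess$cells))
  per_cell <- tibble(cell_id = tess$cells$cell_id,
                     area_um2 = tess$cells$area_um2,
                     n_hiel = counts)
  fit <- stats::lm(n_hiel ~ area_um2, data = per_cell)
  sm <- summary(fit)$coefficients
  structure(list(
    per_cell = per_cell,
    mean_per_cell = mean(per_cell$n_hiel),
    fit = fit,
    slope = unname(coef(fit)[2]),
    slope_p = if (nrow(sm) >= 2) sm[2, 4] else NA_real_,
    n_unassigned = n_unassigned
  ), class = "hiel_density")
}

#' @export
print.hiel_density <- function(x, ...) {
  cat(sprintf("<hiel_density> mean %.3f HIEL/EC over %d cells; slope %.3g (p = %.3g)\n",
              x$mean_per_cell, nrow(x$per_cell), x$slope, x$slope_p))
  invisible(x)
}

#' @rdname density_regression
#' @param x A `hiel_density`.
#' @param ... Unused.
#' @method tidy hiel_density
#' @export
tidy.hiel_density <- function(x, ...) {
  tibble(term = c("(Intercept)", "area_um2"),
         estimate = unname(coef(x$fit)),
         p.value = summary(x$fit)$coefficients[, 4])
}

#' @rdname density_regression
#' @method glance hiel_density
#' @export
glance.hiel_density <- function(x, ...) {
  tibble(mean_per_cell = x$mean_per_cell, slope = x$slope,
         slope_p = x$slope_p, n_cells = nrow(x$per_cell),
         n_hiel = sum(x$per_cell$n_hiel), n_unassigned = x$n_unassigned)
}
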