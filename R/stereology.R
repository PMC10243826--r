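#' Stereology parameters linking en face density to section counts
#'
#' Geometric quantities for predicting how many HIEL profiles a thin
#' transverse section should show per unit IEL length, given the areal HIEL
#' density measured en face: `C` artery circumference, HIEL diameter range
#' `d_range`, en face image area `A_xy` (or width `X` and height `Y`),
#' mean HIEL per image `N_hiel`, section thickness `Y_tem` (70 nm), and the
#' 1-section-per-5-micrometer sampling rule guarding against double counts.
#'
#' @param C Artery circumference (micrometers).
#' @param d_range HIEL diameter interval (micrometers).
#' @param N_hiel Mean HIEL count per en face image.
#' @param A_xy En face image area (square micrometers); computed as `X * Y`
#'   when those are given.
#' @param X,Y En face image width and height (micrometers).
#' @param Y_tem Section thickness (micrometers, default 0.070).
#' @param Z Arterial wall thickness (micrometers; carried for completeness).
#' @param section_spacing Minimum spacing between analyzed sections
#'   (micrometers, default 5).
#' @return A `stereo_params` list.
#' @export
stereo_params <- function(C = NULL, d_range, N_hiel, A_xy = NULL,
                          X = NULL, Y = NULL, Y_tem = 0.070, Z = NULL,
                          section_spacing = 5) {
  if (is.null(A_xy)) {
    if (is.null(X) || is.null(Y)) abort("give A_xy or both X and Y")
    A_xy <- X * Y
  } else if (!is.null(X) && !is.null(Y) &&
             abs(A_xy - X * Y) > 1e-6 * A_xy) {
    abort("A_xy must equal X * Y when all three are given")
  }
  stopifnot(length(d_range) == 2, d_range[1] <= d_range[2],
            all(d_range > 0), A_xy > 0, N_hiel >= 0, Y_tem > 0,
            section_spacing > 0)
  structure(list(C = C, d_range = as.numeric(d_range), N_hiel = N_hiel,
                 A_xy = A_xy, X = X, Y = Y, Y_tem = Y_tem, Z = Z,
                 section_spacing = section_spacing),
            class = "stereo_params")
}

#' Predicted HIEL per 1,000 micrometers of IEL in transverse sections
#'
#' A section of thickness `t` intersects a disc of diameter `d` lying in the
#' IEL plane whenever the disc center falls in a band of width `d + t`
#' around the section, so at areal density `rho = N_hiel / A_xy` the
#' expected profile count per IEL length `L` is `rho * (d + t) * L`. Returns
#' the interval over the diameter range.
#'
#' @param p A [stereo_params()].
#' @param L_um IEL length to normalize to (default 1,000 micrometers).
#' @return Tibble `d_um`, `expected_per_L` (rows: low and high diameter),
#'   plus `rho_um2` attribute.
#' @export
predict_counts_per_length <- function(p, L_um = 1000) {
  rho <- p$N_hiel / p$A_xy
  d <- p$d_range
  out <- tibble(d_um = d, expected_per_L = rho * (d + p$Y_tem) * L_um)
  attr(out, "rho_um2") <- rho
  out
}

#' Convert an observed en face density to per-length units
#'
#' Applies the same band-intersection formula with an observed mean HIEL
#' diameter, and flags whether the value falls inside the predicted interval
#' of [predict_counts_per_length()].
#'
#' @param p A [stereo_params()].
#' @param mean_diam_um Observed mean HIEL diameter; defaults to the middle
#'   of `p$d_range`.
#' @param L_um Length normalization (default 1,000).
#' @return Tibble `linear_density`, `low`, `high`, `inside`.
#' @export
enface_density_to_linear <- function(p, mean_diam_um = mean(p$d_range),
                                     L_um = 1000) {
  rho <- p$N_hiel / p$A_xy
  v <- rho * (mean_diam_um + p$Y_tem) * L_um
  pred <- predict_counts_per_length(p, L_um)
  lo <- min(pred$expected_per_L); hi <- max(pred$expected_per_L)
  tibble(linear_density = v, low = lo, high = hi,
         inside = v >= lo & v <= hi)
}

#' Monte Carlo sectioning oracle for the stereology prediction
#'
#' Scatters discs of diameter `d` at density `rho = N_hiel / A_xy` on the
#' unrolled artery (a plane of width `C`), samples transverse bands of
#' thickness `Y_tem` spaced at least `section_spacing` apart (the
#' double-counting guard), counts the discs each band intersects, and
#' reports the empirical mean count per `L_um` of IEL with its standard
#' error.
#'
#' @param p A [stereo_params()]; `C` must be set.
#' @param n_sections Number of sections to sample (>= 100).
#' @param d_um Disc diameter; defaults to the middle of `p$d_range`.
#' @param seed Integer seed.
#' @param L_um Length normalization (default 1,000).
#' @param length_um Optional total artery length to simulate; must
#'   accommodate `n_sections` at the minimum spacing. Auto-sized if NULL.
#' @return Tibble `mean_per_L`, `se_per_L`, `n_sections`, `n_discs`.
#' @export
mc_section_counts <- function(p, n_sections = 1000,
                              d_um = mean(p$d_range), seed = 1L,
                              L_um = 1000, length_um = NULL) {
  stopifnot(n_sections >= 100)
  if (is.null(p$C)) abort("mc_section_counts needs the circumference C")
  spacing <- p$section_spacing
  if (is.null(length_um)) length_um <- (n_sections + 1) * spacing
  if (length_um < (n_sections + 1) * spacing)
    abort("artery length too short for n_sections at the minimum spacing")
  set.seed(seed)
  rho <- p$N_hiel / p$A_xy
  n_discs <- stats::rpois(1, rho * p$C * length_um)
  z <- sort(runif(n_discs, 0, length_um))     # position along artery axis
  s <- spacing * seq_len(n_sections)          # grid satisfying the spacing rule
  # band [s, s + t] catches a disc centered at z iff z in [s - d/2, s + t + d/2]
  counts <- findInterval(s + p$Y_tem + d_um / 2, z) -
    findInterval(s - d_um / 2, z)
  per_L <- counts / p$C * L_um
  tibble(mean_per_L = mean(per_L),
         se_per_L = stats::sd(per_L) / sqrt(n_sections),
         n_sections = n_sections, n_discs = n_discs)
}
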