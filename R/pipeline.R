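#' Run one analysis stage from a config
#'
#' Orchestrates the pipeline stages behind a single entry point with a
#' validated config (a named list or a YAML file path), a fixed seed, and a
#' reproducibility manifest written next to every result. Stages:
#'
#' * `simulate-field` - synthesize a field and write the raster + ground
#'   truth bundle ([synthesize_field()], [write_field()]).
#' * `pattern-test` - load a field bundle, run the placement envelopes and
#'   the verdict ([envelope_distances()], [compare_groups()]); writes
#'   `distances.csv` and `verdict.json`.
#' * `colocalize` - assignment + occupancy/co-occupancy summaries; writes
#'   `assignments.csv` and `colocalization.json` (k and N behind every
#'   percentage).
#' * `stereology` - closed-form prediction, en face conversion, and the
#'   Monte Carlo check; writes `stereology.json`.
#' * `vasoreactivity` - dose-response assembly from a long CSV; writes
#'   `dose_response.csv` and `dose_response_summary.csv`.
#' * `quantify-intensity` - coverage and bin partition of a raster; writes
#'   `intensity.json`.
#'
#' Identical config + seed give byte-identical outputs (no timestamps are
#' written).
#'
#' @param stage Stage name (see above).
#' @param config Named list or path to a YAML file.
#' @param seed Optional integer overriding `config$seed`.
#' @return Invisibly, a named vector of files written.
#' @export
run_stage <- function(stage = c("simulate-field", "pattern-test",
                                "colocalize", "stereology",
                                "vasoreactivity", "quantify-intensity"),
                      config, seed = NULL) {
  stage <- match.arg(stage)
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) abort("config must be a list or a YAML path")
  if (!is.null(seed)) config$seed <- seed
  if (is.null(config$seed)) config$seed <- 1L
  need <- function(keys) {
    miss <- setdiff(keys, names(config))
    if (length(miss) > 0)
      abort(sprintf("config for stage '%s' is missing: %s", stage,
                    paste(miss, collapse = ", ")))
  }
  need("out_dir")
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  files <- character(0)

  if (stage == "simulate-field") {
    spec_args <- config[intersect(names(config), names(formals(field_spec)))]
    spec_args$seed <- config$seed
    if (!is.null(spec_args$marker_occupancy))
      spec_args$marker_occupancy <- unlist(spec_args$marker_occupancy)
    spec <- do.call(field_spec, spec_args)
    field <- synthesize_field(spec)
    files <- write_field(field, out)
  } else if (stage == "pattern-test") {
    need(c("field_dir", "hub_kind"))
    hiel <- read_point_table(file.path(config$field_dir, "hiel.csv"))
    if ("marker_or_provenance" %in% names(hiel))
      hiel <- rename(hiel, provenance = "marker_or_provenance")
    mask <- png::readPNG(file.path(
      config$field_dir, paste0("mask_", config$hub_kind, ".png"))) > 0.5
    px <- jsonlite::read_json(
      file.path(config$field_dir, "spec.json"))$px_size_um
    cfg <- sim_config(
      n_replicates = config$replicates %||% 100,
      seed = config$seed)
    dist <- envelope_distances(hiel, mask, cfg, px)
    verdict <- compare_groups(dist, alpha = config$alpha %||% 0.05,
                              rout_q = config$rout_q %||% 1)
    dcsv <- file.path(out, "distances.csv")
    readr::write_csv(dist, dcsv)
    vj <- file.path(out, "verdict.json")
    jsonlite::write_json(list(
      label = verdict$label, alpha = verdict$alpha,
      p_adjusted = as.list(verdict$p_adjusted),
      welch_p = verdict$welch$p.value,
      brown_forsythe_p = verdict$brown_forsythe$p.value,
      n_real = verdict$n_real_total, n_real_used = verdict$n_real_used,
      descriptives = verdict$descriptives
    ), vj, auto_unbox = TRUE, digits = NA)
    files <- c(dcsv, vj)
  } else if (stage == "colocalize") {
    need("field_dir")
    hiel <- read_point_table(file.path(config$field_dir, "hiel.csv"))
    puncta <- readr::read_csv(file.path(config$field_dir, "puncta.csv"),
                              show_col_types = FALSE)
    radius <- config$radius_um %||% 0.75
    asn <- assign_puncta(puncta, hiel, radius_um = radius)
    acsv <- file.path(out, "assignments.csv")
    readr::write_csv(asn, acsv)
    markers <- unique(puncta$marker)
    occ <- bind_rows(lapply(markers, function(m) occupancy(hiel, asn, m)))
    pairs <- config$cooccupancy_pairs
    cooc <- if (!is.null(pairs)) bind_rows(lapply(pairs, function(pr)
      cooccupancy(hiel, asn, pr[[1]], pr[[2]])))
    cj <- file.path(out, "colocalization.json")
    jsonlite::write_json(list(radius_um = radius, occupancy = occ,
                              cooccupancy = cooc),
                         cj, auto_unbox = TRUE, digits = NA, null = "null")
    files <- c(acsv, cj)
  } else if (stage == "stereology") {
    need(c("d_range", "N_hiel"))
    p <- stereo_params(C = config$C, d_range = unlist(config$d_range),
                       N_hiel = config$N_hiel, A_xy = config$A_xy,
                       X = config$X, Y = config$Y,
                       Y_tem = config$Y_tem %||% 0.070,
                       section_spacing = config$section_spacing %||% 5)
    pred <- predict_counts_per_length(p)
    obs <- enface_density_to_linear(
      p, mean_diam_um = config$mean_diam_um %||% mean(p$d_range))
    mc <- if (!is.null(p$C))
      mc_section_counts(p, n_sections = config$n_sections %||% 1000,
                        seed = config$seed)
    sj <- file.path(out, "stereology.json")
    jsonlite::write_json(list(interval = pred,
                              observed_linear_density = obs,
                              mc_check = mc),
                         sj, auto_unbox = TRUE, digits = NA, null = "null")
    files <- sj
  } else if (stage == "vasoreactivity") {
    need("records_csv")
    rec <- readr::read_csv(config$records_csv, show_col_types = FALSE)
    doses <- if (is.null(config$doses)) c(0.1, 0.3, 0.5, 0.6, 1, 2)
             else unlist(config$doses)
    dr <- dose_response_table(rec, doses = doses)
    f1 <- file.path(out, "dose_response.csv")
    f2 <- file.path(out, "dose_response_summary.csv")
    readr::write_csv(dr$per_artery, f1)
    readr::write_csv(dr$summary, f2)
    files <- c(f1, f2)
  } else if (stage == "quantify-intensity") {
    need("raster_tiff")
    fr <- read_field_tiff(config$raster_tiff, config$px_size_um %||% 1)
    r <- fr$channels[[config$channel %||% 1]]
    scale <- config$index_levels %||% 255
    idx <- round(r * scale)
    cov <- coverage_fraction(idx, config$black_cutoff %||% 0)
    bins <- intensity_bins(idx, config$split_index %||% floor(scale / 3))
    ij <- file.path(out, "intensity.json")
    jsonlite::write_json(list(coverage_pct = cov, bins = bins),
                         ij, auto_unbox = TRUE, digits = NA)
    files <- ij
  }

  manifest <- file.path(out, "manifest.json")
  jsonlite::write_json(list(
    stage = stage, seed = config$seed, config = config,
    package = "mejpattern",
    version = as.character(utils::packageVersion("mejpattern"))
  ), manifest, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(files, manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
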