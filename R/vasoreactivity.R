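#' Pressure-myography quantification formulas
#'
#' The standard diameter-based quantities used on pressurized resistance
#' arteries, all returned in percent:
#'
#' * `myogenic_tone(D_act, D_pass)` = `100 * (D_pass - D_act) / D_pass`:
#'   pressure-induced constriction relative to the passive (Ca2+-free)
#'   diameter at the same pressure.
#' * `percent_change_vs_20(D_x, D_20)` = `100 * (D_x - D_20) / D_20`:
#'   diameter change relative to the 20 mmHg reference.
#' * `percent_dilation(D_resp, D_pe, D_max)` =
#'   `100 * (D_resp - D_pe) / (D_max - D_pe)`: dilation from the
#'   phenylephrine-preconstricted baseline normalized to the maximal
#'   (Ca2+-free) diameter.
#' * `lipid_response(D_post, D_eq)` = `100 * (D_post - D_eq) / D_eq`:
#'   percent diameter change from the equilibrated myogenic-tone baseline
#'   after lipid application (the same form serves PIP2 and the
#'   PS-preincubation window).
#'
#' All functions are vectorized.
#'
#' @param D_act,D_pass Active and passive diameters at a pressure.
#' @param D_x,D_20 Diameter at any pressure and at 20 mmHg.
#' @param D_resp,D_pe,D_max Response, preconstricted, and maximal diameters.
#' @param D_post,D_eq Post-lipid and equilibrated-baseline diameters.
#' @return Numeric vector of percentages.
#' @examples
#' myogenic_tone(80, 100)        # 20
#' percent_dilation(150, 100, 200)  # 50
#' @name vasoreactivity
NULL

#' @rdname vasoreactivity
#' @export
myogenic_tone <- function(D_act, D_pass) {
  stopifnot(all(D_pass > 0))
  if (any(D_act > D_pass))
    warn("D_act exceeds D_pass: negative tone returned")
  100 * (D_pass - D_act) / D_pass
}

#' @rdname vasoreactivity
#' @export
percent_change_vs_20 <- function(D_x, D_20) {
  stopifnot(all(D_20 > 0))
  100 * (D_x - D_20) / D_20
}

#' @rdname vasoreactivity
#' @export
percent_dilation <- function(D_resp, D_pe, D_max) {
  if (any(D_max <= D_pe))
    abort("percent dilation undefined when D_max <= D_pe")
  100 * (D_resp - D_pe) / (D_max - D_pe)
}

#' @rdname vasoreactivity
#' @export
lipid_response <- function(D_post, D_eq) {
  stopifnot(all(D_eq > 0))
  100 * (D_post - D_eq) / D_eq
}

#' Extract the lipid response from a diameter trace
#'
#' Finds the extremum diameter within the observation window after lipid
#' application, reports the percent change from the equilibrated baseline
#' and the time of the extremum rounded to the nearest half-minute. When
#' `exclude_reconstriction` is set, responses in which the diameter
#' re-constricts below the baseline after a transient peak (myogenic tone
#' redeveloping over the response) are flagged and the response is not
#' recorded.
#'
#' @param trace Tibble with `time_min` and `diameter_um`.
#' @param D_eq Equilibrated baseline diameter.
#' @param window Length-2 numeric, observation window in minutes.
#' @param direction `"dilation"` (max) or `"constriction"` (min).
#' @param exclude_reconstriction Apply the post-peak re-constriction filter.
#' @param reconstriction_tol_pct Re-constriction below baseline by more than
#'   this percentage triggers exclusion.
#' @return Tibble `response_pct`, `D_post`, `time_to_max_min` (nearest
#'   half-minute), `excluded`.
#' @export
trace_response <- function(trace, D_eq, window = range(trace$time_min),
                           direction = c("dilation", "constriction"),
                           exclude_reconstriction = FALSE,
                           reconstriction_tol_pct = 2) {
  direction <- match.arg(direction)
  stopifnot(D_eq > 0)
  w <- trace[trace$time_min >= window[1] & trace$time_min <= window[2], ]
  if (nrow(w) == 0) abort("empty observation window")
  k <- if (direction == "dilation") which.max(w$diameter_um)
       else which.min(w$diameter_um)
  D_post <- w$diameter_um[k]
  t_peak <- w$time_min[k]
  excluded <- FALSE
  if (exclude_reconstriction && direction == "dilation") {
    after <- w$diameter_um[w$time_min > t_peak]
    if (length(after) > 0 &&
        min(after) < D_eq * (1 - reconstriction_tol_pct / 100))
      excluded <- TRUE
  }
  tibble(response_pct = if (excluded) NA_real_ else
           lipid_response(D_post, D_eq),
         D_post = D_post,
         time_to_max_min = round(t_peak * 2) / 2,
         excluded = excluded)
}

#' Assemble a dose-response table for NS309 curves
#'
#' Computes per-artery percent dilation at each dose from the
#' preconstricted (`D_pe`) and maximal (`D_max`) diameters, then group
#' means with SEM. Arteries missing `D_max` are excluded with a message.
#'
#' @param records Tibble with columns `artery_id`, `dose_um`, `D_resp`,
#'   `D_pe`, `D_max`, and optionally `group`.
#' @param doses Dose ladder to keep; default the NS309 ladder
#'   0.1, 0.3, 0.5, 0.6, 1, 2 micromolar. Use `NULL` to keep all.
#' @return A `dose_response` list: `per_artery` (long tibble with
#'   `pct_dilation`) and `summary` (per group x dose mean, SEM, n).
#' @export
dose_response_table <- function(records,
                                doses = c(0.1, 0.3, 0.5, 0.6, 1, 2)) {
  records <- tibble::as_tibble(records)
  if (!"group" %in% names(records)) records$group <- "all"
  if (nrow(records) == 0) {
    empty <- tibble(group = character(), dose_um = numeric(),
                    mean_pct = numeric(), sem_pct = numeric(),
                    n = integer())
    return(structure(list(per_artery = records, summary = empty),
                     class = "dose_response"))
  }
  if (!is.null(doses)) records <- records[records$dose_um %in% doses, ]
  bad <- unique(records$artery_id[is.na(records$D_max)])
  if (length(bad) > 0) {
    warn(sprintf("excluding %d arteries missing D_max: %s", length(bad),
                 paste(bad, collapse = ", ")))
    records <- records[!records$artery_id %in% bad, ]
  }
  per <- records %>%
    mutate(pct_dilation = percent_dilation(.data$D_resp, .data$D_pe,
                                           .data$D_max))
  summ <- per %>%
    group_by(.data$group, .data$dose_um) %>%
    summarise(mean_pct = mean(.data$pct_dilation),
              sem_pct = if (n() > 1) sd(.data$pct_dilation) / sqrt(n())
                        else NA_real_,
              n = n(), .groups = "drop")
  structure(list(per_artery = per, summary = summ),
            class = "dose_response")
}

#' @export
print.dose_response <- function(x, ...) {
  cat("<dose_response> ", nrow(x$per_artery), " artery-dose records\n",
      sep = "")
  print(x$summary)
  invisible(x)
}

#' Plot a dose-response summary
#'
#' @param object A `dose_response` from [dose_response_table()].
#' @param ... Unused.
#' @method autoplot dose_response
#' @export
autoplot.dose_response <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(s, ggplot2::aes(x = .data$dose_um, y = .data$mean_pct,
                                  color = .data$group,
                                  group = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_pct - .data$sem_pct,
      ymax = .data$mean_pct + .data$sem_pct)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose (µM)", y = "dilation (% of maximum)",
                  color = NULL) +
    ggplot2::theme_minimal()
}
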