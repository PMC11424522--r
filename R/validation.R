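#' Signed relative error between an actual and a fitted median
#'
#' The per-row quantity of a back-substitution table:
#' `(actual - fitted) / actual`, unrounded.  Report rendering rounds to
#' 2 decimal places half away from zero.
#'
#' @param actual full-data fitted median (P50); strictly positive.
#' @param fitted subsample fitted median (P50).
#' @return the signed relative error, unrounded.
#' @examples
#' relative_error(37.38, 35.90)   # 0.0396, rendered 0.04
#' @export
relative_error <- function(actual, fitted) {
  if (!is.numeric(actual) || !is.numeric(fitted) ||
      anyNA(actual) || anyNA(fitted) ||
      any(!is.finite(actual)) || any(!is.finite(fitted))) {
    stop("`actual` and `fitted` must be finite and numeric", call. = FALSE)
  }
  if (any(actual <= 0)) stop("`actual` must be strictly positive", call. = FALSE)
  (actual - fitted) / actual
}

#' Classify forecasting accuracy from MAPE (Lewis bands)
#'
#' Mean absolute percentage error below 10% is "Highly accurate", 10--20%
#' "Good", 20--50% "Reasonable", 50% and above "Inaccurate".  Intervals are
#' left-closed: a MAPE of exactly 10% is "Good", since only errors *below*
#' 10% count as highly accurate.
#'
#' @param mape_percent MAPE in percent, non-negative; may be a vector.
#' @return character vector of accuracy labels.
#' @examples
#' classify_mape(c(5, 10, 25, 60))
#' @export
classify_mape <- function(mape_percent) {
  if (!is.numeric(mape_percent) || anyNA(mape_percent) || any(mape_percent < 0)) {
    stop("MAPE must be numeric and non-negative", call. = FALSE)
  }
  as.character(cut(mape_percent, breaks = c(0, 10, 20, 50, Inf), right = FALSE,
                   labels = c("Highly accurate", "Good", "Reasonable", "Inaccurate")))
}

#' Back-substitution cross-validation of a growth reference
#'
#' Validates the stability of a fitted reference by refitting on a random
#' subsample: draws a seeded simple random subsample without replacement
#' within each (sex, age group) stratum, refits the LMS parameters on it,
#' and compares the subsample medians ("fitted") against the full-data
#' medians ("actual") for every measure.  With `fraction = 1` the subsample
#' is the whole cohort and every error is exactly zero, because the fitter
#' is deterministic.
#'
#' Two summary error measures are reported per (sex, measure): the mean of
#' the unrounded signed relative errors, and the true MAPE (mean absolute
#' percentage error, in percent), which drives the Lewis accuracy class.
#' They answer different questions and are never interchanged.
#'
#' @inheritParams build_reference
#' @param fraction subsampling fraction in (0, 1], default 0.5.
#' @param seed integer seed; required, so the report is reproducible.
#' @return an object of class `validation_report`: a list with
#'   `by_age` (sex, measure, age_group, actual_p50, fitted_p50, rel_error),
#'   `by_measure` (sex, measure, mean_rel_error, mape_pct, accuracy),
#'   plus `fraction` and `seed`.
#' @examples
#' cohort <- generate_cohort(n_per_cell = 60, seed = 7)
#' back_substitution(cohort, fraction = 0.5, seed = 7, min_n = 25)
#' @export
back_substitution <- function(cohort, fraction = 0.5, seed, age_window = c(12, 16),
                              percentiles = NULL, min_n = 20, fit_options = list()) {
  if (!is.numeric(fraction) || length(fraction) != 1 || fraction <= 0 || fraction > 1) {
    stop("`fraction` must lie in (0, 1]", call. = FALSE)
  }
  if (missing(seed)) stop("an explicit `seed` is required for reproducibility", call. = FALSE)
  cohort <- validate_cohort(cohort)
  full <- build_reference(cohort, age_window = age_window, percentiles = percentiles,
                          min_n = min_n, fit_options = fit_options)
  in_win <- cohort$age_group >= age_window[1] & cohort$age_group <= age_window[2]
  cohort <- cohort[in_win, , drop = FALSE]
  strata <- split(seq_len(nrow(cohort)),
                  list(sex = cohort$sex, age = cohort$age_group), drop = TRUE)
  n_sub <- vapply(strata, function(i) ceiling(fraction * length(i)), numeric(1))
  too_small <- n_sub < min_n
  if (any(too_small)) {
    stop("subsample below the minimum fitting size in: ",
         paste(names(strata)[too_small], collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  idx <- unlist(lapply(seq_along(strata), function(k) {
    i <- strata[[k]]
    if (n_sub[k] == length(i)) i else sample(i, n_sub[k])
  }))
  sub <- build_reference(cohort[sort(idx), , drop = FALSE], age_window = age_window,
                         percentiles = percentiles, min_n = min_n,
                         fit_options = fit_options)
  joined <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(full), "sex", "measure", "age_group", actual_p50 = "mu"),
    dplyr::select(tibble::as_tibble(sub), "sex", "measure", "age_group", fitted_p50 = "mu"),
    by = c("sex", "measure", "age_group")
  )
  # fresh tibble: drop any table attributes carried through the join
  by_age <- tibble::tibble(
    sex = joined$sex, measure = joined$measure, age_group = joined$age_group,
    actual_p50 = joined$actual_p50, fitted_p50 = joined$fitted_p50,
    rel_error = relative_error(joined$actual_p50, joined$fitted_p50)
  )
  by_age <- dplyr::arrange(by_age, .data$sex, .data$measure, .data$age_group)
  by_measure <- dplyr::summarise(
    dplyr::group_by(by_age, .data$sex, .data$measure),
    mean_rel_error = mean(.data$rel_error),
    mape_pct = mean(abs(.data$rel_error)) * 100,
    .groups = "drop"
  )
  by_measure$accuracy <- classify_mape(by_measure$mape_pct)
  new_validation_report(by_age, by_measure, fraction = fraction, seed = seed)
}

new_validation_report <- function(by_age, by_measure, fraction, seed) {
  structure(list(by_age = by_age, by_measure = by_measure,
                 fraction = fraction, seed = seed),
            class = "validation_report")
}

#' Recompute a validation report's summaries from its per-age rows
#'
#' Used when deserialising: the per-measure block is a deterministic
#' function of the per-age block.
#' @noRd
summarise_validation <- function(by_age, fraction, seed) {
  by_measure <- dplyr::summarise(
    dplyr::group_by(by_age, .data$sex, .data$measure),
    mean_rel_error = mean(.data$rel_error),
    mape_pct = mean(abs(.data$rel_error)) * 100,
    .groups = "drop"
  )
  by_measure$accuracy <- classify_mape(by_measure$mape_pct)
  new_validation_report(by_age, by_measure, fraction = fraction, seed = seed)
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Back-substitution validation (fraction = %g, seed = %d)\n",
              x$fraction, x$seed))
  df <- as.data.frame(x$by_measure)
  df$mean_rel_error <- round_half_up(df$mean_rel_error, 3)
  df$mape_pct <- round_half_up(df$mape_pct, 2)
  print(df, row.names = FALSE)
  invisible(x)
}
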