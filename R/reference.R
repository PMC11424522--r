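#' Body mass index
#'
#' Weight in kilograms divided by the square of height in metres.  BMI is
#' always recomputed from height and weight, never trusted from an input
#' file.
#'
#' @param weight_kg weight in kilograms, strictly positive.
#' @param height_cm height in centimetres, strictly positive.
#' @return BMI in kg/m^2, unrounded.
#' @examples
#' compute_bmi(50, 160)
#' @export
compute_bmi <- function(weight_kg, height_cm) {
  if (!is.numeric(weight_kg) || !is.numeric(height_cm) ||
      anyNA(weight_kg) || anyNA(height_cm) ||
      any(!is.finite(weight_kg)) || any(!is.finite(height_cm))) {
    stop("weight and height must be finite and numeric", call. = FALSE)
  }
  if (any(weight_kg <= 0) || any(height_cm <= 0)) {
    stop("weight and height must be strictly positive", call. = FALSE)
  }
  weight_kg / (height_cm / 100)^2
}

#' Stratify a cohort into age--sex--measure fitting groups
#'
#' Splits validated records by sex and completed year of age
#' (`age_group = floor(age_years)`) and stacks the three measures, so each
#' in-window record contributes one value to each of its height, weight and
#' BMI groups.  Records outside the age window are excluded with a message
#' giving the count.
#'
#' @param cohort a cohort data frame as returned by [read_cohort()] or
#'   [generate_cohort()]: columns `subject_id`, `sex`, `age_years`,
#'   `height_cm`, `weight_kg` (and optionally `bmi`, which is recomputed).
#' @param age_window inclusive integer age range kept, default `c(12, 16)`.
#' @return a tibble with one row per (sex, age_group, measure): columns
#'   `sex`, `age_group`, `measure`, `n` and a list-column `values`.
#' @export
stratify_cohort <- function(cohort, age_window = c(12, 16)) {
  cohort <- validate_cohort(cohort)
  in_window <- cohort$age_group >= age_window[1] & cohort$age_group <= age_window[2]
  if (any(!in_window)) {
    message(sprintf("excluding %d record(s) outside the age window [%d, %d]",
                    sum(!in_window), age_window[1], age_window[2]))
    cohort <- cohort[in_window, , drop = FALSE]
  }
  long <- tidyr::pivot_longer(
    dplyr::select(cohort, "sex", "age_group", "height_cm", "weight_kg", "bmi"),
    cols = c("height_cm", "weight_kg", "bmi"),
    names_to = "measure", values_to = "value"
  )
  long$measure <- c(height_cm = "height", weight_kg = "weight", bmi = "bmi")[long$measure]
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$sex, .data$age_group, .data$measure),
    n = dplyr::n(), values = list(.data$value), .groups = "drop"
  )
  out$measure <- factor(out$measure, levels = c("height", "weight", "bmi"))
  dplyr::arrange(out, .data$sex, .data$measure, .data$age_group)
}

#' Build an age- and sex-specific percentile reference table
#'
#' Fits one LMS triple per (sex, age group, measure) cell by maximum
#' likelihood, optionally smooths each parameter series across age, and
#' evaluates the configured percentile set, producing the reference table a
#' growth study publishes.  Deterministic given the cohort and options.
#'
#' @inheritParams stratify_cohort
#' @param percentiles named list of probability vectors per measure;
#'   defaults to [default_percentiles()] for each.
#' @param smooth_edf `NULL` for raw per-age fits (the default), or the
#'   equivalent degrees of freedom passed to [smooth_lms_series()].
#' @param min_n minimum cell size for fitting.
#' @param allow_small if `TRUE`, cells below `min_n` (or empty) are dropped
#'   with a warning instead of raising an error.
#' @param fit_options extra arguments passed to [lms_fit()].
#' @return a `percentile_table`: a tibble with columns `sex`, `age_group`,
#'   `measure`, `lambda`, `mu`, `sigma`, `n` and one column per percentile
#'   label (`NA` where a label is not in that measure's set).
#' @examples
#' cohort <- generate_cohort(n_per_cell = 50, seed = 1)
#' ref <- build_reference(cohort, min_n = 30)
#' head(ref)
#' @export
build_reference <- function(cohort, age_window = c(12, 16), percentiles = NULL,
                            smooth_edf = NULL, min_n = 20, allow_small = FALSE,
                            fit_options = list()) {
  groups <- stratify_cohort(cohort, age_window = age_window)
  expected <- tidyr::expand_grid(
    sex = sort(unique(groups$sex)),
    age_group = seq(age_window[1], age_window[2]),
    measure = factor(c("height", "weight", "bmi"), levels = levels(groups$measure))
  )
  groups <- dplyr::left_join(expected, groups, by = c("sex", "age_group", "measure"))
  groups$n[is.na(groups$n)] <- 0L
  small <- groups$n < min_n
  if (any(small)) {
    keys <- sprintf("%s/%s/age %d (n = %d)", groups$sex[small],
                    groups$measure[small], groups$age_group[small], groups$n[small])
    if (!allow_small) {
      stop("cells below the minimum fitting size: ", paste(keys, collapse = ", "),
           call. = FALSE)
    }
    warning("skipping unfittable cells: ", paste(keys, collapse = ", "), call. = FALSE)
    groups <- groups[!small, , drop = FALSE]
  }
  fits <- lapply(seq_len(nrow(groups)), function(i) {
    fit <- tryCatch(
      do.call(lms_fit, c(list(y = groups$values[[i]], min_n = min_n), fit_options)),
      error = function(e) {
        stop(sprintf("LMS fit failed for %s/%s/age %d: %s", groups$sex[i],
                     groups$measure[i], groups$age_group[i], conditionMessage(e)),
             call. = FALSE)
      }
    )
    tibble::tibble(lambda = fit$lambda, mu = fit$mu, sigma = fit$sigma)
  })
  lms <- dplyr::bind_cols(
    groups[, c("sex", "age_group", "measure", "n")],
    dplyr::bind_rows(fits)
  )
  if (!is.null(smooth_edf)) {
    lms <- dplyr::bind_rows(lapply(
      split(lms, list(lms$sex, lms$measure), drop = TRUE),
      smooth_lms_series, edf = smooth_edf
    ))
    lms <- dplyr::arrange(lms, .data$sex, .data$measure, .data$age_group)
  }
  reference_from_lms(lms, percentiles = percentiles,
                     provenance = list(age_window = age_window,
                                       smooth_edf = smooth_edf, min_n = min_n))
}

#' Evaluate a percentile table from given LMS parameters
#'
#' Builds the same table as [build_reference()] but from an already-known
#' parameter set (for example a published reference), bypassing fitting.
#'
#' @param lms a data frame with columns `sex`, `age_group` (or `age`),
#'   `measure`, `lambda`, `mu`, `sigma` and optionally `n`.
#' @inheritParams build_reference
#' @param provenance optional list echoed as the table's `provenance`
#'   attribute.
#' @return a `percentile_table` tibble.
#' @examples
#' reference_from_lms(south_punjab_lms())
#' @export
reference_from_lms <- function(lms, percentiles = NULL, provenance = list()) {
  lms <- tibble::as_tibble(lms)
  if ("age" %in% names(lms) && !"age_group" %in% names(lms)) {
    lms <- dplyr::rename(lms, age_group = "age")
  }
  need <- c("sex", "age_group", "measure", "lambda", "mu", "sigma")
  miss <- setdiff(need, names(lms))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (!"n" %in% names(lms)) lms$n <- NA_integer_
  if (anyDuplicated(lms[, c("sex", "age_group", "measure")])) {
    stop("duplicate (sex, age_group, measure) rows", call. = FALSE)
  }
  if (is.null(percentiles)) percentiles <- list()
  measures <- as.character(unique(lms$measure))
  sets <- lapply(stats::setNames(measures, measures), function(m) {
    p <- percentiles[[m]]
    if (is.null(p)) p <- default_percentiles(m)
    percentile_spec(p)
  })
  labels <- unique(unlist(lapply(sets, function(s) s$label)))
  # order label columns by probability
  labels <- labels[order(label_to_p(labels))]
  cells <- matrix(NA_real_, nrow = nrow(lms), ncol = length(labels),
                  dimnames = list(NULL, labels))
  for (i in seq_len(nrow(lms))) {
    spec <- sets[[as.character(lms$measure[i])]]
    cells[i, spec$label] <- lms_centile(spec$p, lms$lambda[i], lms$mu[i], lms$sigma[i])
  }
  out <- dplyr::bind_cols(
    lms[, c("sex", "age_group", "measure", "lambda", "mu", "sigma", "n")],
    tibble::as_tibble(cells)
  )
  out <- dplyr::arrange(out, .data$sex, .data$measure, .data$age_group)
  new_percentile_table(out, percentile_sets = lapply(sets, function(s) s$p),
                       provenance = provenance)
}

new_percentile_table <- function(x, percentile_sets, provenance = list()) {
  structure(x,
            percentile_sets = percentile_sets,
            provenance = provenance,
            class = c("percentile_table", class(tibble::tibble())))
}

#' @export
print.percentile_table <- function(x, ...) {
  measures <- if ("measure" %in% names(x)) {
    paste(unique(as.character(x[["measure"]])), collapse = ", ")
  } else "?"
  cat(sprintf("Percentile reference table: %d row(s), measures: %s\n",
              nrow(x), measures))
  NextMethod()
}

#' Smooth an LMS parameter series across age
#'
#' Replaces each of the lambda/mu/sigma series for one (sex, measure) strand
#' by a least-squares polynomial of the requested equivalent degrees of
#' freedom evaluated at the age grid (edf = number of coefficients, so
#' edf = 2 is a straight line and edf equal to the number of ages returns
#' the series unchanged by interpolation).
#'
#' @param lms_series a data frame with columns `age_group`, `lambda`, `mu`,
#'   `sigma` (one sex/measure strand; extra columns pass through).
#' @param edf a single edf applied to all three parameters, or a named
#'   vector/list with entries `lambda`, `mu`, `sigma`.
#' @return the input with the three parameter columns replaced by their
#'   smoothed values.
#' @export
smooth_lms_series <- function(lms_series, edf) {
  lms_series <- tibble::as_tibble(lms_series)
  n_ages <- nrow(lms_series)
  if (n_ages < 2) stop("smoothing needs at least 2 ages", call. = FALSE)
  if (is.null(names(edf)) && length(edf) == 1) {
    edf <- list(lambda = edf, mu = edf, sigma = edf)
  }
  edf <- as.list(edf)
  for (param in c("lambda", "mu", "sigma")) {
    df <- edf[[param]]
    if (is.null(df)) df <- n_ages
    if (df < 1 || df > n_ages) {
      stop(sprintf("edf for %s must lie in [1, %d]", param, n_ages), call. = FALSE)
    }
    if (df == n_ages) next  # interpolation: unchanged
    age <- lms_series$age_group
    yv <- lms_series[[param]]
    fit <- if (df == 1) rep(mean(yv), n_ages) else {
      stats::fitted(stats::lm(yv ~ stats::poly(age, degree = df - 1)))
    }
    lms_series[[param]] <- as.numeric(fit)
  }
  lms_series
}

#' Median growth between the boundary ages of a reference
#'
#' For each sex and measure, the difference between the median (P50, i.e. the
#' fitted M) at the oldest and youngest tabulated age: total median height
#' growth in cm, weight gain in kg, or BMI rise in kg/m^2 across the age
#' window.
#'
#' @param table a `percentile_table`.
#' @return a tibble with columns `sex`, `measure`, `age_first`, `age_last`,
#'   `p50_first`, `p50_last`, `change`.
#' @examples
#' median_growth_summary(south_punjab_reference())
#' @export
median_growth_summary <- function(table) {
  stopifnot(inherits(table, "percentile_table") || is.data.frame(table))
  out <- dplyr::summarise(
    dplyr::group_by(table, .data$sex, .data$measure),
    age_first = min(.data$age_group),
    age_last = max(.data$age_group),
    p50_first = .data$mu[which.min(.data$age_group)],
    p50_last = .data$mu[which.max(.data$age_group)],
    change = .data$p50_last - .data$p50_first,
    .groups = "drop"
  )
  if (any(out$age_first == out$age_last)) {
    warning("single-age series: change reported as 0 by convention", call. = FALSE)
  }
  out
}

validate_cohort <- function(cohort) {
  cohort <- tibble::as_tibble(cohort)
  need <- c("sex", "age_years", "height_cm", "weight_kg")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) {
    stop("cohort is missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!"subject_id" %in% names(cohort)) {
    cohort$subject_id <- sprintf("S%05d", seq_len(nrow(cohort)))
  }
  bad_sex <- !tolower(cohort$sex) %in% c("male", "female")
  if (any(bad_sex)) {
    stop(sprintf("unknown sex code(s): %s",
                 paste(unique(cohort$sex[bad_sex]), collapse = ", ")), call. = FALSE)
  }
  cohort$sex <- factor(tolower(cohort$sex), levels = c("male", "female"))
  num_ok <- is.finite(cohort$age_years) & is.finite(cohort$height_cm) &
    is.finite(cohort$weight_kg) & cohort$age_years >= 0 &
    cohort$height_cm > 0 & cohort$weight_kg > 0
  if (any(!num_ok)) {
    stop(sprintf("%d record(s) have non-positive or missing measurements; clean the cohort with read_cohort()",
                 sum(!num_ok)), call. = FALSE)
  }
  cohort$age_group <- as.integer(floor(cohort$age_years))
  cohort$bmi <- compute_bmi(cohort$weight_kg, cohort$height_cm)
  cohort
}
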