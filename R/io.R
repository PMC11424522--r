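#' Read and write cohort files
#'
#' Cohorts travel as comma-separated UTF-8 text with a header and columns
#' `id`, `sex`, `age_years`, `height_cm`, `weight_kg` ("." decimal
#' separator; sex as "male"/"female", case-insensitive on read, canonical
#' lower case on write).  On read, rows failing validation — unknown sex
#' code, missing or non-positive age, height or weight — are rejected and
#' counted per reason to standard error; more than `max_reject` of rows
#' rejected is a hard error.  BMI is derived from height and weight, never
#' read from the file.
#'
#' @param path file path.
#' @param max_reject maximum tolerated fraction of rejected rows.
#' @return `read_cohort()`: a validated cohort tibble (`subject_id`, `sex`,
#'   `age_years`, `age_group`, `height_cm`, `weight_kg`, `bmi`).
#'   `write_cohort()`: the path, invisibly.
#' @export
read_cohort <- function(path, max_reject = 0.1) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  need <- c("id", "sex", "age_years", "height_cm", "weight_kg")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("cohort file is missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  for (col in c("age_years", "height_cm", "weight_kg")) {
    raw[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
  }
  reasons <- list(
    "unknown sex code" = !tolower(raw$sex) %in% c("male", "female"),
    "missing or negative age" = !is.finite(raw$age_years) | raw$age_years < 0,
    "missing or non-positive height" = !is.finite(raw$height_cm) | raw$height_cm <= 0,
    "missing or non-positive weight" = !is.finite(raw$weight_kg) | raw$weight_kg <= 0
  )
  bad <- Reduce(`|`, reasons)
  for (why in names(reasons)) {
    n_why <- sum(reasons[[why]], na.rm = TRUE)
    if (n_why > 0) message(sprintf("rejected %d row(s): %s", n_why, why))
  }
  if (nrow(raw) > 0 && sum(bad) / nrow(raw) > max_reject) {
    stop(sprintf("%d of %d rows (%.1f%%) failed validation, above the %.0f%% limit",
                 sum(bad), nrow(raw), 100 * sum(bad) / nrow(raw), 100 * max_reject),
         call. = FALSE)
  }
  raw <- raw[!bad, , drop = FALSE]
  names(raw)[names(raw) == "id"] <- "subject_id"
  validate_cohort(raw[, c("subject_id", "sex", "age_years", "height_cm", "weight_kg")])
}

#' @rdname read_cohort
#' @param cohort a cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  out <- tibble::tibble(
    id = cohort$subject_id, sex = as.character(cohort$sex),
    age_years = format_full(cohort$age_years),
    height_cm = format_full(cohort$height_cm),
    weight_kg = format_full(cohort$weight_kg)
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read and write percentile reference tables
#'
#' The on-disk layout mirrors a published reference table: one row per
#' (sex, age group, measure) with the fitted `lambda`, `mu`, `sigma`, the
#' group size `n` and one column per percentile label.  Parameters and
#' percentile values are written at full precision (the round trip is
#' bit-exact); `display = TRUE` additionally writes `*_2dp` columns rounded
#' half away from zero for human readers, which are ignored on read.
#' A provenance block (config echo) is embedded as `#` comment lines.
#'
#' @param table a `percentile_table`.
#' @param path file path.
#' @param display also write 2-decimal display columns.
#' @return `read_percentile_table()`: a `percentile_table`;
#'   `write_percentile_table()`: the path, invisibly.
#' @export
write_percentile_table <- function(table, path, display = TRUE) {
  stopifnot(inherits(table, "percentile_table"))
  df <- tibble::as_tibble(table)
  pct_cols <- grep("^P[0-9.]+$", names(df), value = TRUE)
  if (display) {
    for (col in c("mu", pct_cols)) {
      df[[paste0(col, "_2dp")]] <- round_half_up(df[[col]], 2)
    }
  }
  # parameters and percentile values at full (round-trippable) precision
  for (col in c("lambda", "mu", "sigma", pct_cols)) {
    df[[col]] <- format_full(df[[col]])
  }
  prov <- attr(table, "provenance")
  header <- c(
    sprintf("# lmsgrowth percentile table (version %s)",
            as.character(utils::packageVersion("lmsgrowth"))),
    if (length(prov)) sprintf("# %s: %s", names(prov),
                              vapply(prov, function(v) paste(format(v), collapse = " "), character(1)))
  )
  writeLines(header, path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE, na = "", progress = FALSE)
  invisible(path)
}

#' @rdname write_percentile_table
#' @export
read_percentile_table <- function(path) {
  # read as text and convert with strtod, which (unlike the fast parser)
  # is correctly rounded, so the round trip is bit-exact
  df <- readr::read_csv(path, comment = "#", na = c("", "NA"),
                        col_types = readr::cols(.default = readr::col_character()),
                        show_col_types = FALSE, progress = FALSE)
  need <- c("sex", "age_group", "measure", "lambda", "mu", "sigma")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("percentile table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- df[, !grepl("_2dp$", names(df)), drop = FALSE]
  if (!"n" %in% names(df)) df$n <- NA_integer_
  pct_cols <- grep("^P[0-9.]+$", names(df), value = TRUE)
  for (col in c("lambda", "mu", "sigma", pct_cols)) {
    parsed <- as.numeric(df[[col]])
    bad <- !is.na(df[[col]]) & is.na(parsed)
    if (any(bad)) {
      stop(sprintf("malformed percentile table %s: non-numeric '%s' in column %s, data line %d",
                   path, df[[col]][which(bad)[1]], col, which(bad)[1]), call. = FALSE)
    }
    df[[col]] <- parsed
  }
  df$age_group <- as.integer(df$age_group)
  df$n <- as.integer(df$n)
  pct_cols <- pct_cols[order(label_to_p(pct_cols))]
  df$measure <- factor(df$measure, levels = c("height", "weight", "bmi"))
  df$sex <- factor(df$sex, levels = c("male", "female"))
  sets <- lapply(split(df, df$measure, drop = TRUE), function(block) {
    present <- pct_cols[colSums(!is.na(block[, pct_cols, drop = FALSE])) > 0]
    sort(label_to_p(present))
  })
  out <- df[, c("sex", "age_group", "measure", "lambda", "mu", "sigma", "n", pct_cols)]
  out <- dplyr::arrange(out, .data$sex, .data$measure, .data$age_group)
  new_percentile_table(out, percentile_sets = sets,
                       provenance = list(source = path))
}

#' Read and write back-substitution validation reports
#'
#' The per-age block is serialised as CSV at full precision with the
#' subsample fraction and seed embedded as `#` comment lines; the
#' per-measure summaries are a deterministic function of the per-age rows
#' and are recomputed on read, so a report regenerated from its own file is
#' identical.
#'
#' @param report a `validation_report`.
#' @param path file path.
#' @return `read_validation_report()`: a `validation_report`;
#'   `write_validation_report()`: the path, invisibly.
#' @export
write_validation_report <- function(report, path) {
  stopifnot(inherits(report, "validation_report"))
  writeLines(c(sprintf("# fraction: %.17g", report$fraction),
               sprintf("# seed: %d", report$seed)), path)
  by_age <- report$by_age
  for (col in c("actual_p50", "fitted_p50", "rel_error")) {
    by_age[[col]] <- format_full(by_age[[col]])
  }
  readr::write_csv(by_age, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_validation_report
#' @export
read_validation_report <- function(path) {
  lines <- readLines(path, n = 10)
  grab <- function(key) {
    hit <- grep(sprintf("^# %s:", key), lines, value = TRUE)
    if (!length(hit)) stop("missing '# ", key, ":' header in ", path, call. = FALSE)
    sub(sprintf("^# %s:\\s*", key), "", hit[1])
  }
  by_age <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                            col_types = readr::cols(.default = readr::col_character()),
                            progress = FALSE)
  for (col in c("actual_p50", "fitted_p50", "rel_error")) {
    by_age[[col]] <- as.numeric(by_age[[col]])
  }
  by_age$age_group <- as.integer(by_age$age_group)
  by_age$sex <- factor(by_age$sex, levels = c("male", "female"))
  by_age$measure <- factor(by_age$measure, levels = c("height", "weight", "bmi"))
  summarise_validation(by_age, fraction = as.numeric(grab("fraction")),
                       seed = as.integer(grab("seed")))
}

# render a double so that parsing it back restores the identical value
format_full <- function(x) {
  ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
}

#' Render a percentile chart
#'
#' Plots the smoothed percentile curves of one measure and sex against age:
#' one labelled curve per percentile in the table's set.  The curves cannot
#' cross, because the centile transform is strictly increasing in p at
#' every age.
#'
#' @param table a `percentile_table` with at least two ages for the
#'   selection.
#' @param measure `"height"`, `"weight"` or `"bmi"`.
#' @param sex `"male"` or `"female"`.
#' @param path optional output file (`.png` or `.pdf`); written
#'   deterministically for fixed inputs.
#' @param width,height,dpi device geometry passed to [ggplot2::ggsave()].
#' @return the ggplot object, invisibly.
#' @export
render_chart <- function(table, measure, sex, path = NULL,
                         width = 7, height = 5, dpi = 150) {
  stopifnot(inherits(table, "percentile_table"))
  measure <- match.arg(measure, c("height", "weight", "bmi"))
  sex <- match.arg(sex, c("male", "female"))
  df <- tibble::as_tibble(table)
  df <- df[as.character(df$measure) == measure & as.character(df$sex) == sex, , drop = FALSE]
  if (nrow(df) < 2) {
    stop(sprintf("need at least 2 ages to draw curves for %s/%s (got %d)",
                 sex, measure, nrow(df)), call. = FALSE)
  }
  pct_cols <- grep("^P[0-9.]+$", names(df), value = TRUE)
  long <- tidyr::pivot_longer(df[, c("age_group", pct_cols)], cols = -"age_group",
                              names_to = "percentile", values_to = "value")
  long <- long[!is.na(long$value), , drop = FALSE]
  long$percentile <- factor(long$percentile,
                            levels = pct_cols[order(label_to_p(pct_cols))])
  unit <- c(height = "height (cm)", weight = "weight (kg)",
            bmi = expression(BMI ~ (kg/m^2)))[[measure]]
  plt <- ggplot2::ggplot(long, ggplot2::aes(x = .data$age_group, y = .data$value,
                                            colour = .data$percentile)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::scale_colour_viridis_d(end = 0.9) +
    ggplot2::labs(x = "age (completed years)", y = unit, colour = NULL,
                  title = sprintf("%s percentiles, %s", measure, sex)) +
    ggplot2::theme_minimal(base_size = 11)
  if (!is.null(path)) {
    ggplot2::ggsave(path, plt, width = width, height = height, dpi = dpi)
  }
  invisible(plt)
}
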