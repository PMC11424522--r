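#' Compare local medians with external reference standards
#'
#' Joins a local reference's P50 series against one or more external
#' reference median tables (for example WHO, US-CDC or other national
#' references) on (sex, age group, measure), and reports the per-age
#' difference `local - external` plus per-source summary extremes.
#' External cells that are absent (some sources publish no weight medians)
#' are skipped with a message.
#'
#' @param local a `percentile_table` (its `mu` column is the local P50).
#' @param external a data frame of external medians with columns `source`,
#'   `sex`, `age` (or `age_group`), `measure`, `p50`; see
#'   [external_reference_medians()] for the shipped table.
#' @return an object of class `reference_comparison`: a list with `by_age`
#'   (source, sex, measure, age_group, local_p50, external_p50, difference)
#'   and `summary` (per source/sex/measure min, max and mean difference).
#' @examples
#' cmp <- compare_medians(south_punjab_reference(), external_reference_medians())
#' cmp$summary
#' @export
compare_medians <- function(local, external) {
  stopifnot(is.data.frame(local))
  external <- tibble::as_tibble(external)
  if ("age" %in% names(external) && !"age_group" %in% names(external)) {
    external <- dplyr::rename(external, age_group = "age")
  }
  need <- c("source", "sex", "age_group", "measure", "p50")
  miss <- setdiff(need, names(external))
  if (length(miss)) stop("external reference is missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(external[, c("source", "sex", "age_group", "measure")])) {
    stop("duplicate (source, sex, age, measure) keys in external reference", call. = FALSE)
  }
  absent <- is.na(external$p50)
  if (any(absent)) {
    message(sprintf("skipping %d external cell(s) with no published median", sum(absent)))
    external <- external[!absent, , drop = FALSE]
  }
  loc <- tibble::as_tibble(local)[, c("sex", "age_group", "measure", "mu")]
  names(loc)[names(loc) == "mu"] <- "local_p50"
  loc$sex <- as.character(loc$sex)
  loc$measure <- as.character(loc$measure)
  external$sex <- as.character(external$sex)
  external$measure <- as.character(external$measure)
  by_age <- dplyr::inner_join(external, loc, by = c("sex", "age_group", "measure"))
  if (nrow(by_age) == 0) {
    stop("no overlapping (sex, age, measure) cells between local and external references",
         call. = FALSE)
  }
  ratio <- by_age$p50 / by_age$local_p50
  if (any(ratio > 3 | ratio < 1 / 3)) {
    warning("external medians differ from local by more than 3x; check units",
            call. = FALSE)
  }
  by_age <- tibble::tibble(
    source = by_age$source, sex = by_age$sex, measure = by_age$measure,
    age_group = by_age$age_group, local_p50 = by_age$local_p50,
    external_p50 = by_age$p50, difference = by_age$local_p50 - by_age$p50
  )
  by_age <- dplyr::arrange(by_age, .data$source, .data$sex, .data$measure, .data$age_group)
  summary <- dplyr::summarise(
    dplyr::group_by(by_age, .data$source, .data$sex, .data$measure),
    min_difference = min(.data$difference),
    max_difference = max(.data$difference),
    mean_difference = mean(.data$difference),
    .groups = "drop"
  )
  structure(list(by_age = by_age, summary = summary), class = "reference_comparison")
}

#' @export
print.reference_comparison <- function(x, ...) {
  cat(sprintf("Median comparison against %d external source(s), %d overlapping cell(s)\n",
              length(unique(x$by_age$source)), nrow(x$by_age)))
  df <- as.data.frame(x$summary)
  for (col in c("min_difference", "max_difference", "mean_difference")) {
    df[[col]] <- round_half_up(df[[col]], 2)
  }
  print(df, row.names = FALSE)
  invisible(x)
}
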