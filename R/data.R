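#' Published South Punjab adolescent growth reference
#'
#' The published age- and sex-specific reference for 12--16-year-old
#' adolescents surveyed in South Punjab, Pakistan (2019 school survey):
#' per-age LMS parameters and the percentile cells as printed, shipped with
#' the package as a plain-text fixture.
#'
#' `south_punjab_reference()` returns the full `percentile_table` with the
#' printed percentile cells; `south_punjab_lms()` returns just the L/M/S
#' parameter rows (the input [reference_from_lms()] and [generate_cohort()]
#' consume).  A handful of printed off-median cells are internally
#' inconsistent with their own row's L/M/S under the LMS transform (see the
#' package vignette); the loaders return the cells exactly as printed.
#'
#' @return `south_punjab_reference()`: a `percentile_table`.
#'   `south_punjab_lms()`: a tibble with columns `sex`, `age_group`,
#'   `measure`, `lambda`, `mu`, `sigma`, `n`.
#' @examples
#' south_punjab_lms()
#' @export
south_punjab_reference <- function() {
  read_percentile_table(pkg_extdata("south_punjab_reference.csv"))
}

#' @rdname south_punjab_reference
#' @export
south_punjab_lms <- function() {
  tbl <- south_punjab_reference()
  tibble::as_tibble(tbl)[, c("sex", "age_group", "measure", "lambda", "mu", "sigma", "n")]
}

#' Published external reference medians
#'
#' Median (P50) height, weight and BMI values by sex and age from five
#' external growth references — WHO (2006), US-CDC (2012), India (2011),
#' Turkey (2015) and China (2013) — as tabulated for comparison with the
#' South Punjab reference.  WHO publishes no weight-for-age medians in this
#' age range; those cells are absent (`NA`), not zero.
#'
#' @return a tibble with columns `source`, `sex`, `age`, `measure`, `p50`.
#' @examples
#' head(external_reference_medians())
#' @export
external_reference_medians <- function() {
  readr::read_csv(pkg_extdata("external_reference_medians.csv"),
                  col_types = "ccicd", progress = FALSE)
}

#' Published back-substitution test values
#'
#' The published back-substitution cross-validation of the South Punjab
#' reference: per sex, measure and age, the full-data ("actual") and
#' subsample ("fitted") P50 values and the printed per-row signed relative
#' error.
#'
#' @return a tibble with columns `measure`, `sex`, `age`, `actual_p50`,
#'   `fitted_p50`, `printed_error`.
#' @examples
#' south_punjab_backsubstitution()
#' @export
south_punjab_backsubstitution <- function() {
  readr::read_csv(pkg_extdata("south_punjab_backsubstitution.csv"),
                  col_types = "cciddd", progress = FALSE)
}

pkg_extdata <- function(file) {
  path <- system.file("extdata", file, package = "lmsgrowth")
  if (path == "") stop("fixture not found: ", file, call. = FALSE)
  path
}
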