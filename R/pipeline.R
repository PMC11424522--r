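#' Read a pipeline run configuration
#'
#' A flat YAML key-value file configures a whole reference-construction run.
#' Every key has a documented default; unknown keys are rejected.  Keys and
#' defaults:
#'
#' * `seed` (1): master seed for simulation and validation subsampling.
#' * `n_per_cell` (297): children per (sex, age) cell of the synthetic
#'   cohort.
#' * `rho` (0.5): height--weight copula correlation.
#' * `bmi_mode` ("derive_from_hw"): see [generate_cohort()].
#' * `age_min`, `age_max` (12, 16): inclusive age window.
#' * `fraction` (0.5): back-substitution subsample fraction.
#' * `smooth_edf` (NULL): cross-age smoothing edf, NULL for raw per-age
#'   fits.
#' * `min_n` (20): minimum cell size for fitting.
#' * `charts` (TRUE): render percentile charts.
#' * `out_dir` ("lmsgrowth-run"): output directory.
#' * `cohort_file` (NULL): read this cohort instead of simulating one.
#' * `external_reference` ("builtin"): path to an external-median CSV, or
#'   "builtin" for the shipped table.
#'
#' @param path YAML file path.
#' @return a validated config list with all defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  defaults <- list(
    seed = 1L, n_per_cell = 297L, rho = 0.5, bmi_mode = "derive_from_hw",
    age_min = 12L, age_max = 16L, fraction = 0.5, smooth_edf = NULL,
    min_n = 20L, charts = TRUE, out_dir = "lmsgrowth-run",
    cohort_file = NULL, external_reference = "builtin"
  )
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  utils::modifyList(defaults, cfg)
}

#' Run the full reference-construction pipeline
#'
#' One call performs the whole workflow from a single configuration:
#' simulate (or read) a cohort, fit the age- and sex-specific LMS reference,
#' cross-validate it by back-substitution, compare its medians against
#' external references, and render the percentile charts.  All outputs are
#' written under `out_dir`; no network access is needed.
#'
#' @param config a config list from [read_run_config()], or the path of a
#'   YAML config file.
#' @param out_dir overrides the config's output directory.
#' @return invisibly, a list with `cohort`, `reference`, `validation`,
#'   `comparison` and `paths` (the files written).
#' @examples
#' \donttest{
#' cfg_file <- tempfile(fileext = ".yaml")
#' writeLines(c("seed: 7", "n_per_cell: 60", "min_n: 25",
#'              sprintf("out_dir: %s", file.path(tempdir(), "run"))), cfg_file)
#' res <- run_pipeline(cfg_file)
#' res$validation
#' }
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (!is.null(out_dir)) config$out_dir <- out_dir
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  age_window <- c(config$age_min, config$age_max)

  message("step 1/5: cohort")
  cohort <- if (!is.null(config$cohort_file)) {
    read_cohort(config$cohort_file)
  } else {
    generate_cohort(n_per_cell = config$n_per_cell, seed = config$seed,
                    rho = config$rho, bmi_mode = config$bmi_mode)
  }
  paths$cohort <- file.path(config$out_dir, "cohort.csv")
  write_cohort(cohort, paths$cohort)

  message("step 2/5: LMS reference fit")
  reference <- build_reference(cohort, age_window = age_window,
                               smooth_edf = config$smooth_edf,
                               min_n = config$min_n)
  paths$reference <- file.path(config$out_dir, "reference.csv")
  write_percentile_table(reference, paths$reference)

  message("step 3/5: back-substitution validation")
  validation <- back_substitution(cohort, fraction = config$fraction,
                                  seed = config$seed, age_window = age_window,
                                  min_n = config$min_n)
  paths$validation <- file.path(config$out_dir, "validation.csv")
  write_validation_report(validation, paths$validation)

  message("step 4/5: external median comparison")
  external <- if (identical(config$external_reference, "builtin")) {
    external_reference_medians()
  } else {
    readr::read_csv(config$external_reference, show_col_types = FALSE, progress = FALSE)
  }
  comparison <- compare_medians(reference, external)
  paths$comparison <- file.path(config$out_dir, "comparison.csv")
  readr::write_csv(comparison$by_age, paths$comparison, progress = FALSE)

  if (isTRUE(config$charts)) {
    message("step 5/5: percentile charts")
    paths$charts <- character()
    for (m in c("height", "weight", "bmi")) {
      for (s in c("male", "female")) {
        f <- file.path(config$out_dir, sprintf("chart_%s_%s.png", m, s))
        render_chart(reference, m, s, path = f)
        paths$charts <- c(paths$charts, f)
      }
    }
  } else {
    message("step 5/5: charts skipped")
  }
  invisible(list(cohort = cohort, reference = reference, validation = validation,
                 comparison = comparison, paths = paths))
}
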