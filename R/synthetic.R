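#' Generate a synthetic adolescent cohort from an LMS parameter table
#'
#' Draws a cross-sectional cohort whose height and weight within each
#' age--sex cell follow the Box--Cox-normal (LMS) distribution of a supplied
#' parameter table: a standard-normal deviate z is drawn per child and
#' mapped through \eqn{y = M (1 + L S z)^{1/L}} (log form at \eqn{L = 0}).
#' The default parameter table is the published South Punjab adolescent
#' reference ([south_punjab_lms()]), ages 12--16, two sexes, so the default
#' cohort emulates the survey the reference was built from (2,970 children,
#' about 600 per age group, split evenly by sex).
#'
#' Height and weight deviates are coupled through a Gaussian copula with
#' correlation `rho` (default 0.5), so each child's BMI — recomputed
#' arithmetically from its height and weight in `"derive_from_hw"` mode —
#' is physiologically coherent.  In `"independent_lms"` mode BMI is instead
#' drawn from its own LMS triple, which matches a published BMI reference
#' exactly but breaks within-child arithmetic consistency.
#'
#' The rare z with \eqn{1 + L S z \le 0} is rejected and redrawn; a cell
#' whose theoretical rejection rate \eqn{\Phi(-1/|LS|)} exceeds `max_reject`
#' raises an error (the parameters are implausible) rather than silently
#' truncating the distribution.  Ages are drawn uniformly within the
#' completed year.
#' Identical spec and seed give an identical cohort.
#'
#' @param lms_table data frame with columns `sex`, `age` (or `age_group`),
#'   `measure`, `lambda`, `mu`, `sigma`; must contain height and weight
#'   triples for every (sex, age), and BMI triples in `"independent_lms"`
#'   mode.
#' @param n_per_cell children per (sex, age) cell; the default 297 yields
#'   2,970 records on the default 2 x 5 grid.
#' @param seed integer seed; required.
#' @param rho Gaussian-copula correlation between the height and weight
#'   deviates, in \[-1, 1\].
#' @param bmi_mode `"derive_from_hw"` (default) or `"independent_lms"`.
#' @param max_reject maximum tolerated positivity rejection rate per cell.
#' @return a cohort tibble: `subject_id`, `sex`, `age_years`, `age_group`,
#'   `height_cm`, `weight_kg`, `bmi`.
#' @examples
#' cohort <- generate_cohort(n_per_cell = 20, seed = 42)
#' dplyr::count(cohort, sex, age_group)
#' @export
generate_cohort <- function(lms_table = south_punjab_lms(), n_per_cell = 297,
                            seed, rho = 0.5,
                            bmi_mode = c("derive_from_hw", "independent_lms"),
                            max_reject = 0.01) {
  bmi_mode <- match.arg(bmi_mode)
  if (missing(seed)) stop("an explicit `seed` is required for reproducibility", call. = FALSE)
  if (!is.numeric(n_per_cell) || n_per_cell < 0) stop("`n_per_cell` must be >= 0", call. = FALSE)
  if (!is.numeric(rho) || abs(rho) > 1) stop("`rho` must lie in [-1, 1]", call. = FALSE)
  lms_table <- tibble::as_tibble(lms_table)
  if ("age" %in% names(lms_table) && !"age_group" %in% names(lms_table)) {
    lms_table <- dplyr::rename(lms_table, age_group = "age")
  }
  lms_table$sex <- as.character(lms_table$sex)
  lms_table$measure <- as.character(lms_table$measure)
  cells <- unique(lms_table[, c("sex", "age_group")])
  need <- c("height", "weight", if (bmi_mode == "independent_lms") "bmi")
  for (m in need) {
    have <- unique(lms_table[lms_table$measure == m, c("sex", "age_group")])
    if (nrow(dplyr::anti_join(cells, have, by = c("sex", "age_group")))) {
      stop(sprintf("`lms_table` must provide a %s triple for every (sex, age) cell", m),
           call. = FALSE)
    }
  }
  if (n_per_cell == 0) {
    return(tibble::tibble(subject_id = character(), sex = factor(levels = c("male", "female")),
                          age_years = numeric(), age_group = integer(),
                          height_cm = numeric(), weight_kg = numeric(), bmi = numeric()))
  }
  set.seed(seed)
  triple <- function(sex, age, m) {
    row <- lms_table[lms_table$sex == sex & lms_table$age_group == age &
                       lms_table$measure == m, ]
    list(lambda = row$lambda[1], mu = row$mu[1], sigma = row$sigma[1])
  }
  # a triple's theoretical positivity-violation probability P(1 + L*S*z <= 0)
  reject_rate <- function(tr) {
    if (abs(tr$lambda) < .lms_zero_tol) 0 else stats::pnorm(-1 / abs(tr$lambda * tr$sigma))
  }
  check_plausible <- function(tr, label) {
    rate <- reject_rate(tr)
    if (rate > max_reject) {
      stop(sprintf("positivity rejection rate %.2f%% in cell %s exceeds %.2f%%: implausible LMS parameters",
                   100 * rate, label, 100 * max_reject), call. = FALSE)
    }
  }
  # rejection-sample z until 1 + L*S*z > 0
  draw_z <- function(n, tr) {
    z <- stats::rnorm(n)
    repeat {
      bad <- abs(tr$lambda) >= .lms_zero_tol & (1 + tr$lambda * tr$sigma * z) <= 0
      if (!any(bad)) break
      z[bad] <- stats::rnorm(sum(bad))
    }
    z
  }
  out <- vector("list", nrow(cells))
  for (k in seq_len(nrow(cells))) {
    sex <- cells$sex[k]; age <- cells$age_group[k]
    th <- triple(sex, age, "height")
    tw <- triple(sex, age, "weight")
    check_plausible(th, sprintf("%s/height/%d", sex, age))
    check_plausible(tw, sprintf("%s/weight/%d", sex, age))
    zh <- draw_z(n_per_cell, th)
    # couple weight to height through the copula, then repair positivity
    zw <- rho * zh + sqrt(1 - rho^2) * stats::rnorm(n_per_cell)
    bad <- abs(tw$lambda) >= .lms_zero_tol & (1 + tw$lambda * tw$sigma * zw) <= 0
    if (any(bad)) zw[bad] <- draw_z(sum(bad), tw)
    height <- lms_centile_from_z(zh, th)
    weight <- lms_centile_from_z(zw, tw)
    cell <- tibble::tibble(
      sex = sex, age_years = age + stats::runif(n_per_cell), age_group = age,
      height_cm = height, weight_kg = weight,
      bmi = compute_bmi(weight, height)
    )
    if (bmi_mode == "independent_lms") {
      tb <- triple(sex, age, "bmi")
      check_plausible(tb, sprintf("%s/bmi/%d", sex, age))
      cell$bmi <- lms_centile_from_z(draw_z(n_per_cell, tb), tb)
    }
    out[[k]] <- cell
  }
  cohort <- dplyr::bind_rows(out)
  cohort <- tibble::add_column(cohort,
                               subject_id = sprintf("S%05d", seq_len(nrow(cohort))),
                               .before = 1)
  cohort$sex <- factor(cohort$sex, levels = c("male", "female"))
  cohort$age_group <- as.integer(cohort$age_group)
  cohort
}

# forward LMS transform of an already-drawn standard-normal deviate
lms_centile_from_z <- function(z, tr) {
  if (abs(tr$lambda) < .lms_zero_tol) {
    tr$mu * exp(tr$sigma * z)
  } else {
    tr$mu * (1 + tr$lambda * tr$sigma * z)^(1 / tr$lambda)
  }
}

#' Emulate a stratified school-sampling design
#'
#' Produces the cluster labels of a stratified random school survey —
#' `strata` administrative strata, `schools_per_stratum` schools drawn per
#' stratum, `students_per_school` students per school (the default
#' 3 x 20 x 50 = 3,000) — so design-aware analyses can be exercised on
#' synthetic cohorts.  Labels are sampling metadata only; they never alter
#' measurement distributions.
#'
#' @param strata number of strata.
#' @param schools_per_stratum schools sampled per stratum.
#' @param students_per_school students sampled per school.
#' @param seed integer seed (labels are assigned in a seeded random order).
#' @return a tibble with one row per student: `stratum`, `school`,
#'   `student`, where `school` is unique across strata.
#' @examples
#' design <- emulate_sampling_design(seed = 1)
#' nrow(design); length(unique(design$school))
#' @export
emulate_sampling_design <- function(strata = 3, schools_per_stratum = 20,
                                    students_per_school = 50, seed) {
  if (missing(seed)) stop("an explicit `seed` is required for reproducibility", call. = FALSE)
  counts <- c(strata, schools_per_stratum, students_per_school)
  if (!is.numeric(counts) || any(counts < 1) || any(counts != floor(counts))) {
    stop("strata, schools and students per school must be positive integers", call. = FALSE)
  }
  set.seed(seed)
  idx <- tidyr::expand_grid(
    stratum = sprintf("stratum_%d", seq_len(strata)),
    school_in_stratum = seq_len(schools_per_stratum),
    student = seq_len(students_per_school)
  )
  idx$school <- sprintf("%s_school_%02d", idx$stratum, idx$school_in_stratum)
  idx <- idx[sample(nrow(idx)), c("stratum", "school", "student")]
  tibble::as_tibble(idx)
}

#' Required sample size for a proportion under clustered sampling
#'
#' The standard survey sample-size equation
#' \deqn{n = \lceil Z^2 P Q / e^2 \times D \rceil,}
#' with P the anticipated proportion, Q = 1 - P, Z the normal deviate of
#' the confidence level, e the precision and D the design effect.
#'
#' @param P anticipated proportion, in (0, 1).
#' @param Z normal deviate for the confidence level (1.96 for 95%).
#' @param e absolute precision, > 0.
#' @param D design effect, >= 1.
#' @return the required sample size, as an integer (ceiling).
#' @examples
#' sample_size(P = 0.4)         # 369
#' sample_size(P = 0.5)         # 385
#' @export
sample_size <- function(P, Z = 1.96, e = 0.05, D = 1) {
  if (!is.numeric(P) || length(P) != 1 || P <= 0 || P >= 1) {
    stop("`P` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!is.numeric(Z) || Z <= 0) stop("`Z` must be positive", call. = FALSE)
  if (!is.numeric(e) || e <= 0) stop("`e` must be positive", call. = FALSE)
  if (!is.numeric(D) || D < 1) stop("`D` must be at least 1", call. = FALSE)
  Q <- 1 - P
  as.integer(ceiling(Z^2 * P * Q / e^2 * D))
}
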