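test_that("BMI derivation follows weight / height_m^2", {
  expect_equal(compute_bmi(50, 160), 50 / 1.6^2)
  expect_identical(compute_bmi(80, 200), 20)
  expect_error(compute_bmi(0, 160), "strictly positive")
  expect_error(compute_bmi(50, NA), "finite")
  expect_equal(compute_bmi(c(50, 80), c(160, 200)), c(50 / 1.6^2, 20))
})

test_that("stratification splits by sex and completed year, one group per measure", {
  cohort <- tibble::tibble(
    subject_id = sprintf("S%02d", 1:10),
    sex = rep(c("male", "female"), 5),
    age_years = c(12.0, 12.2, 12.5, 12.9, 12.99, 12.1, 12.4, 12.6, 12.3, 12.8),
    height_cm = runif(10, 140, 160), weight_kg = runif(10, 35, 50)
  )
  groups <- stratify_cohort(cohort)
  expect_equal(nrow(groups), 6)                      # 2 sexes x 3 measures, age 12 only
  expect_true(all(groups$age_group == 12L))          # floor convention
  expect_equal(sum(groups$n), 30)                    # each record in all 3 measures
  # records outside the window are excluded with a message
  cohort$age_years[1] <- 45
  expect_message(g2 <- stratify_cohort(cohort), "outside the age window")
  expect_equal(sum(g2$n), 27)
})

test_that("a reference built from a synthetic cohort is self-consistent", {
  lms <- south_punjab_lms()
  cohort <- generate_cohort(lms, n_per_cell = 250, seed = 21)
  ref <- build_reference(cohort, min_n = 100)
  expect_s3_class(ref, "percentile_table")
  expect_equal(nrow(ref), 30)                        # 2 sexes x 5 ages x 3 measures
  # P50 column equals the fitted median exactly
  expect_identical(ref$P50, ref$mu)
  # every percentile cell agrees with its own row's triple through the transform
  for (i in seq_len(nrow(ref))) {
    p <- attr(ref, "percentile_sets")[[as.character(ref$measure[i])]]
    cells <- unlist(ref[i, paste0("P", round(100 * p))])
    expect_equal(unname(cells),
                 lms_centile(p, ref$lambda[i], ref$mu[i], ref$sigma[i]))
  }
  # fitted P50 lies between the empirical 40th and 60th percentiles (n = 250)
  groups <- stratify_cohort(cohort)
  joined <- merge(as.data.frame(ref[, c("sex", "age_group", "measure", "mu")]),
                  as.data.frame(groups))
  for (i in seq_len(nrow(joined))) {
    q <- quantile(joined$values[[i]], c(0.4, 0.6))
    expect_gt(joined$mu[i], q[1])
    expect_lt(joined$mu[i], q[2])
  }
  # bit-reproducible: same cohort, same options, identical table
  expect_identical(ref, build_reference(cohort, min_n = 100))
})

test_that("the reference build recovers the generating medians within 1%", {
  lms <- south_punjab_lms()
  boys <- lms[lms$sex == "male", ]
  cohort <- generate_cohort(boys, n_per_cell = 600, seed = 31)
  ref <- build_reference(cohort)
  fitted <- merge(as.data.frame(ref[, c("sex", "age_group", "measure", "mu")]),
                  as.data.frame(boys[boys$measure %in% c("height", "weight"), ]),
                  by = c("sex", "age_group", "measure"))
  expect_equal(nrow(fitted), 10)
  expect_true(all(abs(fitted$mu.x / fitted$mu.y - 1) < 0.01))
})

test_that("single-group cohorts and undersized cells are handled", {
  y <- draw_bccg(200, 0.2, 45, 0.18, seed = 5)
  h <- draw_bccg(200, 3, 150, 0.07, seed = 6)
  cohort <- tibble::tibble(subject_id = sprintf("S%03d", 1:200), sex = "male",
                           age_years = 12 + runif(200), height_cm = h, weight_kg = y)
  ref <- build_reference(cohort, age_window = c(12, 12))
  expect_equal(nrow(ref), 3)                         # one row per measure
  expect_identical(ref$P50, ref$mu)
  # grid cells below min_n: error by default, skipped when allowed
  expect_error(build_reference(cohort, age_window = c(12, 13)), "minimum fitting size")
  expect_warning(ref2 <- build_reference(cohort, age_window = c(12, 13),
                                         allow_small = TRUE), "unfittable")
  expect_equal(nrow(ref2), 3)
})

test_that("cross-age smoothing honours its degrees of freedom", {
  lms <- south_punjab_lms()
  strand <- lms[lms$sex == "male" & lms$measure == "height", ]
  # edf equal to the number of ages: interpolation, unchanged
  expect_equal(smooth_lms_series(strand, edf = 5), strand)
  # constant series: unchanged at any edf
  const <- strand
  const$lambda <- 2; const$mu <- 150; const$sigma <- 0.05
  for (edf in 1:4) {
    sm <- smooth_lms_series(const, edf = edf)
    expect_equal(sm$mu, const$mu)
    expect_equal(sm$lambda, const$lambda)
  }
  # cubic fit to the monotone published median series stays monotone
  sm3 <- smooth_lms_series(strand, edf = 3)
  expect_true(all(diff(sm3$mu) >= 0))
  expect_error(smooth_lms_series(strand, edf = 6), "must lie in")
  expect_error(smooth_lms_series(strand[1, ], edf = 1), "at least 2 ages")
  # per-parameter edf: smooth mu only
  sm_mu <- smooth_lms_series(strand, edf = c(lambda = 5, mu = 2, sigma = 5))
  expect_equal(sm_mu$lambda, strand$lambda)
  expect_false(isTRUE(all.equal(sm_mu$mu, strand$mu)))
  # build_reference accepts smoothing end to end
  cohort <- generate_cohort(n_per_cell = 120, seed = 41)
  ref_sm <- build_reference(cohort, smooth_edf = 3, min_n = 50)
  expect_equal(nrow(ref_sm), 30)
  expect_identical(ref_sm$P50, ref_sm$mu)
})

test_that("median growth summary reproduces the published gain figures", {
  summary <- median_growth_summary(south_punjab_reference())
  get <- function(s, m) summary$change[summary$sex == s & summary$measure == m]
  expect_equal(get("male", "height"), 18.07)
  expect_equal(get("female", "height"), 10.49)
  expect_equal(get("male", "weight"), 12.30)
  expect_equal(get("male", "bmi"), 0.89)
  expect_equal(get("female", "weight"), 8.42)
  # single-age table: zero change, flagged
  one_age <- reference_from_lms(south_punjab_lms()[south_punjab_lms()$age_group == 12, ])
  expect_warning(s1 <- median_growth_summary(one_age), "single-age")
  expect_true(all(s1$change == 0))
})
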