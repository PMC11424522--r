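test_that("centile transform reproduces published reference cells and closed forms", {
  # published boys' reference rows, age 12
  expect_equal(round_half_up(lms_centile(0.90, 3.020, 149.72, 0.069)), 161.93)
  expect_equal(round_half_up(lms_centile(0.03, 0.531, 37.38, 0.246)), 21.98)
  # at the median the transform is the identity
  expect_identical(lms_centile(0.5, 3.020, 149.72, 0.069), 149.72)
  expect_identical(lms_centile(0.5, 0, 100, 0.1), 100)
  # lognormal limit: closed form M*exp(S*z)
  expect_equal(round_half_up(lms_centile(0.975, 0, 100, 0.1)), 121.65)
  expect_equal(lms_centile(0.975, 0, 100, 0.1), 100 * exp(0.1 * qnorm(0.975)))
})

test_that("centile is continuous at lambda = 0", {
  p <- seq(0.01, 0.99, by = 0.01)
  for (sigma in c(0.05, 0.1, 0.3)) {
    direct <- 100 * (1 + 1e-8 * sigma * qnorm(p))^(1 / 1e-8)  # power form just off zero
    expect_lt(max(abs(direct - lms_centile(p, 0, 100, sigma))), 1e-6 * 100)
    expect_lt(max(abs(lms_centile(p, 1e-8, 100, sigma) - lms_centile(p, 0, 100, sigma))),
              1e-6 * 100)
  }
})

test_that("centile and zscore are strictly monotone and mutually inverse", {
  p <- seq(0.01, 0.99, by = 0.01)
  triples <- list(c(3.020, 149.72, 0.069), c(-1.879, 17.48, 0.125),
                  c(0, 16, 0.2), c(0.531, 37.38, 0.246))
  for (tr in triples) {
    cent <- lms_centile(p, tr[1], tr[2], tr[3])
    expect_true(all(diff(cent) > 0))
    # round trip back to the normal quantile
    expect_lt(max(abs(lms_zscore(cent, tr[1], tr[2], tr[3]) - qnorm(p))), 1e-9)
    # zscore increasing in y
    y <- seq(0.7, 1.4, by = 0.05) * tr[2]
    expect_true(all(diff(lms_zscore(y, tr[1], tr[2], tr[3])) > 0))
  }
})

test_that("zscore maps the median to zero and inverts published cells", {
  expect_identical(lms_zscore(149.72, 3.020, 149.72, 0.069), 0)
  # published P3 cell of the boys' height row at age 12
  expect_equal(lms_zscore(126.98, 3.020, 149.72, 0.069), qnorm(0.03), tolerance = 2e-3)
  # log-form identity: y = M*exp(S) is one coefficient of variation above M
  expect_equal(lms_zscore(100 * exp(0.1), 0, 100, 0.1), 1, tolerance = 1e-12)
})

test_that("transforms reject invalid inputs and name the offending percentile", {
  expect_error(lms_centile(0, 1, 100, 0.1), "between 0 and 1")
  expect_error(lms_centile(0.5, 1, -1, 0.1), "mu")
  expect_error(lms_centile(0.5, 1, 100, 0), "sigma")
  expect_error(lms_centile(0.5, NA, 100, 0.1), "finite")
  expect_error(lms_zscore(-5, 1, 100, 0.1), "strictly positive")
  # 1 + L*S*z goes negative far in the upper tail for strongly negative L
  expect_error(lms_centile(0.99, -2, 100, 0.5), "P99")
})

test_that("log-likelihood matches the closed form and is order-invariant", {
  # single observation at the median with L = 1: -ln M - ln S - ln(2*pi)/2
  expect_equal(lms_loglik(100, 1, 100, 0.1),
               -log(100) - log(0.1) - 0.5 * log(2 * pi), tolerance = 1e-9)
  expect_equal(round(lms_loglik(100, 1, 100, 0.1), 4), -3.2215)
  y <- draw_bccg(200, 0.5, 40, 0.2, seed = 11)
  expect_equal(lms_loglik(y, 0.5, 40, 0.2), lms_loglik(rev(sample(y)), 0.5, 40, 0.2))
  # symmetric two-point sample: likelihood peaks at the midpoint under L = 1
  y2 <- c(90, 110)
  ll <- sapply(c(90, 100, 110), function(m) lms_loglik(y2, 1, m, 0.1))
  expect_gt(ll[2], ll[1])
  expect_gt(ll[2], ll[3])
  expect_error(lms_loglik(numeric(0), 1, 100, 0.1), "nonempty")
  expect_error(lms_loglik(100, 1, -1, 0.1), "positive")
  expect_identical(lms_loglik(100, 1, -1, 0.1, probe = TRUE), -Inf)
})

test_that("maximum-likelihood fit recovers generating parameters", {
  y <- draw_bccg(5000, -0.5, 17, 0.13, seed = 101)
  fit <- lms_fit(y)
  expect_lt(abs(fit$lambda + 0.5), 0.3)
  expect_lt(abs(fit$mu / 17 - 1), 0.01)
  expect_lt(abs(fit$sigma / 0.13 - 1), 0.05)
  # lognormal data has Box-Cox power zero
  y0 <- draw_bccg(5000, 0, 16, 0.15, seed = 102)
  expect_lt(abs(lms_fit(y0)$lambda), 0.3)
})

test_that("fit attains at least the best point of a brute-force grid", {
  y <- draw_bccg(50, 0.5, 40, 0.2, seed = 7)
  fit <- lms_fit(y)
  cv <- sd(y) / mean(y)
  best_grid <- grid_best_loglik(
    y,
    lambdas = seq(-3, 3, length.out = 50),
    mus = seq(quantile(y, 0.4), quantile(y, 0.6), length.out = 50),
    sigmas = seq(cv / 2, 2 * cv, length.out = 50)
  )
  expect_gte(fit$loglik, best_grid - 1e-6)
})

test_that("fit is deterministic and rejects unusable samples", {
  y <- draw_bccg(100, 0.5, 40, 0.2, seed = 3)
  expect_identical(lms_fit(y)[c("lambda", "mu", "sigma")],
                   lms_fit(y)[c("lambda", "mu", "sigma")])
  expect_error(lms_fit(rep(40, 100)), "degenerate")
  expect_error(lms_fit(y[1:10]), "at least 20")
  expect_error(lms_fit(c(y, -1), min_n = 20), "strictly positive")
})

test_that("percentile specs carry full-precision normal quantiles", {
  spec <- percentile_spec(c(0.5, 0.03, 0.9))
  expect_equal(spec$label, c("P3", "P50", "P90"))
  expect_identical(spec$z[spec$p == 0.5], 0)
  expect_equal(spec$z, qnorm(spec$p))
  expect_error(percentile_spec(c(0.5, 1)), "between 0 and 1")
  expect_equal(default_percentiles("bmi"), c(0.05, 0.15, 0.5, 0.85, 0.9, 0.95))
})

test_that("published-table rounding is half away from zero", {
  expect_identical(round_half_up(c(0.005, -0.005, 2.675, 1.004)),
                   c(0.01, -0.01, 2.68, 1.00))
})
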