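#' The LMS (Box--Cox Cole--Green) transforms
#'
#' The LMS method summarises the distribution of a positive measurement by
#' three parameters: the Box--Cox power \eqn{L} (lambda) that removes
#' skewness, the median \eqn{M} (mu) and the coefficient of variation
#' \eqn{S} (sigma).  Under the model, \eqn{z = ((y/M)^L - 1)/(L S)} (or
#' \eqn{z = \log(y/M)/S} when \eqn{L = 0}) is standard normal, so any
#' centile or z-score follows in closed form:
#' \deqn{C_p = M (1 + L S z_p)^{1/L}, \qquad C_p = M \exp(S z_p) \ (L = 0),}
#' with \eqn{z_p} the standard-normal quantile of \eqn{p}.
#'
#' `lms_centile()` evaluates the centile transform; `lms_zscore()` is its
#' exact inverse.  Both are vectorised with the usual recycling rules.
#' Normal quantiles come from [stats::qnorm()] at full floating precision;
#' internal computation is never rounded (use [round_half_up()] only to
#' render published-style 2-decimal tables).
#'
#' The power transform is only defined while its argument
#' \eqn{1 + L S z > 0}; requesting a centile outside that range is an error
#' naming the offending percentile.  `|lambda| < 1e-7` switches to the
#' log-form (lognormal-limit) expressions for numerical stability.
#'
#' @param p probability in (0, 1); may be a vector.
#' @param y positive measurement value(s).
#' @param lambda Box--Cox power L (unitless; may be negative or zero).
#' @param mu median M, in measurement units; strictly positive.
#' @param sigma coefficient of variation S; strictly positive.
#' @return `lms_centile()`: the p-th centile of the measurement, in
#'   measurement units. `lms_zscore()`: the standard-normal equivalent
#'   deviate of `y`.
#' @examples
#' # published boys' height reference at age 12: L = 3.020, S = 0.069, M = 149.72
#' lms_centile(c(0.03, 0.5, 0.9), lambda = 3.020, mu = 149.72, sigma = 0.069)
#' lms_zscore(161.93, lambda = 3.020, mu = 149.72, sigma = 0.069)
#' @seealso [lms_fit()] to estimate the triple from data, [percentile_spec()]
#'   for label/probability bookkeeping.
#' @export
lms_centile <- function(p, lambda, mu, sigma) {
  check_probability(p)
  check_lms(lambda, mu, sigma)
  n <- max(length(p), length(lambda), length(mu), length(sigma))
  p <- rep_len(p, n)
  lambda <- rep_len(lambda, n)
  mu <- rep_len(mu, n)
  sigma <- rep_len(sigma, n)
  z <- stats::qnorm(p)
  arg <- 1 + lambda * sigma * z
  log_form <- abs(lambda) < .lms_zero_tol
  bad <- !log_form & arg <= 0
  if (any(bad)) {
    stop(sprintf(
      "Box-Cox argument 1 + L*S*z is non-positive for percentile %s (lambda = %g, sigma = %g)",
      pct_label(p[which(bad)[1]]), lambda[which(bad)[1]], sigma[which(bad)[1]]
    ), call. = FALSE)
  }
  out <- numeric(n)
  out[log_form] <- mu[log_form] * exp(sigma[log_form] * z[log_form])
  i <- !log_form
  out[i] <- mu[i] * arg[i]^(1 / lambda[i])
  out
}

#' @rdname lms_centile
#' @export
lms_zscore <- function(y, lambda, mu, sigma) {
  if (!is.numeric(y) || anyNA(y) || any(!is.finite(y))) {
    stop("`y` must be finite and numeric", call. = FALSE)
  }
  if (any(y <= 0)) stop("measurements must be strictly positive", call. = FALSE)
  check_lms(lambda, mu, sigma)
  n <- max(length(y), length(lambda), length(mu), length(sigma))
  y <- rep_len(y, n)
  lambda <- rep_len(lambda, n)
  mu <- rep_len(mu, n)
  sigma <- rep_len(sigma, n)
  log_form <- abs(lambda) < .lms_zero_tol
  z <- numeric(n)
  z[log_form] <- log(y[log_form] / mu[log_form]) / sigma[log_form]
  i <- !log_form
  z[i] <- ((y[i] / mu[i])^lambda[i] - 1) / (lambda[i] * sigma[i])
  z
}

# switch point between the power-form and log-form expressions
.lms_zero_tol <- 1e-7

#' Box--Cox Cole--Green log-likelihood
#'
#' Log-likelihood of one group of positive measurements under the LMS model,
#' \deqn{\ell = \sum_i (L-1)\log y_i - L\log M - \log S - \tfrac12\log 2\pi - z_i^2/2,}
#' where \eqn{z_i} is the LMS z-score of \eqn{y_i}.  The density's positivity
#' truncation term is omitted, as is standard for the Cole--Green model when
#' \eqn{S} is small relative to \eqn{1/|Lz|}.
#'
#' @inheritParams lms_centile
#' @param y vector of strictly positive measurements (one age--sex cell).
#' @param probe if `TRUE`, invalid parameters return `-Inf` instead of
#'   raising an error; used by the optimiser while probing the boundary.
#' @return a finite scalar (the sum over observations).
#' @export
lms_loglik <- function(y, lambda, mu, sigma, probe = FALSE) {
  if (!is.numeric(y) || length(y) == 0 || anyNA(y) || any(!is.finite(y)) || any(y <= 0)) {
    stop("`y` must be a nonempty vector of finite, strictly positive values", call. = FALSE)
  }
  ok <- length(lambda) == 1 && length(mu) == 1 && length(sigma) == 1 &&
    is.finite(lambda) && is.finite(mu) && is.finite(sigma) && mu > 0 && sigma > 0
  if (!ok) {
    if (probe) return(-Inf)
    stop("invalid LMS parameters: mu and sigma must be finite and positive", call. = FALSE)
  }
  z <- lms_zscore(y, lambda, mu, sigma)
  sum((lambda - 1) * log(y) - lambda * log(mu) - log(sigma) -
        0.5 * log(2 * pi) - z^2 / 2)
}

#' Fit the LMS parameters for one group by maximum likelihood
#'
#' Direct numerical maximisation of the Box--Cox Cole--Green log-likelihood
#' over \eqn{(L, M, S)} for a single age--sex--measure cell.  The optimiser
#' starts at \eqn{(1, \mathrm{median}(y), \mathrm{sd}(y)/\mathrm{mean}(y))},
#' runs box-constrained quasi-Newton (`L-BFGS-B`) and then a Nelder--Mead
#' polish, and is fully deterministic: the same sample and options always
#' return the same triple.
#'
#' @param y strictly positive measurements; at least `min_n` of them.
#' @param start optional named start vector `c(lambda, mu, sigma)`.
#' @param lambda_bounds allowed range for the Box--Cox power.
#' @param sigma_bounds allowed range for the coefficient of variation.
#' @param min_n minimum group size; three-parameter maximum likelihood is
#'   unstable below about 20 observations.
#' @param maxit iteration cap per optimiser stage.
#' @return a list of class `"lms_fit"` with elements `lambda`, `mu`,
#'   `sigma`, `loglik`, `n` and `convergence` (0 = converged).
#' @examples
#' set.seed(1)
#' z <- rnorm(500)
#' y <- 17 * (1 + (-0.5) * 0.13 * z)^(1 / -0.5)
#' lms_fit(y)
#' @export
lms_fit <- function(y, start = NULL, lambda_bounds = c(-5, 7),
                    sigma_bounds = c(1e-4, 1), min_n = 20, maxit = 1000) {
  if (!is.numeric(y) || anyNA(y) || any(!is.finite(y))) {
    stop("`y` must be finite and numeric", call. = FALSE)
  }
  y <- as.numeric(y)
  if (any(y <= 0)) stop("measurements must be strictly positive", call. = FALSE)
  n <- length(y)
  if (n < min_n) {
    stop(sprintf("need at least %d observations to fit an LMS triple (got %d)", min_n, n), call. = FALSE)
  }
  if (diff(range(y)) == 0) {
    stop("degenerate sample: all values identical, coefficient of variation is zero", call. = FALSE)
  }
  cv <- stats::sd(y) / mean(y)
  if (is.null(start)) {
    start <- c(lambda = 1, mu = stats::median(y),
               sigma = min(max(cv, sigma_bounds[1] * 2), sigma_bounds[2] * 0.9))
  }
  lower <- c(lambda_bounds[1], min(y) / 2, sigma_bounds[1])
  upper <- c(lambda_bounds[2], max(y) * 2, sigma_bounds[2])
  # penalty kept finite and modest so finite-difference gradients cannot
  # overflow inside the optimiser
  big <- 1e10
  negll <- function(th) {
    if (any(th < lower) || any(th > upper)) return(big)
    ll <- lms_loglik(y, th[1], th[2], th[3], probe = TRUE)
    if (!is.finite(ll)) return(big)
    min(-ll, big)
  }
  fit1 <- stats::optim(start, negll, method = "L-BFGS-B",
                       lower = lower, upper = upper,
                       control = list(maxit = maxit, factr = 1e5))
  fit2 <- stats::optim(fit1$par, negll, method = "Nelder-Mead",
                       control = list(maxit = maxit, reltol = 1e-12))
  best <- if (fit2$value < fit1$value) fit2 else fit1
  if (fit1$convergence != 0 && fit2$convergence != 0) {
    cond <- simpleError(sprintf(
      "LMS fit did not converge within %d iterations (last iterate: lambda = %.4g, mu = %.4g, sigma = %.4g)",
      maxit, best$par[1], best$par[2], best$par[3]
    ))
    cond$last_iterate <- as.list(stats::setNames(best$par, c("lambda", "mu", "sigma")))
    stop(cond)
  }
  structure(
    list(lambda = unname(best$par[1]), mu = unname(best$par[2]),
         sigma = unname(best$par[3]), loglik = -best$value, n = n,
         convergence = 0L),
    class = "lms_fit"
  )
}

#' @export
print.lms_fit <- function(x, ...) {
  cat(sprintf("LMS fit (n = %d): L = %.4f, M = %.4f, S = %.4f, logLik = %.3f\n",
              x$n, x$lambda, x$mu, x$sigma, x$loglik))
  invisible(x)
}

#' Percentile specifications
#'
#' Bookkeeping for a set of reference percentiles: each probability gets its
#' full-precision standard-normal quantile and a display label ("P3", "P50",
#' "P97.5").  The quantile is always computed by [stats::qnorm()]; 2-digit
#' approximations such as 1.28 or 1.64 are never used, because published
#' reference cells only reproduce with full-precision quantiles.
#'
#' @param p vector of probabilities in (0, 1).
#' @return a tibble with columns `label`, `p`, `z`, ordered by `p`.
#' @examples
#' percentile_spec(c(0.03, 0.5, 0.97))
#' @export
percentile_spec <- function(p) {
  check_probability(p)
  p <- sort(unique(p))
  tibble::tibble(label = pct_label(p), p = p, z = stats::qnorm(p))
}

#' Default percentile sets per measure
#'
#' Height and weight references report P3, P10, P35, P50, P65, P90; BMI
#' references report P5, P15, P50, P85, P90, P95.  Both are overridable
#' wherever a percentile set is accepted.
#'
#' @param measure one of `"height"`, `"weight"`, `"bmi"`.
#' @return numeric vector of probabilities.
#' @export
default_percentiles <- function(measure) {
  measure <- match.arg(measure, c("height", "weight", "bmi"))
  if (measure == "bmi") {
    c(0.05, 0.15, 0.50, 0.85, 0.90, 0.95)
  } else {
    c(0.03, 0.10, 0.35, 0.50, 0.65, 0.90)
  }
}

#' Round half away from zero
#'
#' Published reference tables are rendered to 2 decimal places with ties
#' rounded away from zero (so 0.005 -> 0.01), unlike base [round()]'s
#' round-half-even.  Internal computation is never rounded.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

pct_label <- function(p) {
  # fixed-point rendering, trailing zeros stripped: 0.03 -> "P3", 0.975 -> "P97.5"
  paste0("P", sub("\\.?0+$", "", sprintf("%.6f", 100 * p)))
}

label_to_p <- function(label) {
  as.numeric(sub("^P", "", label)) / 100
}

check_probability <- function(p) {
  if (!is.numeric(p) || length(p) == 0 || anyNA(p) || any(p <= 0) || any(p >= 1)) {
    stop("probabilities must lie strictly between 0 and 1", call. = FALSE)
  }
  invisible(p)
}

check_lms <- function(lambda, mu, sigma) {
  vals <- c(lambda, mu, sigma)
  if (!is.numeric(vals) || anyNA(vals) || any(!is.finite(vals))) {
    stop("LMS parameters must be finite and numeric", call. = FALSE)
  }
  if (any(mu <= 0)) stop("`mu` (median M) must be strictly positive", call. = FALSE)
  if (any(sigma <= 0)) stop("`sigma` (coefficient of variation S) must be strictly positive", call. = FALSE)
  invisible(NULL)
}
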