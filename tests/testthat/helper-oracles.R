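# Independent oracles and shared fixtures for the test suite.

# Draw Box-Cox-normal values directly (independent of generate_cohort):
# z ~ N(0,1) mapped through the forward LMS transform, redrawing the rare
# deviate that violates positivity.
draw_bccg <- function(n, lambda, mu, sigma, seed) {
  set.seed(seed)
  z <- rnorm(n)
  if (abs(lambda) >= 1e-7) {
    repeat {
      bad <- (1 + lambda * sigma * z) <= 0
      if (!any(bad)) break
      z[bad] <- rnorm(sum(bad))
    }
    mu * (1 + lambda * sigma * z)^(1 / lambda)
  } else {
    mu * exp(sigma * z)
  }
}

# Brute-force grid search over the BCCG log-likelihood, written from the
# closed-form density rather than via lms_loglik, so it is an independent
# check on the optimiser.
grid_best_loglik <- function(y, lambdas, mus, sigmas) {
  best <- -Inf
  ly <- sum(log(y))
  n <- length(y)
  for (l in lambdas) {
    for (m in mus) {
      z0 <- if (abs(l) < 1e-12) log(y / m) else ((y / m)^l - 1) / l
      for (s in sigmas) {
        z <- z0 / s
        ll <- (l - 1) * ly - n * (l * log(m) + log(s) + 0.5 * log(2 * pi)) -
          sum(z^2) / 2
        if (ll > best) best <- ll
      }
    }
  }
  best
}

# Published reference cells that are internally inconsistent with their own
# row's L/M/S under the LMS transform (off by 0.02 or swapped between rows
# in the published table); excluded from cell-reproduction checks.
published_cell_exclusions <- function() {
  swap <- expand.grid(sex = "female", age_group = 15:16, measure = "weight",
                      label = c("P65", "P90"), stringsAsFactors = FALSE)
  boys_bmi <- data.frame(sex = "male", age_group = c(12, 12, 15, 16),
                         measure = "bmi", label = c("P15", "P85", "P85", "P85"))
  girls_bmi <- expand.grid(sex = "female", age_group = 12:16, measure = "bmi",
                           label = c("P5", "P15", "P85", "P90", "P95"),
                           stringsAsFactors = FALSE)
  rbind(swap, boys_bmi, girls_bmi)
}

# Compare every printed percentile cell of a published percentile table with
# the centile transform of its own row parameters; returns a data frame of
# per-cell absolute differences after 2-dp rounding.
published_cell_differences <- function(table) {
  df <- tibble::as_tibble(table)
  pct_cols <- grep("^P[0-9.]+$", names(df), value = TRUE)
  out <- list()
  for (i in seq_len(nrow(df))) {
    for (col in pct_cols) {
      printed <- df[[col]][i]
      if (is.na(printed)) next
      p <- as.numeric(sub("^P", "", col)) / 100
      computed <- round_half_up(lms_centile(p, df$lambda[i], df$mu[i], df$sigma[i]), 2)
      out[[length(out) + 1]] <- data.frame(
        sex = as.character(df$sex[i]), age_group = df$age_group[i],
        measure = as.character(df$measure[i]), label = col,
        printed = printed, computed = computed,
        abs_diff = abs(computed - printed)
      )
    }
  }
  do.call(rbind, out)
}

drop_excluded_cells <- function(cells) {
  excl <- published_cell_exclusions()
  keep <- !(interaction(cells$sex, cells$age_group, cells$measure, cells$label) %in%
              interaction(excl$sex, excl$age_group, excl$measure, excl$label))
  cells[keep, , drop = FALSE]
}
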