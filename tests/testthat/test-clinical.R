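# Survival screening, rank-sum plasma screen, paired-expression regression
# and the bootstrap gene-set correlation null.

test_that("Cox beta matches direct partial-likelihood maximization (tiny n)", {
  co <- tibble::tibble(time_months = c(2, 4, 5, 7, 9, 12),
                       event = c(1, 1, 0, 1, 1, 1),
                       X = c(1.2, 0.8, -0.3, -1.1, 0.4, -1.5))
  fit <- cox_univariate(co, "X")
  # independent oracle: maximize the Breslow partial likelihood numerically
  neg_pl <- function(beta) {
    t <- co$time_months; e <- co$event; x <- co$X
    ll <- 0
    for (i in which(e == 1)) {
      risk <- t >= t[i]
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
    -ll
  }
  opt <- stats::optimize(neg_pl, c(-5, 5), tol = 1e-10)
  expect_equal(fit$beta, opt$minimum, tolerance = 1e-6)
  expect_equal(fit$hr, exp(opt$minimum), tolerance = 1e-6)
})

test_that("a null covariate at large n yields HR near 1 inside its CI", {
  co <- simulate_cohort(800, c(X = 0), censor_rate = 0.2, seed = 101)
  fit <- cox_univariate(co, "X")
  expect_true(fit$conf_low <= 1 && 1 <= fit$conf_high)
  expect_equal(fit$hr, 1, tolerance = 0.2)
  expect_error(cox_univariate(dplyr::mutate(co, X = 1), "X"),
               class = "evcargo_input_error")
})

test_that("Cox HR is equivariant to covariate scaling", {
  co <- simulate_cohort(200, c(X = 0.7), censor_rate = 0.2, seed = 103)
  f1 <- cox_univariate(co, "X")
  co2 <- dplyr::mutate(co, X = X * 4)
  f2 <- cox_univariate(co2, "X")
  expect_equal(f2$beta, f1$beta / 4, tolerance = 1e-6)
})

test_that("identical groups give a null log-rank test", {
  base <- tibble::tibble(time_months = c(3, 5, 8, 11), event = c(1, 1, 0, 1))
  co <- dplyr::bind_rows(dplyr::mutate(base, X = 0),
                         dplyr::mutate(base, X = 10))
  km <- km_quantile_split(co, "X", q = 0.5)
  expect_equal(km$logrank_chisq, 0, tolerance = 1e-10)
  expect_equal(km$logrank_p, 1, tolerance = 1e-10)
})

test_that("KM median equals the sample median event time without censoring", {
  withr::with_seed(7, {
    co <- tibble::tibble(time_months = sample(1:100, 30),
                         event = 1L, X = rnorm(30))
  })
  km <- km_quantile_split(co, "X", q = 0.5)
  for (g in c("low", "high")) {
    grp_times <- co$time_months[(co$X > km$cut) == (g == "high")]
    expect_equal(km$medians$median_months[km$medians$group == g],
                 median(grp_times))
  }
  # KM curves are proper survival functions
  curves <- tidy(km)
  for (g in c("low", "high")) {
    s <- curves$survival[curves$group == g]
    expect_true(all(diff(s) <= 1e-12))
    expect_true(all(s >= 0 & s <= 1))
  }
})

test_that("exact log-rank p equals exhaustive permutation (n = 8)", {
  co <- tibble::tibble(time_months = c(1, 2, 3, 4, 10, 12, 14, 16),
                       event = rep(1L, 8),
                       X = c(9, 8, 7, 6, 1, 2, 3, 4)) # high X relapses early
  km <- km_quantile_split(co, "X", q = 0.5, p_method = "exact")
  # independent oracle: own O-E statistic over all 70 labelings
  grp_obs <- factor(ifelse(co$X > median(co$X), "high", "low"))
  stat_obs <- oracle_logrank_chisq(co$time_months, co$event, grp_obs)
  combos <- utils::combn(8, 4)
  stats_perm <- apply(combos, 2, function(ii) {
    g <- factor(ifelse(seq_len(8) %in% ii, "high", "low"))
    oracle_logrank_chisq(co$time_months, co$event, g)
  })
  p_oracle <- mean(stats_perm >= stat_obs - 1e-9)
  expect_equal(km$logrank_p, p_oracle, tolerance = 1e-9)
  expect_lt(km$logrank_p, 0.05)
  # symmetric under label swap
  km2 <- km_quantile_split(dplyr::mutate(co, X = -X), "X", q = 0.5,
                           p_method = "exact")
  expect_equal(km2$logrank_chisq, km$logrank_chisq, tolerance = 1e-9)
})

test_that("plasma screen reproduces exact rank-sum results", {
  d <- tibble::tibble(protein = "MSR1",
                      group = rep(c("case", "control"), each = 3),
                      level = c(1, 2, 3, 4, 5, 6))
  res <- plasma_marker_screen(d)
  expect_equal(res$u_case, 0)
  expect_equal(res$p_value, 0.1, tolerance = 1e-12)
  expect_equal(res$direction, "up_in_control")

  # identical distributions -> p = 1
  d2 <- tibble::tibble(protein = "X",
                       group = rep(c("case", "control"), each = 3),
                       level = rep(c(1, 2, 3), 2))
  expect_equal(plasma_marker_screen(d2)$p_value, 1)

  # all tied -> flagged p = 1
  d3 <- tibble::tibble(protein = "X",
                       group = rep(c("case", "control"), each = 4),
                       level = 5)
  r3 <- plasma_marker_screen(d3)
  expect_true(r3$all_tied)
  expect_equal(r3$p_value, 1)
})

test_that("exact and approximate rank-sum branches agree for n = 12", {
  withr::with_seed(23, {
    for (i in 1:5) {
      lv <- rnorm(12)
      d <- tibble::tibble(protein = "X",
                          group = rep(c("case", "control"), each = 6),
                          level = lv)
      p_exact <- plasma_marker_screen(d)$p_value
      p_approx <- suppressWarnings(
        wilcox.test(lv[1:6], lv[7:12], exact = FALSE,
                    correct = TRUE)$p.value)
      expect_lt(abs(p_exact - p_approx), 0.05)
    }
  })
})

test_that("paired-expression regression matches the closed form", {
  d <- tibble::tibble(x = c(1, 2, 3, 4, 5), y = c(1.1, 1.9, 3.2, 3.8, 5.1))
  res <- regress_paired_expression(d)
  # closed-form OLS + t test on slope
  b <- cov(d$x, d$y) / var(d$x)
  a <- mean(d$y) - b * mean(d$x)
  resid <- d$y - a - b * d$x
  se <- sqrt(sum(resid^2) / 3 / sum((d$x - mean(d$x))^2))
  p_ref <- 2 * pt(-abs(b / se), df = 3)
  expect_equal(res$slope, b, tolerance = 1e-12)
  expect_equal(res$p_value, p_ref, tolerance = 1e-10)

  exact <- suppressWarnings(
    regress_paired_expression(tibble::tibble(x = 1:4, y = 1:4)))
  expect_equal(exact$slope, 1)
  expect_equal(exact$r_squared, 1)
  expect_error(regress_paired_expression(tibble::tibble(x = rep(1, 5),
                                                        y = 1:5)),
               class = "evcargo_input_error")
})

test_that("slope-test p-values are uniform under independence", {
  withr::with_seed(29, {
    p <- replicate(400, {
      regress_paired_expression(tibble::tibble(x = rnorm(10),
                                               y = rnorm(10)))$p_value
    })
  })
  expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 0.01)
})

test_that("bootstrap correlation handles edge cases and is deterministic", {
  pe <- simulate_paired_expression(100, 100, 0.5, seed = 31)
  # marker set = whole universe: every draw equals the observed set
  res <- bootstrap_geneset_correlation(pe$expression, pe$markers,
                                       n_boot = 200, seed = 1)
  expect_equal(res$p_value, 1)
  expect_true(all(res$null_r == res$observed_r))

  pe2 <- simulate_paired_expression(300, 30, 0.9, seed = 32)
  r1 <- bootstrap_geneset_correlation(pe2$expression, pe2$markers,
                                      n_boot = 500, seed = 9)
  r2 <- bootstrap_geneset_correlation(pe2$expression, pe2$markers,
                                      n_boot = 500, seed = 9)
  expect_identical(r1$null_r, r2$null_r)
  # correlated markers in an uncorrelated background: small p, grid-valued
  expect_lt(r1$p_value, 0.05)
  expect_equal(r1$p_value * 500, round(r1$p_value * 500), tolerance = 1e-9)
  # +1 convention shifts by at most 1/n_boot
  r3 <- bootstrap_geneset_correlation(pe2$expression, pe2$markers,
                                      n_boot = 500, seed = 9, add_one = TRUE)
  expect_lte(abs(r3$p_value - r1$p_value), 1 / 500 + 1e-12)
  expect_error(bootstrap_geneset_correlation(pe2$expression, "NOTAGENE",
                                             n_boot = 10),
               class = "evcargo_input_error")
})
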