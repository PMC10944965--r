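test_that("standardization is exact and rejects constants", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  withr::with_seed(3, v <- rnorm(50, 10, 4))
  z <- standardize(v)
  expect_equal(mean(z), 0)
  expect_equal(stats::sd(z), 1)
  expect_error(standardize(rep(2, 5)),
               class = "clockbench_error_zero_variance")
})

test_that("with no group variance the LMM reduces to OLS", {
  withr::with_seed(8, {
    x <- rnorm(120)
    y <- 1.5 + 0.5 * x + rnorm(120)
    g <- rep(sprintf("G%d", 1:12), each = 10)
  })
  fit <- fit_random_intercept_lmm(y, cbind(intercept = 1, x = x), g)
  ols <- stats::lm(y ~ x)
  expect_lt(max(abs(fit$beta - coef(ols))), 1e-6)
})

test_that("the fixed balanced fixture matches the grid-search REML oracle", {
  # printed fixture: 4 groups x 5 observations
  y <- c(1.62, 0.91, 1.45, 2.03, 1.11,
         2.75, 3.10, 2.20, 2.95, 2.64,
         0.48, 0.95, 0.52, 1.30, 0.70,
         2.05, 1.66, 2.40, 1.91, 2.29)
  x <- c(-1.21, 0.28, 1.08, -2.35, 0.43,
         0.51, -0.57, -0.55, -0.56, -0.89,
         -0.48, -1.00, -0.78, 0.06, 0.96,
         -0.11, -0.51, -0.91, -0.84, 2.42)
  g <- rep(c("A", "B", "C", "D"), each = 5)
  fit <- fit_random_intercept_lmm(y, cbind(intercept = 1, x = x), g)
  oracle <- grid_reml(y, cbind(1, x), g)
  expect_lt(max(abs(fit$beta - oracle$beta)), 1e-5)
  expect_lt(abs(fit$tau2 - oracle$tau2), 1e-5)
  expect_lt(abs(fit$sigma2 - oracle$sigma2), 1e-5)
})

test_that("estimates agree with an established REML implementation", {
  withr::with_seed(14, {
    g <- rep(sprintf("G%02d", 1:15), each = 8)
    x <- rnorm(120)
    y <- 0.4 * x + rep(rnorm(15, 0, 0.8), each = 8) + rnorm(120)
  })
  fit <- fit_random_intercept_lmm(y, cbind(intercept = 1, x = x), g)
  lmer_fit <- lme4::lmer(y ~ x + (1 | g),
                         data = data.frame(y, x, g), REML = TRUE)
  expect_lt(max(abs(fit$beta - lme4::fixef(lmer_fit))), 1e-5)
  vc <- as.data.frame(lme4::VarCorr(lmer_fit))
  expect_lt(abs(fit$tau2 - vc$vcov[1]), 1e-4)
  expect_lt(abs(fit$sigma2 - vc$vcov[2]), 1e-4)
  expect_lt(max(abs(fit$se -
                      summary(lmer_fit)$coefficients[, "Std. Error"])),
            1e-4)
})

test_that("the profiled REML criterion is minimized at the returned theta", {
  withr::with_seed(15, {
    g <- rep(sprintf("G%d", 1:10), each = 6)
    y <- rep(rnorm(10, 0, 0.6), each = 6) + rnorm(60)
  })
  fit <- fit_random_intercept_lmm(y, matrix(1, 60, 1), g)
  expect_gt(fit$theta, 0)
  for (eps in c(0.9, 1.1)) {
    expect_gte(fit$criterion(fit$theta * eps), fit$reml - 1e-8)
  }
})

test_that("degenerate LMM designs raise named errors", {
  y <- rnorm(20)
  expect_error(fit_random_intercept_lmm(y, cbind(1, rep(2, 20)),
                                        rep(c("a", "b"), 10)),
               class = "clockbench_error_bad_code")
  expect_error(fit_random_intercept_lmm(y, cbind(1, rnorm(20)),
                                        rep("a", 20)),
               class = "clockbench_error_bad_code")
})

test_that("Monte-Carlo parameter recovery over simulated score tables", {
  est <- vapply(1:200, function(i) {
    tab <- simulate_score_table(30, 0.5, 0.5, 1, seed = 1000 + i)
    x <- standardize(log(tab$subsample_size))
    fit <- fit_random_intercept_lmm(tab$adjusted_r2,
                                    cbind(intercept = 1, x = x),
                                    tab$gse_id)
    c(fit$beta[["x"]], fit$tau2)
  }, c(0, 0))
  expect_lt(abs(mean(est[1, ]) - 0.5), 0.05)
  expect_lt(abs(mean(est[2, ]) - 0.25), 0.025)   # within 10% of truth
})

test_that("the Wald t-test matches a numeric t-CDF oracle", {
  expect_equal(wald_t(0, 1, 10)$t, 0)
  expect_equal(wald_t(0, 1, 10)$p, 1)
  tt <- wald_t(2, 1, 10)
  dens <- function(u, df) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + u^2 / df)^(-(df + 1) / 2)
  }
  p_oracle <- 2 * stats::integrate(dens, 2, Inf, df = 10)$value
  expect_lt(abs(tt$p - p_oracle), 1e-8)
  expect_equal(wald_t(-2, 1, 10)$p, tt$p)
  expect_error(wald_t(1, 0, 10), class = "clockbench_error_bad_code")
})

test_that("Benjamini-Yekutieli adjustment matches hand-derived values", {
  expect_equal(by_adjust(0.2), 0.2)                      # m = 1
  expect_equal(by_adjust(c(0.01, 0.04)), c(0.03, 0.06))  # c(2) = 1.5
  m <- 7
  q <- 0.02
  cm <- sum(1 / seq_len(m))
  expect_equal(by_adjust(rep(q, m)), rep(min(1, q * cm * m / m), m))
  withr::with_seed(21, p <- runif(20))
  expect_true(all(by_adjust(p) >= stats::p.adjust(p, "BH")))
  srt <- order(p)
  expect_true(all(diff(by_adjust(p)[srt]) >= -1e-12))
  expect_error(by_adjust(c(0.5, 1.2)),
               class = "clockbench_error_beta_range")
})

test_that("partial correlation equals Pearson r in the tau2 = 0 limit", {
  withr::with_seed(22, {
    x <- rnorm(200)
    y <- 0.6 * x + rnorm(200, 0, 0.8)
    g <- rep(sprintf("G%d", 1:10), each = 20)
  })
  zy <- standardize(y)
  zx <- standardize(x)
  fit <- fit_random_intercept_lmm(zy, cbind(intercept = 1, x = zx), g)
  if (fit$tau2 < 1e-8) {
    expect_lt(abs(fit$beta[["x"]] - stats::cor(y, x)), 1e-6)
  } else {
    expect_lt(abs(fit$beta[["x"]] - stats::cor(y, x)), 1e-2)
  }
})

test_that("compare_scores detects a real size effect with power", {
  hits <- vapply(1:200, function(i) {
    tab <- simulate_score_table(30, 0.5, 0.5, 1, seed = 40000 + i)
    r <- compare_scores(tab, "size", "adjusted_r2")
    r$partial_corr > 0 && r$p_value < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("a null sex contrast stays null", {
  # identical score distributions for sex-specific and joint clocks
  hits <- vapply(1:100, function(i) {
    tab <- simulate_score_table(20, 0.3, 0.4, 1, seed = 60000 + i)
    tab$sex_config <- rep_len(c("joint", "male", "female"), nrow(tab))
    tab$validation_sex <- ifelse(tab$sex_config == "joint",
                                 rep_len(c("male", "female"), nrow(tab)),
                                 tab$sex_config)
    r <- compare_scores(tab, "sex_specific", "adjusted_r2")
    by_adjust(r$p_value) > 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("compare_scores validates its inputs", {
  tab <- simulate_score_table(5, 0.2, 0.3, 1, seed = 1)
  expect_error(compare_scores(tab, "penalty", "adjusted_r2"),
               class = "clockbench_error_bad_code")
  expect_error(compare_scores(tab, "penalty", "adjusted_r2",
                              pair = c("ridge", "elastic_net")),
               class = "clockbench_error_bad_code")
  one_gse <- tab[tab$gse_id == tab$gse_id[1], ]
  expect_error(compare_scores(one_gse, "size", "adjusted_r2"),
               class = "clockbench_error_bad_code")
})
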