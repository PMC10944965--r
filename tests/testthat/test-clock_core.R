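random_problem <- function(seed, n = 20, p = 5) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("cg%02d", seq_len(p))))
    w <- rnorm(p) * rbinom(p, 1, 0.6)
    y <- drop(X %*% w) + rnorm(n, 0, 0.5)
    list(X = X, y = y)
  })
}

test_that("appending lambda = 0 reproduces ordinary least squares", {
  pb <- random_problem(1)
  path <- fit_path(pb$X, pb$y, "elastic_net", lambda = c(0.5, 0.1, 0))
  ols <- stats::lm.fit(cbind(1, pb$X), pb$y)$coefficients
  expect_lt(max(abs(path$coef[, 3] - ols[-1])), 1e-6)
  expect_lt(abs(path$intercept[3] - ols[1]), 1e-6)
})

test_that("lambda_max zeroes every coefficient for L1 penalties", {
  for (pen in c("lasso", "elastic_net")) {
    pb <- random_problem(2)
    path <- fit_path(pb$X, pb$y, pen)
    expect_true(all(path$coef[, 1] == 0))
    expect_equal(path$intercept[1], mean(pb$y))
    # the explicit lambda_max formula also zeroes exactly
    std <- std_design(pb$X, pb$y)
    alpha <- penalty_spec(pen)$alpha
    lmax <- max(abs(crossprod(std$Xs, std$yc))) / (std$n * alpha)
    single <- fit_path(pb$X, pb$y, pen, lambda = lmax)
    expect_true(all(single$coef == 0))
  }
})

test_that("ridge solutions match the closed form to 1e-8", {
  for (seed in 1:5) {
    pb <- random_problem(seed)
    std <- std_design(pb$X, pb$y)
    for (lam in c(1, 0.1, 0.01)) {
      path <- fit_path(pb$X, pb$y, "ridge", lambda = lam)
      closed <- solve(crossprod(std$Xs) / std$n + lam * diag(ncol(std$Xs)),
                      crossprod(std$Xs, std$yc) / std$n)
      expect_lt(max(abs(path$coef_std - closed)), 1e-8)
    }
  }
})

test_that("the objective decreases monotonically across sweeps", {
  pb <- random_problem(3, n = 40, p = 12)
  for (pen in c("ridge", "elastic_net", "lasso")) {
    path <- fit_path(pb$X, pb$y, pen)
    for (tr in path$objective) {
      if (length(tr) > 1) expect_true(all(diff(tr) <= 1e-10))
    }
  }
})

test_that("warm-started path solutions match cold starts within 10 tol", {
  pb <- random_problem(4, n = 30, p = 10)
  path <- fit_path(pb$X, pb$y, "elastic_net")
  for (i in c(10, 25, 49)) {
    cold <- fit_path(pb$X, pb$y, "elastic_net", lambda = path$lambda[i])
    expect_lt(max(abs(cold$coef - path$coef[, i])), 10 * 1e-7)
  }
})

test_that("KKT conditions hold at convergence for every lambda", {
  pb <- random_problem(5, n = 30, p = 15)
  for (pen in c("lasso", "elastic_net")) {
    path <- fit_path(pb$X, pb$y, pen)
    kkt <- vapply(seq_along(path$lambda), function(i)
      clockbench:::kkt_residual(pb$X, pb$y, path, i), 0)
    expect_lt(max(kkt), 1e-7)
  }
})

test_that("degenerate designs are handled as documented", {
  pb <- random_problem(6)
  expect_error(fit_path(pb$X, rep(50, 20), "lasso"),
               class = "clockbench_error_bad_code")
  Xz <- cbind(pb$X, cgZZ = rep(1, 20))
  expect_warning(path <- fit_path(Xz, pb$y, "lasso"),
                 "zero-variance")
  expect_true(all(path$coef["cgZZ", ] == 0))
})

test_that("fold counts follow the leave-one-out rule at n < 10", {
  pb9 <- random_problem(7, n = 9, p = 3)
  cv9 <- cross_validate_lambda(pb9$X, pb9$y, "elastic_net", seed = 1)
  expect_equal(cv9$nfolds, 9L)
  pb10 <- random_problem(8, n = 10, p = 3)
  cv10 <- cross_validate_lambda(pb10$X, pb10$y, "elastic_net", seed = 1)
  expect_equal(cv10$nfolds, 10L)
  expect_error(cross_validate_lambda(pb9$X[1:2, ], pb9$y[1:2], "lasso"),
               class = "clockbench_error_bad_code")
})

test_that("the selected lambda attains the cross-validation minimum", {
  withr::with_seed(9, {
    X <- matrix(rnorm(150), 50, 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- drop(X %*% c(2, -1, 0.5))        # noiseless linear signal
  })
  cv <- cross_validate_lambda(X, y, "elastic_net", seed = 2)
  expect_equal(cv$cvm[cv$index], min(cv$cvm))
  expect_lt(cv$cvm[cv$index], cv$cvm[1])
})

test_that("fit_clock is deterministic and achieves R2 = 1 noiselessly", {
  cfg <- generator_config(tissues = "A03", datasets_per_tissue = 1,
                          samples_per_dataset = 60, n_background_cpgs = 20,
                          n_shared_clock_cpgs = 5,
                          n_tissue_specific_clock_cpgs = 0, noise_sd = 0,
                          batch_sd = 0, missing_rate = 0, n_xy_probes = 0,
                          n_rs_probes = 0, dataset_noise_mult = c(1, 1),
                          seed = 12)
  gen <- simulate_study(cfg)
  m1 <- suppressWarnings(fit_clock(gen$study, "elastic_net", seed = 4))
  m2 <- suppressWarnings(fit_clock(gen$study, "elastic_net", seed = 4))
  expect_identical(m1$coefficients, m2$coefficients)
  rec <- score_clock(m1, study_to_m(gen$study), gen$study$samples$age,
                     split = "training")
  expect_lt(abs(rec$adjusted_r2 - 1), 1e-6)
  expect_identical(m1$provenance$n_train, nrow(gen$study$samples))
})

test_that("methylage prediction is the stated linear functional", {
  model <- clock_model(intercept = 10, coefficients = c(cgA = 2))
  M <- matrix(c(1.5, -1), 2, 1, dimnames = list(NULL, "cgA"))
  expect_equal(predict_methylage(model, M), c(13, 8))
  zero <- clock_model(intercept = 33, coefficients = c(cgA = 0))
  expect_equal(predict_methylage(zero, M), c(33, 33))
  extra <- cbind(M, cgB = c(9, 9))      # extra probes are ignored
  expect_equal(predict_methylage(model, extra), c(13, 8))
  expect_error(predict_methylage(model,
                                 matrix(1, 1, 1,
                                        dimnames = list(NULL, "cgX"))),
               class = "clockbench_error_missing_probe")
})

test_that("solutions agree with the reference penalized-regression solver", {
  pb <- random_problem(10)
  sd_n <- function(v) sqrt(mean((v - mean(v))^2))
  for (lam in c(0.3, 0.1, 0.02)) {
    g <- glmnet::glmnet(pb$X, pb$y, alpha = 1, lambda = lam,
                        standardize = TRUE, thresh = 1e-14)
    ours <- fit_path(pb$X, pb$y, "lasso", lambda = lam)
    expect_lt(max(abs(as.numeric(g$beta) - ours$coef)), 1e-6)
    expect_lt(abs(as.numeric(g$a0) - ours$intercept), 1e-6)
    # glmnet standardizes the response internally, which rescales its L2
    # penalty by 1/sd(y); compare ridge at the converted penalty
    gr <- glmnet::glmnet(pb$X, pb$y, alpha = 0, lambda = lam,
                         standardize = TRUE, thresh = 1e-16)
    ours_r <- fit_path(pb$X, pb$y, "ridge", lambda = lam / sd_n(pb$y))
    expect_lt(max(abs(as.numeric(gr$beta) - ours_r$coef)), 1e-5)
  }
})
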