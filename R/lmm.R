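#' Standardize a vector to mean 0, SD 1
#'
#' Sample SD (denominator `n - 1`). Both the response and every covariate
#' (including dummy variables) entering the comparison models are
#' standardized, which makes each fixed-effect partial slope interpretable
#' as a partial correlation.
#'
#' @param v Numeric vector, length at least 2.
#' @param name Variable name used in the zero-variance error message.
#' @return The standardized vector.
#' @export
standardize <- function(v, name = deparse(substitute(v))) {
  if (length(v) < 2) cb_stop_code("standardize requires length >= 2")
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) {
    cb_stop(sprintf("variable '%s' has zero variance", name),
            "clockbench_error_zero_variance")
  }
  (v - mean(v)) / s
}

#' Random-intercept linear mixed model by profiled REML
#'
#' Fits `y = X b + a_g + e` with `a_g ~ N(0, tau^2)` per group and
#' `e ~ N(0, sigma^2)`, by restricted maximum likelihood. The likelihood
#' is profiled over the variance ratio `theta = tau^2 / sigma^2`
#' (one-dimensional optimization on the log scale, with the boundary
#' `theta = 0` checked explicitly); fixed effects are the GLS solution at
#' the optimum. With a single grouping factor the required matrix inverses
#' have a closed per-group form, so the fit is O(n) per criterion
#' evaluation.
#'
#' @param y Numeric response.
#' @param X Fixed-effects design matrix including the intercept column.
#' @param groups Grouping labels (dataset of origin, `GSE`).
#' @return A `lmm_fit` list: `beta`, `se`, `tau2`, `sigma2`, `theta`,
#'   `df` (residual degrees of freedom, `n - ncol(X) - n_groups`),
#'   `n_obs`, `n_groups`, `reml` (profiled criterion at the optimum).
#' @export
fit_random_intercept_lmm <- function(y, X, groups) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  stopifnot(nrow(X) == n, length(groups) == n)
  groups <- as.character(groups)
  glev <- unique(groups)
  g <- length(glev)
  if (g < 2) cb_stop_code("need at least 2 groups for a random intercept")
  if (qr(X)$rank < p) cb_stop_code("fixed-effects design is singular")

  gi <- split(seq_len(n), factor(groups, levels = glev))
  ng <- lengths(gi)

  # REML criterion profiled over theta (up to an additive constant):
  # log|V0| + log|X' V0^-1 X| + (n - p) log(r' V0^-1 r),
  # V0 = I + theta Z Z',  V0^-1 = I - theta/(1 + theta n_g) J per group.
  crossparts <- function(theta) {
    A <- crossprod(X)            # X' V0^-1 X, corrected per group below
    bvec <- crossprod(X, y)
    yy <- sum(y * y)
    for (k in seq_len(g)) {
      idx <- gi[[k]]
      ck <- theta / (1 + theta * ng[k])
      sx <- colSums(X[idx, , drop = FALSE])
      sy <- sum(y[idx])
      A <- A - ck * tcrossprod(sx)
      bvec <- bvec - ck * sx * sy
      yy <- yy - ck * sy * sy
    }
    beta <- solve(A, bvec)
    rss <- yy - 2 * sum(beta * bvec) + sum(beta * (A %*% beta))
    # guard tiny negative rounding
    rss <- max(rss, 1e-300)
    list(A = A, beta = drop(beta), rss = rss)
  }
  criterion <- function(theta) {
    parts <- crossparts(theta)
    sum(log1p(theta * ng)) + determinant(parts$A)$modulus[1] +
      (n - p) * log(parts$rss)
  }

  opt <- stats::optimize(function(lt) criterion(exp(lt)),
                         interval = c(log(1e-10), log(1e8)),
                         tol = 1e-10)
  theta <- exp(opt$minimum)
  crit <- opt$objective
  crit0 <- criterion(0)
  if (crit0 <= crit) {
    theta <- 0
    crit <- crit0
  }
  parts <- crossparts(theta)
  sigma2 <- parts$rss / (n - p)
  vcov_beta <- solve(parts$A) * sigma2
  se <- sqrt(diag(vcov_beta))
  structure(list(beta = parts$beta, se = se, tau2 = theta * sigma2,
                 sigma2 = sigma2, theta = theta, df = n - p - g,
                 n_obs = n, n_groups = g, reml = crit,
                 criterion = criterion),
            class = "lmm_fit")
}

#' Wald t-test of a fixed-effect coefficient
#'
#' `t = estimate / se`, two-sided p-value from Student's t on `df` degrees
#' of freedom (here the conservative `n_obs - n_fixed - n_groups`).
#'
#' @param estimate,se Coefficient and its standard error (`se > 0`).
#' @param df Degrees of freedom, at least 1.
#' @return A list with `t` and `p`.
#' @export
wald_t <- function(estimate, se, df) {
  if (!is.finite(se) || se <= 0) cb_stop_code("se must be positive")
  if (df < 1) cb_stop_code("df must be >= 1")
  t <- estimate / se
  list(t = t, p = 2 * stats::pt(-abs(t), df))
}

#' Benjamini-Yekutieli adjustment
#'
#' Step-up false-discovery-rate adjustment valid under arbitrary
#' dependence: the Benjamini-Hochberg adjustment inflated by
#' `c(m) = sum_{i=1}^m 1/i`. Delegates to [stats::p.adjust()].
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
by_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    cb_stop_range("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BY")
}

#' Mixed-model comparison of clock scores
#'
#' Fits one of the five random-intercept models on a score table and
#' returns the contrast of interest as a partial correlation (the
#' standardized fixed-effect slope) with a Wald t-test:
#'
#' * `"size"`: `score ~ log(sample size) + (1|GSE)`; covariate of
#'   interest is the log sample size.
#' * `"penalty"`: `score ~ log(sample size) + penalty_dummy + (1|GSE)`,
#'   restricted to the two penalties in `pair` (dummy 1 for `pair[1]`).
#' * `"sex_specific"`: dummy 1 when the clock was trained sex-specifically
#'   (training sex equal to the validation sex), 0 when trained jointly.
#' * `"tissue_pair"`: dummy 1 for `pair[1]`, 0 for `pair[2]`, restricted
#'   to those tissue labels.
#' * `"tissue_specific"`: dummy from the `tissue_specific` column
#'   (1 tissue-trained, 0 blood-trained).
#'
#' Response and all covariates (dummies included) are standardized, and
#' the natural log of `subsample_size` is used. The caller pre-filters the
#' table to the analysis family (split, penalty, sex configuration).
#'
#' @param scores Score table (see [write_scores()] for columns).
#' @param formula_id One of `"size"`, `"penalty"`, `"sex_specific"`,
#'   `"tissue_pair"`, `"tissue_specific"`.
#' @param response `"adjusted_r2"` or `"rmse"`.
#' @param pair Length-2 character vector of levels for the pair formulas.
#' @return A one-row `data.frame`: `formula_id`, `response`, `contrast`,
#'   `partial_corr`, `se`, `t_statistic`, `df`, `p_value`, `p_by` (`NA`
#'   until [adjust_comparison_family()]), `tau2`, `sigma2`, `n_obs`,
#'   `n_groups`.
#' @export
compare_scores <- function(scores, formula_id = c("size", "penalty",
                                                  "sex_specific",
                                                  "tissue_pair",
                                                  "tissue_specific"),
                           response = c("adjusted_r2", "rmse"),
                           pair = NULL) {
  formula_id <- match.arg(formula_id)
  response <- match.arg(response)
  df <- scores
  contrast <- formula_id

  dummy <- NULL
  if (formula_id == "penalty") {
    if (is.null(pair) || length(pair) != 2) {
      cb_stop_code("formula 'penalty' needs a pair of penalty names")
    }
    df <- df[df$penalty %in% pair, , drop = FALSE]
    if (length(unique(df$penalty)) < 2) {
      cb_stop_code("both penalty levels must be present in the table")
    }
    dummy <- as.numeric(df$penalty == pair[1])
    contrast <- paste(pair, collapse = " vs ")
  } else if (formula_id == "sex_specific") {
    dummy <- as.numeric(df$sex_config != "joint")
    if (length(unique(dummy)) < 2) {
      cb_stop_code("need both sex-specific and joint clocks in the table")
    }
  } else if (formula_id == "tissue_pair") {
    if (is.null(pair) || length(pair) != 2) {
      cb_stop_code("formula 'tissue_pair' needs a pair of tissue labels")
    }
    df <- df[df$tissue %in% pair, , drop = FALSE]
    if (length(unique(df$tissue)) < 2) {
      cb_stop_code("both tissue levels must be present in the table")
    }
    dummy <- as.numeric(df$tissue == pair[1])
    contrast <- paste(pair, collapse = " vs ")
  } else if (formula_id == "tissue_specific") {
    dummy <- as.numeric(df$tissue_specific)
    if (length(unique(dummy)) < 2) {
      cb_stop_code("need both tissue-trained and blood-trained records")
    }
  }

  if (length(unique(df$gse_id)) < 2) {
    cb_stop_code("need at least 2 datasets (GSE groups)")
  }
  y <- standardize(df[[response]], response)
  logsize <- standardize(log(df$subsample_size), "log(subsample_size)")
  if (formula_id == "size") {
    X <- cbind(intercept = 1, logsize = logsize)
    of_interest <- "logsize"
  } else {
    X <- cbind(intercept = 1, logsize = logsize,
               dummy = standardize(dummy, "contrast dummy"))
    of_interest <- "dummy"
  }
  fit <- fit_random_intercept_lmm(y, X, df$gse_id)
  est <- fit$beta[[of_interest]]
  se <- fit$se[[which(colnames(X) == of_interest)]]
  test <- wald_t(est, se, fit$df)
  data.frame(formula_id = formula_id, response = response,
             contrast = contrast, partial_corr = est, se = se,
             t_statistic = test$t, df = fit$df, p_value = test$p,
             p_by = NA_real_, tau2 = fit$tau2, sigma2 = fit$sigma2,
             n_obs = fit$n_obs, n_groups = fit$n_groups,
             stringsAsFactors = FALSE)
}

#' Benjamini-Yekutieli adjustment within a comparison family
#'
#' The rows passed in form one adjustment family (the contrasts reported
#' together); their `p_by` column is filled from [by_adjust()].
#'
#' @param results Row-bound output of [compare_scores()].
#' @return `results` with `p_by` filled.
#' @export
adjust_comparison_family <- function(results) {
  results$p_by <- by_adjust(results$p_value)
  results
}
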