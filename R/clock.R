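#' Penalty specification
#'
#' Fixed mapping from penalty name to the L1 mixing weight `alpha`:
#' ridge 0, elastic_net 0.5 (equally weighted L1 and L2), lasso 1.
#'
#' @param name One of `"ridge"`, `"lasso"`, `"elastic_net"`.
#' @return A `penalty_spec` list with `name` and `alpha`.
#' @export
penalty_spec <- function(name = c("elastic_net", "lasso", "ridge")) {
  name <- match.arg(name)
  alpha <- c(ridge = 0, elastic_net = 0.5, lasso = 1)[[name]]
  structure(list(name = name, alpha = alpha), class = "penalty_spec")
}

# Column standardization used by the solver: mean 0 and SD 1 with the 1/n
# variance convention, so that (1/n) x_j'x_j = 1 exactly.
standardize_columns <- function(X) {
  n <- nrow(X)
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  scale <- sqrt(colSums(Xc^2) / n)
  list(center = center, scale = scale, Xs = Xc, n = n)
}

# lambda grid: lambda_max zeroes all coefficients for alpha > 0 (exact by
# the soft-threshold KKT condition); ridge uses alpha = 0.001 in the
# formula only.
lambda_grid <- function(Xs, yc, alpha, nlambda) {
  n <- nrow(Xs)
  a <- max(alpha, 0.001)
  lmax <- max(abs(crossprod(Xs, yc))) / (n * a)
  ratio <- if (n < ncol(Xs)) 0.01 else 1e-4
  exp(seq(log(lmax), log(lmax * ratio), length.out = nlambda))
}

#' Fit a penalized regression path of age on M-values
#'
#' Minimizes, for each penalty value `lambda`,
#' `(1/(2n)) sum_i (age_i - b0 - m_i'w)^2 +
#'  lambda * (alpha * ||w||_1 + (1-alpha)/2 * ||w||_2^2)`
#' by cyclic coordinate descent with warm starts along a decreasing
#' `lambda` sequence. Predictors are standardized internally (mean 0,
#' SD 1 with the 1/n convention); coefficients are returned on both the
#' standardized and the original scale. Zero-variance probes are dropped
#' with a warning (their coefficients are zero).
#'
#' @param M Numeric matrix, samples by probes, no missing values.
#' @param age Numeric vector of ages in years.
#' @param penalty A [penalty_spec()] or a penalty name.
#' @param nlambda Length of the automatic `lambda` sequence (default 50).
#' @param lambda Optional explicit decreasing `lambda` sequence (overrides
#'   `nlambda`); may include 0 for the unpenalized limit.
#' @param tol Convergence tolerance on the maximum standardized-coefficient
#'   change per sweep.
#' @param max_sweeps Sweep cap per `lambda`.
#' @return An object of class `enet_path` with elements `lambda`,
#'   `coef` (original scale, probes x nlambda), `coef_std`, `intercept`
#'   (per lambda), `objective` (per-sweep traces), `sweeps`, and the
#'   standardization constants.
#' @export
fit_path <- function(M, age, penalty = penalty_spec("elastic_net"),
                     nlambda = 50, lambda = NULL, tol = 1e-7,
                     max_sweeps = 1e5) {
  if (is.character(penalty)) penalty <- penalty_spec(penalty)
  stopifnot(inherits(penalty, "penalty_spec"))
  M <- as.matrix(M)
  n <- nrow(M)
  if (n < 2) cb_stop_code("need at least 2 samples to fit a path")
  if (ncol(M) < 1) cb_stop_code("need at least 1 probe")
  if (anyNA(M) || anyNA(age)) cb_stop_code("missing values in M or age")
  if (stats::var(age) == 0) cb_stop_code("age vector is constant")

  std <- standardize_columns(M)
  keep <- std$scale > 0
  if (!all(keep)) {
    warning(sprintf("dropping %d zero-variance probe(s)", sum(!keep)))
  }
  Xs <- sweep(std$Xs[, keep, drop = FALSE], 2, std$scale[keep], "/")
  ybar <- mean(age)
  yc <- age - ybar

  if (is.null(lambda)) {
    lambda <- lambda_grid(Xs, yc, penalty$alpha, nlambda)
  } else {
    if (is.unsorted(rev(lambda))) {
      cb_stop_code("lambda sequence must be decreasing")
    }
  }

  n_ <- nrow(Xs)
  G <- crossprod(Xs) / n_
  q <- drop(crossprod(Xs, yc)) / n_
  fit <- cd_enet_path(G, q, sum(yc^2) / n_, penalty$alpha, lambda, tol,
                      as.integer(max_sweeps))
  p_all <- ncol(M)
  coef_std <- matrix(0, p_all, length(lambda))
  coef_std[keep, ] <- fit$coef
  rownames(coef_std) <- colnames(M)
  coef_orig <- coef_std
  coef_orig[keep, ] <- fit$coef / std$scale[keep]
  intercept <- ybar - drop(crossprod(coef_orig, std$center))

  structure(list(lambda = lambda, coef = coef_orig, coef_std = coef_std,
                 intercept = intercept, objective = fit$objective,
                 sweeps = fit$sweeps, penalty = penalty,
                 center = std$center, scale = std$scale, n = n,
                 ybar = ybar),
            class = "enet_path")
}

#' @export
print.enet_path <- function(x, ...) {
  cat(sprintf("<enet_path> %s, %d lambda values in [%.4g, %.4g], %d probes\n",
              x$penalty$name, length(x$lambda), min(x$lambda), max(x$lambda),
              nrow(x$coef)))
  invisible(x)
}

# KKT residuals of a path solution at one lambda, on the standardized
# scale: zero (within solver tolerance) iff the subgradient conditions of
# the elastic-net objective hold. Primary solver oracle at scale.
kkt_residual <- function(M, age, path, which_lambda) {
  std <- standardize_columns(as.matrix(M))
  keep <- std$scale > 0
  Xs <- sweep(std$Xs[, keep, drop = FALSE], 2, std$scale[keep], "/")
  yc <- age - mean(age)
  w <- path$coef_std[keep, which_lambda]
  lam <- path$lambda[which_lambda]
  alpha <- path$penalty$alpha
  r <- yc - Xs %*% w
  g <- drop(crossprod(Xs, r)) / nrow(Xs) - lam * (1 - alpha) * w
  active <- w != 0
  res <- numeric(length(w))
  res[active] <- abs(g[active] - lam * alpha * sign(w[active]))
  res[!active] <- pmax(abs(g[!active]) - lam * alpha, 0)
  max(res, 0)
}

#' Cross-validated penalty selection
#'
#' The `lambda` grid is computed once on the full data; fold assignment is
#' a seeded uniform permutation into folds of as-equal-as-possible size.
#' Ten folds are used when `n >= 10`, otherwise leave-one-out (`n` folds).
#' The selected `lambda` minimizes the mean held-out squared error.
#'
#' @inheritParams fit_path
#' @param seed Integer seed for the fold assignment.
#' @return A list with `lambda_selected`, `lambda`, `cvm` (mean CV MSE per
#'   lambda), `cvsd` (SE over folds), `folds` (assignment vector) and
#'   `nfolds`.
#' @export
cross_validate_lambda <- function(M, age, penalty = penalty_spec("elastic_net"),
                                  nlambda = 50, seed = 1L, tol = 1e-7) {
  if (is.character(penalty)) penalty <- penalty_spec(penalty)
  M <- as.matrix(M)
  n <- nrow(M)
  if (n < 3) cb_stop_code("cross-validation requires at least 3 samples")
  full <- fit_path(M, age, penalty, nlambda = nlambda, tol = tol)
  lambda <- full$lambda
  nfolds <- if (n >= 10) 10L else n
  folds <- with_seed(seed, {
    sample(rep_len(seq_len(nfolds), n))
  })
  fold_mse <- matrix(NA_real_, nfolds, length(lambda))
  for (k in seq_len(nfolds)) {
    tr <- folds != k
    fit_k <- suppressWarnings(
      fit_path(M[tr, , drop = FALSE], age[tr], penalty, lambda = lambda,
               tol = tol))
    pred <- sweep(M[!tr, , drop = FALSE] %*% fit_k$coef, 2,
                  fit_k$intercept, "+")
    fold_mse[k, ] <- colMeans((pred - age[!tr])^2)
  }
  wts <- as.vector(table(folds)) / n
  cvm <- drop(wts %*% fold_mse)
  cvsd <- apply(fold_mse, 2, stats::sd) / sqrt(nfolds)
  best <- which.min(cvm)
  list(lambda_selected = lambda[best], lambda = lambda, cvm = cvm,
       cvsd = cvsd, folds = folds, nfolds = nfolds, index = best)
}

#' Construct a clock model
#'
#' @param intercept Intercept in years.
#' @param coefficients Named numeric vector of per-CpG weights (years per
#'   M-unit, original scale); zeros allowed.
#' @param coef_std The same weights on the standardized-predictor scale.
#' @param penalty A [penalty_spec()].
#' @param lambda Selected penalty value.
#' @param provenance List: `tissue`, `sex_config`, `n_train`, `gse_ids`,
#'   `subsample_size`, `seed`.
#' @return A `clock_model`.
#' @export
clock_model <- function(intercept, coefficients, coef_std = coefficients,
                        penalty = penalty_spec("elastic_net"), lambda = NA,
                        provenance = list()) {
  if (!is.finite(intercept) || any(!is.finite(coefficients))) {
    cb_stop("non-finite value in clock model", "clockbench_error_nonfinite")
  }
  structure(list(intercept = intercept, coefficients = coefficients,
                 coef_std = coef_std, penalty = penalty, lambda = lambda,
                 provenance = provenance),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf(
    "<clock_model> %s (alpha=%.1f), lambda=%.4g, %d non-zero CpG(s)\n",
    x$penalty$name, x$penalty$alpha, x$lambda, sum(x$coefficients != 0)))
  if (!is.null(x$provenance$tissue)) {
    cat(sprintf("  tissue=%s sex=%s n_train=%s\n", x$provenance$tissue,
                x$provenance$sex_config %||% "joint",
                x$provenance$n_train %||% "?"))
  }
  invisible(x)
}

#' Train a clock on a preprocessed study
#'
#' Composes [cross_validate_lambda()] (penalty selection at minimum CV
#' mean-squared error) with [fit_path()] at the selected penalty.
#'
#' @param study A preprocessed [methylation_study()] (imputed, probe
#'   filtered), or `NULL` if `M` and `age` are given directly.
#' @param penalty A [penalty_spec()] or name.
#' @param seed Integer seed (cross-validation folds).
#' @param nlambda Path length.
#' @param M,age Optional explicit design (samples x probes) and response,
#'   bypassing `study`.
#' @param provenance Extra provenance fields stored in the model.
#' @param epsilon Logit2 clamp for the M transform.
#' @return A [clock_model()] at the CV-selected penalty.
#' @export
fit_clock <- function(study = NULL, penalty = penalty_spec("elastic_net"),
                      seed = 1L, nlambda = 50, M = NULL, age = NULL,
                      provenance = list(), epsilon = 1e-6) {
  if (is.character(penalty)) penalty <- penalty_spec(penalty)
  if (is.null(M)) {
    stopifnot(inherits(study, "methylation_study"))
    M <- study_to_m(study, epsilon)
    age <- study$samples$age
    provenance$gse_ids <- provenance$gse_ids %||%
      unique(study$samples$gse_id)
  }
  cv <- cross_validate_lambda(M, age, penalty, nlambda = nlambda,
                              seed = seed)
  path <- suppressWarnings(
    fit_path(M, age, penalty, lambda = cv$lambda))
  i <- cv$index
  provenance$n_train <- provenance$n_train %||% nrow(M)
  provenance$seed <- provenance$seed %||% as.integer(seed)
  clock_model(intercept = path$intercept[i],
              coefficients = path$coef[, i],
              coef_std = path$coef_std[, i],
              penalty = penalty, lambda = cv$lambda_selected,
              provenance = provenance)
}

#' Predict methylage
#'
#' `methylage_i = intercept + sum_j w_j M_ij` over the model's CpGs.
#' Probes present in `M` but absent from the model are ignored; a model
#' CpG missing from `M` is an error.
#'
#' @param model A [clock_model()].
#' @param M Numeric matrix, samples by probes, with probe column names.
#' @return Numeric vector of methylage estimates (years).
#' @export
predict_methylage <- function(model, M) {
  stopifnot(inherits(model, "clock_model"))
  M <- as.matrix(M)
  used <- names(model$coefficients)[model$coefficients != 0]
  missing <- setdiff(used, colnames(M))
  if (length(missing) > 0) {
    cb_stop(paste("model CpG(s) missing from the matrix:",
                  paste(missing, collapse = ", ")),
            "clockbench_error_missing_probe")
  }
  if (length(used) == 0) {
    return(rep(model$intercept, nrow(M)))
  }
  drop(model$intercept +
         M[, used, drop = FALSE] %*% model$coefficients[used])
}
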