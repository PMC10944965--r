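#' Calibration regression of methylage on chronological age
#'
#' Ordinary least squares fit of `methylage = theta1 + theta2 * age`.
#' Both performance scores ([rmse()], [adjusted_r2()]) are computed from
#' this fitted line, not from the identity line: a clock whose output is a
#' perfect affine function of age scores perfectly.
#'
#' @param methylage,age Numeric vectors of equal length, `n >= 3`; `age`
#'   must not be constant.
#' @return A `calibration_fit` with `theta1`, `theta2`, `n`, `fitted`,
#'   `residuals` and the response vector `y`.
#' @export
fit_calibration <- function(methylage, age) {
  n <- length(methylage)
  if (length(age) != n) cb_stop_dimension("methylage and age lengths differ")
  if (n < 3) cb_stop_code("calibration requires at least 3 samples")
  if (stats::var(age) == 0) cb_stop_code("age vector is constant")
  fit <- stats::lm.fit(cbind(1, age), methylage)
  theta <- fit$coefficients
  structure(list(theta1 = theta[[1]], theta2 = theta[[2]], n = n,
                 fitted = drop(fit$fitted.values),
                 residuals = drop(fit$residuals), y = methylage),
            class = "calibration_fit")
}

#' Root mean-squared error about the calibration line
#'
#' `sqrt((1/n) * sum (y_i - yhat_i)^2)` with `yhat` from the calibration
#' regression. A constant offset between methylage and age is absorbed by
#' the regression and yields RMSE 0.
#'
#' @param fit A [fit_calibration()] result.
#' @return RMSE in years.
#' @export
rmse <- function(fit) {
  stopifnot(inherits(fit, "calibration_fit"))
  sqrt(mean(fit$residuals^2))
}

#' Adjusted R-squared of the calibration regression
#'
#' `1 - [(1/(n-K)) sum (y - yhat)^2] / [(1/(n-1)) sum (y - ybar)^2]` with
#' the parameter count fixed at `K = 2` (intercept and slope).
#'
#' @param fit A [fit_calibration()] result.
#' @return Adjusted R-squared (at most 1; can be negative).
#' @export
adjusted_r2 <- function(fit) {
  stopifnot(inherits(fit, "calibration_fit"))
  K <- 2
  if (fit$n <= K) cb_stop_code("adjusted R-squared requires n > 2")
  ss_y <- sum((fit$y - mean(fit$y))^2)
  if (ss_y == 0) cb_stop_code("response variance is zero")
  1 - (sum(fit$residuals^2) / (fit$n - K)) / (ss_y / (fit$n - 1))
}

#' Score a clock on one evaluation split
#'
#' Predicts methylage, fits the calibration regression and packages both
#' scores with the experimental-design labels. Fewer than three evaluable
#' samples is a skip signal, not an error: `NULL` is returned and the
#' caller logs the skipped cell.
#'
#' @param model A [clock_model()].
#' @param M Samples-by-probes M-value matrix of the evaluation split.
#' @param age Ages of the evaluation samples.
#' @param split `"training"`, `"test"` or `"validation"`.
#' @param gse_id Dataset label of the split (`"pooled"` for multi-dataset
#'   splits).
#' @param tissue,sex_config,validation_sex,subsample_size,tissue_specific
#'   Design labels copied into the record.
#' @return A one-row score data frame, or `NULL` when `n < 3`.
#' @export
score_clock <- function(model, M, age, split = "validation",
                        gse_id = "pooled", tissue = NA_character_,
                        sex_config = "joint", validation_sex = "joint",
                        subsample_size = NA_integer_, tissue_specific = 1L) {
  n <- length(age)
  if (n < 3) return(NULL)
  methylage <- predict_methylage(model, M)
  cal <- fit_calibration(methylage, age)
  data.frame(adjusted_r2 = adjusted_r2(cal), rmse = rmse(cal),
             split = split, n = n, gse_id = gse_id, tissue = tissue,
             penalty = model$penalty$name, sex_config = sex_config,
             validation_sex = validation_sex,
             subsample_size = as.integer(subsample_size),
             tissue_specific = as.integer(tissue_specific),
             stringsAsFactors = FALSE)
}
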