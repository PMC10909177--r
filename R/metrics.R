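#' Regression error metrics
#'
#' The four size-regression metrics: mean absolute error
#' `MAE = mean(|e|)` (cm), mean squared error `MSE = mean(e^2)`, coefficient
#' of determination `R^2 = 1 - sum(e^2) / sum((y - mean(y))^2)`, and mean
#' absolute percentage error `MAPE = mean(|e| / y)` (as a fraction), with
#' `e = y - yhat`. A constant predictor at the target mean has `R^2 = 0` by
#' construction.
#'
#' @param y_true,y_pred Equal-length numeric vectors; `y_true` must be
#'   strictly positive (MAPE) and non-constant (R^2).
#' @return List with `mae_cm`, `mse`, `r2`, `mape`, `n`, and the pooled
#'   standard deviation of absolute errors `abs_err_sd`.
#' @examples
#' compute_metrics(c(10, 20), c(12, 18))  # MAE 2, MSE 4, MAPE 0.15, R2 0.84
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) == 0 || length(y_true) != length(y_pred)) {
    stop_traymetry("traymetry_validation_error",
                   "y_true and y_pred must be equal-length, nonempty")
  }
  if (any(y_true == 0)) {
    stop_traymetry("traymetry_undefined_metric",
                   "MAPE undefined: y_true contains zero")
  }
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) {
    stop_traymetry("traymetry_undefined_metric",
                   "R^2 undefined: y_true has zero variance")
  }
  e <- y_true - y_pred
  list(mae_cm = mean(abs(e)),
       mse = mean(e^2),
       r2 = 1 - sum(e^2) / ss_tot,
       mape = mean(abs(e) / y_true),
       abs_err_sd = if (length(e) > 1) sd(abs(e)) else 0,
       n = length(e))
}
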