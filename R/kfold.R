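#' Repeated k-fold evaluation of a size regressor
#'
#' The evaluation protocol for size regression: `repeats` independent
#' shuffles (seeded `base_seed + i - 1` for repeat `i`) are each split into
#' `k` near-equal folds; per training fold the normalization is refitted and
#' the regressor retrained; all `k * repeats` out-of-fold predictions are
#' pooled into a single report. Identical inputs and `base_seed` reproduce
#' the report bit for bit.
#'
#' @inheritParams train_size_regressor
#' @param k Number of folds (default 10).
#' @param repeats Number of shuffled repetitions (default 10).
#' @param base_seed Integer base seed.
#' @return A `regression_report`: pooled `mae_cm`, `mse`, `r2`, `mape`, the
#'   pooled standard deviation of per-instance absolute errors
#'   (`abs_err_sd`), the standard deviation across per-fold MAE means
#'   (`fold_mae_sd`), and a `per_fold` data frame (`repeat_`, `fold`,
#'   `mae_cm`, `n`). Both dispersion figures are reported because a
#'   "mean +/- spread" summary is ambiguous between them.
#' @export
kfold_evaluate <- function(features, targets, model = "gbt",
                           scheme = "minmax_input", k = 10, repeats = 10,
                           base_seed = 1, params = list()) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (k > n) {
    stop_traymetry("traymetry_fold_error",
                   sprintf("k = %d exceeds dataset size %d", k, n))
  }
  if (n != length(targets)) {
    stop_traymetry("traymetry_validation_error",
                   "features and targets disagree in length")
  }
  pooled_true <- numeric(0); pooled_pred <- numeric(0)
  per_fold <- list()
  for (i in seq_len(repeats)) {
    seed_i <- base_seed + i - 1
    set.seed(seed_i)
    ord <- sample.int(n)
    fold_of <- rep(seq_len(k), length.out = n)[order(ord)]
    for (f in seq_len(k)) {
      test <- which(fold_of == f)
      train <- which(fold_of != f)
      m <- train_size_regressor(features[train, , drop = FALSE],
                                targets[train], model, scheme,
                                seed = seed_i, params = params)
      pred <- predict_sizes(m, features[test, , drop = FALSE])
      pooled_true <- c(pooled_true, targets[test])
      pooled_pred <- c(pooled_pred, pred)
      per_fold[[length(per_fold) + 1]] <-
        data.frame(repeat_ = i, fold = f,
                   mae_cm = mean(abs(targets[test] - pred)),
                   n = length(test))
    }
  }
  per_fold <- do.call(rbind, per_fold)
  pooled <- compute_metrics(pooled_true, pooled_pred)
  structure(
    c(pooled,
      list(fold_mae_sd = sd(per_fold$mae_cm), per_fold = per_fold,
           k = k, repeats = repeats, model = model, scheme = scheme,
           base_seed = base_seed)),
    class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf(
    "<regression_report> %s / %s, %dx%d-fold (n = %d)\n", x$model, x$scheme,
    x$repeats, x$k, x$n))
  cat(sprintf("  MAE %.4f +/- %.4f cm (per-instance |err| sd; fold-mean sd %.4f)\n",
              x$mae_cm, x$abs_err_sd, x$fold_mae_sd))
  cat(sprintf("  MSE %.4f   R^2 %.4f   MAPE %.4f\n", x$mse, x$r2, x$mape))
  invisible(x)
}
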