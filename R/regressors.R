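# Pluggable size regressors. The comparison harness mirrors common
# benchmarking practice: every entry delegates to an established
# implementation; only the constant-mean baseline is inlined. All entries
# are deterministic given a seed and a single thread.

regressor_registry <- function() {
  list(
    gbt = list(
      fit = function(X, y, seed, params) {
        p <- modifyList(list(nrounds = 300, max_depth = 6, eta = 0.1,
                             subsample = 1, colsample_bytree = 1,
                             min_child_weight = 1), params)
        xgboost::xgboost(
          x = X, y = y, objective = "reg:squarederror",
          nrounds = p$nrounds, max_depth = p$max_depth,
          learning_rate = p$eta, subsample = p$subsample,
          colsample_bytree = p$colsample_bytree,
          min_child_weight = p$min_child_weight,
          nthreads = 1, seed = seed, verbosity = 0)
      },
      predict = function(fit, X) as.numeric(predict(fit, X))),
    random_forest = list(
      fit = function(X, y, seed, params) {
        p <- modifyList(list(num.trees = 300, min.node.size = 5), params)
        ranger::ranger(x = as.data.frame(X), y = y, num.trees = p$num.trees,
                       min.node.size = p$min.node.size, seed = seed,
                       num.threads = 1)
      },
      predict = function(fit, X) predict(fit, as.data.frame(X),
                                         num.threads = 1)$predictions),
    extra_trees = list(
      fit = function(X, y, seed, params) {
        p <- modifyList(list(num.trees = 300, min.node.size = 5), params)
        ranger::ranger(x = as.data.frame(X), y = y, num.trees = p$num.trees,
                       min.node.size = p$min.node.size,
                       splitrule = "extratrees", num.random.splits = 1,
                       seed = seed, num.threads = 1)
      },
      predict = function(fit, X) predict(fit, as.data.frame(X),
                                         num.threads = 1)$predictions),
    svm_radial = list(
      fit = function(X, y, seed, params) {
        # scaling is owned by the normalization spec, hence scale = FALSE
        args <- modifyList(list(x = X, y = y, kernel = "radial", cost = 1,
                                scale = FALSE), params)
        do.call(e1071::svm, args)
      },
      predict = function(fit, X) as.numeric(predict(fit, X))),
    svm_linear = list(
      fit = function(X, y, seed, params) {
        args <- modifyList(list(x = X, y = y, kernel = "linear", cost = 1,
                                scale = FALSE), params)
        do.call(e1071::svm, args)
      },
      predict = function(fit, X) as.numeric(predict(fit, X))),
    knn = list(
      fit = function(X, y, seed, params) {
        p <- modifyList(list(k = 5), params)
        caret::knnreg(x = as.data.frame(X), y = y, k = p$k)
      },
      predict = function(fit, X) as.numeric(predict(fit, as.data.frame(X)))),
    mean = list(
      fit = function(X, y, seed, params) list(mu = mean(y)),
      predict = function(fit, X) rep(fit$mu, nrow(X)))
  )
}

#' Available size-regressor names
#' @return Character vector of registry names (`"gbt"` is the default used
#'   throughout: gradient-boosted trees).
#' @export
regressor_names <- function() names(regressor_registry())

get_regressor <- function(name) {
  reg <- regressor_registry()
  if (!name %in% names(reg)) {
    stop_traymetry("traymetry_validation_error",
                   sprintf("unknown regressor '%s'; available: %s", name,
                           paste(names(reg), collapse = ", ")))
  }
  reg[[name]]
}

#' Train a size regressor
#'
#' Fits the named regressor on the (normalized) features. The returned model
#' records its normalization spec and feature layout and refuses feature
#' matrices with a different layout at prediction time, so a calibrated
#' model cannot silently consume uncalibrated features.
#'
#' @param features n x p feature matrix (see [dataset_features()]).
#' @param targets Length-n vector of ground-truth lengths (cm).
#' @param model Registry name, see [regressor_names()].
#' @param scheme Normalization scheme, see [fit_normalization()].
#' @param seed Integer seed for stochastic fitters.
#' @param params Named list of regressor hyperparameters (merged over
#'   defaults).
#' @return A `size_model`.
#' @export
train_size_regressor <- function(features, targets, model = "gbt",
                                 scheme = "minmax_input", seed = 1,
                                 params = list()) {
  features <- as.matrix(features)
  if (nrow(features) == 0) {
    stop_traymetry("traymetry_fit_error", "empty training set")
  }
  if (nrow(features) != length(targets)) {
    stop_traymetry("traymetry_validation_error",
                   "features and targets disagree in length")
  }
  spec <- get_regressor(model)
  norm <- fit_normalization(features, targets, scheme)
  Xn <- apply_normalization(norm, features)
  yn <- normalize_targets(norm, targets)
  fit <- spec$fit(Xn, yn, seed, params)
  structure(list(model = model, fit = fit, norm = norm,
                 layout = colnames(features), p = ncol(features),
                 seed = seed, params = params),
            class = "size_model")
}

#' Predict fish sizes
#'
#' @param model A `size_model` from [train_size_regressor()].
#' @param features Feature matrix with the layout the model was trained on.
#' @param floor_cm Predictions are clipped below at this physically positive
#'   floor (default 0.1 cm).
#' @return Numeric vector of lengths in cm.
#' @export
predict_sizes <- function(model, features, floor_cm = 0.1) {
  features <- as.matrix(features)
  if (ncol(features) != model$p ||
      (!is.null(colnames(features)) && !is.null(model$layout) &&
       !identical(colnames(features), model$layout))) {
    stop_traymetry("traymetry_layout_error",
                   sprintf(
                     "feature layout mismatch: model expects %d columns (%s...)",
                     model$p, paste(head(model$layout, 3), collapse = ", ")))
  }
  Xn <- apply_normalization(model$norm, features)
  pred <- get_regressor(model$model)$predict(model$fit, Xn)
  pmax(denormalize_targets(model$norm, pred), floor_cm)
}

#' @export
print.size_model <- function(x, ...) {
  cat(sprintf("<size_model> %s, %d features, normalization '%s'\n",
              x$model, x$p, x$norm$scheme))
  invisible(x)
}
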