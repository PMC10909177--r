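make_xy <- function(n, p = 4, seed = 1, fun = function(X) 2 + 3 * X[, 1]) {
  set.seed(seed)
  X <- matrix(runif(n * p, 1, 10), n, p,
              dimnames = list(NULL, paste0("f", 1:p)))
  list(X = X, y = fun(X))
}

test_that("feature layout matches the documented order and lengths", {
  cat13 <- default_species_catalog()
  ann <- fish_annotation(1, 2, rect_mask(10, 20, 30, 30),
                         bbox = c(10, 20, 50, 30))
  v <- extract_features(ann, cat13)
  expect_length(v, 4 + 1 + 13)
  expect_equal(unname(v[1:4]), c(10, 20, 50, 30))
  expect_equal(unname(v[5]), 900)
  expect_equal(unname(v[6:18]), as.numeric(0:12 == 2))

  corners <- corner_quad(rbind(c(0, 0), c(600, 0), c(600, 400), c(0, 400)))
  v2 <- extract_features(ann, cat13, corners, include_corners = TRUE)
  expect_length(v2, 26)
  expect_equal(unname(v2[19:26]), c(0, 0, 600, 0, 600, 400, 0, 400))
  expect_error(extract_features(ann, cat13, include_corners = TRUE),
               class = "traymetry_missing_calibration")
})

test_that("mask area feature matches the rasterization oracle on random polygons", {
  set.seed(4)
  cat1 <- species_catalog("a")
  for (i in 1:100) {
    len <- runif(1, 10, 40)
    ring <- capsule_points(len, runif(1, 0.15, 0.3) * len,
                           runif(1, 50, 100), runif(1, 50, 100),
                           runif(1, 0, 2 * pi))
    ann <- fish_annotation(1, 0, list(ring))
    area <- extract_features(ann, cat1)[["mask_area_px"]]
    expect_equal(area, oracle_raster_area(list(ring), cell = 0.25),
                 tolerance = 0.01 * area)
  }
})

test_that("minmax normalization maps train range to [0, 1] and preserves order", {
  X <- cbind(a = c(5, 15), b = c(7, 7))
  spec <- fit_normalization(X, scheme = "minmax_input")
  out <- apply_normalization(spec, X)
  expect_equal(out[, "a"], c(0, 1))
  expect_equal(out[, "b"], c(0, 0))  # constant column rule
  expect_equal(unname(apply_normalization(spec, cbind(a = 10, b = 99))[1, "a"]),
               0.5)

  set.seed(2)
  v <- runif(1000, -50, 50)
  spec2 <- fit_normalization(cbind(x = v), scheme = "minmax_input")
  tv <- apply_normalization(spec2, cbind(x = v))[, 1]
  expect_identical(order(tv), order(v))  # rank-preserving
  expect_error(fit_normalization(X[0, , drop = FALSE]),
               class = "traymetry_fit_error")
})

test_that("standard scheme z-scores and minmax_io inverts targets exactly", {
  d <- make_xy(50)
  spec <- fit_normalization(d$X, scheme = "standard_input")
  out <- apply_normalization(spec, d$X)
  expect_equal(colMeans(out), rep(0, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(apply(out, 2, sd), rep(1, 4), tolerance = 1e-12,
               ignore_attr = TRUE)

  spec2 <- fit_normalization(d$X, d$y, scheme = "minmax_io")
  yn <- traymetry:::normalize_targets(spec2, d$y)
  expect_true(all(yn >= 0 & yn <= 1))
  expect_equal(traymetry:::denormalize_targets(spec2, yn), d$y,
               tolerance = 1e-12)
})

test_that("compute_metrics reproduces the hand-derived example exactly", {
  m <- compute_metrics(c(10, 20), c(12, 18))
  expect_identical(m$mae_cm, 2)
  expect_identical(m$mse, 4)
  expect_equal(m$mape, 0.15)
  expect_equal(m$r2, 0.84)

  perfect <- compute_metrics(c(5, 10, 15), c(5, 10, 15))
  expect_equal(perfect[c("mae_cm", "mse", "mape")],
               list(mae_cm = 0, mse = 0, mape = 0))
  expect_equal(perfect$r2, 1)

  # joint permutation invariance
  set.seed(9)
  yt <- runif(20, 5, 50); yp <- yt + rnorm(20)
  p <- sample(20)
  expect_identical(compute_metrics(yt, yp)[1:4],
                   compute_metrics(yt[p], yp[p])[1:4])

  expect_error(compute_metrics(c(1, 1), c(1, 2)),
               class = "traymetry_undefined_metric")
  expect_error(compute_metrics(c(0, 1), c(1, 2)),
               class = "traymetry_undefined_metric")
})

test_that("constant-mean predictor has R^2 = 0 by construction", {
  set.seed(11)
  y <- runif(40, 5, 60)
  m <- compute_metrics(y, rep(mean(y), 40))
  expect_equal(m$r2, 0, tolerance = 1e-12)
})

test_that("k-fold evaluation is reproducible and enumerable on a toy split", {
  d <- make_xy(60)
  r1 <- kfold_evaluate(d$X, d$y, "mean", "none", k = 5, repeats = 2,
                       base_seed = 7)
  r2 <- kfold_evaluate(d$X, d$y, "mean", "none", k = 5, repeats = 2,
                       base_seed = 7)
  expect_identical(r1[c("mae_cm", "mse", "r2", "mape")],
                   r2[c("mae_cm", "mse", "r2", "mape")])
  expect_identical(r1$per_fold, r2$per_fold)

  # k = 2 constant-mean on y = (10,10,30,30): enumerate the folds by hand
  X <- matrix(1, 4, 1, dimnames = list(NULL, "f"))
  y <- c(10, 10, 30, 30)
  set.seed(5)  # reproduce the internal shuffle of repeat 1
  ord <- sample.int(4)
  fold_of <- rep(1:2, length.out = 4)[order(ord)]
  expected_abs <- abs(y - vapply(seq_len(4), function(i)
    mean(y[fold_of != fold_of[i]]), numeric(1)))
  r <- kfold_evaluate(X, y, "mean", "none", k = 2, repeats = 1,
                      base_seed = 5)
  expect_equal(r$mae_cm, mean(expected_abs))

  expect_error(kfold_evaluate(X, y, k = 10), class = "traymetry_fold_error")
})

test_that("an interpolating regressor reaches zero fold error on linear truth", {
  d <- make_xy(40, fun = function(X) 5 + 0 * X[, 1])
  # constant truth: even the mean predictor interpolates
  r <- kfold_evaluate(d$X, rep(5, 40) + 0.001 * seq_len(40), "knn", "none",
                      k = 4, repeats = 1, base_seed = 1,
                      params = list(k = 1))
  expect_lt(r$mae_cm, 0.05)
})

test_that("boosted trees recover a smooth law and respect layout guards", {
  set.seed(3)
  n <- 300
  area <- runif(n, 1e3, 4e4)
  X <- cbind(bbox_x = runif(n, 0, 500), bbox_y = runif(n, 0, 500),
             bbox_w = sqrt(area) * 1.1, bbox_h = sqrt(area) * 0.4,
             mask_area_px = area)
  y <- 0.1 * sqrt(area)
  m <- train_size_regressor(X, y, "gbt", "minmax_input", seed = 2)
  expect_lt(mean(abs(predict_sizes(m, X) - y)), 0.1)

  expect_error(predict_sizes(m, X[, 1:4]), class = "traymetry_layout_error")
  X2 <- cbind(X[, 1:4], other = X[, 5])
  expect_error(predict_sizes(m, X2), class = "traymetry_layout_error")
  expect_error(train_size_regressor(X[0, ], numeric(0)),
               class = "traymetry_fit_error")
})

test_that("single-species one-hot degenerates gracefully", {
  cat1 <- species_catalog("only")
  recs <- generate_dataset(test_scene_config(catalog = cat1,
                                             length_median_cm = 15),
                           4, seed = 2)
  fx <- dataset_features(recs$records, cat1)
  expect_true(all(fx$features[, "sp_0"] == 1))
  m <- train_size_regressor(fx$features, recs$truth$length_cm, "gbt",
                            "minmax_input", seed = 1)
  expect_true(all(predict_sizes(m, fx$features) > 0))
})

test_that("tree reports are invariant to minmax vs raw features (affine map)", {
  d <- make_xy(80, fun = function(X) X[, 1] * X[, 2] + X[, 3])
  r_none <- kfold_evaluate(d$X, d$y, "gbt", "none", k = 4, repeats = 1,
                           base_seed = 3)
  r_mm <- kfold_evaluate(d$X, d$y, "gbt", "minmax_input", k = 4, repeats = 1,
                         base_seed = 3)
  expect_equal(r_none$mae_cm, r_mm$mae_cm, tolerance = 1e-9)
})

test_that("predictions are floored at the physical minimum", {
  X <- matrix(runif(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(c(-5, -4), 10)  # force negative predictions
  m <- train_size_regressor(X, y, "mean", "none")
  expect_true(all(predict_sizes(m, X) == 0.1))
})

test_that("allometric weights follow W = a L^b with coverage errors", {
  coef <- data.frame(species_id = c(0, 1), a = c(1, 0.01), b = c(1, 3))
  expect_equal(allometric_weight(10, 0, coef), 10)
  expect_equal(allometric_weight(10, 1, coef), 10)
  expect_error(allometric_weight(10, 2, coef),
               class = "traymetry_missing_coefficient")
  # monotone in L for b > 0, on a grid, against direct evaluation
  L <- seq(1, 80, by = 0.5)
  w <- allometric_weight(L, rep(1, length(L)), coef)
  expect_equal(w, 0.01 * L^3)
  expect_true(all(diff(w) > 0))
})
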