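test_that("cross-validation folds keep the per-subject 9:1 ratio and partition trials", {
  tbl <- fake_feature_table(n_subjects = 25, n_trials = 30)
  plan <- make_cv_folds(tbl, n_folds = 10, seed = 1)
  expect_equal(nrow(plan), 750)
  counts <- table(plan$fold)
  expect_true(all(counts == 75))
  per_subj <- table(plan$subject, plan$fold)
  expect_true(all(per_subj == 3))
  # every trial is tested exactly once across folds
  expect_equal(sort(unique(plan$fold)), 1:10)
  expect_equal(nrow(dplyr::distinct(plan[c("subject", "trial")])), 750)
  # determinism
  expect_identical(plan, make_cv_folds(tbl, n_folds = 10, seed = 1))
  expect_false(identical(plan$fold, make_cv_folds(tbl, n_folds = 10, seed = 2)$fold))

  small <- fake_feature_table(n_subjects = 2, n_trials = 5)
  expect_error(make_cv_folds(small, n_folds = 10), "fewer than n_folds")
})

test_that("a constant-target table is fit to machine-level loss", {
  withr::with_seed(21, {
    X <- matrix(rexp(30 * 8), 30, 8)
    y <- matrix(rep(c(-5.2, 0.4, -1.7), each = 30), 30, 3)
  })
  fit <- suppressWarnings(
    fit_mlp(X, y, spec = mlp_spec(n_networks = 1, val_fraction = 0, seed = 2)))
  expect_lt(min(fit$history$train_loss), 1e-3)
  pred <- as.matrix(predict(fit, X))
  expect_lt(max(abs(pred - y)), 0.05)
})

test_that("the network is competitive with the least-squares oracle on a linear task", {
  withr::with_seed(33, {
    n <- 300; p <- 10
    X <- matrix(rnorm(n * p), n, p)
    B <- matrix(rnorm(p * 3, sd = 0.5), p, 3)
    y <- X %*% B + matrix(rnorm(n * 3, sd = 0.01), n, 3)
    test_idx <- sample(n, 60)
  })
  tr <- setdiff(seq_len(n), test_idx)
  fit <- suppressWarnings(fit_mlp(
    X[tr, ], y[tr, ],
    spec = mlp_spec(input = "raw", n_networks = 1, val_fraction = 0,
                    weight_decay = 1e-4, learn_rate = 0.01,
                    patience = 500, max_epochs = 8000, seed = 4)))
  mlp_err <- mean(sqrt(rowSums((as.matrix(predict(fit, X[test_idx, ])) - y[test_idx, ])^2)))
  Bhat <- solve(crossprod(cbind(1, X[tr, ])), crossprod(cbind(1, X[tr, ]), y[tr, ]))
  ols_err <- mean(sqrt(rowSums((cbind(1, X[test_idx, ]) %*% Bhat - y[test_idx, ])^2)))
  expect_lte(mlp_err, 2 * ols_err)
})

test_that("with shuffled labels the network degrades to the mean predictor", {
  tbl <- fake_feature_table(n_subjects = 10, n_trials = 20, p = 8, seed = 12)
  fm <- feature_matrices(tbl)
  truths <- dplyr::distinct(tibble::as_tibble(tbl)[c("subject", "x", "y", "z")])
  yshuf <- withr::with_seed(3, fm$y[sample(nrow(fm$y)), ])
  fit <- fit_mlp(fm$X, yshuf, spec = mlp_spec(seed = 5), subject = fm$subject)
  pred <- as.matrix(predict(fit, fm$X))
  err <- mean(sqrt(rowSums((pred - yshuf)^2)))
  baseline <- mean_predictor_baseline(truths)
  expect_lt(abs(err - baseline) / baseline, 0.15)
})

test_that("cross_validate yields one prediction per trial, deterministically", {
  tbl <- fake_feature_table(n_subjects = 5, n_trials = 10, p = 4, seed = 7)
  spec <- mlp_spec(n_networks = 1, max_epochs = 50, patience = 10)
  cv <- cross_validate(tbl, n_folds = 10, spec = spec, seed = 2)
  expect_equal(nrow(cv), nrow(tbl))
  expect_false(anyNA(cv$pred_x))
  expect_equal(sort(unique(cv$fold)), 1:10)
  cv2 <- cross_validate(tbl, n_folds = 10, spec = spec, seed = 2)
  expect_identical(cv$pred_x, cv2$pred_x)
  # identical feature rows give identical predictions
  fit <- attr(cv, "models")[[1]]
  X2 <- feature_matrices(tbl)$X[c(1, 1), ]
  pr <- predict(fit, X2)
  expect_identical(pr[1, ], pr[2, ])
  expect_error(predict(fit, feature_matrices(tbl)$X[, 1:2]), "mismatch")
})

test_that("test-fold rows never influence training (no leakage)", {
  tbl <- fake_feature_table(n_subjects = 5, n_trials = 10, p = 4, seed = 8)
  plan <- make_cv_folds(tbl, n_folds = 10, seed = 3)
  fm <- feature_matrices(tbl)
  tr <- plan$fold != 1
  spec <- mlp_spec(n_networks = 1, max_epochs = 40, patience = 10)
  fit_a <- fit_mlp(fm$X[tr, ], fm$y[tr, ], spec = spec, subject = fm$subject[tr])
  X_perturbed <- fm$X
  X_perturbed[!tr, ] <- X_perturbed[!tr, ] * 100 + 7
  fit_b <- fit_mlp(X_perturbed[tr, ], fm$y[tr, ], spec = spec, subject = fm$subject[tr])
  expect_identical(fit_a$networks, fit_b$networks)
  expect_identical(fit_a$scaler, fit_b$scaler)
})

test_that("the mean-predictor baseline equals the mean centroid distance", {
  truths <- tibble::tibble(x = c(0, 2), y = c(0, 0), z = c(0, 0))
  expect_equal(mean_predictor_baseline(truths), 1)
})
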