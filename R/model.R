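#' Shallow neural-network coordinate regressor
#'
#' A single-hidden-layer perceptron maps per-channel band-power features to
#' 3D hotspot coordinates (cm). Defaults follow the 63-40-3 architecture:
#' `n_hidden = 40`, tanh hidden units, linear output, squared-error loss.
#' Training is full-batch Adam with early stopping: a subject-stratified
#' validation split of the training trials is monitored, and training stops
#' when validation loss has not improved for `patience` epochs, restoring the
#' best weights.
#'
#' @param n_hidden Hidden-layer width.
#' @param input Input representation. `"relative_power"` (default) divides
#'   each trial's features by their mean, so the network sees the band-power
#'   topography with the trial's overall power level factored out;
#'   `"raw"` feeds band powers directly with per-column z-scoring.
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience, in epochs.
#' @param val_fraction Fraction of training trials held out (subject-
#'   stratified) for early stopping; 0 monitors training loss instead.
#' @param learn_rate Adam step size.
#' @param weight_decay L2 penalty on the connection weights (not biases);
#'   regularizes the network against memorizing individual trials.
#' @param n_networks Number of independently initialized networks whose
#'   predictions are averaged (random-restart ensemble).
#' @param standardize Z-score features using training-fold statistics;
#'   default on only for `input = "raw"`.
#' @param seed Seed for weight initialization and the validation split.
#' @return An `mlp_spec` list.
#' @export
mlp_spec <- function(n_hidden = 40, input = c("relative_power", "raw"),
                     max_epochs = 1000, patience = 50,
                     val_fraction = 0.15, learn_rate = 0.05,
                     weight_decay = 1e-3, n_networks = 3,
                     standardize = NULL, seed = 1) {
  input <- match.arg(input)
  structure(list(n_hidden = n_hidden, input = input, max_epochs = max_epochs,
                 patience = patience, val_fraction = val_fraction,
                 learn_rate = learn_rate, weight_decay = weight_decay,
                 n_networks = n_networks,
                 standardize = standardize %||% (input == "raw"), seed = seed),
            class = "mlp_spec")
}

# per-trial relative power: divide each feature row by its mean
.mlp_input <- function(X, input) {
  if (input == "relative_power") {
    m <- rowMeans(X)
    m[m <= 0 | !is.finite(m)] <- 1
    X / m
  } else X
}

.mse <- function(A, B) mean((A - B)^2)

#' Fit the coordinate-regression network
#'
#' @param X Trials x features matrix (band power per channel), or a
#'   `hotspot_features` table (then `y`/`subject` are taken from it).
#' @param y Trials x 3 target coordinate matrix.
#' @param spec An [mlp_spec()].
#' @param subject Optional per-trial subject ids for the stratified
#'   validation split.
#' @return A fitted `hotspot_mlp`: list of trained networks, feature scaler, training history,
#'   `best_epoch`, and `stopped_early`/`hit_max_epochs` flags.
#' @export
fit_mlp <- function(X, y = NULL, spec = mlp_spec(), subject = NULL) {
  if (inherits(X, "hotspot_features")) {
    fm <- feature_matrices(X)
    X <- fm$X; y <- y %||% fm$y; subject <- subject %||% fm$subject
  }
  X <- as.matrix(X); y <- as.matrix(y)
  stopifnot(nrow(X) == nrow(y), ncol(y) == 3)
  n <- nrow(X); p <- ncol(X); h <- spec$n_hidden

  Xt <- .mlp_input(X, spec$input)
  mu <- if (spec$standardize) colMeans(Xt) else rep(0, p)
  sg <- if (spec$standardize) apply(Xt, 2, sd) else rep(1, p)
  sg[sg == 0 | !is.finite(sg)] <- 1
  Xs <- sweep(sweep(Xt, 2, mu), 2, sg, "/")

  with_local_seed(spec$seed, {
    # validation split, stratified within subject
    if (spec$val_fraction > 0 && n >= 10) {
      groups <- if (is.null(subject)) rep("all", n) else as.character(subject)
      val_idx <- unlist(lapply(split(seq_len(n), groups), function(ix) {
        k <- max(1L, round(spec$val_fraction * length(ix)))
        sample(ix, k)
      }), use.names = FALSE)
    } else {
      val_idx <- integer(0)
    }
    tr_idx <- setdiff(seq_len(n), val_idx)
    Xtr <- Xs[tr_idx, , drop = FALSE]; ytr <- y[tr_idx, , drop = FALSE]
    Xva <- Xs[val_idx, , drop = FALSE]; yva <- y[val_idx, , drop = FALSE]

    train_one <- function() {
      r1 <- sqrt(6 / (p + h))
      W1 <- matrix(runif(h * p, -r1, r1), h, p); b1 <- numeric(h)
      # zero output weights + mean bias: the network starts as exactly the
      # mean predictor, so a fit that early-stops immediately (uninformative
      # features) degrades gracefully instead of adding random-init noise
      W2 <- matrix(0, 3, h); b2 <- colMeans(ytr)

      params <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
      m_t <- lapply(params, function(p) p * 0)
      v_t <- lapply(params, function(p) p * 0)
      beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8

      forward <- function(Xm) {
        H <- tanh(sweep(Xm %*% t(params$W1), 2, params$b1, "+"))
        list(H = H, Y = sweep(H %*% t(params$W2), 2, params$b2, "+"))
      }

      best <- list(loss = Inf, params = params, epoch = 0L)
      wait <- 0L; history <- vector("list", spec$max_epochs)
      ntr <- nrow(Xtr)
      epoch <- 0L
      while (epoch < spec$max_epochs) {
        epoch <- epoch + 1L
        fw <- forward(Xtr)
        dY <- 2 * (fw$Y - ytr) / (ntr * 3)
        dH <- dY %*% params$W2 * (1 - fw$H^2)
        grads <- list(W1 = t(dH) %*% Xtr + 2 * spec$weight_decay * params$W1,
                      b1 = colSums(dH),
                      W2 = t(dY) %*% fw$H + 2 * spec$weight_decay * params$W2,
                      b2 = colSums(dY))
        for (nm in names(params)) {
          m_t[[nm]] <- beta1 * m_t[[nm]] + (1 - beta1) * grads[[nm]]
          v_t[[nm]] <- beta2 * v_t[[nm]] + (1 - beta2) * grads[[nm]]^2
          mhat <- m_t[[nm]] / (1 - beta1^epoch)
          vhat <- v_t[[nm]] / (1 - beta2^epoch)
          params[[nm]] <- params[[nm]] - spec$learn_rate * mhat / (sqrt(vhat) + eps)
        }
        train_loss <- .mse(fw$Y, ytr)
        monitor <- if (length(val_idx) > 0) .mse(forward(Xva)$Y, yva) else train_loss
        history[[epoch]] <- c(epoch = epoch, train_loss = train_loss, monitor_loss = monitor)
        if (monitor < best$loss - 1e-9) {
          best <- list(loss = monitor, params = params, epoch = epoch)
          wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= spec$patience) break
        }
      }
      list(weights = best$params, best_epoch = best$epoch, n_epochs = epoch,
           hit_max = epoch >= spec$max_epochs, best_loss = best$loss,
           history = tibble::as_tibble(do.call(rbind, history[seq_len(epoch)])))
    }

    nets <- lapply(seq_len(spec$n_networks), function(e) train_one())
    if (any(vapply(nets, `[[`, logical(1), "hit_max"))) {
      warn(sprintf("training reached max_epochs = %d without early stop; returning best-so-far weights",
                   spec$max_epochs))
    }
    structure(
      list(networks = lapply(nets, `[[`, "weights"),
           scaler = list(mean = mu, sd = sg),
           spec = spec,
           best_epoch = nets[[1]]$best_epoch, n_epochs = nets[[1]]$n_epochs,
           stopped_early = !any(vapply(nets, `[[`, logical(1), "hit_max")),
           hit_max_epochs = any(vapply(nets, `[[`, logical(1), "hit_max")),
           monitor = if (length(val_idx) > 0) "validation" else "training",
           best_loss = mean(vapply(nets, `[[`, numeric(1), "best_loss")),
           history = nets[[1]]$history),
      class = "hotspot_mlp"
    )
  })
}

#' @export
print.hotspot_mlp <- function(x, ...) {
  cat(sprintf("<hotspot_mlp> %d-%d-3, best epoch %d/%d (%s loss %.4g)\n",
              length(x$scaler$mean), x$spec$n_hidden, x$best_epoch, x$n_epochs,
              x$monitor, x$best_loss))
  invisible(x)
}

#' Predict hotspot coordinates
#'
#' @param object A fitted `hotspot_mlp`.
#' @param newdata Trials x features matrix or `hotspot_features` table with
#'   the same feature columns the model was trained on.
#' @param ... Unused.
#' @return Tibble with `pred_x`, `pred_y`, `pred_z` (cm).
#' @export
predict.hotspot_mlp <- function(object, newdata, ...) {
  if (inherits(newdata, "hotspot_features")) newdata <- feature_matrices(newdata)$X
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$scaler$mean)) {
    abort(sprintf("feature-column mismatch: model expects %d features, got %d",
                  length(object$scaler$mean), ncol(X)))
  }
  Xt <- .mlp_input(X, object$spec$input)
  Xs <- sweep(sweep(Xt, 2, object$scaler$mean), 2, object$scaler$sd, "/")
  Y <- matrix(0, nrow(Xs), 3)
  for (W in object$networks) {
    H <- tanh(sweep(Xs %*% t(W$W1), 2, W$b1, "+"))
    Y <- Y + sweep(H %*% t(W$W2), 2, W$b2, "+")
  }
  Y <- Y / length(object$networks)
  tibble::tibble(pred_x = Y[, 1], pred_y = Y[, 2], pred_z = Y[, 3])
}

#' Tenfold cross-validation plan, stratified within subject
#'
#' Within each subject (and hand), trials are randomly permuted and dealt
#' round-robin into the folds, so with 30 trials and 10 folds every fold's
#' test set holds exactly 3 trials of every subject — the 9:1 per-subject
#' train:test ratio.
#'
#' @param table A `hotspot_features` table (needs `subject`, optionally
#'   `hand`, `trial`).
#' @param n_folds Number of folds.
#' @param seed Seed for the per-subject permutations.
#' @return The table's metadata with a `fold` column appended.
#' @export
make_cv_folds <- function(table, n_folds = 10, seed = 1) {
  tbl <- tibble::as_tibble(table)
  key <- paste(tbl$subject, if ("hand" %in% names(tbl)) tbl$hand else "", sep = "/")
  counts <- vapply(split(key, key), length, integer(1))
  if (any(counts < n_folds)) {
    bad <- names(counts)[counts < n_folds][1]
    abort(sprintf("subject %s has %d trials, fewer than n_folds = %d",
                  bad, counts[[bad]], n_folds))
  }
  fold <- integer(nrow(tbl))
  with_local_seed(seed, {
    for (k in unique(key)) {
      ix <- which(key == k)
      fold[ix[sample.int(length(ix))]] <- rep_len(seq_len(n_folds), length(ix))
    }
  })
  out <- tbl[, intersect(c("subject", "hand", "trial"), names(tbl))]
  out$fold <- fold
  out
}

#' Cross-validated hotspot predictions
#'
#' Trains one network per fold on the complementary folds (feature
#' standardization and the early-stopping validation split use training-fold
#' trials only) and predicts the held-out trials, yielding exactly one
#' prediction per trial.
#'
#' @param table A `hotspot_features` table with targets.
#' @param n_folds Number of folds.
#' @param spec An [mlp_spec()].
#' @param seed Seed for the fold plan (fold k trains with weight seed
#'   `spec$seed + k`).
#' @param folds Optional precomputed plan from [make_cv_folds()].
#' @return Tibble of class `hotspot_predictions`: per-trial metadata, truth
#'   `x/y/z`, `fold`, and `pred_x/pred_y/pred_z`.
#' @export
cross_validate <- function(table, n_folds = 10, spec = mlp_spec(), seed = 1,
                           folds = NULL) {
  plan <- folds %||% make_cv_folds(table, n_folds, seed)
  fold <- plan$fold
  fm <- feature_matrices(table)
  preds <- matrix(NA_real_, nrow(table), 3)
  models <- vector("list", max(fold))
  for (k in sort(unique(fold))) {
    tr <- fold != k
    sp <- spec; sp$seed <- spec$seed + k
    fit <- fit_mlp(fm$X[tr, , drop = FALSE], fm$y[tr, , drop = FALSE],
                   spec = sp, subject = fm$subject[tr])
    preds[!tr, ] <- as.matrix(predict(fit, fm$X[!tr, , drop = FALSE]))
    models[[k]] <- fit
  }
  out <- dplyr::bind_cols(
    tibble::as_tibble(table)[, intersect(c("subject", "hand", "trial", "x", "y", "z"),
                                         names(table))],
    tibble::tibble(fold = fold,
                   pred_x = preds[, 1], pred_y = preds[, 2], pred_z = preds[, 3])
  )
  structure(out, band = attr(table, "band"), channels = attr(table, "channels"),
            models = models,
            class = c("hotspot_predictions", class(out)))
}

#' Mean-predictor baseline error
#'
#' Error level of the trivial predictor that always answers the centroid of
#' the ground-truth hotspots: the mean distance of the truths to their
#' centroid. Cross-validated errors well below this line demonstrate that the
#' features carry location information.
#'
#' @param truths Tibble with `x`, `y`, `z` (one row per subject/hand).
#' @return Mean centroid distance, cm.
#' @export
mean_predictor_baseline <- function(truths) {
  M <- as.matrix(tibble::as_tibble(truths)[, c("x", "y", "z")])
  centroid <- colMeans(M)
  mean(sqrt(rowSums(sweep(M, 2, centroid)^2)))
}
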