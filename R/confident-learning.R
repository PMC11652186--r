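# Final label refinement: confident-joint estimation, pruning and
# reweighting, then co-teaching of two peer networks on the cleaned
# three-class data.

#' Estimate the confident joint of observed and true labels
#'
#' For each class `j`, the confidence threshold `t_j` is the mean
#' predicted probability of class `j` among samples observed as `j`. A
#' sample counts in cell `(observed, predicted)` where `predicted` is the
#' argmax over classes whose probability reaches their threshold; samples
#' confident for no class are left unassigned. Off-diagonal mass flags
#' likely label errors.
#'
#' @param probs `n x K` matrix of (ideally out-of-sample) predicted class
#'   probabilities; rows must sum to 1.
#' @param labels Observed labels in `0:(K-1)`.
#' @return An object of class `confident_joint` with `counts` (K x K,
#'   rows = observed), `thresholds`, `assigned` (row indices),
#'   `predicted` (for assigned rows) and `noise_estimate` (off-diagonal
#'   fraction).
#' @export
estimate_confident_joint <- function(probs, labels) {
  probs <- as_feature_matrix_input(probs)
  abort_if(anyNA(probs) || any(!is.finite(probs)),
           "`probs` contains NA or non-finite values")
  abort_if(any(abs(rowSums(probs) - 1) > 1e-6), "rows of `probs` must sum to 1")
  k <- ncol(probs)
  labels <- as.integer(labels)
  abort_if(length(labels) != nrow(probs), "`labels` length mismatch")
  abort_if(!all(labels %in% 0:(k - 1L)), "labels out of range")

  thresholds <- vapply(seq_len(k), function(j) {
    mean(probs[labels == j - 1L, j])
  }, numeric(1))
  thresholds[is.nan(thresholds)] <- Inf  # class never observed

  above <- sweep(probs, 2, thresholds, ">=")
  masked <- probs
  masked[!above] <- -Inf
  assigned <- which(rowSums(above) > 0L)
  predicted <- max.col(masked[assigned, , drop = FALSE],
                       ties.method = "first") - 1L
  counts <- matrix(0L, k, k,
                   dimnames = list(observed = 0:(k - 1L),
                                   predicted = 0:(k - 1L)))
  tab <- table(factor(labels[assigned], levels = 0:(k - 1L)),
               factor(predicted, levels = 0:(k - 1L)))
  counts[] <- as.integer(tab)
  off <- sum(counts) - sum(diag(counts))
  structure(list(counts = counts, thresholds = thresholds,
                 assigned = assigned, predicted = predicted,
                 noise_estimate = if (sum(counts) > 0) off / sum(counts) else 0),
            class = "confident_joint")
}

#' Prune likely-mislabeled samples and reweight classes
#'
#' Removes the samples falling in off-diagonal cells of the confident
#' joint (observed label contradicted by a confident prediction) and
#' attaches inverse-frequency class weights (normalized to mean 1) to the
#' retained samples, compensating the imbalance pruning can introduce.
#'
#' @param data Tibble the joint was estimated on (same row order).
#' @param joint A [estimate_confident_joint()] result.
#' @param label_col Name of the observed-label column.
#' @return A list: `data` (retained rows with a `.weight` column),
#'   `class_weights` (named vector), `pruned` (removed rows).
#' @export
prune_and_reweight <- function(data, joint, label_col = "label") {
  abort_if(!inherits(joint, "confident_joint"), "`joint` must be a confident_joint")
  labels <- as.integer(data[[label_col]])
  k <- ncol(joint$counts)
  drop_idx <- joint$assigned[joint$predicted != labels[joint$assigned]]
  keep <- setdiff(seq_len(nrow(data)), drop_idx)
  kept_labels <- labels[keep]
  counts <- table(factor(kept_labels, levels = 0:(k - 1L)))
  abort_if(any(counts == 0 & table(factor(labels, levels = 0:(k - 1L))) > 0),
           "pruning would remove every sample of a class")
  freq <- as.numeric(counts)
  w <- ifelse(freq > 0, 1 / freq, 0)
  w <- w / mean(w[freq > 0])
  names(w) <- 0:(k - 1L)
  out <- data[keep, , drop = FALSE]
  out$.weight <- w[as.character(kept_labels)]
  list(data = out, class_weights = w, pruned = data[drop_idx, , drop = FALSE])
}

#' Out-of-fold class probabilities by cross-validation
#'
#' Fits the compact network on `folds` training splits and predicts each
#' sample from the model that did not see it, so the confident joint is
#' estimated from probabilities free of self-confirmation.
#'
#' @param x Feature matrix.
#' @param y Labels in `0:(K-1)`.
#' @param k Number of classes.
#' @param folds Number of folds (default 5).
#' @param config A [classifier_config()]; small-loss selection is
#'   disabled for these plain fits.
#' @param seed Integer seed.
#' @return `n x K` matrix of out-of-fold probabilities.
#' @export
cv_probabilities <- function(x, y, k, folds = 5L,
                             config = classifier_config(), seed = 1L) {
  x <- as_feature_matrix_input(x)
  n <- nrow(x)
  gaussian <- identical(config$architecture, "gaussian")
  if (!gaussian) config$small_loss <- FALSE
  fold_id <- with_seed_or_not(seed, sample(rep_len(seq_len(folds), n)))
  probs <- matrix(NA_real_, n, k)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    if (gaussian) {
      fit <- fit_gaussian_classifier(x[tr, , drop = FALSE], y[tr],
                                     config = config,
                                     seed = derive_seed(seed, f))
      probs[!tr, ] <- softmax_rows(predict_gaussian(fit, x[!tr, , drop = FALSE]))
    } else {
      fit <- fit_net(x[tr, , drop = FALSE], y[tr], k = k, config = config,
                     seed = derive_seed(seed, f))
      probs[!tr, ] <- predict_net(fit, x[!tr, , drop = FALSE], type = "prob")
    }
  }
  probs
}

#' Co-teaching of two peer networks on noisy labels
#'
#' Trains two identically structured, independently initialized networks.
#' After the warm-up epochs, in every epoch each network ranks all samples
#' by its own current loss and hands its small-loss subset to the *peer*,
#' which updates only on that subset; the keep rate decays from 1 to
#' `1 - forget_rate` over ten epochs. Peer selection prevents a single
#' model from confirming its own mistakes on mislabeled samples.
#'
#' @param data Tibble of cleaned samples (all classes present), e.g. from
#'   [prune_and_reweight()].
#' @param config A [classifier_config()]; `forget_rate` sets the final
#'   exclusion fraction.
#' @param seed Integer seed (the peers use `seed` and a derived seed).
#' @param feature_cols Feature column names.
#' @param label_col Label column (values `0:(K-1)`).
#' @param weight_col Optional per-sample weight column (e.g. `.weight`).
#' @param n_classes Number of classes (default 3).
#' @param noise_estimate Estimated residual label-noise fraction (e.g.
#'   from [estimate_confident_joint()]); the keep rate decays to
#'   `1 - min(noise_estimate, 0.3)`. Defaults to `config$forget_rate`.
#' @return An object of class `coteach_fit` with the two networks and the
#'   keep-rate schedule actually used.
#' @export
coteach_train <- function(data, config = classifier_config(), seed = 1L,
                          feature_cols = c("sd_wps", "sd_coverage"),
                          label_col = "label", weight_col = NULL,
                          n_classes = 3L, noise_estimate = NULL) {
  x <- dataset_features(data, feature_cols)
  y <- as.integer(data[[label_col]])
  abort_if(length(unique(y)) < n_classes,
           "all classes must be present for co-teaching")
  n <- nrow(x)
  sw <- if (!is.null(weight_col)) data[[weight_col]] else rep(1, n)
  ctr <- colMeans(x); scl <- apply(x, 2, stats::sd); scl[scl <= 0] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  hidden <- if (identical(config$architecture, "mlp")) config$hidden_units else 0L
  forget <- min(noise_estimate %||% config$forget_rate, 0.3)
  keep_rate <- function(e) {
    if (e <= config$warmup_epochs) 1
    else 1 - forget * min(1, (e - config$warmup_epochs) / 10)
  }

  seeds <- c(seed, derive_seed(seed, 77L))
  nets <- lapply(seeds, function(s) {
    withr::with_seed(s, init_net(ncol(xs), n_classes, hidden))
  })
  states <- lapply(nets, adam_state)
  schedule <- numeric(config$epochs)

  withr::with_seed(derive_seed(seed, 78L), {
    for (e in seq_len(config$epochs)) {
      kr <- keep_rate(e)
      schedule[e] <- kr
      nkeep <- max(n_classes, ceiling(kr * n))
      sel <- lapply(nets, function(par) {
        if (kr >= 1) seq_len(n) else order(net_losses(par, xs, y))[seq_len(nkeep)]
      })
      # Peer update: model 2 trains on model 1's clean subset and vice versa.
      for (m in 1:2) {
        idx <- sample(sel[[3L - m]])
        batches <- split(idx, ceiling(seq_along(idx) / config$batch_size))
        for (b in batches) {
          g <- net_gradients(nets[[m]], xs[b, , drop = FALSE], y[b],
                             n_classes, sw[b])
          upd <- adam_step(nets[[m]], g, states[[m]], config$learning_rate)
          nets[[m]] <- upd$par; states[[m]] <- upd$state
        }
      }
    }
  })

  wrap <- function(par, s) {
    structure(list(par = par, center = ctr, scale = scl, k = n_classes,
                   hidden = hidden, config = config, seed = s),
              class = "softmax_net")
  }
  structure(list(model_a = wrap(nets[[1L]], seeds[1L]),
                 model_b = wrap(nets[[2L]], seeds[2L]),
                 keep_schedule = schedule, feature_cols = feature_cols,
                 n_classes = n_classes),
            class = "coteach_fit")
}

#' Averaged class probabilities of the co-taught pair
#'
#' @param models A [coteach_train()] fit.
#' @param newdata Tibble with the feature columns, or a matrix.
#' @return `n x K` matrix of averaged probabilities.
#' @export
coteach_probs <- function(models, newdata) {
  abort_if(!inherits(models, "coteach_fit"), "`models` must be a coteach_fit")
  x <- if (is.data.frame(newdata)) {
    dataset_features(newdata, models$feature_cols)
  } else {
    as_feature_matrix_input(newdata)
  }
  (predict_net(models$model_a, x, type = "prob") +
     predict_net(models$model_b, x, type = "prob")) / 2
}

#' Final three-class prediction
#'
#' Argmax of the averaged class probabilities of the two co-taught
#' networks; ties break deterministically to the lowest class index.
#'
#' @inheritParams coteach_probs
#' @return Integer labels in `0:(K-1)`.
#' @export
predict_final <- function(models, newdata) {
  p <- coteach_probs(models, newdata)
  max.col(p, ties.method = "first") - 1L
}
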