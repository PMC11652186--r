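#' Configuration of the noise-tolerant classifier
#'
#' Settings for the compact pluggable classifier that supplies the
#' class-probability input of the sensitized chart. The default
#' architecture is a linear (softmax) model on the summary features; an
#' optional one-hidden-layer network (`architecture = "mlp"`) is available
#' for richer inputs. Noise tolerance comes from small-loss sample
#' selection after a warm-up phase: each epoch only the fraction of
#' samples with the smallest current loss (ramping down to
#' `1 - forget_rate`) is used for updates, so likely-mislabeled samples
#' are progressively excluded.
#'
#' @param architecture `"gaussian"` (default; robust shrinkage Gaussian
#'   class-conditionals whose log-likelihood-ratio score stays calibrated
#'   off the training manifold — observations resembling neither class get
#'   an uncertain-to-closed score instead of a saturated one), `"linear"`
#'   (softmax regression) or `"mlp"` (one hidden layer).
#' @param hidden_units Hidden width when `architecture = "mlp"`.
#' @param learning_rate Adam learning rate; default 0.05, sized for the
#'   compact model and full-feature standardization.
#' @param batch_size Minibatch size (default 128).
#' @param epochs Training epochs (default 150).
#' @param warmup_epochs Epochs trained on all samples before small-loss
#'   selection starts (default 10).
#' @param n_seeds Number of independent seeds over which evaluation
#'   metrics are averaged (default 5).
#' @param small_loss Enable small-loss selection (default `TRUE`).
#' @param forget_rate Final fraction of samples excluded per epoch
#'   (default 0.2, matching a 20% label-noise working point).
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(architecture = c("gaussian", "linear", "mlp"),
                              hidden_units = 8L, learning_rate = 0.05,
                              batch_size = 128L, epochs = 150L,
                              warmup_epochs = 10L, n_seeds = 5L,
                              small_loss = TRUE, forget_rate = 0.2) {
  architecture <- match.arg(architecture)
  abort_if(epochs < warmup_epochs || warmup_epochs < 0,
           "need epochs >= warmup_epochs >= 0")
  check_number(learning_rate, "learning_rate", lower = 0, closed_lower = FALSE)
  check_number(forget_rate, "forget_rate", lower = 0, upper = 0.9)
  structure(list(architecture = architecture,
                 hidden_units = as.integer(hidden_units),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 warmup_epochs = as.integer(warmup_epochs),
                 n_seeds = as.integer(n_seeds),
                 small_loss = small_loss, forget_rate = forget_rate),
            class = "classifier_config")
}

dataset_features <- function(data, feature_cols) {
  abort_if(!all(feature_cols %in% names(data)),
           paste("missing feature columns:",
                 paste(setdiff(feature_cols, names(data)), collapse = ", ")))
  as.matrix(data[, feature_cols])
}

#' Train the noise-tolerant binary classifier
#'
#' Fits the compact classifier on a labeled dataset tibble using the
#' observed (possibly noisy) binary labels, with warm-up followed by
#' small-loss sample selection. Deterministic given `seed`.
#'
#' @param data A tibble with the feature columns and a binary label
#'   column (e.g. from [make_dataset()]).
#' @param config A [classifier_config()].
#' @param seed Integer seed.
#' @param feature_cols Feature column names; default the two dispersion
#'   summaries `sd_wps`, `sd_coverage`.
#' @param label_col Name of the 0/1 label column.
#' @return An object of class `ocr_classifier`.
#' @export
train_classifier <- function(data, config = classifier_config(), seed = 1L,
                             feature_cols = c("sd_wps", "sd_coverage"),
                             label_col = "observed_label") {
  x <- dataset_features(data, feature_cols)
  y <- as.integer(data[[label_col]])
  abort_if(length(unique(y)) < 2L, "both classes must be present")
  abort_if(!all(y %in% 0:1), "labels must be 0/1")
  fit <- if (identical(config$architecture, "gaussian")) {
    fit_gaussian_classifier(x, y, config = config, seed = seed)
  } else {
    fit_net(x, y, k = 2L, config = config, seed = seed)
  }
  structure(list(fit = fit, feature_cols = feature_cols, config = config,
                 seed = seed),
            class = "ocr_classifier")
}

#' Classifier probability of openness
#'
#' Returns the raw linear output `theta` (log-odds of the open class) and
#' `pc = sigmoid(theta)`, the classifier probability fused into the
#' sensitized statistic.
#'
#' @param model An [train_classifier()] fit.
#' @param newdata Tibble with the model's feature columns, or a numeric
#'   matrix.
#' @return A tibble with columns `theta` and `pc`.
#' @export
prob_classifier <- function(model, newdata) {
  abort_if(!inherits(model, "ocr_classifier"), "`model` must be an ocr_classifier")
  x <- if (is.data.frame(newdata)) dataset_features(newdata, model$feature_cols)
       else as_feature_matrix_input(newdata)
  s <- if (inherits(model$fit, "gaussian_classifier")) {
    predict_gaussian(model$fit, x)
  } else {
    predict_net(model$fit, x, type = "score")
  }
  # Clamp the raw score so pc stays strictly inside (0, 1) in double
  # precision even for observations far from both classes.
  theta <- pmin(pmax(s[, 2L] - s[, 1L], -30), 30)
  tibble::tibble(theta = as.numeric(theta), pc = sigmoid(as.numeric(theta)))
}

#' @export
predict.ocr_classifier <- function(object, newdata,
                                   type = c("prob", "class"), ...) {
  type <- match.arg(type)
  p <- prob_classifier(object, newdata)
  if (type == "prob") p$pc else as.integer(p$pc > 0.5)
}

# Robust Gaussian class-conditional classifier. Each class is modelled by
# a shrinkage-regularized Gaussian fitted with small-loss trimming after a
# warm-up fit: samples with the largest negative log-likelihood under
# their own class (the likely mislabeled ones) are excluded and the class
# models refitted. The score columns are log prior + log density, so the
# binary theta is the log posterior odds — calibrated also for
# observations far from both classes.
fit_gaussian_classifier <- function(x, y, config, seed = 1L,
                                    shrinkage = 0.1, rounds = 3L) {
  x <- as_feature_matrix_input(x)
  classes <- sort(unique(y))
  fit_class <- function(xc) {
    mu <- colMeans(xc)
    s <- stats::cov(xc)
    s <- s + shrinkage * (sum(diag(s)) / ncol(xc)) * diag(ncol(xc))
    list(mu = mu, sigma = s)
  }
  models <- lapply(classes, function(cl) fit_class(x[y == cl, , drop = FALSE]))
  if (isTRUE(config$small_loss) && config$forget_rate > 0) {
    for (r in seq_len(rounds)) {
      models <- lapply(seq_along(classes), function(i) {
        xc <- x[y == classes[i], , drop = FALSE]
        d2 <- stats::mahalanobis(xc, models[[i]]$mu, models[[i]]$sigma)
        keep <- order(d2)[seq_len(max(ncol(x) + 2L,
                                      ceiling((1 - config$forget_rate) * nrow(xc))))]
        fit_class(xc[keep, , drop = FALSE])
      })
    }
  }
  priors <- as.numeric(table(factor(y, levels = classes))) / length(y)
  structure(list(models = models, classes = classes, priors = priors,
                 p = ncol(x)),
            class = "gaussian_classifier")
}

predict_gaussian <- function(fit, x) {
  x <- as_feature_matrix_input(x)
  scores <- vapply(seq_along(fit$classes), function(i) {
    m <- fit$models[[i]]
    ev <- eigen(m$sigma, symmetric = TRUE, only.values = TRUE)$values
    log(fit$priors[i]) - 0.5 * sum(log(ev)) -
      0.5 * stats::mahalanobis(x, m$mu, m$sigma)
  }, numeric(nrow(x)))
  matrix(scores, nrow = nrow(x))
}
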