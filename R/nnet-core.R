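# Compact Adam-trained softmax / one-hidden-layer network with optional
# small-loss sample selection. Shared by the binary noise-tolerant
# classifier and the three-class co-teaching stage. All randomness
# (initialization, shuffling) is seeded by the caller.

init_net <- function(d, k, hidden) {
  if (hidden > 0L) {
    list(W1 = matrix(stats::rnorm(d * hidden, sd = sqrt(2 / d)), d, hidden),
         b1 = numeric(hidden),
         W2 = matrix(stats::rnorm(hidden * k, sd = sqrt(2 / hidden)), hidden, k),
         b2 = numeric(k))
  } else {
    list(W2 = matrix(stats::rnorm(d * k, sd = 0.01), d, k), b2 = numeric(k))
  }
}

net_scores <- function(par, x) {
  if (!is.null(par$W1)) {
    h <- pmax(x %*% par$W1 + rep(par$b1, each = nrow(x)), 0)
    list(scores = h %*% par$W2 + rep(par$b2, each = nrow(h)), hidden = h)
  } else {
    list(scores = x %*% par$W2 + rep(par$b2, each = nrow(x)), hidden = NULL)
  }
}

softmax_rows <- function(s) {
  s <- s - apply(s, 1, max)
  e <- exp(s)
  e / rowSums(e)
}

net_probs <- function(par, x) softmax_rows(net_scores(par, x)$scores)

# Per-sample cross-entropy; y is 0-based class index.
net_losses <- function(par, x, y) {
  p <- net_probs(par, x)
  -log(pmax(p[cbind(seq_len(nrow(x)), y + 1L)], 1e-12))
}

net_gradients <- function(par, x, y, k, sample_weights) {
  n <- nrow(x)
  fwd <- net_scores(par, x)
  p <- softmax_rows(fwd$scores)
  d_scores <- p
  d_scores[cbind(seq_len(n), y + 1L)] <-
    d_scores[cbind(seq_len(n), y + 1L)] - 1
  d_scores <- d_scores * sample_weights / sum(sample_weights)
  g <- list()
  if (!is.null(par$W1)) {
    g$W2 <- t(fwd$hidden) %*% d_scores
    g$b2 <- colSums(d_scores)
    d_h <- (d_scores %*% t(par$W2)) * (fwd$hidden > 0)
    g$W1 <- t(x) %*% d_h
    g$b1 <- colSums(d_h)
  } else {
    g$W2 <- t(x) %*% d_scores
    g$b2 <- colSums(d_scores)
  }
  g
}

adam_state <- function(par) {
  list(m = lapply(par, function(w) w * 0), v = lapply(par, function(w) w * 0),
       t = 0L)
}

adam_step <- function(par, grad, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  for (nm in names(grad)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * grad[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * grad[[nm]]^2
    mhat <- st$m[[nm]] / (1 - beta1^st$t)
    vhat <- st$v[[nm]] / (1 - beta2^st$t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, state = st)
}

# Fit one network. `keep_fraction(epoch)` returns the fraction of
# smallest-loss samples trained on in that epoch (1 during warm-up).
fit_net <- function(x, y, k, config, seed = 1L, sample_weights = NULL,
                    keep_fraction = NULL) {
  x <- as_feature_matrix_input(x)
  n <- nrow(x); d <- ncol(x)
  sample_weights <- sample_weights %||% rep(1, n)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl <= 0] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  hidden <- if (identical(config$architecture, "mlp")) config$hidden_units else 0L
  if (is.null(keep_fraction)) {
    keep_fraction <- if (isTRUE(config$small_loss)) {
      function(e) {
        if (e <= config$warmup_epochs) 1
        else 1 - config$forget_rate *
          min(1, (e - config$warmup_epochs) / 10)
      }
    } else {
      function(e) 1
    }
  }

  withr::with_seed(seed, {
    par <- init_net(d, k, hidden)
    st <- adam_state(par)
    for (e in seq_len(config$epochs)) {
      idx <- seq_len(n)
      kf <- keep_fraction(e)
      if (kf < 1) {
        losses <- net_losses(par, xs, y)
        nkeep <- max(k, ceiling(kf * n))
        idx <- order(losses)[seq_len(nkeep)]
      }
      idx <- sample(idx)
      batches <- split(idx, ceiling(seq_along(idx) / config$batch_size))
      for (b in batches) {
        g <- net_gradients(par, xs[b, , drop = FALSE], y[b], k,
                           sample_weights[b])
        upd <- adam_step(par, g, st, config$learning_rate)
        par <- upd$par; st <- upd$state
      }
    }
    structure(list(par = par, center = ctr, scale = scl, k = k,
                   hidden = hidden, config = config, seed = seed),
              class = "softmax_net")
  })
}

predict_net <- function(fit, x, type = c("prob", "class", "score")) {
  type <- match.arg(type)
  x <- as_feature_matrix_input(x)
  abort_if(ncol(x) != length(fit$center), "feature dimension mismatch")
  xs <- sweep(sweep(x, 2, fit$center), 2, fit$scale, "/")
  s <- net_scores(fit$par, xs)$scores
  switch(type,
         score = s,
         prob = softmax_rows(s),
         class = max.col(softmax_rows(s), ties.method = "first") - 1L)
}
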