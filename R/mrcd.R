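#' Minimum regularized covariance determinant (MRCD) estimator
#'
#' Robust multivariate location and scatter for the in-control model of
#' the robust Hotelling T-squared chart. The data are standardized by
#' coordinatewise median and MAD, the scatter target is the identity on
#' that scale, and the estimator searches for the size-`h` subset
#' (`h = ceiling(n * (1 - alpha_trim))`) minimizing the determinant of the
#' regularized scatter `rho * I + (1 - rho) * c * S_h`, where `c` is the
#' chi-square consistency factor. The search runs C-steps from six
#' deterministic initial scatter estimates; `rho` is the smallest value on
#' a grid keeping the condition number below `cond_max`.
#'
#' With `alpha_trim = 0` and `rho = 0` the estimate reduces exactly to the
#' classical mean and covariance.
#'
#' @param x Numeric matrix or data frame, `n` rows by `p >= 2` columns,
#'   `n > p`.
#' @param alpha_trim Trimming fraction in `[0, 0.5]`; default 0.25.
#' @param rho Fixed regularization weight in `[0, 1]`, or `NULL` (default)
#'   to select the smallest grid value bounding the condition number.
#' @param cond_max Condition-number bound used when `rho` is selected.
#' @param max_csteps Maximum C-step iterations per start.
#' @param reweight Apply a one-step chi-square reweighting that restores
#'   efficiency on clean data (default `FALSE`: reweighting partially
#'   re-admits moderate outliers and is left off where robustness against
#'   mislabeled windows matters more than efficiency).
#'
#' @return An object of class `mrcd` with elements `location`, `scatter`,
#'   `rho`, `h`, `p`, `n`, `subset` (row indices), `objective`
#'   (log-determinant) and the standardization (`center0`, `scale0`).
#' @export
fit_mrcd <- function(x, alpha_trim = 0.25, rho = NULL, cond_max = 50,
                     max_csteps = 50L, reweight = FALSE) {
  x <- as_feature_matrix_input(x)
  n <- nrow(x); p <- ncol(x)
  abort_if(p < 2L, "need at least two variables")
  abort_if(n <= p, "need more observations than variables")
  check_number(alpha_trim, "alpha_trim", lower = 0, upper = 0.5)
  if (!is.null(rho)) check_number(rho, "rho", lower = 0, upper = 1)

  center0 <- apply(x, 2, stats::median)
  scale0 <- apply(x, 2, stats::mad)
  zero <- scale0 <= 0
  if (any(zero)) scale0[zero] <- apply(x[, zero, drop = FALSE], 2, stats::sd)
  abort_if(any(scale0 <= 0), "degenerate scatter: a variable is constant")
  z <- sweep(sweep(x, 2, center0), 2, scale0, "/")

  h <- min(n, max(p + 1L, as.integer(ceiling(n * (1 - alpha_trim)))))
  cfac <- consistency_factor(h, n, p)
  rho_grid <- if (is.null(rho)) {
    c(0, 0.001, 0.005, 0.01, 0.025, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5)
  } else {
    rho
  }

  reg_scatter <- function(subset) {
    m <- colMeans(z[subset, , drop = FALSE])
    s_h <- stats::cov(z[subset, , drop = FALSE])
    k <- NULL; rho_used <- NA_real_
    for (r in rho_grid) {
      cand <- r * diag(p) + (1 - r) * cfac * s_h
      ev <- eigen(cand, symmetric = TRUE, only.values = TRUE)$values
      if (ev[p] > 1e-12 && ev[1] / ev[p] <= cond_max) {
        k <- cand; rho_used <- r
        break
      }
    }
    if (is.null(k)) {  # fall back to the most regularized grid value
      rho_used <- rho_grid[length(rho_grid)]
      k <- rho_used * diag(p) + (1 - rho_used) * cfac * s_h
    }
    ev <- eigen(k, symmetric = TRUE, only.values = TRUE)$values
    abort_if(ev[p] <= 1e-12, "degenerate scatter: duplicate/constant rows?")
    list(m = m, k = k, rho = rho_used, logdet = sum(log(ev)))
  }

  run_csteps <- function(subset) {
    est <- reg_scatter(subset)
    for (it in seq_len(max_csteps)) {
      d2 <- stats::mahalanobis(z, est$m, est$k)
      new_subset <- sort(order(d2)[seq_len(h)])
      if (identical(new_subset, subset)) break
      subset <- new_subset
      est <- reg_scatter(subset)
    }
    c(est, list(subset = subset))
  }

  best <- NULL
  for (s0 in initial_scatters(z)) {
    d2 <- stats::mahalanobis(z, rep(0, p), s0)
    fit <- run_csteps(sort(order(d2)[seq_len(h)]))
    if (is.null(best) || fit$logdet < best$logdet) best <- fit
  }

  # One-step reweighting (standard for trimmed covariance estimators):
  # recompute mean/cov from the observations the raw estimate does not
  # flag, restoring efficiency on clean data. Skipped when h = n so the
  # untrimmed, unregularized limit stays exactly classical.
  if (reweight && h < n) {
    d2 <- stats::mahalanobis(z, best$m, best$k)
    w <- d2 <= stats::qchisq(0.975, df = p)
    if (sum(w) > p + 1L) {
      m_w <- colMeans(z[w, , drop = FALSE])
      s_w <- stats::cov(z[w, , drop = FALSE]) * consistency_factor_frac(0.975, p)
      k_w <- NULL
      for (r in rho_grid) {
        cand <- r * diag(p) + (1 - r) * s_w
        ev <- eigen(cand, symmetric = TRUE, only.values = TRUE)$values
        if (ev[p] > 1e-12 && ev[1] / ev[p] <= cond_max) {
          k_w <- cand
          best$rho <- r
          break
        }
      }
      if (!is.null(k_w)) {
        best$m <- m_w
        best$k <- k_w
        ev <- eigen(k_w, symmetric = TRUE, only.values = TRUE)$values
        best$logdet <- sum(log(ev))
      }
    }
  }

  location <- center0 + scale0 * best$m
  scatter <- diag(scale0) %*% best$k %*% diag(scale0)
  dimnames(scatter) <- list(colnames(x), colnames(x))
  structure(list(location = stats::setNames(location, colnames(x)),
                 scatter = scatter, rho = best$rho, h = h, p = p, n = n,
                 subset = best$subset, objective = best$logdet,
                 consistency = cfac, center0 = center0, scale0 = scale0),
            class = "mrcd")
}

# Consistency factor of the h-subset covariance under normality.
consistency_factor <- function(h, n, p) {
  if (h >= n) return(1)
  consistency_factor_frac(h / n, p)
}

consistency_factor_frac <- function(a, p) {
  a / stats::pchisq(stats::qchisq(a, df = p), df = p + 2)
}

# Six deterministic initial scatter estimates (on standardized data).
initial_scatters <- function(z) {
  p <- ncol(z); n <- nrow(z)
  fix_pd <- function(s) {
    s <- (s + t(s)) / 2
    e <- eigen(s, symmetric = TRUE)
    e$values <- pmax(e$values, 1e-6 * max(e$values, 1e-6))
    e$vectors %*% diag(e$values, p) %*% t(e$vectors)
  }
  ranks <- apply(z, 2, rank)
  nscores <- stats::qnorm((ranks - 1 / 3) / (n + 1 / 3))
  list(diag(p),
       fix_pd(stats::cor(ranks)),                    # Spearman
       fix_pd(stats::cor(tanh(z))),                  # bounded transform
       fix_pd(stats::cor(sign(z))),                  # quadrant correlation
       fix_pd(stats::cor(nscores)),                  # normal scores
       fix_pd(0.75 * stats::cov(z) + 0.25 * diag(diag(stats::cov(z)), p)))
}

#' Hotelling T-squared statistic
#'
#' Quadratic form `(x - location)' scatter^{-1} (x - location)` against an
#' in-control model: either a fitted [fit_mrcd()] object (robust chart) or
#' a plain `list(location =, scatter =)` with the classical mean and
#' covariance.
#'
#' @param model An `mrcd` fit or a `list(location, scatter)`.
#' @param x A length-`p` vector or an `n x p` matrix/data frame.
#' @return Numeric vector of nonnegative T-squared values.
#' @export
t2_statistic <- function(model, x) {
  loc <- model$location
  sc <- model$scatter %||% model$cov
  abort_if(is.null(loc) || is.null(sc), "`model` needs location and scatter")
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as_feature_matrix_input(x)
  abort_if(ncol(x) != length(loc), "dimension mismatch between `x` and model")
  as.numeric(stats::mahalanobis(x, loc, sc))
}

#' Classical in-control model
#'
#' Sample mean and covariance packaged for [t2_statistic()].
#' @param x Numeric matrix or data frame.
#' @return A `list(location, scatter)`.
#' @export
classical_model <- function(x) {
  x <- as_feature_matrix_input(x)
  list(location = colMeans(x), scatter = stats::cov(x))
}

#' @export
print.mrcd <- function(x, ...) {
  cat(sprintf("MRCD fit: n = %d, p = %d, h = %d, rho = %g, logdet = %.3f\n",
              x$n, x$p, x$h, x$rho, x$objective))
  invisible(x)
}
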