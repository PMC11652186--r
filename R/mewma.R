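#' Fit the in-control MEWMA model
#'
#' Stores the in-control mean and covariance of the monitored summary
#' vectors together with the smoothing weight `lam`, and the smoothed
#' covariance `SZ = (lam / (2 - lam)) * S` used by the MEWMA statistic.
#'
#' @param ic_data In-control observations: matrix or data frame with `p`
#'   numeric columns (for chromatin monitoring, the `sd_wps` /
#'   `sd_coverage` summary vectors of closed regions).
#' @param lam Smoothing weight in (0, 1]; default 0.2. `lam = 1` recovers
#'   the memoryless Hotelling chart.
#' @return An object of class `mewma_model` with `lam`, `center`, `S`,
#'   `SZ`, `p`.
#' @export
mewma_model <- function(ic_data, lam = 0.2) {
  check_number(lam, "lam", lower = 0, upper = 1, closed_lower = FALSE)
  x <- as_feature_matrix_input(ic_data)
  abort_if(nrow(x) <= ncol(x), "need more in-control rows than variables")
  s <- stats::cov(x)
  structure(list(lam = lam, center = colMeans(x), S = s,
                 SZ = (lam / (2 - lam)) * s, p = ncol(x)),
            class = "mewma_model")
}

#' MEWMA T-squared statistics
#'
#' Applies the multivariate EWMA recursion `Z_i = lam * (X_i - center) +
#' (1 - lam) * Z_{i-1}` with `Z_0 = 0` and returns
#' `T2_i = Z_i' SZ^{-1} Z_i`. In `"single"` mode (the default) every row
#' is monitored independently with its own one-step recursion, matching a
#' chart queried with one incoming observation per sample interval; in
#' `"sequence"` mode the recursion runs down the rows in order.
#'
#' @param model A [mewma_model()].
#' @param x Matrix/data frame of observations (rows) or a single vector.
#' @param mode `"single"` or `"sequence"`.
#' @return Numeric vector of T-squared values, one per row.
#' @export
mewma_t2 <- function(model, x, mode = c("single", "sequence")) {
  mode <- match.arg(mode)
  abort_if(!inherits(model, "mewma_model"), "`model` must be a mewma_model")
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as_feature_matrix_input(x)
  abort_if(ncol(x) != model$p, "dimension mismatch with the MEWMA model")
  ev <- eigen(model$SZ, symmetric = TRUE, only.values = TRUE)$values
  abort_if(min(ev) <= 1e-12, "singular smoothed covariance SZ")
  dev <- sweep(x, 2, model$center)
  if (mode == "single") {
    z <- model$lam * dev
    return(as.numeric(stats::mahalanobis(z, rep(0, model$p), model$SZ)))
  }
  zi <- rep(0, model$p)
  szi <- solve(model$SZ)
  out <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    zi <- model$lam * dev[i, ] + (1 - model$lam) * zi
    out[i] <- drop(zi %*% szi %*% zi)
  }
  out
}

#' Bootstrap control-limit percentile of in-control statistics
#'
#' Mean over `B` bootstrap resamples of the empirical `1 - alpha` quantile
#' of the in-control T-squared statistics.
#'
#' @param ic_t2 In-control T-squared sample (length >= 50).
#' @param alpha Type-I error rate.
#' @param B Number of bootstrap resamples (>= 1).
#' @param seed Integer seed.
#' @return The bootstrap percentile `BD` (a single number).
#' @export
bootstrap_bd <- function(ic_t2, alpha = 0.05, B = 1000L, seed = NULL) {
  abort_if(length(ic_t2) < 50L, "need at least 50 in-control statistics")
  abort_if(B < 1L, "`B` must be at least 1")
  check_number(alpha, "alpha", lower = 0, upper = 1,
               closed_lower = FALSE, closed_upper = FALSE)
  with_seed_or_not(seed, {
    mean(vapply(seq_len(B), function(b) {
      stats::quantile(sample(ic_t2, replace = TRUE), 1 - alpha, names = FALSE)
    }, numeric(1)))
  })
}

#' Chart probability of openness from a MEWMA statistic
#'
#' Maps the MEWMA T-squared statistic onto (0, 1) through
#' `sigmoid((t2 - bd) / bd)`, where `bd` is the bootstrap in-control
#' percentile: the probability that the observation belongs to the open
#' (out-of-control) class. Equals 0.5 exactly at `t2 = bd` and is strictly
#' increasing in `t2`.
#'
#' @param t2 T-squared value(s).
#' @param bd Bootstrap control percentile (> 0) from [bootstrap_bd()].
#' @return Probabilities in (0, 1).
#' @export
prob_t2 <- function(t2, bd) {
  check_number(bd, "bd", lower = 0, closed_lower = FALSE)
  abort_if(any(t2 < 0), "T-squared values must be nonnegative")
  sigmoid((t2 - bd) / bd)
}
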