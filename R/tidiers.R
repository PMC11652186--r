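# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.mrcd <- function(x, ...) {
  tibble::tibble(variable = names(x$location) %||%
                   paste0("x", seq_along(x$location)),
                 location = as.numeric(x$location),
                 scale = sqrt(diag(x$scatter)))
}

#' @exportS3Method generics::glance
glance.mrcd <- function(x, ...) {
  ev <- eigen(x$scatter, symmetric = TRUE, only.values = TRUE)$values
  tibble::tibble(n = x$n, p = x$p, h = x$h, rho = x$rho,
                 objective = x$objective, condition = ev[1] / ev[x$p])
}

#' @exportS3Method generics::glance
glance.chart_calibration <- function(x, ...) {
  tibble::tibble(d_hat = x$d_hat, q_hat = x$q_hat, ucl = x$ucl,
                 alpha = x$alpha, p = x$p, n = x$n, n_mc = x$n_mc,
                 mc_mean = x$mc_mean, mc_var = x$mc_var, robust = x$robust)
}

#' @exportS3Method generics::tidy
tidy.confident_joint <- function(x, ...) {
  k <- ncol(x$counts)
  tidyr::expand_grid(observed = 0:(k - 1L), predicted = 0:(k - 1L)) |>
    dplyr::mutate(count = as.integer(t(x$counts))[
      .data$observed * k + .data$predicted + 1L])
}

#' @exportS3Method generics::glance
glance.confident_joint <- function(x, ...) {
  tibble::tibble(n_assigned = sum(x$counts),
                 noise_estimate = x$noise_estimate)
}

#' @exportS3Method generics::glance
glance.sensitized_chart <- function(x, ...) {
  tibble::tibble(eta = x$eta, bd = x$bd, cl = x$cl %||% NA_real_,
                 cl_adjusted = x$cl_adjusted %||% NA_real_,
                 alpha = x$alpha %||% NA_real_, tau = x$tau %||% NA_real_)
}

#' @exportS3Method generics::tidy
tidy.ocr_pipeline <- function(x, ...) {
  dplyr::select(x$test, -dplyr::any_of("features"))
}

#' @exportS3Method generics::glance
glance.ocr_pipeline <- function(x, ...) {
  dplyr::bind_cols(
    x$metrics[x$metrics$stage == "final",
              c("acc", "rec", "pre", "f1", "balanced_acc", "auc", "aupr")],
    tibble::tibble(n_filtered = x$n_filtered, n_pruned = x$n_pruned,
                   ucl = x$calibration$ucl, cl = x$chart$cl_adjusted,
                   seed = x$config$seed))
}
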