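#' Classifier confidence
#'
#' `delta = 2 * |pc - 0.5|`: how decisive the classifier is about an
#' observation. Zero at maximal uncertainty (`pc = 0.5`), one at either
#' extreme; gates the weight the chart probability receives in the
#' sensitized statistic.
#'
#' @param pc Classifier probabilities in `[0, 1]`.
#' @return Values in `[0, 1]`.
#' @export
confidence_delta <- function(pc) {
  abort_if(any(pc < 0 | pc > 1), "`pc` must lie in [0, 1]")
  2 * abs(pc - 0.5)
}

#' Sensitized T-squared statistic
#'
#' Fuses the chart probability `pt2` (from the MEWMA transform) and the
#' classifier probability `pc` into
#' `ST2 = eta * delta * pt2 + (1 - eta * delta) * pc`, with
#' `delta = 2 |pc - 0.5|`. When the classifier is uncertain the chart gets
#' no weight and `ST2 = pc`; when both probabilities agree the statistic
#' equals their common value.
#'
#' @param pt2 Chart probability in (0, 1) from [prob_t2()].
#' @param pc Classifier probability in `[0, 1]`.
#' @param eta Chart weight in (0, 1], default 0.3. Values >= 0.7 trigger a
#'   warning: at that weight the statistic of partially open regions is
#'   pulled below the control limit and the three-class bands collapse.
#' @return ST-squared values in `[0, 1]`.
#' @export
sensitized_statistic <- function(pt2, pc, eta = 0.3) {
  check_eta(eta)
  abort_if(any(pt2 < 0 | pt2 > 1), "`pt2` must lie in [0, 1]")
  d <- confidence_delta(pc)
  eta * d * pt2 + (1 - eta * d) * pc
}

check_eta <- function(eta) {
  check_number(eta, "eta", lower = 0, upper = 1, closed_lower = FALSE)
  if (eta >= 0.7) {
    rlang::warn(paste("eta >= 0.7 suppresses the partially-open band and",
                      "leads to inaccurate three-class calls; use eta <= 0.6"),
                class = "ocrchart_eta_warning")
  }
  invisible(eta)
}

#' Construct a sensitized T-squared chart
#'
#' Bundles the fitted MEWMA model, its bootstrap percentile `bd`, the
#' trained classifier and the chart weight `eta`. The chart must be
#' calibrated with [calibrate_cl()] before regions can be classified.
#'
#' @param mewma A [mewma_model()].
#' @param bd Bootstrap in-control percentile from [bootstrap_bd()].
#' @param classifier An [train_classifier()] fit.
#' @param eta Chart weight in (0, 1], default 0.3.
#' @return An object of class `sensitized_chart`.
#' @export
sensitized_chart <- function(mewma, bd, classifier, eta = 0.3) {
  check_eta(eta)
  check_number(bd, "bd", lower = 0, closed_lower = FALSE)
  structure(list(mewma = mewma, bd = bd, classifier = classifier,
                 eta = eta, cl = NULL, cl_adjusted = NULL, alpha = NULL,
                 tau = NULL),
            class = "sensitized_chart")
}

#' Bootstrap control limit of the sensitized chart
#'
#' `cl` is the bootstrap mean of the `1 - alpha` empirical quantile of the
#' in-control ST-squared values; `cl_adjusted = cl * tau` applies the
#' mixture-ratio fine-tuning that sharpens the partially-open band (the
#' unadjusted limit is used when `tau` is `NULL`). Errors if the adjusted
#' limit leaves no room for the partially-open band
#' (`cl_adjusted >= 1 - eta`).
#'
#' @param ic_st2 In-control ST-squared values (length >= 50).
#' @param chart A [sensitized_chart()].
#' @param alpha Type-I error rate, default 0.05.
#' @param B Bootstrap resamples.
#' @param tau Mixture ratio used to scale the limit, or `NULL`.
#' @param seed Integer seed.
#' @return The chart with `cl`, `cl_adjusted`, `alpha`, `tau` filled in.
#' @export
calibrate_cl <- function(ic_st2, chart, alpha = 0.05, B = 1000L, tau = NULL,
                         seed = NULL) {
  abort_if(!inherits(chart, "sensitized_chart"), "`chart` must be a sensitized_chart")
  if (!is.null(tau)) check_number(tau, "tau", lower = 0, upper = 1,
                                  closed_lower = FALSE)
  cl <- bootstrap_bd(ic_st2, alpha = alpha, B = B, seed = seed)
  cl_adjusted <- if (is.null(tau)) cl else cl * tau
  abort_if(cl_adjusted >= 1 - chart$eta,
           sprintf(paste0("adjusted control limit %.3f >= 1 - eta = %.3f: ",
                          "the partially-open band is empty"),
                   cl_adjusted, 1 - chart$eta))
  chart$cl <- cl
  chart$cl_adjusted <- cl_adjusted
  chart$alpha <- alpha
  chart$tau <- tau
  chart
}

#' Three-class decision rule of the sensitized chart
#'
#' Maps ST-squared onto the three chromatin states by its band:
#' closed (0) for `ST2` in `[0, CL]`, partially open (2) for
#' `(CL, 1 - eta]`, open (1) for `(1 - eta, 1]`, with `CL` the adjusted
#' control limit.
#'
#' @param st2 ST-squared values in `[0, 1]`.
#' @param chart A calibrated [sensitized_chart()].
#' @return Integer labels: 0 = closed, 1 = open, 2 = partially open.
#' @export
classify_region <- function(st2, chart) {
  abort_if(is.null(chart$cl_adjusted), "chart is not calibrated; run calibrate_cl()")
  abort_if(any(st2 < 0 | st2 > 1), "ST-squared values must lie in [0, 1]")
  ifelse(st2 <= chart$cl_adjusted, 0L,
         ifelse(st2 <= 1 - chart$eta, 2L, 1L))
}

#' Score and classify samples with the sensitized chart
#'
#' Pipe-friendly wrapper: computes the MEWMA statistic and its probability
#' transform, the classifier probability, the confidence gate and the
#' fused ST-squared for every row, and (if the chart is calibrated) the
#' three-class label.
#'
#' @param data Tibble with the chart's feature columns (`sd_wps`,
#'   `sd_coverage` by default, via the classifier's `feature_cols`).
#' @param chart A [sensitized_chart()].
#' @return `data` with columns `t2`, `pt2`, `pc`, `delta`, `st2` and
#'   (when calibrated) `label` appended.
#' @export
chart_augment <- function(data, chart) {
  abort_if(!inherits(chart, "sensitized_chart"), "`chart` must be a sensitized_chart")
  x <- dataset_features(data, chart$classifier$feature_cols)
  t2 <- mewma_t2(chart$mewma, x)
  pt2 <- prob_t2(t2, chart$bd)
  pc <- prob_classifier(chart$classifier, x)$pc
  out <- dplyr::mutate(data, t2 = t2, pt2 = pt2, pc = pc,
                       delta = confidence_delta(pc),
                       st2 = sensitized_statistic(pt2, pc, chart$eta))
  if (!is.null(chart$cl_adjusted)) {
    out <- dplyr::mutate(out, label = classify_region(.data$st2, chart))
  }
  out
}

#' @export
print.sensitized_chart <- function(x, ...) {
  cat(sprintf("Sensitized T2 chart: eta = %g, bd = %.4f", x$eta, x$bd))
  if (!is.null(x$cl)) {
    cat(sprintf(", CL = %.4f (adjusted %.4f)", x$cl, x$cl_adjusted))
  }
  cat("\n")
  invisible(x)
}
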