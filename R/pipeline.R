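#' Pipeline configuration
#'
#' All tunable parameters of the three-stage pipeline, with the standard
#' working values: 20-kbp segments tiled by 200-bp windows, a 120-bp WPS
#' window, significance level 0.05 for both charts, MEWMA smoothing 0.2,
#' chart weight `eta = 0.3`, composite rate `tau = 0.7`, 1000 bootstrap
#' resamples and 1000 Monte-Carlo calibration replicates, and a 400
#' open / 1000 closed training split. Every source of randomness derives
#' from the single root `seed`.
#'
#' @param segment_bp,window_bp,wps_w Segment, tiling-window and WPS
#'   window sizes in bp.
#' @param alpha Significance level for control limits.
#' @param lam MEWMA smoothing weight.
#' @param eta Sensitized-chart weight; >= 0.7 warns (band collapse).
#' @param tau Composite rate for partially open features and the
#'   control-limit adjustment.
#' @param B Bootstrap resamples for percentile limits.
#' @param n_mc Monte-Carlo replicates for the robust-chart limit.
#' @param noise_rate Label-noise fraction injected into the training set.
#' @param n_ocr,n_ccr Open/closed training sample counts.
#' @param n_test_per_class Held-out evaluation samples per class.
#' @param n_mrcd_rows Window observations (rows) used for the MRCD fit.
#' @param candidate_bp Width in bp of the labeled candidate region at the
#'   centre of each training segment (the region whose label is kept or
#'   dropped by chart-call overlap).
#' @param sim A [sim_params()] object.
#' @param classifier A [classifier_config()].
#' @param balance Balance the filtered training classes by downsampling.
#' @param seed Root seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(segment_bp = 20000L, window_bp = 200L,
                            wps_w = 120L, alpha = 0.05, lam = 0.2,
                            eta = 0.3, tau = 0.7, B = 1000L, n_mc = 1000L,
                            noise_rate = 0.2, n_ocr = 400L, n_ccr = 1000L,
                            n_test_per_class = 100L, n_mrcd_rows = 1000L,
                            candidate_bp = 2000L,
                            sim = sim_params(), classifier = classifier_config(),
                            balance = FALSE, seed = 1L) {
  check_eta(eta)
  check_number(tau, "tau", lower = 0, upper = 1, closed_lower = FALSE)
  check_number(alpha, "alpha", lower = 0, upper = 1,
               closed_lower = FALSE, closed_upper = FALSE)
  check_number(lam, "lam", lower = 0, upper = 1, closed_lower = FALSE)
  structure(list(segment_bp = as.integer(segment_bp),
                 window_bp = as.integer(window_bp), wps_w = as.integer(wps_w),
                 alpha = alpha, lam = lam, eta = eta, tau = tau,
                 B = as.integer(B), n_mc = as.integer(n_mc),
                 noise_rate = noise_rate, n_ocr = as.integer(n_ocr),
                 n_ccr = as.integer(n_ccr),
                 n_test_per_class = as.integer(n_test_per_class),
                 n_mrcd_rows = as.integer(n_mrcd_rows),
                 candidate_bp = as.integer(candidate_bp),
                 sim = sim, classifier = classifier, balance = balance,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as JSON
#'
#' The round trip is lossless; nested [sim_params()] and
#' [classifier_config()] objects are restored with their classes.
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `path` / the restored `pipeline_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass_deep(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$sim <- do.call(sim_params, raw$sim)
  cls <- raw$classifier
  raw$classifier <- do.call(classifier_config, cls)
  do.call(pipeline_config, raw)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(sprintf("pipeline stage '%s' failed: %s", name,
                         conditionMessage(e)),
                 class = "ocrchart_stage_error", parent = e)
  })
}

#' Run the full three-stage pipeline on synthetic data
#'
#' Executes, in order: (1) synthetic training-set generation and
#' robust-chart filtering — an MRCD Hotelling T-squared chart with a
#' Monte-Carlo F control limit scores every 200-bp window, the run rules
#' call open regions, and training candidates whose noisy binary label
#' contradicts the calls are dropped; (2) sensitized-chart construction —
#' a MEWMA model and bootstrap percentile on the filtered closed samples,
#' the noise-tolerant classifier on the filtered binary labels, fusion
#' into ST-squared, bootstrap control limit with mixture-ratio
#' adjustment, and three-class relabeling of the filtered samples plus
#' simulated partially open composites; (3) confident-learning pruning
#' and co-teaching on the chart labels. A fresh labeled test set is
#' generated and scored by both the chart alone and the final co-taught
#' pair.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, calls (BED), labels
#'   (TSV), metrics and calibrations (JSON) and the config are written
#'   there.
#' @return An object of class `ocr_pipeline` (a list of stage artifacts;
#'   see `$metrics` for the chart-only and final test metrics).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  abort_if(!inherits(config, "pipeline_config"),
           "`config` must come from pipeline_config()")
  s <- config$seed

  train <- stage("simulate", {
    make_dataset(tau = config$tau, noise_rate = config$noise_rate,
                 params = config$sim, seed = derive_seed(s, 1L),
                 n_ocr = config$n_ocr, n_ccr = config$n_ccr, n_pocr = 0L,
                 segment_bp = config$segment_bp, window_bp = config$window_bp,
                 wps_w = config$wps_w)
  })

  robust <- stage("robust_chart", {
    ic_rows <- do.call(rbind, lapply(
      train$features[train$observed_label == 0L], feature_matrix))
    if (nrow(ic_rows) > config$n_mrcd_rows) {
      keep <- with_seed_or_not(derive_seed(s, 2L),
                               sort(sample(nrow(ic_rows), config$n_mrcd_rows)))
      ic_rows <- ic_rows[keep, , drop = FALSE]
    }
    mrcd <- fit_mrcd(ic_rows)
    calib <- calibrate_limits(p = 4L, n = nrow(ic_rows), alpha = config$alpha,
                              n_mc = config$n_mc, seed = derive_seed(s, 3L))
    calls <- purrr::imap_dfr(train$features, function(fw, i) {
      cc <- apply_run_rules(t2_statistic(mrcd, feature_matrix(fw)),
                            calib$ucl, window_bp = config$window_bp)
      if (nrow(cc) > 0L) {
        cc$chrom <- as.character(train$sample_id[i])
        cc$start <- cc$start + train$start[i]
        cc$end <- cc$end + train$start[i]
      }
      cc
    })
    list(mrcd = mrcd, calib = calib, calls = calls)
  })

  filtered <- stage("filter_train", {
    # The labeled candidate is a central sub-region of its monitored
    # segment (a gene/TSS-scale region inside a 20-kbp interval).
    margin <- (config$segment_bp - config$candidate_bp) %/% 2L
    cand <- dplyr::mutate(train, chrom = as.character(.data$sample_id),
                          start = .data$start + margin,
                          end = .data$end - margin)
    out <- filter_training_set(cand, robust$calls, balance = config$balance,
                               seed = derive_seed(s, 4L))
    out$start <- out$start - margin
    out$end <- out$end + margin
    out
  })

  chart <- stage("sensitized_chart", {
    ic <- dplyr::filter(filtered, .data$observed_label == 0L)
    abort_if(nrow(ic) < 50L, "too few filtered closed samples")
    clf <- train_classifier(filtered, config = config$classifier,
                            seed = derive_seed(s, 5L))
    mw <- mewma_model(ic[, c("sd_wps", "sd_coverage")], lam = config$lam)
    ic_t2 <- mewma_t2(mw, as.matrix(ic[, c("sd_wps", "sd_coverage")]))
    bd <- bootstrap_bd(ic_t2, alpha = config$alpha, B = config$B,
                       seed = derive_seed(s, 6L))
    ch <- sensitized_chart(mw, bd, clf, eta = config$eta)
    ic_st2 <- chart_augment(ic, ch)$st2
    calibrate_cl(ic_st2, ch, alpha = config$alpha, B = config$B,
                 tau = config$tau, seed = derive_seed(s, 7L))
  })

  relabeled <- stage("relabel", {
    n_pocr <- max(10L, nrow(filtered) %/% 3L)
    pocr <- make_dataset(tau = config$tau, noise_rate = 0,
                         params = config$sim, seed = derive_seed(s, 8L),
                         n_ocr = 0L, n_ccr = 0L, n_pocr = n_pocr,
                         segment_bp = config$segment_bp,
                         window_bp = config$window_bp, wps_w = config$wps_w)
    pool <- dplyr::bind_rows(
      dplyr::select(filtered, dplyr::all_of(c("true_class", "observed_label",
                                              "sd_wps", "sd_coverage"))),
      dplyr::select(pocr, dplyr::all_of(c("true_class", "observed_label",
                                          "sd_wps", "sd_coverage"))))
    chart_augment(pool, chart)
  })

  refined <- stage("confident_learning", {
    # The refinement model sees the summary features plus the chart's
    # fused statistic, mirroring a final model consuming both raw
    # features and the chart's evidence.
    feat3 <- c("sd_wps", "sd_coverage", "st2")
    probs <- cv_probabilities(as.matrix(relabeled[, feat3]),
                              relabeled$label, k = 3L,
                              config = config$classifier,
                              seed = derive_seed(s, 9L))
    joint <- estimate_confident_joint(probs, relabeled$label)
    pruned <- prune_and_reweight(relabeled, joint, label_col = "label")
    # pruning removes the detected label errors; the co-teaching
    # schedule only needs to forget the small undetected remainder
    # (unassigned samples that would have landed off-diagonal)
    unassigned <- setdiff(seq_len(nrow(relabeled)), joint$assigned)
    resid_noise <- max(0.05, joint$noise_estimate *
                         length(unassigned) / max(1L, nrow(relabeled)))
    ct_cfg <- config$classifier
    if (identical(ct_cfg$architecture, "gaussian")) {
      ct_cfg$architecture <- "linear"   # co-teaching trains peer networks
    }
    fit <- coteach_train(pruned$data, config = ct_cfg,
                         seed = derive_seed(s, 10L), weight_col = ".weight",
                         feature_cols = feat3, noise_estimate = resid_noise)
    list(joint = joint, pruned = pruned, fit = fit)
  })

  evaluation <- stage("evaluate", {
    test <- make_dataset(n_per_class = config$n_test_per_class,
                         tau = config$tau, noise_rate = 0,
                         params = config$sim, seed = derive_seed(s, 11L),
                         segment_bp = config$segment_bp,
                         window_bp = config$window_bp, wps_w = config$wps_w)
    scored <- chart_augment(test, chart)
    probs <- coteach_probs(refined$fit, scored)
    scored$final_label <- max.col(probs, ties.method = "first") - 1L
    metrics <- dplyr::bind_rows(
      dplyr::mutate(compute_metrics(scored$true_class, scored$label),
                    stage = "chart", .before = 1L),
      dplyr::mutate(compute_metrics(scored$true_class, scored$final_label,
                                    scores = probs),
                    stage = "final", .before = 1L))
    list(test = scored, probs = probs, metrics = metrics)
  })

  result <- structure(
    list(config = config, mrcd = robust$mrcd, calibration = robust$calib,
         calls = robust$calls, n_filtered = nrow(filtered),
         n_removed = attr(filtered, "n_removed"), chart = chart,
         joint = refined$joint, n_pruned = nrow(refined$pruned$pruned),
         coteach = refined$fit, test = evaluation$test,
         metrics = evaluation$metrics),
    class = "ocr_pipeline")
  if (!is.null(out_dir)) write_pipeline(result, out_dir)
  result
}

write_pipeline <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  write_config(cfg, file.path(out_dir, "config.json"))
  calls <- result$calls
  if (nrow(calls) > 0L) {
    utils::write.table(
      data.frame(calls$chrom, calls$start, calls$end, calls$rules),
      file.path(out_dir, "calls.bed"), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  } else {
    file.create(file.path(out_dir, "calls.bed"))
  }
  cal <- result$calibration
  jsonlite::write_json(
    list(d_hat = cal$d_hat, q_hat = cal$q_hat, ucl = cal$ucl,
         alpha = cal$alpha, seed = cal$seed,
         cl = result$chart$cl, cl_adjusted = result$chart$cl_adjusted,
         bd = result$chart$bd, eta = result$chart$eta),
    file.path(out_dir, "calibration.json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(
    dplyr::select(result$test, -dplyr::any_of("features")),
    file.path(out_dir, "labels.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  jsonlite::write_json(as.list(result$metrics[result$metrics$stage == "final",
                                              c("acc", "rec", "pre", "f1",
                                                "balanced_acc", "auc", "aupr")]),
                       file.path(out_dir, "metrics.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(out_dir)
}

#' @export
print.ocr_pipeline <- function(x, ...) {
  cat(sprintf("Chromatin-state pipeline (seed %d)\n", x$config$seed))
  cat(sprintf("  training samples kept after chart filtering: %d (%d removed)\n",
              x$n_filtered, x$n_removed))
  cat(sprintf("  pruned by confident learning: %d\n", x$n_pruned))
  print(as.data.frame(x$metrics), digits = 3, row.names = FALSE)
  invisible(x)
}
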