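#' Monte-Carlo moment-matched F control limit for the T-squared chart
#'
#' The out-of-sample distribution of the (robust) Hotelling T-squared
#' statistic is approximated by a `d`-scaled F(p, q) distribution. `n_mc`
#' clean p-variate standard-normal datasets of size `n` are simulated; on
#' each, the in-control model is fitted (MRCD by default, classical
#' optionally) and T-squared values of fresh out-of-sample observations
#' are pooled. The empirical mean `m` and variance `v` are matched to
#' `E[T2] = d q / (q - 2)` and `Var[T2] = 2 d^2 q^2 (p + q - 2) /
#' (p (q - 4) (q - 2)^2)`, which solve to
#' `q = (2 m^2 p - 4 m^2 + 4 v p) / (v p - 2 m^2)` and
#' `d = m (q - 2) / q`. The upper control limit is
#' `UCL = d * F_{1 - alpha}(p, q)`.
#'
#' @param p Number of monitored variables.
#' @param n In-control sample size per simulated dataset.
#' @param alpha Significance level (default 0.05).
#' @param n_mc Number of Monte-Carlo replicates (>= 200).
#' @param seed Integer seed (mandatory for reproducibility).
#' @param robust Fit MRCD (`TRUE`, default) or the classical mean/cov.
#' @param alpha_trim Trimming fraction passed to [fit_mrcd()].
#' @param n_eval Fresh out-of-sample observations per replicate.
#'
#' @return An object of class `chart_calibration` with `d_hat`, `q_hat`,
#'   `ucl`, `alpha`, `p`, `n`, `n_mc`, `seed`, `mc_mean`, `mc_var`.
#' @export
calibrate_limits <- function(p, n, alpha = 0.05, n_mc = 1000L, seed = 1L,
                             robust = TRUE, alpha_trim = 0.25, n_eval = 20L) {
  abort_if(n_mc < 200L, "`n_mc` must be at least 200")
  check_number(alpha, "alpha", lower = 0, upper = 1,
               closed_lower = FALSE, closed_upper = FALSE)
  abort_if(n <= p, "need n > p")

  t2s <- with_seed_or_not(seed, {
    unlist(lapply(seq_len(n_mc), function(i) {
      x <- matrix(stats::rnorm(n * p), n, p)
      model <- if (robust) fit_mrcd(x, alpha_trim = alpha_trim)
               else classical_model(x)
      xnew <- matrix(stats::rnorm(n_eval * p), n_eval, p)
      t2_statistic(model, xnew)
    }))
  })
  m <- mean(t2s)
  v <- stats::var(t2s)
  # The scaled-F family has Var >= 2 m^2 / p, attained in the q -> Inf
  # (scaled chi-square) limit. A pooled variance at or slightly below that
  # floor maps to the limiting member; far below it no member matches.
  v_floor <- 2 * m^2 / p
  abort_if(v < 0.9 * v_floor,
           sprintf(paste0("moment matching failed: pooled variance %.4f is ",
                          "below the scaled-F family floor 2 m^2 / p = %.4f ",
                          "(mean %.4f)"), v, v_floor, m))
  denom <- v * p - 2 * m^2
  if (denom <= 0) {
    q_hat <- Inf
    d_hat <- m
    ucl <- m * stats::qchisq(1 - alpha, p) / p
  } else {
    q_hat <- (2 * m^2 * p - 4 * m^2 + 4 * v * p) / denom
    abort_if(q_hat <= 4,
             sprintf("moment matching failed: matched q = %.3f <= 4", q_hat))
    d_hat <- m * (q_hat - 2) / q_hat
    ucl <- d_hat * stats::qf(1 - alpha, p, q_hat)
  }
  structure(list(d_hat = d_hat, q_hat = q_hat, ucl = ucl,
                 alpha = alpha, p = p, n = n, n_mc = n_mc, seed = seed,
                 robust = robust, mc_mean = m, mc_var = v),
            class = "chart_calibration")
}

#' @export
print.chart_calibration <- function(x, ...) {
  cat(sprintf("T2 chart calibration (%s): p = %d, n = %d, n_mc = %d\n",
              if (x$robust) "MRCD" else "classical", x$p, x$n, x$n_mc))
  cat(sprintf("  d_hat = %.4f, q_hat = %.2f, UCL(alpha = %g) = %.4f\n",
              x$d_hat, x$q_hat, x$alpha, x$ucl))
  invisible(x)
}

runs_of_exceedance <- function(exceed) {
  r <- rle(exceed)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  data.frame(start = starts[idx], end = ends[idx])
}

#' Apply the genomic run rules to a T-squared sequence
#'
#' Upgrades single control-limit exceedances to open-region calls using
#' three run rules on the windowed statistic sequence of one monitored
#' segment:
#'
#' 1. three or more consecutive windows above the control limit;
#' 2. the first or last window above the limit (a region possibly spanning
#'    two segments) — called together with its two inward neighbours,
#'    600 bp at the default 200-bp window;
#' 3. two exceedance runs separated by fewer than three sub-limit windows
#'    are merged into one call (the intervening windows included).
#'
#' Overlapping calls are merged and annotated with all contributing rules.
#'
#' @param stats Numeric vector of T-squared values, one per window, in
#'   genomic order.
#' @param ucl Upper control limit.
#' @param window_bp Window width in bp (default 200).
#'
#' @return A tibble with one row per call: `start_window`, `end_window`
#'   (0-based, inclusive), `start`, `end` (bp, half-open), `width_bp`,
#'   `n_windows`, `rules` (comma-separated rule ids).
#' @export
apply_run_rules <- function(stats, ucl, window_bp = 200L) {
  abort_if(length(stats) == 0L, "`stats` must be non-empty")
  check_number(ucl, "ucl", lower = 0)
  nw <- length(stats)
  exceed <- stats > ucl
  empty <- tibble::tibble(start_window = integer(), end_window = integer(),
                          start = integer(), end = integer(),
                          width_bp = integer(), n_windows = integer(),
                          rules = character())
  calls <- list()

  runs <- runs_of_exceedance(exceed)
  if (nrow(runs) > 0L) {
    # Group runs whose gaps are < 3 sub-limit windows (rule 3).
    grp <- cumsum(c(1L, as.integer(
      runs$start[-1L] - runs$end[-nrow(runs)] - 1L >= 3L)))
    for (g in unique(grp)) {
      rr <- runs[grp == g, , drop = FALSE]
      rules <- character()
      if (any(rr$end - rr$start + 1L >= 3L)) rules <- c(rules, "1")
      if (nrow(rr) >= 2L) rules <- c(rules, "3")
      if (length(rules) > 0L) {
        calls[[length(calls) + 1L]] <-
          c(start = min(rr$start), end = max(rr$end), rules = list(rules))
      }
    }
  }
  if (exceed[1L]) {
    calls[[length(calls) + 1L]] <-
      c(start = 1L, end = min(3L, nw), rules = list("2"))
  }
  if (exceed[nw]) {
    calls[[length(calls) + 1L]] <-
      c(start = max(1L, nw - 2L), end = nw, rules = list("2"))
  }
  if (length(calls) == 0L) return(empty)

  df <- tibble::tibble(
    start = vapply(calls, function(cl) as.integer(cl$start), integer(1)),
    end = vapply(calls, function(cl) as.integer(cl$end), integer(1)),
    rules = lapply(calls, function(cl) cl$rules))
  df <- df[order(df$start, df$end), ]

  # Merge overlapping calls, unioning rule ids.
  merged <- list(df[1L, ])
  if (nrow(df) > 1L) for (i in 2L:nrow(df)) {
    last <- merged[[length(merged)]]
    if (df$start[i] <= last$end) {
      last$end <- max(last$end, df$end[i])
      last$rules <- list(union(last$rules[[1L]], df$rules[[i]][[1L]]))
      merged[[length(merged)]] <- last
    } else {
      merged[[length(merged) + 1L]] <- df[i, ]
    }
  }
  out <- dplyr::bind_rows(merged)
  tibble::tibble(
    start_window = out$start - 1L,
    end_window = out$end - 1L,
    start = (out$start - 1L) * as.integer(window_bp),
    end = out$end * as.integer(window_bp),
    width_bp = (out$end - out$start + 1L) * as.integer(window_bp),
    n_windows = out$end - out$start + 1L,
    rules = vapply(out$rules, function(r) paste(sort(r), collapse = ","),
                   character(1)))
}

#' Filter a noisy binary training set by chart calls
#'
#' Keeps an open-labeled candidate iff it overlaps (>= 1 bp, half-open
#' coordinates) any called open region on its chromosome, and a
#' closed-labeled candidate iff it overlaps none: candidates whose label
#' contradicts the chart are treated as noise and dropped.
#'
#' @param candidates Tibble with `chrom`, `start`, `end` (0-based
#'   half-open) and `observed_label` (1 = open, 0 = closed).
#' @param calls Tibble of called regions with `chrom`, `start`, `end`.
#' @param balance If `TRUE`, downsample the majority retained class to the
#'   minority size.
#' @param seed Seed used when `balance = TRUE`.
#'
#' @return The retained rows of `candidates`, with attribute `n_removed`.
#' @export
filter_training_set <- function(candidates, calls, balance = FALSE,
                                seed = NULL) {
  abort_if(!all(c("chrom", "start", "end", "observed_label") %in%
                  names(candidates)),
           "`candidates` needs chrom/start/end/observed_label")
  hit <- logical(nrow(candidates))
  if (nrow(calls) > 0L) {
    for (ch in unique(candidates$chrom)) {
      ci <- which(candidates$chrom == ch)
      ki <- which(calls$chrom == ch)
      if (length(ki) == 0L) next
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(candidates$start[ci] + 1L, candidates$end[ci]),
        IRanges::IRanges(calls$start[ki] + 1L, calls$end[ki]))
      hit[ci[unique(S4Vectors::queryHits(ov))]] <- TRUE
    }
  }
  keep <- ifelse(candidates$observed_label == 1L, hit, !hit)
  out <- candidates[keep, , drop = FALSE]
  if (balance && nrow(out) > 0L) {
    tab <- table(factor(out$observed_label, levels = 0:1))
    nmin <- min(tab)
    out <- with_seed_or_not(seed, {
      idx <- unlist(lapply(0:1, function(lb) {
        w <- which(out$observed_label == lb)
        if (length(w) > nmin) sort(sample(w, nmin)) else w
      }))
      out[sort(idx), , drop = FALSE]
    })
  }
  attr(out, "n_removed") <- nrow(candidates) - sum(keep)
  out
}
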