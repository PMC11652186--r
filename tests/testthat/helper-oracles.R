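# Brute-force oracles and small fixtures, independent of the package's
# implementation paths.

# O(n * L) per-base membership count.
brute_coverage <- function(frags, L) {
  cov <- numeric(L)
  for (i in seq_len(nrow(frags))) {
    s <- frags$start[i]; e <- frags$end[i]
    idx <- seq.int(max(s, 0L), min(e, L) - 1L)
    cov[idx + 1L] <- cov[idx + 1L] + 1
  }
  cov
}

# Direct application of the span/endpoint WPS definition at each base.
brute_wps <- function(frags, L, w) {
  half <- w / 2
  out <- numeric(L)
  for (i in 0:(L - 1L)) {
    lo <- i - half; hi <- i + half  # window [lo, hi)
    span <- sum(frags$start <= lo & frags$end >= hi)
    endpt <- sum((frags$start >= lo & frags$start < hi) |
                   (frags$end - 1L >= lo & frags$end - 1L < hi))
    out[i + 1L] <- span - endpt
  }
  out
}

brute_ends <- function(frags, L) {
  uend <- numeric(L); dend <- numeric(L)
  for (i in seq_len(nrow(frags))) {
    uend[frags$start[i] + 1L] <- uend[frags$start[i] + 1L] + 1
    dend[frags$end[i]] <- dend[frags$end[i]] + 1
  }
  list(uend = uend, dend = dend)
}

random_fragments <- function(n, L, seed, min_len = 2L, max_len = 60L) {
  withr::with_seed(seed, {
    len <- sample(min_len:max_len, n, replace = TRUE)
    start <- sample(0:(L - max_len - 1L), n, replace = TRUE)
    tibble::tibble(chrom = "t", start = start, end = start + len)
  })
}

# Two well-separated Gaussian classes in 2-d for classifier tests.
toy_two_class <- function(n_per, seed, gap = 6) {
  withr::with_seed(seed, {
    x <- rbind(matrix(stats::rnorm(n_per * 2), n_per, 2),
               matrix(stats::rnorm(n_per * 2, mean = gap), n_per, 2))
    tibble::tibble(sd_wps = x[, 1], sd_coverage = x[, 2],
                   observed_label = rep(0:1, each = n_per))
  })
}

# Three ordered Gaussian classes in 2-d (closed / partial / open layout).
toy_three_class <- function(n_per, seed, centers = c(0, 4, 8), sd = 1) {
  withr::with_seed(seed, {
    lab <- rep(0:2, each = n_per)
    mu <- centers[lab + 1L]
    tibble::tibble(sd_wps = stats::rnorm(3 * n_per, mu, sd),
                   sd_coverage = stats::rnorm(3 * n_per, mu, sd),
                   label = lab)
  })
}

flip_fraction <- function(labels, noise, seed) {
  withr::with_seed(seed, {
    flip <- stats::runif(length(labels)) < noise
    ifelse(flip, 1L - labels, labels)
  })
}

fast_params <- function(...) sim_params(...)

featurize_bundle <- function(frags, window_bp = 200L, wps_w = 120L) {
  window_average(compute_tracks(frags, wps_w = wps_w), window_bp = window_bp)
}
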