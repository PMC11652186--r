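test_that("fragment simulation is seeded, bounded and state-aware", {
  p <- sim_params()
  f1 <- simulate_fragments(20000, "CCR", p, seed = 42)
  f2 <- simulate_fragments(20000, "CCR", p, seed = 42)
  expect_identical(f1, f2)
  expect_true(all(f1$end > f1$start))
  expect_true(all(f1$start >= 0 & f1$end <= 20000))

  f3 <- simulate_fragments(20000, "CCR", p, seed = 43)
  expect_false(identical(f1$start, f3$start))

  # zero depth -> empty set
  empty <- simulate_fragments(20000, "CCR",
                              sim_params(depth_ccr = 0), seed = 1)
  expect_identical(nrow(empty), 0L)

  expect_error(simulate_fragments(-5, "CCR", p, seed = 1))
  expect_error(sim_params(ocr_depletion = 1.2))
  expect_error(sim_params(ocr_depletion = 0))
})

test_that("closed-state coverage is periodic at the nucleosome repeat", {
  # Jitter-free lattice makes the periodicity sharp; the autocorrelation
  # of per-base coverage must peak within +-10 bp of the 190 bp repeat.
  p <- sim_params(placement_jitter_bp = 5, occupancy_sd = 0)
  frags <- simulate_fragments(20000, "CCR", p, seed = 1)
  cov <- compute_coverage(frags)
  ac <- stats::acf(cov, lag.max = 250, plot = FALSE)$acf[-1]
  search <- 150:230
  peak_lag <- search[which.max(ac[search])]
  expect_gte(peak_lag, 180)
  expect_lte(peak_lag, 200)
})

test_that("open-state coverage is depleted by the configured factor", {
  p <- sim_params()
  ratios <- vapply(1:20, function(i) {
    mean(compute_coverage(simulate_fragments(20000, "OCR", p, seed = i))) /
      mean(compute_coverage(simulate_fragments(20000, "CCR", p, seed = 100 + i)))
  }, numeric(1))
  expect_true(all(ratios < 1))
  # depth here gives a standard error well under 5%
  expect_lt(abs(mean(ratios) - p$ocr_depletion) / p$ocr_depletion, 0.1)
})

test_that("partially open mixtures are exact convex combinations", {
  p <- sim_params()
  fo <- featurize_bundle(simulate_fragments(4000, "OCR", p, seed = 1))
  fc <- featurize_bundle(simulate_fragments(4000, "CCR", p, seed = 2))

  # identity and midpoint
  expect_equal(simulate_pocr_features(fo, fc, tau = 1 - 1e-12)$coverage,
               fo$coverage, tolerance = 1e-6)
  m_ocr <- fo; m_ccr <- fc
  for (cn in c("wps", "coverage", "uend", "dend")) {
    m_ocr[[cn]] <- rep(2, nrow(fo)); m_ccr[[cn]] <- rep(0, nrow(fc))
  }
  mid <- simulate_pocr_features(m_ocr, m_ccr, tau = 0.5)
  expect_true(all(abs(mid$wps - 1) < 1e-12))

  # element-wise convex combination bounds
  mix <- simulate_pocr_features(fo, fc, tau = 0.7)
  for (cn in c("wps", "coverage", "uend", "dend")) {
    expect_true(all(mix[[cn]] >= pmin(fo[[cn]], fc[[cn]]) - 1e-9))
    expect_true(all(mix[[cn]] <= pmax(fo[[cn]], fc[[cn]]) + 1e-9))
  }

  # least-squares recovery of the composite rate
  y <- unlist(mix[, c("wps", "coverage", "uend", "dend")])
  a <- unlist(fo[, c("wps", "coverage", "uend", "dend")])
  b <- unlist(fc[, c("wps", "coverage", "uend", "dend")])
  fit <- stats::lm(y ~ a + b - 1)
  expect_equal(unname(stats::coef(fit)["a"]), 0.7, tolerance = 1e-8)
  expect_equal(unname(stats::coef(fit)["b"]), 0.3, tolerance = 1e-8)

  expect_error(simulate_pocr_features(matrix(1, 3, 4), matrix(1, 2, 4)))
})

test_that("datasets carry correctly flipped and randomized labels", {
  d0 <- make_dataset(n_per_class = 8, noise_rate = 0, seed = 7,
                     segment_bp = 2000)
  bin <- d0$true_class < 2L
  expect_identical(d0$observed_label[bin], d0$true_class[bin])
  expect_true(all(d0$observed_label %in% 0:1))

  d1 <- make_dataset(n_per_class = 8, noise_rate = 0, seed = 7,
                     segment_bp = 2000)
  expect_identical(d0, d1)

  # flipped fraction close to the nominal rate (binomial, 2000 samples)
  d2 <- make_dataset(noise_rate = 0.2, seed = 3, segment_bp = 2000,
                     n_ocr = 1000, n_ccr = 1000, n_pocr = 20)
  frac <- mean(d2$flipped[d2$true_class < 2L])
  expect_lt(abs(frac - 0.2), 0.03)
  obs_vs_true <- mean(d2$observed_label[d2$true_class < 2L] !=
                        d2$true_class[d2$true_class < 2L])
  expect_equal(obs_vs_true, frac)

  expect_error(make_dataset(n_per_class = 0, seed = 1))
  expect_error(make_dataset(n_per_class = 5, noise_rate = 0.5, seed = 1))
})
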