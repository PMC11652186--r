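mk_chart <- function(eta = 0.3, seed = 1) {
  ic <- withr::with_seed(seed, matrix(stats::rnorm(200 * 2), 200, 2))
  m <- mewma_model(ic, lam = 0.2)
  d <- toy_two_class(60, seed = seed)
  clf <- train_classifier(d, classifier_config(epochs = 30), seed = seed)
  bd <- bootstrap_bd(mewma_t2(m, ic), B = 200, seed = seed)
  sensitized_chart(m, bd, clf, eta = eta)
}

test_that("classifier confidence is symmetric and piecewise linear", {
  expect_equal(confidence_delta(0.5), 0)
  expect_equal(confidence_delta(1), 1)
  expect_equal(confidence_delta(0), 1)
  expect_equal(confidence_delta(0.8), 0.6)
  p <- seq(0, 1, by = 0.05)
  expect_equal(confidence_delta(p), confidence_delta(1 - p))
  expect_equal(diff(confidence_delta(c(0.6, 0.7))) / 0.1, 2)
  expect_error(confidence_delta(1.2))
})

test_that("the fused statistic follows the weighting algebra", {
  # chart weight vanishes at maximal classifier uncertainty
  expect_equal(sensitized_statistic(0.9, 0.5, eta = 0.3), 0.5)
  expect_equal(sensitized_statistic(0.1, 0.5, eta = 0.3), 0.5)
  # hand-evaluated fusion
  expect_equal(sensitized_statistic(0.8, 0.9, eta = 0.3), 0.876)
  # fixed point when both probabilities agree
  for (v in c(0.2, 0.5, 0.9)) {
    expect_equal(sensitized_statistic(v, v, eta = 0.45), v)
  }
  # bounded between the two probabilities
  grid <- expand.grid(pt2 = seq(0.05, 0.95, by = 0.15),
                      pc = seq(0.05, 0.95, by = 0.15))
  st <- sensitized_statistic(grid$pt2, grid$pc, eta = 0.3)
  expect_true(all(st >= pmin(grid$pt2, grid$pc) - 1e-12))
  expect_true(all(st <= pmax(grid$pt2, grid$pc) + 1e-12))
  expect_true(all(st > 0 & st < 1))
})

test_that("a large chart weight triggers the degradation warning", {
  expect_warning(sensitized_statistic(0.5, 0.9, eta = 0.7),
                 class = "ocrchart_eta_warning")
  expect_warning(pipeline_config(eta = 0.8),
                 class = "ocrchart_eta_warning")
  expect_silent(sensitized_statistic(0.5, 0.9, eta = 0.6))
})

test_that("control-limit calibration honors the band structure", {
  ch <- mk_chart()
  ch1 <- calibrate_cl(rep(0.21, 80), ch, B = 50, seed = 1)
  expect_equal(ch1$cl, 0.21)
  expect_equal(ch1$cl_adjusted, 0.21)        # no tau supplied

  ch2 <- calibrate_cl(rep(0.21, 80), ch, B = 50, tau = 1 - 1e-9, seed = 1)
  expect_equal(ch2$cl_adjusted, ch2$cl, tolerance = 1e-6)

  ch3 <- calibrate_cl(rep(0.21, 80), ch, B = 50, tau = 0.7, seed = 1)
  expect_equal(ch3$cl_adjusted, 0.21 * 0.7)

  ic_st2 <- withr::with_seed(2, stats::runif(100, 0, 0.5))
  a <- calibrate_cl(ic_st2, ch, B = 300, seed = 5)
  b <- calibrate_cl(ic_st2, ch, B = 300, seed = 5)
  expect_identical(a$cl, b$cl)

  # empty partially-open band -> error
  expect_error(calibrate_cl(rep(0.75, 80), ch, B = 50, seed = 1),
               "band")
})

test_that("the three-band decision rule is monotone in the statistic", {
  ch <- calibrate_cl(rep(0.4, 80), mk_chart(), B = 50, seed = 1)
  expect_identical(classify_region(0.2, ch), 0L)
  expect_identical(classify_region(0.4, ch), 0L)   # closed band is [0, CL]
  expect_identical(classify_region(0.55, ch), 2L)
  expect_identical(classify_region(0.7, ch), 2L)   # middle band is (CL, 1-eta]
  expect_identical(classify_region(0.9, ch), 1L)

  st <- seq(0, 1, by = 0.01)
  lab <- classify_region(st, ch)
  ord <- c(0L, 2L, 1L)  # closed -> partial -> open
  pos <- match(lab, ord)
  expect_true(all(diff(pos) >= 0))
  expect_error(classify_region(1.2, ch))
  expect_error(classify_region(0.5, mk_chart()))   # uncalibrated
})

test_that("chart augmentation scores and labels a dataset", {
  ch <- mk_chart(seed = 3)
  d <- toy_two_class(60, seed = 9)
  ch <- calibrate_cl(chart_augment(d[d$observed_label == 0, ], ch)$st2,
                     ch, B = 100, tau = 0.7, seed = 3)
  out <- chart_augment(d, ch)
  expect_true(all(c("t2", "pt2", "pc", "delta", "st2", "label") %in%
                    names(out)))
  expect_equal(out$delta, confidence_delta(out$pc))
  expect_equal(out$st2,
               sensitized_statistic(out$pt2, out$pc, ch$eta))
  expect_true(all(out$label %in% 0:2))
})
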