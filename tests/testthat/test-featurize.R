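test_that("coverage matches the per-base membership oracle", {
  L <- 500L
  frags <- random_fragments(40, L, seed = 11)
  expect_equal(compute_coverage(frags, L), brute_coverage(frags, L))

  none <- frags[0, ]
  expect_equal(compute_coverage(none, 30L), numeric(30))

  one <- tibble::tibble(chrom = "t", start = 0L, end = 10L)
  expect_equal(compute_coverage(one, 20L),
               c(rep(1, 10), rep(0, 10)))

  # conservation: total coverage equals total clipped fragment bases
  expect_equal(sum(compute_coverage(frags, L)),
               sum(pmin(frags$end, L) - pmax(frags$start, 0L)))
})

test_that("WPS follows the span-minus-endpoint definition", {
  one <- tibble::tibble(chrom = "t", start = 0L, end = 200L)
  w <- compute_wps(one, 200L, w = 120L)
  expect_equal(w[100 + 1], 1)   # window fully inside the fragment
  expect_equal(w[10 + 1], -1)   # start endpoint inside the window

  expect_equal(compute_wps(one[0, ], 50L, w = 20L), numeric(50))
  expect_error(compute_wps(one, 100L, w = 120L))
  expect_error(compute_wps(one, 200L, w = 15L))

  L <- 400L
  frags <- random_fragments(25, L, seed = 5, min_len = 10, max_len = 80)
  expect_equal(compute_wps(frags, L, w = 40L), brute_wps(frags, L, 40L))
  frags2 <- random_fragments(30, L, seed = 9, min_len = 100, max_len = 200)
  expect_equal(compute_wps(frags2, L, w = 120L), brute_wps(frags2, L, 120L))
})

test_that("end signals tally fragment boundaries", {
  one <- tibble::tibble(chrom = "t", start = 5L, end = 10L)
  ends <- compute_end_signals(one, 20L)
  expect_equal(which(ends$uend == 1), 6)   # base 5, 1-indexed
  expect_equal(which(ends$dend == 1), 10)  # last covered base 9

  L <- 300L
  frags <- random_fragments(35, L, seed = 21)
  oracle <- brute_ends(frags, L)
  got <- compute_end_signals(frags, L)
  expect_equal(got$uend, oracle$uend)
  expect_equal(got$dend, oracle$dend)
  expect_equal(sum(got$uend), nrow(frags))
  expect_equal(sum(got$dend), nrow(frags))
})

test_that("window averaging tiles the segment and matches slice means", {
  frags <- simulate_fragments(20000, "CCR", sim_params(), seed = 2)
  tracks <- compute_tracks(frags)
  fw <- window_average(tracks, window_bp = 200L)
  expect_identical(nrow(fw), 100L)
  expect_identical(ncol(feature_matrix(fw)), 4L)

  # brute-force slice means
  for (k in c(1, 37, 100)) {
    idx <- ((k - 1) * 200 + 1):(k * 200)
    expect_equal(fw$coverage[k], mean(tracks$coverage[idx]))
    expect_equal(fw$wps[k], mean(tracks$wps[idx]))
  }

  # constant tracks reproduce the constants
  const <- tracks
  const$wps <- 3; const$coverage <- 2; const$uend <- 1; const$dend <- 0
  cw <- window_average(const, 200L)
  expect_true(all(cw$wps == 3) && all(cw$coverage == 2))

  # trailing partial window dropped with a message
  expect_message(short <- window_average(tracks[1:450, ], 200L), "partial")
  expect_identical(nrow(short), 2L)
  expect_error(window_average(tracks, 0))
})

test_that("dispersion summary is the population standard deviation", {
  fw <- featurize_bundle(simulate_fragments(4000, "CCR", sim_params(),
                                            seed = 3))
  s <- summarize_std(fw)
  sd_pop_oracle <- function(x) sqrt(sum((x - mean(x))^2) / length(x))
  expect_equal(s$sd_wps, sd_pop_oracle(fw$wps))
  expect_equal(s$sd_coverage, sd_pop_oracle(fw$coverage))

  const <- fw; const$wps <- 1; const$coverage <- 5
  expect_equal(summarize_std(const), list(sd_wps = 0, sd_coverage = 0))
  two <- fw[1:2, ]; two$wps <- c(0, 2)
  expect_equal(summarize_std(two)$sd_wps, 1)
  expect_error(summarize_std(fw[1, ]))
})

test_that("image encoding conserves fragment counts", {
  p <- sim_params()
  frags <- simulate_fragments(4000, "CCR", p, seed = 4)
  img <- encode_image(frags, len_range = c(60L, 400L))
  lens <- frags$end - frags$start
  expect_equal(sum(img$lengths), sum(lens >= 60 & lens <= 400))

  none <- frags[0, ]
  img0 <- encode_image(none, segment_length = 4000L)
  expect_true(all(img0$lengths == 0) && all(img0$coverage == 0))

  one <- tibble::tibble(chrom = "t", start = 600L, end = 767L)
  img1 <- encode_image(one, segment_length = 2000L)
  expect_equal(sum(img1$lengths), 1)
  expect_equal(unname(img1$lengths[600 %/% 200 + 1, "167"]), 1L)
})

test_that("closed-state WPS windows fluctuate more than depth-matched open ones", {
  p <- sim_params()
  vars <- vapply(1:20, function(i) {
    vc <- stats::var(featurize_bundle(
      simulate_fragments(20000, "CCR", p, seed = i))$wps)
    vo <- stats::var(featurize_bundle(
      simulate_fragments(20000, "OCR", p, seed = 1000 + i))$wps)
    vc > vo
  }, logical(1))
  expect_true(all(vars))
})

test_that("featurization is deterministic", {
  frags <- simulate_fragments(6000, "CCR", sim_params(), seed = 12)
  expect_identical(featurize_bundle(frags), featurize_bundle(frags))
})
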