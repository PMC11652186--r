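mk_stats <- function(nw, exceed_idx, ucl = 10) {
  s <- rep(1, nw)
  s[exceed_idx + 1L] <- ucl + 5   # indices given 0-based
  s
}

test_that("rule 1 flags runs of three or more consecutive exceedances", {
  calls <- apply_run_rules(mk_stats(100, 10:12), ucl = 10)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$start_window, 10L)
  expect_identical(calls$end_window, 12L)
  expect_identical(calls$rules, "1")
  expect_identical(calls$start, 2000L)
  expect_identical(calls$end, 2600L)

  # two consecutive only -> no call
  expect_identical(nrow(apply_run_rules(mk_stats(100, 10:11), 10)), 0L)
})

test_that("rule 2 calls a 600-bp boundary region", {
  calls <- apply_run_rules(mk_stats(100, 0), ucl = 10)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$rules, "2")
  expect_identical(calls$width_bp, 600L)
  expect_identical(calls$start, 0L)
  expect_identical(calls$end, 600L)

  last <- apply_run_rules(mk_stats(100, 99), ucl = 10)
  expect_identical(last$width_bp, 600L)
  expect_identical(last$start_window, 97L)
  expect_identical(last$end_window, 99L)
})

test_that("rule 3 merges exceedance runs separated by fewer than three windows", {
  # gap of 2 -> merged call spanning both runs and the gap
  calls <- apply_run_rules(mk_stats(100, c(10, 11, 14, 15)), ucl = 10)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$start_window, 10L)
  expect_identical(calls$end_window, 15L)
  expect_identical(calls$rules, "3")

  # gap of 3 -> two short runs, neither long enough -> nothing
  none <- apply_run_rules(mk_stats(100, c(10, 11, 15, 16)), ucl = 10)
  expect_identical(nrow(none), 0L)

  # merged run containing a length-3 run carries both rule ids
  both <- apply_run_rules(mk_stats(100, c(10, 11, 12, 14)), ucl = 10)
  expect_identical(both$rules, "1,3")
})

test_that("run-rule output is invariant under joint positive scaling", {
  s <- withr::with_seed(2, stats::runif(100, 0, 20))
  a <- apply_run_rules(s, 10)
  b <- apply_run_rules(s * 7.3, 73)
  expect_identical(a, b)
})

test_that("lowering the control limit never removes a called region", {
  for (seed in 1:10) {
    s <- withr::with_seed(seed, stats::rchisq(100, df = 4))
    hi <- apply_run_rules(s, 9)
    lo <- apply_run_rules(s, 6)
    covered <- function(calls, nw = 100) {
      out <- logical(nw)
      for (i in seq_len(nrow(calls))) {
        out[(calls$start_window[i]:calls$end_window[i]) + 1L] <- TRUE
      }
      out
    }
    expect_true(all(!covered(hi) | covered(lo)))
  }
})

test_that("training-set filtering keeps labels consistent with calls", {
  cand <- tibble::tibble(
    chrom = "c1",
    start = c(0L, 1000L, 2000L, 3000L),
    end = c(500L, 1500L, 2500L, 3500L),
    observed_label = c(1L, 1L, 0L, 0L))
  calls <- tibble::tibble(chrom = "c1", start = 100L, end = 2000L)

  kept <- filter_training_set(cand, calls)
  # open candidate overlapping a call kept; disjoint open candidate dropped
  expect_true(all(c(0L, 1000L) %in% kept$start[kept$observed_label == 1]))
  # closed candidate [2000, 2500) abuts the call end -> no overlap -> kept
  expect_true(2000L %in% kept$start)
  expect_true(3000L %in% kept$start)
  expect_identical(attr(kept, "n_removed"), 0L)

  # closed candidate overlapping a call is dropped
  calls2 <- tibble::tibble(chrom = "c1", start = 100L, end = 2001L)
  kept2 <- filter_training_set(cand, calls2)
  expect_false(2000L %in% kept2$start)

  # open candidate abutting a call (shared boundary) is non-overlapping
  cand3 <- tibble::tibble(chrom = "c1", start = 2000L, end = 2500L,
                          observed_label = 1L)
  expect_identical(nrow(filter_training_set(cand3, calls)), 0L)

  # balance downsamples the majority class
  cand4 <- tibble::tibble(chrom = "c1",
                          start = seq(0L, 9000L, by = 1000L),
                          end = seq(0L, 9000L, by = 1000L) + 400L,
                          observed_label = c(rep(1L, 3), rep(0L, 7)))
  calls4 <- tibble::tibble(chrom = "c1", start = 0L, end = 2500L)
  bal <- filter_training_set(cand4, calls4, balance = TRUE, seed = 1)
  expect_identical(as.integer(table(bal$observed_label)), c(3L, 3L))
})
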