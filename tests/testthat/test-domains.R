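mk_track <- function(means, w = 1e5, chrom = "chr1", partial = FALSE) {
  n <- length(means)
  out <- tibble::tibble(
    chrom = chrom, start = as.integer((seq_len(n) - 1) * w),
    end = as.integer(seq_len(n) * w),
    partial = rep_len(partial, n), n_cpgs = 100L, mean_meth = means)
  attr(out, "w") <- w
  class(out) <- c("window_track", class(out))
  out
}

test_that("identical tracks flag nothing; a uniform shift flags everything", {
  a <- mk_track(rep(0.7, 20))
  expect_identical(n_hypomethylated(differential_windows(a, a)), 0L)
  b <- mk_track(rep(0.9, 20))
  d <- differential_windows(a, b, delta = 0.15)
  expect_identical(n_hypomethylated(d), 20L)
  expect_equal(d$delta, rep(-0.2, 20))
})

test_that("missing windows are incomparable and partial windows not counted", {
  a <- mk_track(c(0.2, NA, 0.2, 0.2))
  b <- mk_track(c(0.8, 0.8, NA, 0.8))
  d <- differential_windows(a, b)
  expect_identical(n_hypomethylated(d), 2L)
  expect_identical(attr(d, "n_incomparable"), 2L)
  ap <- mk_track(c(0.2, 0.2), partial = c(FALSE, TRUE))
  bp <- mk_track(c(0.8, 0.8), partial = c(FALSE, TRUE))
  expect_identical(n_hypomethylated(differential_windows(ap, bp)), 1L)
  expect_identical(
    n_hypomethylated(differential_windows(ap, bp, include_partial = TRUE)),
    2L)
  expect_error(differential_windows(mk_track(rep(0.5, 3)),
                                    mk_track(rep(0.5, 4))),
               "tiling")
})

test_that("opposite-direction comparisons flag disjoint windows", {
  set.seed(60)
  a <- mk_track(runif(50))
  b <- mk_track(runif(50))
  fa <- differential_windows(a, b)$flagged
  fb <- differential_windows(b, a)$flagged
  expect_false(any(fa & fb))
})

test_that("flagged-window counts are non-increasing in the cutoff", {
  set.seed(61)
  a <- mk_track(runif(200, 0, 0.6))
  b <- mk_track(runif(200, 0.2, 0.9))
  counts <- sapply(c(0.05, 0.10, 0.15, 0.20, 0.25), function(delta) {
    n_hypomethylated(differential_windows(a, b, delta = delta))
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("adjacent flagged windows merge into domains with gap control", {
  a <- mk_track(c(0.3, 0.3, 0.8, 0.8, 0.3, 0.8, 0.3))
  b <- mk_track(rep(0.8, 7))
  d <- differential_windows(a, b)
  doms <- call_dpds(mk_track(rep(0.8, 7)), a)  # same flags via ko < wt - delta
  expect_identical(nrow(doms), 3L)
  expect_identical(doms$end[1] - doms$start[1], 200000L)
  merged_gap <- methdomains:::merge_flagged(d, "PMD", gap = 1L)
  expect_identical(nrow(merged_gap), 2L)
  min2 <- methdomains:::merge_flagged(d, "PMD", min_windows = 2L)
  expect_identical(nrow(min2), 1L)
})

test_that("conserved domains require support from every comparison", {
  base <- mk_track(rep(0.8, 10))
  rep1 <- mk_track(c(rep(0.4, 3), rep(0.8, 4), rep(0.4, 3)))
  rep2 <- mk_track(c(rep(0.4, 3), rep(0.8, 7)))  # second domain missing
  d1 <- differential_windows(rep1, base)
  d2 <- differential_windows(rep2, base)
  pmds <- call_conserved_pmds(list(small = d1, large = d2))
  expect_identical(nrow(pmds), 1L)
  expect_identical(pmds$start, 0L)
  expect_identical(pmds$end, 300000L)
  expect_identical(attr(pmds, "provenance"), c("small", "large"))
  expect_warning(single <- call_conserved_pmds(list(d1)), "fewer than 2")
  expect_identical(nrow(single), 2L)
})

test_that("knockout-specific loss yields DPDs and none under identity", {
  wt <- mk_track(rep(0.8, 10))
  ko <- mk_track(c(rep(0.8, 4), rep(0.45, 3), rep(0.8, 3)))
  dpds <- call_dpds(wt, ko)
  expect_identical(nrow(dpds), 1L)
  expect_identical(dpds$label, "DPD")
  expect_equal(dpds$mean_delta, -0.35)
  expect_identical(nrow(call_dpds(wt, wt)), 0L)
})

test_that("interval Jaccard scores overlap of interval sets", {
  a <- tibble::tibble(chrom = "chr1", start = 0L, end = 100L)
  b <- tibble::tibble(chrom = "chr1", start = 50L, end = 150L)
  expect_equal(interval_jaccard(a, a), 1)
  expect_equal(interval_jaccard(a, b), 50 / 150)
  expect_equal(interval_jaccard(a, tibble::tibble(chrom = "chr2",
                                                  start = 0L, end = 100L)),
               0)
})

test_that("rank correlation handles identity, antisymmetry and degenerate input", {
  wins <- tibble::tibble(chrom = "chr1", start = as.integer(0:19 * 100),
                         end = as.integer(1:20 * 100),
                         value = c(1:20) / 20)
  self <- correlate_with_track(wins, wins$value)
  expect_equal(self$estimate, 1)
  neg <- correlate_with_track(wins, -wins$value)
  expect_equal(neg$estimate, -1)
  expect_error(correlate_with_track(wins, rep(1, 20)), "constant")
  expect_error(correlate_with_track(wins[1:5, ], wins$value[1:5]),
               "fewer than 10")
  td <- tidy(self)
  expect_equal(td$estimate, 1)
  expect_identical(glance(self)$n, 20L)
})
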