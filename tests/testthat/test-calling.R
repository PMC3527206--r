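# Hand fixture: chr1 = AACGTTCATTACGTT
#   CpG dyads at 0-based 2-3 and 11-12; one plus-strand CH cytosine at 6.
hand_genome <- function() genome_from_seq(chr1 = "AACGTTCATTACGTT")

test_that("per-site counting matches the worked example (3 C + 1 T = 0.75)", {
  g <- hand_genome()
  reads <- mk_reads("chr1",
                    pos = c(0, 0, 2, 1),
                    seq = c("AACGTT", "AATGTT", "CGTT", "ACG"),
                    protocol = "+")
  calls <- call_methylation(reads, g, context = "CG")
  site <- calls[calls$pos == 2 & calls$strand == "+", ]
  expect_identical(site$n_meth, 3L)
  expect_identical(site$n_total, 4L)
  expect_equal(site$ratio, 0.75)
})

test_that("reads inform only the strand their protocol tag names", {
  g <- hand_genome()
  plus_only <- mk_reads("chr1", 0, "AACGTT", protocol = "+")
  calls <- call_methylation(plus_only, g, context = "CG")
  expect_true(all(calls$strand == "+"))
  # the G of the dyad is a minus-strand cytosine: only "-" protocol reads call it
  minus <- mk_reads("chr1", 0, "AACGTT", protocol = "-")
  calls2 <- call_methylation(minus, g, context = "CG")
  expect_identical(calls2$strand, "-")
  expect_identical(calls2$pos, 3L)
  expect_identical(calls2$n_meth, 1L)  # G = methylated on the minus strand
})

test_that("mismatching base calls are ignored and untagged reads skipped", {
  g <- hand_genome()
  reads <- mk_reads("chr1", pos = c(2, 2), seq = c("AGTT", "CGTT"),
                    protocol = "+")
  calls <- call_methylation(reads, g, context = "CG")
  site <- calls[calls$pos == 2, ]
  expect_identical(site$n_total, 1L)  # the A call does not count
  untagged <- mk_reads("chr1", 0, "AACGTT", protocol = NA_character_)
  calls2 <- call_methylation(rbind(reads, untagged), g, context = "CG")
  expect_identical(attr(calls2, "n_skipped"), 1L)
  expect_identical(sum(calls2$n_total), 1L)
})

test_that("conversion-rate arithmetic matches the quoted formula", {
  g <- hand_genome()
  reads <- mk_reads("chr1", 6, c(rep("CA", 2), rep("TA", 98)), protocol = "+")
  est <- estimate_conversion(reads, g)
  expect_identical(est$n_c, 2L)
  expect_identical(est$n_bases, 100L)
  expect_equal(est$rate, 0.98)
  # zero C calls give the boundary rate 1; mismatches only enter the denominator
  est2 <- estimate_conversion(
    mk_reads("chr1", 6, c("GA", rep("TA", 99)), protocol = "+"), g)
  expect_identical(est2$n_c, 0L)
  expect_identical(est2$n_bases, 100L)
  expect_equal(est2$rate, 1)
  expect_error(estimate_conversion(mk_reads("chr1", 0, "AA", protocol = "+"),
                                   g),
               "undefined")
})

test_that("calling equals the brute-force pileup exactly on a simulated fixture", {
  g <- build_genome(bare_spec(len = 6e4, seed = 40))
  truth <- assign_truth_methylome(g)
  reads <- simulate_bisulfite_reads(g, truth, "normal", coverage = 6,
                                    read_length = 60L, seed = 41)
  expect_lt(nrow(reads), 10000)
  calls <- call_methylation(reads, g, context = "all")
  oracle <- brute_pileup(reads, g)
  expect_equal(
    as.data.frame(calls[, c("chrom", "pos", "strand", "context",
                            "n_meth", "n_total")]),
    as.data.frame(oracle), ignore_attr = TRUE)
  est <- estimate_conversion(reads, g)
  bf <- brute_conversion(reads, g)
  expect_identical(est$n_c, bf$n_c)
  expect_identical(est$n_bases, bf$n_bases)
})

test_that("counts are conserved under genome partition and strand pooling", {
  g <- build_genome(bare_spec(len = 5e4, seed = 42))
  truth <- assign_truth_methylome(g)
  reads <- simulate_bisulfite_reads(g, truth, "normal", coverage = 5, seed = 43)
  calls <- call_methylation(reads, g, context = "CG")
  expect_true(all(calls$n_meth <= calls$n_total))
  # partition by position: totals over halves sum to the genome-wide total
  lo <- calls[calls$pos < 25000, ]
  hi <- calls[calls$pos >= 25000, ]
  expect_identical(sum(lo$n_total) + sum(hi$n_total), sum(calls$n_total))
  pooled <- call_methylation(reads, g, context = "CG", pool_strands = TRUE)
  expect_true(all(pooled$strand == "*"))
  expect_identical(sum(pooled$n_meth), sum(calls$n_meth))
  expect_identical(sum(pooled$n_total), sum(calls$n_total))
  # pooled records sit at dyad starts
  dyads <- g$sites[g$sites$context == "CG" & g$sites$strand == "+", ]
  expect_true(all(pooled$pos %in% dyads$pos))
})

test_that("plus and minus strand ratios are statistically indistinguishable on symmetric truth", {
  g <- build_genome(bare_spec(len = 4e5, seed = 44))
  truth <- assign_truth_methylome(g)
  reads <- simulate_bisulfite_reads(g, truth, "normal", coverage = 10, seed = 45)
  calls <- call_methylation(reads, g, context = "CG")
  ks <- suppressWarnings(
    stats::ks.test(calls$ratio[calls$strand == "+"],
                   calls$ratio[calls$strand == "-"]))
  expect_gt(ks$p.value, 0.01)
})

test_that("mean methylation is the arithmetic mean over covered sites", {
  calls <- mk_calls("chr1", c(0, 10, 20), c(0.2, 0.4, 0.9))
  expect_equal(mean_methylation(calls), 0.5)
  expect_equal(mean_methylation(mk_calls("chr1", 0:4, 1)), 1)
  expect_error(mean_methylation(calls[0, ]), "no called sites")
})

test_that("call tables round-trip through the TSV dialect", {
  g <- build_genome(bare_spec(len = 3e4, seed = 46))
  truth <- assign_truth_methylome(g)
  reads <- simulate_bisulfite_reads(g, truth, "wt", coverage = 4, seed = 47)
  calls <- call_methylation(reads, g)
  f <- tempfile(fileext = ".tsv")
  write_calls(calls, f)
  back <- read_calls(f)
  expect_equal(as.data.frame(back),
               as.data.frame(calls[, names(back)]), ignore_attr = TRUE)
})
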