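test_that("state classification uses strict outer thresholds", {
  expect_identical(as.character(classify_methylation_state(
    c(0.04, 0.05, 0.5, 0.95, 0.96))),
    c("unmethylated", "partial", "partial", "partial", "fully_methylated"))
  expect_error(classify_methylation_state(1.2), "\\[0, 1\\]")
  expect_error(classify_methylation_state(c(0.1, NA)), "missing")
})

test_that("binned distributions report the toy fractions and histogram", {
  calls <- mk_calls("chr1", 0:4, c(0, 0, 1, 1, 0.5))
  b <- bin_distribution(calls)
  expect_equal(b$states$fraction, c(0.4, 0.2, 0.4))
  expect_identical(sum(b$states$n), 5L)
  expect_identical(sum(b$histogram$n), 5L)
  all_one <- bin_distribution(mk_calls("chr1", 0:9, 1))
  expect_equal(all_one$states$fraction[3], 1)
  expect_error(bin_distribution(calls[0, ]), "no called sites")
})

test_that("bin fractions equal sitewise classification exactly", {
  set.seed(50)
  calls <- mk_calls("chr1", seq_len(5000), round(runif(5000), 3))
  b <- bin_distribution(calls)
  st <- classify_methylation_state(calls$ratio)
  expect_identical(b$states$n, as.integer(table(st)))
})

test_that("feature averages honour the CpG-count and coverage filters", {
  calls <- rbind(
    mk_calls("chr1", c(100, 110, 120), 0.1, n_total = 3L),
    mk_calls("chr1", c(500, 510), 0.8, n_total = 5L),
    mk_calls("chr1", c(900, 910, 920), 0.6, n_total = 2L))
  feats <- tibble::tibble(chrom = "chr1",
                          start = c(50L, 450L, 850L),
                          end = c(200L, 600L, 1000L),
                          name = c("a", "b", "c"), category = "promoter")
  fm <- feature_methylation(calls, feats, min_cpgs = 3, min_coverage = 3)
  tf <- tidy(fm)
  expect_equal(tf$mean_ratio[tf$name == "a"], 0.1)
  expect_false(tf$included[tf$name == "b"])  # only 2 qualifying CpGs
  expect_false(tf$included[tf$name == "c"])  # coverage below 3
  expect_equal(glance(fm)$mean_ratio, 0.1)
  expect_identical(glance(fm)$n_excluded, 2L)
})

test_that("raising min_coverage never recovers qualifying sites", {
  g <- build_genome(bare_spec(len = 1e5, seed = 51))
  truth <- assign_truth_methylome(g)
  reads <- simulate_bisulfite_reads(g, truth, "normal", coverage = 6, seed = 52)
  calls <- call_methylation(reads, g)
  feats <- tibble::tibble(chrom = "chrA", start = seq(0L, 90000L, 10000L),
                          end = seq(10000L, 100000L, 10000L))
  counts <- sapply(1:6, function(mc) {
    sum(tidy(feature_methylation(calls, feats, min_cpgs = 1,
                                 min_coverage = mc))$n_sites)
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("promoters are 1-kb upstream of the TSS on the coding strand", {
  calls <- rbind(
    mk_calls("chr1", c(9100, 9500, 9900), 0.2),    # upstream of + gene
    mk_calls("chr1", c(10500, 11500), 0.8),        # inside gene body
    mk_calls("chr1", c(30100, 30500), 0.3),        # downstream of - gene end
    mk_calls("chr1", c(50000, 50100), 0.6))        # intergenic
  genes <- tibble::tibble(
    chrom = "chr1", start = c(10000L, 25000L), end = c(13600L, 30000L),
    name = c("gp", "gm"), strand = c("+", "-"))
  subregions <- tibble::tibble(
    chrom = "chr1", start = c(10000L, 25000L), end = c(13600L, 30000L),
    gene = c("gp", "gm"), category = "exon", strand = c("+", "-"))
  part <- partition_genic(calls, genes, subregions)
  comp <- part$compartments
  expect_equal(comp$mean_ratio[comp$category == "promoter"],
               mean(c(0.2, 0.2, 0.2, 0.3, 0.3)))
  expect_identical(comp$n_sites[comp$category == "promoter"], 5L)
  expect_equal(comp$mean_ratio[comp$category == "gene_body"], 0.8)
  expect_equal(comp$mean_ratio[comp$category == "intergenic"], 0.6)
  expect_error(partition_genic(calls, dplyr::mutate(genes, strand = "."),
                               subregions),
               "strand")
})

test_that("overlap priority is promoter over gene body over intergenic", {
  # a site inside both a promoter (of gene B) and the body of gene A
  calls <- mk_calls("chr1", 5500, 0.4)
  genes <- tibble::tibble(
    chrom = "chr1", start = c(1000L, 6000L), end = c(5800L, 9000L),
    name = c("A", "B"), strand = "+")
  subregions <- tibble::tibble(
    chrom = "chr1", start = c(1000L, 6000L), end = c(5800L, 9000L),
    gene = c("A", "B"), category = "exon", strand = "+")
  part <- suppressWarnings(partition_genic(calls, genes, subregions))
  expect_identical(part$sites$compartment, "promoter")
  # exon beats intron for a site under both records
  calls2 <- mk_calls("chr1", 2000, 0.4)
  sub2 <- tibble::tibble(
    chrom = "chr1", start = c(1500L, 1500L), end = c(2500L, 2500L),
    gene = "A", category = c("intron", "exon"), strand = "+")
  expect_warning(part2 <- partition_genic(calls2, genes[1, ], sub2),
                 "intergenic")  # one gene covers every covered site
  expect_identical(part2$subregions$category, "exon")
})

test_that("genic partition covers every site exactly once", {
  g <- build_genome(genome_spec(chrom_lengths = c(chr1 = 1e6), seed = 53))
  truth <- assign_truth_methylome(g)
  reads <- simulate_bisulfite_reads(g, truth, "normal", coverage = 4, seed = 54)
  calls <- call_methylation(reads, g)
  part <- partition_genic(calls, g$annotations$genes,
                          g$annotations$subregions)
  expect_identical(sum(part$compartments$n_sites), nrow(part$sites))
  expect_identical(nrow(part$sites), sum(calls$n_total >= 1))
})

test_that("per-gene subregion means pool all records of a subregion", {
  calls <- rbind(mk_calls("chr1", c(100, 300), c(0.2, 0.4)),
                 mk_calls("chr1", 900, 0.9))
  subs <- tibble::tibble(
    chrom = "chr1", start = c(50L, 250L, 850L), end = c(150L, 350L, 950L),
    gene = "g1", category = c("exon", "exon", "intron"), strand = "+")
  sm <- gene_subregion_means(calls, subs)
  expect_equal(sm$mean_ratio[sm$category == "exon"], 0.3)
  expect_identical(sm$n_sites[sm$category == "exon"], 2L)
  expect_equal(sm$mean_ratio[sm$category == "intron"], 0.9)
})
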