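test_that("built chromosomes have exactly the requested lengths", {
  spec <- genome_spec(chrom_lengths = c(chr1 = 123457, chr2 = 80000),
                      genes = list(n_genes = 0), repeats = NULL, seed = 2)
  g <- build_genome(spec)
  expect_identical(nchar(g$seq[["chr1"]]), 123457L)
  expect_identical(nchar(g$seq[["chr2"]]), 80000L)
  expect_identical(unname(g$chrom_lengths), c(123457L, 80000L))
})

test_that("identical spec and seed give byte-identical genomes and annotations", {
  spec <- genome_spec(chrom_lengths = c(chr1 = 3e5), seed = 9)
  g1 <- build_genome(spec)
  g2 <- build_genome(spec)
  expect_identical(g1$seq, g2$seq)
  expect_identical(g1$annotations, g2$annotations)
  expect_identical(g1$sites, g2$sites)
  f1 <- tempfile(fileext = ".fa")
  f2 <- tempfile(fileext = ".fa")
  write_genome_fasta(g1, f1)
  write_genome_fasta(g2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("CpG density follows the domain plan within binomial error", {
  len <- 2e6L
  doms <- tibble::tibble(
    chrom = "chrA", start = c(0L, 1000000L), end = c(500000L, 1500000L),
    type = c("DPD", "PMD"), cpg_mult = c(4, 0.3),
    shift_wt = 0, shift_ko = 0)
  spec <- genome_spec(chrom_lengths = c(chrA = len), cpg_per_kb = 10,
                      domains = doms, genes = list(n_genes = 0),
                      repeats = NULL,
                      lamina = list(coupling = 0, outside_max = 0),
                      seed = 5)
  g <- build_genome(spec)
  dyads <- g$sites[g$sites$context == "CG" & g$sites$strand == "+", ]
  dens <- function(lo, hi) sum(dyads$pos >= lo & dyads$pos < hi) / (hi - lo) * 1000
  # binomial sd on a 500-kb interval at 40/kb is ~0.28 per kb; allow 4 sd
  expect_lt(abs(dens(0, 5e5) - 40), 1.5)
  expect_lt(abs(dens(1e6, 1.5e6) - 3), 0.5)
  expect_lt(abs(dens(1.5e6, 2e6) - 10), 1)
})

test_that("zero-gene zero-repeat specs emit only domain annotations", {
  spec <- bare_spec(len = 1e5, seed = 3)
  g <- build_genome(spec)
  expect_identical(nrow(g$annotations$genes), 0L)
  expect_identical(nrow(g$annotations$repeats), 0L)
  expect_identical(nrow(g$annotations$cgi), 0L)
  expect_gt(nrow(g$annotations$domains), 0L)
  d <- tempfile()
  write_genome_annotations(g, d)
  expect_identical(nrow(read_bed(file.path(d, "genes.bed"))), 0L)
  expect_gt(nrow(read_bed(file.path(d, "domains_truth.bed"))), 0L)
})

test_that("overlapping planted domains are rejected", {
  doms <- tibble::tibble(chrom = "chrA", start = c(0L, 400000L),
                         end = c(500000L, 900000L),
                         type = c("PMD", "DPD"))
  expect_error(genome_spec(chrom_lengths = c(chrA = 1e6), domains = doms),
               "disjoint")
  expect_error(
    genome_spec(chrom_lengths = c(chrA = 1e6),
                domains = tibble::tibble(chrom = "chrA", start = 0L,
                                         end = 2e6L, type = "PMD")),
    "bounds")
})

test_that("every scanned site matches its reference context", {
  g <- build_genome(genome_spec(chrom_lengths = c(chr1 = 5e4), seed = 11))
  s <- g$seq[["chr1"]]
  cg_plus <- g$sites[g$sites$context == "CG" & g$sites$strand == "+", ]
  expect_true(all(substring(s, cg_plus$pos + 1, cg_plus$pos + 2) == "CG"))
  cg_minus <- g$sites[g$sites$context == "CG" & g$sites$strand == "-", ]
  expect_true(all(substring(s, cg_minus$pos, cg_minus$pos + 1) == "CG"))
  ch_plus <- g$sites[g$sites$context == "CH" & g$sites$strand == "+", ]
  expect_true(all(substring(s, ch_plus$pos + 1, ch_plus$pos + 1) == "C"))
  expect_true(all(substring(s, ch_plus$pos + 2, ch_plus$pos + 2) != "G"))
  # minus-strand CH sites are G not preceded by C
  ch_minus <- g$sites[g$sites$context == "CH" & g$sites$strand == "-", ]
  expect_true(all(substring(s, ch_minus$pos + 1, ch_minus$pos + 1) == "G"))
  expect_true(all(substring(s, ch_minus$pos, ch_minus$pos) != "C"))
})

test_that("the lamina field saturates inside PMD-like intervals and genes avoid them", {
  g <- build_genome(genome_spec(chrom_lengths = c(chr1 = 4e6), seed = 13))
  pmds <- g$annotations$domains
  pmds <- pmds[pmds$type == "PMD", ]
  lam <- g$lamina
  mid <- (lam$start + lam$end) / 2
  in_pmd <- rep(FALSE, nrow(lam))
  for (i in seq_len(nrow(pmds))) {
    in_pmd <- in_pmd | (lam$chrom == pmds$chrom[i] & mid >= pmds$start[i] &
                          mid < pmds$end[i])
  }
  expect_true(all(lam$lambda[in_pmd] == 1))
  expect_true(all(lam$lambda[!in_pmd] <= 0.4))
  genes <- g$annotations$genes
  for (i in seq_len(nrow(pmds))) {
    same <- genes$chrom == pmds$chrom[i]
    expect_false(any(same & genes$start < pmds$end[i] &
                       genes$end > pmds$start[i]))
  }
})
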