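test_that("fold-change selection is strict at the threshold and partitions genes", {
  tab <- tibble::tibble(gene = c("a", "b", "c", "d"),
                        fold_change = c(2.1, 1.9, 3.0, 0.4))
  de <- select_de_genes(tab)
  expect_identical(as.character(de$direction),
                   c("up", "unchanged", "up", "down"))
  toy <- select_de_genes(tibble::tibble(gene = c("x", "y", "z"),
                                        fold_change = c(3.0, 0.4, 1.0)))
  expect_identical(attr(toy, "n_up"), 1L)
  expect_identical(attr(toy, "n_down"), 1L)
  expect_identical(attr(toy, "n_unchanged"), 1L)
  expect_warning(bad <- select_de_genes(
    tibble::tibble(gene = c("a", "b"), fold_change = c(-1, 2.5))),
    "non-positive")
  expect_identical(attr(bad, "n_rejected"), 1L)
  # up, down, unchanged are disjoint and exhaustive
  expect_identical(attr(de, "n_up") + attr(de, "n_down") +
                     attr(de, "n_unchanged"), nrow(de))
})

test_that("gene deltas come from the midpoint window, with overlap weighting optional", {
  diff <- tibble::tibble(
    chrom = "chr1", start = as.integer(0:3 * 1e5), end = as.integer(1:4 * 1e5),
    partial = FALSE, mean_test = 0.5, mean_baseline = 0.7,
    delta = c(-0.2, -0.05, -0.3, 0), flagged = c(TRUE, FALSE, TRUE, FALSE))
  class(diff) <- c("diff_track", class(diff))
  genes <- tibble::tibble(chrom = "chr1", start = c(10000L, 150000L),
                          end = c(30000L, 210000L),
                          name = c("gA", "gB"))
  out <- gene_window_delta(genes, diff)
  expect_equal(out$delta, c(-0.2, -0.05))  # midpoints at 20 kb and 180 kb
  expect_equal(attr(out, "fraction_flagged"), 0.5)
  # overlap method: gB spans windows 2 and 3 with 50/10 kb weights
  out2 <- gene_window_delta(genes, diff, method = "overlap")
  expect_equal(out2$delta[out2$gene == "gB"],
               (-0.05 * 50000 - 0.3 * 10000) / 60000)
  outside <- tibble::tibble(chrom = "chr2", start = 0L, end = 100L,
                            name = "far")
  out3 <- gene_window_delta(outside, diff)
  expect_identical(nrow(out3), 0L)
  expect_identical(attr(out3, "n_outside"), 1L)
  empty <- gene_window_delta(genes[0, ], diff)
  expect_identical(nrow(empty), 0L)
  expect_true(is.na(attr(empty, "fraction_flagged")))
})

test_that("identical conditions are never significant and tiny cells are skipped", {
  sm <- simulate_gene_subregion_methylation(n_genes = 30, seed = 70)
  sm$mean_ko <- sm$mean_wt  # exact null
  out <- subregion_differential_test(sm)
  expect_true(all(!out$significant))
  expect_true(all(out$p_value == 1))
  tiny <- sm[sm$gene %in% c("up_gene1", "down_gene1"), ]
  out2 <- subregion_differential_test(tiny)
  expect_true(all(!out2$tested))
  expect_true(all(is.na(out2$p_value)))
})

test_that("swapping conditions flips every t statistic and keeps p-values", {
  sm <- simulate_gene_subregion_methylation(
    n_genes = 40, shift = c(up.five_utr = -0.2, down.exon = -0.15),
    seed = 71)
  out <- subregion_differential_test(sm)
  swapped <- dplyr::rename(sm, mean_wt = "mean_ko", mean_ko = "mean_wt")
  out2 <- subregion_differential_test(swapped)
  expect_equal(out2$statistic, -out$statistic)
  expect_equal(out2$p_value, out$p_value)
})

test_that("a planted subregion shift is detected in the planted cell", {
  sm <- simulate_gene_subregion_methylation(
    n_genes = 100, shift = c(up.five_utr = -0.2), seed = 72)
  out <- subregion_differential_test(sm)
  hit <- out[out$set == "up" & out$category == "five_utr", ]
  expect_true(hit$significant)
  others <- out[!(out$set == "up" & out$category == "five_utr"), ]
  expect_true(all(!others$significant))
})

test_that("deregulated genes planted in DPDs land in hypomethylated windows", {
  g <- build_genome(genome_spec(chrom_lengths = c(chr1 = 4e6), seed = 73))
  expr <- simulate_expression_table(g, n_up = 6, n_down = 6,
                                    frac_in_dpd = 1, seed = 74)
  de <- select_de_genes(expr)
  expect_identical(attr(de, "n_up"), 6L)
  expect_identical(attr(de, "n_down"), 6L)
  expect_identical(as.character(de$direction), de$true_direction)
  # a noiseless differential track: loss of 0.3 exactly in DPD windows
  doms <- g$annotations$domains
  tiles <- methdomains:::tile_windows(g$chrom_lengths, 1e5)
  in_dpd <- rep(FALSE, nrow(tiles))
  for (i in which(doms$type == "DPD")) {
    in_dpd <- in_dpd | (tiles$chrom == doms$chrom[i] &
                          tiles$start >= doms$start[i] &
                          tiles$end <= doms$end[i])
  }
  diff <- dplyr::mutate(tiles, mean_test = ifelse(in_dpd, 0.4, 0.7),
                        mean_baseline = 0.7,
                        delta = ifelse(in_dpd, -0.3, 0), flagged = in_dpd)
  class(diff) <- c("diff_track", class(diff))
  de_genes <- g$annotations$genes
  de_genes <- de_genes[de_genes$name %in%
                         de$gene[de$direction != "unchanged"], ]
  out <- gene_window_delta(de_genes, diff)
  expect_gte(attr(out, "fraction_flagged"), 0.9)
})
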