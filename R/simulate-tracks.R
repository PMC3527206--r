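#' Simulate external genomic signal tracks tied to the domain plan
#'
#' Emits bedGraph-style tracks that mirror the chromatin biology the domain
#' plan encodes: a nuclear-lamina association signal reading out the
#' genome's latent lamina field (continuous genome-wide, saturating at 1
#' inside PMD-like intervals, which coincide with lamina-associated
#' domains), an H3K4me1 signal and an expression signal high inside
#' DPD-like intervals (DPDs are active, regulatory-mark-rich chromatin),
#' each with additive Gaussian noise.
#'
#' @param genome A `meth_genome` built from a spec with a domain plan.
#' @param bin Bin width in bp (default 20000).
#' @param noise_sd Gaussian noise standard deviation (default 0.15).
#' @param seed Integer seed.
#' @return Named list of bedGraph tibbles: `lamina`, `h3k4me1`,
#'   `expression`.
#' @export
simulate_tracks <- function(genome, bin = 20000L, noise_sd = 0.15,
                            seed = 1L) {
  dom <- genome$annotations$domains
  tiles <- tile_windows(genome$chrom_lengths, bin)
  mid <- (tiles$start + tiles$end) %/% 2L
  type <- rep(NA_character_, nrow(tiles))
  for (ch in unique(tiles$chrom)) {
    sel <- tiles$chrom == ch
    d <- dom[dom$chrom == ch, , drop = FALSE]
    if (nrow(d) == 0) next
    i <- interval_index(mid[sel], d$start, d$end)
    type[sel][!is.na(i)] <- d$type[i[!is.na(i)]]
  }
  in_pmd <- !is.na(type) & type == "PMD"
  in_dpd <- !is.na(type) & type == "DPD"
  lam <- if (!is.null(genome$lamina)) {
    lambda_at(genome$lamina, tiles$chrom, mid)
  } else {
    ifelse(in_pmd, 1, 0)
  }
  with_seed(seed, {
    mk <- function(level) {
      tibble(chrom = tiles$chrom, start = tiles$start, end = tiles$end,
             value = level + rnorm(nrow(tiles), 0, noise_sd))
    }
    list(
      lamina = mk(lam),
      h3k4me1 = mk(ifelse(in_dpd, 1, 0.1 + 0.2 * (1 - lam))),
      expression = mk(ifelse(in_dpd, 1, ifelse(in_pmd, 0.05,
                                               0.4 * (1 - lam))))
    )
  })
}

#' Simulate a deregulated-gene fold-change table
#'
#' Picks `n_up` + `n_down` deregulated genes, placing a fraction
#' `frac_in_dpd` of them among genes whose midpoints lie inside DPD-like
#' intervals (Dnmt3a-dependent methylation loss concentrates in active
#' domains, where deregulated genes reside), and draws linear fold changes:
#' above `fold` for upregulated genes, below `1/fold` for downregulated
#' ones, and within `(1/fold, fold)` for the rest.
#'
#' @param genome A `meth_genome` with gene annotations.
#' @param n_up,n_down Numbers of up-/downregulated genes.
#' @param fold Fold-change threshold the simulation respects (default 2).
#' @param frac_in_dpd Target fraction of deregulated genes inside DPD-like
#'   intervals (default 0.9, capped by availability).
#' @param seed Integer seed.
#' @return Tibble `gene`, `fold_change`, plus the hidden truth column
#'   `true_direction`.
#' @export
simulate_expression_table <- function(genome, n_up = 8L, n_down = 10L,
                                      fold = 2, frac_in_dpd = 0.9,
                                      seed = 1L) {
  genes <- genome$annotations$genes
  if (nrow(genes) == 0) abort("genome has no annotated genes")
  dom <- genome$annotations$domains
  dpd <- dom[dom$type == "DPD", , drop = FALSE]
  mid <- (genes$start + genes$end) %/% 2L
  in_dpd <- rep(FALSE, nrow(genes))
  for (ch in unique(genes$chrom)) {
    sel <- genes$chrom == ch
    d <- dpd[dpd$chrom == ch, , drop = FALSE]
    if (nrow(d) == 0) next
    in_dpd[sel] <- !is.na(interval_index(mid[sel], d$start, d$end))
  }
  n_de <- n_up + n_down
  if (n_de > nrow(genes)) abort("more deregulated genes requested than exist")
  with_seed(seed, {
    n_from_dpd <- min(round(frac_in_dpd * n_de), sum(in_dpd))
    pool_dpd <- sample(which(in_dpd), n_from_dpd)
    pool_rest <- sample(setdiff(seq_len(nrow(genes)), pool_dpd),
                        n_de - n_from_dpd)
    de_idx <- sample(c(pool_dpd, pool_rest))
    up_idx <- de_idx[seq_len(n_up)]
    down_idx <- de_idx[n_up + seq_len(n_down)]
    fc <- 2^runif(nrow(genes), -0.9, 0.9)  # unchanged: within the threshold
    fc[up_idx] <- fold * 2^runif(n_up, 0.1, 1.5)
    fc[down_idx] <- 1 / (fold * 2^runif(n_down, 0.1, 1.5))
    dir <- rep("unchanged", nrow(genes))
    dir[up_idx] <- "up"
    dir[down_idx] <- "down"
    tibble(gene = genes$name, fold_change = fc, true_direction = dir)
  })
}

#' Simulate per-gene subregion methylation means for test calibration
#'
#' Draws per-gene subregion methylation means for the wildtype and knockout
#' conditions around a common baseline, optionally planting an additive
#' knockout shift in chosen (gene set, subregion) cells. Used to study the
#' calibration and power of [subregion_differential_test()] without
#' simulating reads.
#'
#' @param n_genes Genes per set (default 100).
#' @param base_mean,sd Baseline methylation mean and between-gene standard
#'   deviation.
#' @param shift Named numeric of knockout shifts keyed
#'   `"<set>.<category>"`, e.g. `c(up.five_utr = -0.2)`; unnamed cells get
#'   0.
#' @param seed Integer seed.
#' @return Tidy tibble suitable for [subregion_differential_test()]:
#'   `gene`, `set`, `category`, `mean_wt`, `mean_ko`.
#' @export
simulate_gene_subregion_methylation <- function(n_genes = 100L,
                                                base_mean = 0.7, sd = 0.1,
                                                shift = c(),
                                                seed = 1L) {
  cats <- c("five_utr", "exon", "intron", "three_utr")
  sets <- c("up", "down")
  with_seed(seed, {
    grid <- tidyr::expand_grid(set = sets, category = cats,
                               gene_i = seq_len(n_genes))
    n <- nrow(grid)
    key <- paste(grid$set, grid$category, sep = ".")
    cell_shift <- rep(0, n)
    if (length(shift) > 0) {
      m <- match(key, names(shift))
      cell_shift[!is.na(m)] <- shift[m[!is.na(m)]]
    }
    tibble(
      gene = paste0(grid$set, "_gene", grid$gene_i),
      set = grid$set,
      category = grid$category,
      mean_wt = clip01(rnorm(n, base_mean, sd)),
      mean_ko = clip01(rnorm(n, base_mean + cell_shift, sd))
    )
  })
}
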