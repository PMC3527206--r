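#' Assign a ground-truth methylome to a synthetic genome
#'
#' Draws a true methylation probability for every CpG dyad from a
#' three-component mixture (near-0, intermediate, near-1 Beta components with
#' the spec's weights), then applies condition-specific additive shifts inside
#' planted domains: PMD-like intervals are hypomethylated in both tumour
#' conditions, DPD-like intervals only in the knockout condition. CpG-island
#' CpGs are drawn unmethylated in all conditions; repeat-copy CpGs are drawn
#' around the family mean. Both strands of a dyad receive the same
#' probability; non-CpG cytosines have true methylation 0.
#'
#' Shifts that would leave the unit interval are clipped to [0, 1]; the
#' number of clipped values is recorded in the `clipped` attribute.
#'
#' @param genome A `meth_genome` from [build_genome()].
#' @param spec The originating [genome_spec()]; defaults to `genome$spec`.
#' @return A tibble of class `truth_methylome`: one row per CpG cytosine
#'   (both strands), columns `chrom`, `pos` (0-based), `strand`,
#'   `dyad_start` (position of the forward-strand C), `p_normal`, `p_wt`,
#'   `p_ko`. Attributes: `conversion` (named per-condition conversion rates
#'   from the spec) and `domains` (the planted-domain plan).
#' @examples
#' g <- build_genome(genome_spec(chrom_lengths = c(chr1 = 1e6), seed = 3))
#' truth <- assign_truth_methylome(g)
#' @export
assign_truth_methylome <- function(genome, spec = genome$spec) {
  stopifnot(inherits(genome, "meth_genome"))
  if (is.null(spec)) abort("no `genome_spec` available for truth assignment")
  dyads <- genome$sites %>%
    filter(.data$context == "CG", .data$strand == "+") %>%
    select("chrom", dyad_start = "pos")
  with_seed(spec$seed + 1L, {
    n <- nrow(dyads)
    comp <- sample.int(3L, n, replace = TRUE, prob = spec$meth_weights)
    shp <- spec$meth_shapes
    p0 <- rbeta(n, shp[[1]][1], shp[[1]][2])
    p1 <- rbeta(n, shp[[2]][1], shp[[2]][2])
    p2 <- rbeta(n, shp[[3]][1], shp[[3]][2])
    p_base <- cbind(p0, p1, p2)[cbind(seq_len(n), comp)]

    # overrides: CpG islands unmethylated; repeat copies around family mean
    anns <- genome$annotations
    for (ch in unique(dyads$chrom)) {
      sel <- dyads$chrom == ch
      pos <- dyads$dyad_start[sel]
      rep_ch <- anns$repeats[anns$repeats$chrom == ch, , drop = FALSE]
      if (nrow(rep_ch) > 0) {
        ri <- interval_index(pos, rep_ch$start, rep_ch$end)
        hit <- !is.na(ri)
        if (any(hit)) {
          fam_meth <- spec$repeats$meth[match(rep_ch$family[ri[hit]],
                                              spec$repeats$family)]
          p_base[sel][hit] <- rbeta(sum(hit), fam_meth * 20,
                                    (1 - fam_meth) * 20)
        }
      }
      cgi_ch <- anns$cgi[anns$cgi$chrom == ch, , drop = FALSE]
      if (nrow(cgi_ch) > 0) {
        hit <- !is.na(interval_index(pos, cgi_ch$start, cgi_ch$end))
        if (any(hit)) p_base[sel][hit] <- rbeta(sum(hit), 0.5, 50)
      }
    }

    # condition shifts: planted domains override; elsewhere tumour loss is
    # graded by the lamina-association field (loss = coupling * lambda)
    coupling <- spec$lamina$coupling %||% 0
    if (coupling > 0 && !is.null(genome$lamina)) {
      lam <- lambda_at(genome$lamina, dyads$chrom, dyads$dyad_start)
      shift_wt <- -coupling * lam
      shift_ko <- -coupling * lam
    } else {
      shift_wt <- rep(0, n)
      shift_ko <- rep(0, n)
    }
    dom <- spec$domains
    for (ch in unique(dyads$chrom)) {
      sel <- dyads$chrom == ch
      dom_ch <- dom[dom$chrom == ch, , drop = FALSE]
      if (nrow(dom_ch) == 0) next
      di <- interval_index(dyads$dyad_start[sel], dom_ch$start, dom_ch$end)
      hit <- !is.na(di)
      shift_wt[sel][hit] <- dom_ch$shift_wt[di[hit]]
      shift_ko[sel][hit] <- dom_ch$shift_ko[di[hit]]
    }
    p_wt_raw <- p_base + shift_wt
    p_ko_raw <- p_base + shift_ko
    n_clipped <- sum(p_wt_raw < 0 | p_wt_raw > 1) +
      sum(p_ko_raw < 0 | p_ko_raw > 1)

    truth <- tibble(
      chrom = rep(dyads$chrom, each = 2L),
      pos = as.integer(rep(dyads$dyad_start, each = 2L) + c(0L, 1L)),
      strand = rep(c("+", "-"), n),
      dyad_start = rep(dyads$dyad_start, each = 2L),
      p_normal = rep(clip01(p_base), each = 2L),
      p_wt = rep(clip01(p_wt_raw), each = 2L),
      p_ko = rep(clip01(p_ko_raw), each = 2L)
    )
    attr(truth, "conversion") <- spec$conversion
    attr(truth, "domains") <- spec$domains
    attr(truth, "clipped") <- n_clipped
    class(truth) <- c("truth_methylome", class(truth))
    truth
  })
}

#' @rdname assign_truth_methylome
#' @param truth A `truth_methylome`.
#' @param path Output TSV path (columns chrom, pos, strand, p_normal, p_wt,
#'   p_ko).
#' @export
write_truth <- function(truth, path) {
  readr::write_tsv(truth[, c("chrom", "pos", "strand",
                             "p_normal", "p_wt", "p_ko")],
                   path, progress = FALSE)
  invisible(path)
}
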