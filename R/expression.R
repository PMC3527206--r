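#' Select deregulated genes from a fold-change table
#'
#' Splits genes into upregulated (`fold_change > fold`), downregulated
#' (`fold_change < 1/fold`) and unchanged sets at a strict linear-scale
#' threshold (default 2-fold). Records with non-positive fold changes are
#' rejected and counted.
#'
#' @param expression Tibble with columns `gene`, `fold_change`
#'   (knockout vs wildtype, linear scale, > 0).
#' @param fold Fold-change threshold (default 2).
#' @return The table with a `direction` factor (`up` / `down` /
#'   `unchanged`); attributes `n_up`, `n_down`, `n_unchanged`,
#'   `n_rejected`.
#' @examples
#' tab <- tibble::tibble(gene = c("a", "b", "c"),
#'                       fold_change = c(3, 0.4, 1))
#' select_de_genes(tab)
#' @export
select_de_genes <- function(expression, fold = 2) {
  assert_cols(expression, c("gene", "fold_change"), "expression")
  bad <- !is.finite(expression$fold_change) | expression$fold_change <= 0
  if (any(bad)) {
    warn(sprintf("rejecting %d record(s) with non-positive fold change",
                 sum(bad)))
  }
  x <- expression[!bad, ]
  x$direction <- factor(
    ifelse(x$fold_change > fold, "up",
           ifelse(x$fold_change < 1 / fold, "down", "unchanged")),
    levels = c("up", "down", "unchanged"))
  attr(x, "n_up") <- sum(x$direction == "up")
  attr(x, "n_down") <- sum(x$direction == "down")
  attr(x, "n_unchanged") <- sum(x$direction == "unchanged")
  attr(x, "n_rejected") <- sum(bad)
  x
}

#' Methylation delta of gene-associated windows
#'
#' Looks up, for each gene, the differential-track window containing the
#' gene midpoint (default) or the coverage-weighted mean delta over all
#' windows the gene overlaps, and reports the fraction of genes lying in
#' flagged (hypomethylated) windows. Genes outside the track are excluded
#' and counted.
#'
#' @param genes Gene tibble (`chrom`, `start`, `end`, `name`).
#' @param diff A `diff_track` from [differential_windows()].
#' @param method `"midpoint"` or `"overlap"`.
#' @return Tibble: `gene`, `chrom`, `delta`, `flagged`; attributes
#'   `fraction_flagged` and `n_outside`.
#' @export
gene_window_delta <- function(genes, diff, method = c("midpoint", "overlap")) {
  method <- match.arg(method)
  assert_cols(genes, c("chrom", "start", "end", "name"), "genes")
  if (nrow(genes) == 0) {
    out <- tibble(gene = character(), chrom = character(),
                  delta = double(), flagged = logical())
    attr(out, "fraction_flagged") <- NA_real_
    attr(out, "n_outside") <- 0L
    return(out)
  }
  if (method == "midpoint") {
    mid <- (genes$start + genes$end) %/% 2L
    pts <- tibble(chrom = genes$chrom, pos = mid, gene = genes$name)
    rows <- list()
    for (ch in unique(pts$chrom)) {
      p <- pts[pts$chrom == ch, ]
      d <- diff[diff$chrom == ch, ]
      if (nrow(d) == 0) {
        p$delta <- NA_real_
        p$flagged <- NA
        p$.hit <- FALSE
      } else {
        i <- interval_index(p$pos, d$start, d$end)
        p$delta <- d$delta[i]
        p$flagged <- d$flagged[i]
        p$.hit <- !is.na(i)
      }
      rows[[length(rows) + 1]] <- p
    }
    res <- bind_rows(rows)
    n_outside <- sum(!res$.hit)
    res <- res[res$.hit, ]
    out <- tibble(gene = res$gene, chrom = res$chrom, delta = res$delta,
                  flagged = res$flagged)
  } else {
    feats <- tibble(chrom = genes$chrom, start = genes$start,
                    end = genes$end, gene = genes$name,
                    .fid = seq_len(nrow(genes)))
    wins <- diff %>% mutate(.wid = dplyr::row_number())
    hits <- list()
    for (ch in unique(feats$chrom)) {
      f <- feats[feats$chrom == ch, ]
      d <- wins[wins$chrom == ch, ]
      if (nrow(d) == 0) next
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(start = f$start + 1L, end = f$end),
        IRanges::IRanges(start = d$start + 1L, end = d$end))
      if (length(ov) == 0) next
      q <- S4Vectors::queryHits(ov)
      s <- S4Vectors::subjectHits(ov)
      olap <- pmin(f$end[q], d$end[s]) - pmax(f$start[q], d$start[s])
      hits[[length(hits) + 1]] <- tibble(
        gene = f$gene[q], chrom = ch, delta = d$delta[s],
        flagged = d$flagged[s], wt = olap)
    }
    if (length(hits) == 0) {
      res <- tibble(gene = character(), chrom = character(),
                    delta = double(), flagged = logical())
      n_outside <- nrow(genes)
    } else {
      res <- bind_rows(hits) %>%
        group_by(.data$gene, .data$chrom) %>%
        summarise(delta = sum(.data$delta * .data$wt) / sum(.data$wt),
                  flagged = any(.data$flagged), .groups = "drop")
      n_outside <- nrow(genes) - nrow(res)
    }
    out <- res
  }
  attr(out, "fraction_flagged") <-
    if (nrow(out) > 0) mean(out$flagged, na.rm = TRUE) else NA_real_
  attr(out, "n_outside") <- n_outside
  out
}

#' Subregion differential-methylation tests between conditions
#'
#' For each gene set (up / down) and gene-body subregion (5'-UTR, exon,
#' intron, 3'-UTR), compares per-gene subregion methylation means between
#' wildtype and knockout with an unpaired Welch two-sample t-test (set
#' `paired = TRUE` for a paired test), calling significance at `alpha`.
#' Cells with fewer than 2 genes are skipped and marked `tested = FALSE`.
#'
#' @param subregion_means Tidy tibble with columns `gene`, `set` (`"up"` /
#'   `"down"`), `category` (subregion), `mean_wt`, `mean_ko`.
#' @param alpha Significance level (default 0.01).
#' @param paired Use a paired t-test (default FALSE).
#' @return Tibble of class `subregion_tests`: `set`, `category`, `n`,
#'   `mean_wt`, `mean_ko`, `statistic`, `p_value`, `significant`,
#'   `tested`.
#' @export
subregion_differential_test <- function(subregion_means, alpha = 0.01,
                                        paired = FALSE) {
  assert_cols(subregion_means,
              c("gene", "set", "category", "mean_wt", "mean_ko"),
              "subregion_means")
  cell_test <- function(df, key) {
    tt <- if (nrow(df) >= 2) {
      tryCatch(t.test(df$mean_wt, df$mean_ko, paired = paired,
                      var.equal = FALSE),
               error = function(e) NULL)
    } else NULL
    tibble(n = nrow(df),
           mean_wt = mean(df$mean_wt), mean_ko = mean(df$mean_ko),
           statistic = if (is.null(tt)) NA_real_ else unname(tt$statistic),
           p_value = if (is.null(tt)) NA_real_ else tt$p.value)
  }
  out <- subregion_means %>%
    group_by(.data$set, .data$category) %>%
    group_modify(cell_test) %>%
    ungroup() %>%
    mutate(tested = !is.na(.data$p_value),
           significant = !is.na(.data$p_value) & .data$p_value < alpha)
  class(out) <- c("subregion_tests", class(out))
  attr(out, "alpha") <- alpha
  out
}
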