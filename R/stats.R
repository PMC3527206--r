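#' Classify methylation ratios into states
#'
#' A site is unmethylated when its ratio is below `t_low`, fully methylated
#' when above `t_high`, and partially methylated otherwise. The boundary
#' values themselves (default 0.05 and 0.95) fall in the partial class: the
#' outer classes use strict inequalities.
#'
#' @param ratio Numeric vector in \[0, 1\].
#' @param t_low,t_high State thresholds (defaults 0.05 / 0.95).
#' @return Factor with levels `unmethylated`, `partial`, `fully_methylated`.
#' @examples
#' classify_methylation_state(c(0.04, 0.05, 0.5, 0.96))
#' @export
classify_methylation_state <- function(ratio, t_low = 0.05, t_high = 0.95) {
  if (any(is.na(ratio)) || any(ratio < 0 | ratio > 1)) {
    abort("`ratio` must be in [0, 1] with no missing values")
  }
  factor(ifelse(ratio < t_low, "unmethylated",
                ifelse(ratio > t_high, "fully_methylated", "partial")),
         levels = c("unmethylated", "partial", "fully_methylated"))
}

#' Binned methylation-ratio distribution and state fractions
#'
#' Builds the histogram of per-site methylation ratios over \[0, 1\] together
#' with the three-state classification fractions (see
#' [classify_methylation_state()]). Sites without informative coverage are
#' excluded.
#'
#' @param calls A `meth_calls` tibble.
#' @param context Restrict to `"CG"` or `"CH"` sites, or `"all"`.
#' @param bin_width Histogram bin width (default 0.05).
#' @param t_low,t_high State thresholds.
#' @return Object of class `meth_state_bins`: list with `states` (tibble
#'   `state`, `n`, `fraction`), `histogram` (tibble `bin_start`, `bin_end`,
#'   `n`, `fraction`) and `n_sites`.
#' @export
bin_distribution <- function(calls, context = "CG", bin_width = 0.05,
                             t_low = 0.05, t_high = 0.95) {
  assert_cols(calls, c("context", "ratio", "n_total"), "calls")
  x <- calls[calls$n_total > 0, ]
  if (context != "all") x <- x[x$context == context, ]
  if (nrow(x) == 0) abort("no called sites of the requested context")
  st <- classify_methylation_state(x$ratio, t_low, t_high)
  states <- tibble(
    state = levels(st),
    n = as.integer(table(st)),
  ) %>% mutate(fraction = .data$n / sum(.data$n))
  breaks <- seq(0, 1, by = bin_width)
  if (tail(breaks, 1) < 1) breaks <- c(breaks, 1)
  # left-closed bins [b_i, b_{i+1}); ratio == 1 counted in the last bin
  bi <- pmin(findInterval(x$ratio, breaks), length(breaks) - 1L)
  histogram <- tibble(
    bin_start = head(breaks, -1), bin_end = breaks[-1],
    n = tabulate(bi, nbins = length(breaks) - 1L)
  ) %>% mutate(fraction = .data$n / sum(.data$n))
  structure(list(states = states, histogram = histogram, n_sites = nrow(x),
                 t_low = t_low, t_high = t_high),
            class = "meth_state_bins")
}

#' @export
print.meth_state_bins <- function(x, ...) {
  cat("<meth_state_bins> ", x$n_sites, " sites\n", sep = "")
  f <- setNames(x$states$fraction, x$states$state)
  cat(sprintf("  unmethylated %.1f%% | partial %.1f%% | fully methylated %.1f%%\n",
              100 * f[["unmethylated"]], 100 * f[["partial"]],
              100 * f[["fully_methylated"]]))
  invisible(x)
}

#' @export
tidy.meth_state_bins <- function(x, ...) x$states

#' @export
glance.meth_state_bins <- function(x, ...) {
  f <- setNames(x$states$fraction, x$states$state)
  tibble(n_sites = x$n_sites,
         frac_unmethylated = f[["unmethylated"]],
         frac_partial = f[["partial"]],
         frac_fully_methylated = f[["fully_methylated"]])
}

#' Feature-level average methylation
#'
#' For each annotated feature, averages per-site methylation ratios over the
#' CpG sites inside the interval whose coverage is at least `min_coverage`;
#' features with fewer than `min_cpgs` qualifying sites are excluded from
#' the category average and counted separately. Both strands of a dyad are
#' pooled into the per-feature mean.
#'
#' @param calls A `meth_calls` tibble.
#' @param features Tibble of intervals: `chrom`, `start`, `end`, optional
#'   `name` and `category` (defaults to `"feature"`).
#' @param min_cpgs Minimum qualifying CpG sites per feature (default 3).
#' @param min_coverage Minimum reads per site (default 3).
#' @param context Site context to use (default `"CG"`).
#' @return Object of class `feature_meth`: `features` (per-feature tibble
#'   with `n_sites`, `mean_ratio`, `included`) and `summary` (per-category
#'   tibble with `n_features`, `n_excluded`, `mean_ratio` -- the mean over
#'   included features' means).
#' @export
feature_methylation <- function(calls, features, min_cpgs = 3,
                                min_coverage = 3, context = "CG") {
  assert_cols(calls, c("chrom", "pos", "context", "n_total", "ratio"), "calls")
  assert_cols(features, c("chrom", "start", "end"), "features")
  if (any(features$end <= features$start)) {
    abort("features must be non-degenerate intervals")
  }
  feats <- as_tibble(features)
  if (!"name" %in% names(feats)) feats$name <- paste0("feature", seq_len(nrow(feats)))
  if (!"category" %in% names(feats)) feats$category <- "feature"
  x <- calls[calls$n_total >= min_coverage, ]
  if (context != "all") x <- x[x$context == context, ]

  per_feat <- feats %>% mutate(.fid = dplyr::row_number())
  hits <- overlap_pairs(x, per_feat)
  stats <- hits %>%
    group_by(.data$.fid) %>%
    summarise(n_sites = dplyr::n(), mean_ratio = mean(.data$ratio),
              .groups = "drop")
  per_feat <- per_feat %>%
    left_join(stats, by = ".fid") %>%
    mutate(n_sites = dplyr::coalesce(.data$n_sites, 0L),
           included = .data$n_sites >= min_cpgs) %>%
    select(-".fid")
  summary <- per_feat %>%
    group_by(.data$category) %>%
    summarise(n_features = sum(.data$included),
              n_excluded = sum(!.data$included),
              mean_ratio = if (any(.data$included))
                mean(.data$mean_ratio[.data$included]) else NA_real_,
              .groups = "drop")
  if (all(!per_feat$included)) {
    warn("no features pass the filters; category averages undefined")
  }
  structure(list(features = per_feat, summary = summary,
                 min_cpgs = min_cpgs, min_coverage = min_coverage),
            class = "feature_meth")
}

#' @export
print.feature_meth <- function(x, ...) {
  cat("<feature_meth> filters: >=", x$min_cpgs, "CpGs, coverage >=",
      x$min_coverage, "\n")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.feature_meth <- function(x, ...) x$features

#' @export
glance.feature_meth <- function(x, ...) x$summary

# (site, feature) overlap pairs; returns site rows with .fid attached.
overlap_pairs <- function(sites, features) {
  out <- list()
  for (ch in intersect(unique(sites$chrom), unique(features$chrom))) {
    s <- sites[sites$chrom == ch, ]
    f <- features[features$chrom == ch, ]
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(start = s$pos + 1L, width = 1L),
      IRanges::IRanges(start = f$start + 1L, end = f$end))
    if (length(ov) == 0) next
    rows <- s[S4Vectors::queryHits(ov), ]
    rows$.fid <- f$.fid[S4Vectors::subjectHits(ov)]
    out[[length(out) + 1]] <- rows
  }
  if (length(out) == 0) {
    empty <- sites[0, ]
    empty$.fid <- integer(0)
    return(empty)
  }
  bind_rows(out)
}

#' Partition CpG calls into genic compartments and summarise methylation
#'
#' Defines promoters as the 1-kb region upstream of each annotated
#' transcription start site on the coding strand (`[TSS-1000, TSS)` for
#' plus-strand genes, `[TSS, TSS+1000)` on reference coordinates for
#' minus-strand genes), gene bodies as the union of annotated subregions,
#' and intergenic space as the remainder. Each CpG site is assigned to
#' exactly one compartment with priority promoter > gene body > intergenic;
#' within gene bodies, overlapping subregion records resolve with priority
#' exon > UTR > intron. Average methylation is reported per compartment and
#' per gene-body subregion (5'-UTR, exon, intron, 3'-UTR).
#'
#' @param calls A `meth_calls` tibble.
#' @param genes Gene tibble from the simulator (columns `chrom`, `start`,
#'   `end`, `name`, `strand`; `tss` optional -- derived from strand if
#'   absent). Genes without strand are rejected.
#' @param subregions Subregion tibble (`chrom`, `start`, `end`, `gene`,
#'   `category` in `five_utr`/`exon`/`intron`/`three_utr`).
#' @param min_coverage Minimum reads per site (default 1).
#' @return List of class `genic_partition`: `compartments` (tibble
#'   `category`, `n_sites`, `mean_ratio` for promoter / gene_body /
#'   intergenic), `subregions` (same per gene-body subregion), and `sites`
#'   (the calls annotated with their assigned compartment).
#' @export
partition_genic <- function(calls, genes, subregions, min_coverage = 1) {
  assert_cols(genes, c("chrom", "start", "end", "strand"), "genes")
  if (any(is.na(genes$strand)) || !all(genes$strand %in% c("+", "-"))) {
    abort("all genes must have strand '+' or '-'")
  }
  assert_cols(subregions, c("chrom", "start", "end", "category"), "subregions")
  x <- calls[calls$n_total >= min_coverage & calls$context == "CG", ]

  tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  promoters <- tibble(
    chrom = genes$chrom,
    start = as.integer(ifelse(genes$strand == "+", tss - 1000L, tss)),
    end = as.integer(ifelse(genes$strand == "+", tss, tss + 1000L)))
  promoters$start <- pmax(promoters$start, 0L)

  sub_rank <- c(exon = 1L, five_utr = 2L, three_utr = 2L, intron = 3L)
  layers <- bind_rows(
    promoters %>% mutate(category = "promoter", priority = 0L),
    subregions %>%
      select("chrom", "start", "end", "category") %>%
      mutate(priority = dplyr::coalesce(sub_rank[.data$category], 3L))
  )
  layers$.fid <- seq_len(nrow(layers))
  hits <- overlap_pairs(x %>% mutate(.sid = dplyr::row_number()), layers)
  assigned <- hits %>%
    mutate(category = layers$category[.data$.fid],
           priority = layers$priority[.data$.fid]) %>%
    group_by(.data$.sid) %>%
    arrange(.data$priority, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup()
  x$category <- "intergenic"
  x$category[assigned$.sid] <- assigned$category
  x$compartment <- ifelse(x$category == "promoter", "promoter",
                          ifelse(x$category == "intergenic", "intergenic",
                                 "gene_body"))
  if (!any(x$compartment == "intergenic")) {
    warn("intergenic partition is empty")
  }
  compartments <- x %>%
    group_by(category = .data$compartment) %>%
    summarise(n_sites = dplyr::n(), mean_ratio = mean(.data$ratio),
              .groups = "drop")
  subregion_summary <- x %>%
    filter(.data$compartment == "gene_body") %>%
    group_by(category = .data$category) %>%
    summarise(n_sites = dplyr::n(), mean_ratio = mean(.data$ratio),
              .groups = "drop")
  structure(list(compartments = compartments, subregions = subregion_summary,
                 sites = x),
            class = "genic_partition")
}

#' @export
print.genic_partition <- function(x, ...) {
  cat("<genic_partition>\n")
  print(x$compartments)
  invisible(x)
}

#' Per-gene subregion methylation means
#'
#' Pools the qualifying CpG sites of all records of each (gene, subregion)
#' pair -- e.g. all exons of a gene -- into one mean methylation ratio.
#' Used to compare subregion methylation between conditions gene-by-gene.
#'
#' @param calls A `meth_calls` tibble.
#' @param subregions Subregion tibble (`chrom`, `start`, `end`, `gene`,
#'   `category`).
#' @param min_coverage Minimum reads per site (default 1).
#' @return Tibble: `gene`, `category`, `n_sites`, `mean_ratio`.
#' @export
gene_subregion_means <- function(calls, subregions, min_coverage = 1) {
  assert_cols(subregions, c("chrom", "start", "end", "gene", "category"),
              "subregions")
  x <- calls[calls$n_total >= min_coverage & calls$context == "CG", ]
  feats <- subregions %>% mutate(.fid = dplyr::row_number())
  hits <- overlap_pairs(x, feats)
  hits %>%
    mutate(gene = feats$gene[.data$.fid],
           category = feats$category[.data$.fid]) %>%
    group_by(.data$gene, .data$category) %>%
    summarise(n_sites = dplyr::n(), mean_ratio = mean(.data$ratio),
              .groups = "drop")
}
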