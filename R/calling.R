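#' Strand-aware per-cytosine methylation calling
#'
#' For every reference cytosine of the requested context, on each strand
#' independently, counts methylated (C) and unmethylated (T) base calls from
#' the reads informative for that strand: original-top reads (`protocol ==
#' "+"`) inform forward-strand cytosines; original-bottom reads (`protocol
#' == "-"`) inform reverse-strand cytosines, whose calls appear in forward
#' orientation as G (methylated) / A (converted). Other base calls
#' (mismatches) are ignored; sites with no informative coverage are omitted.
#' Reads without a protocol tag are skipped and counted in the `n_skipped`
#' attribute.
#'
#' With `pool_strands = TRUE`, counts for the two cytosines of each CpG dyad
#' are summed into a single record at the dyad start with `strand = "*"`
#' (CH-context sites are never pooled). Strands are kept separate by
#' default.
#'
#' @param reads A `bs_reads` tibble (typically from [read_bs_sam()] then
#'   [trim_reads()]).
#' @param genome A `meth_genome` (provides reference cytosine sites and
#'   their contexts).
#' @param context `"CG"`, `"CH"` or `"all"`.
#' @param pool_strands Pool CpG dyad counts across strands (default FALSE).
#' @return A tibble of class `meth_calls`: `chrom`, `pos` (0-based),
#'   `strand`, `context`, `n_meth`, `n_total`, `ratio`.
#' @examples
#' g <- build_genome(genome_spec(chrom_lengths = c(chr1 = 5e4), seed = 2))
#' tr <- assign_truth_methylome(g)
#' reads <- simulate_bisulfite_reads(g, tr, "normal", coverage = 4, seed = 5)
#' calls <- call_methylation(reads, g)
#' @export
call_methylation <- function(reads, genome, context = c("CG", "CH", "all"),
                             pool_strands = FALSE) {
  context <- match.arg(context)
  assert_cols(reads, c("chrom", "pos", "protocol", "seq"), "reads")
  no_tag <- is.na(reads$protocol) | !(reads$protocol %in% c("+", "-"))
  n_skipped <- sum(no_tag)
  reads <- reads[!no_tag, ]
  sites <- genome$sites
  if (context != "all") sites <- sites[sites$context == context, ]

  res <- list()
  for (ch in intersect(unique(sites$chrom), unique(reads$chrom))) {
    sites_ch <- sites[sites$chrom == ch, ]
    reads_ch <- reads[reads$chrom == ch, ]
    for (st in c("+", "-")) {
      s_st <- sites_ch[sites_ch$strand == st, ]
      r_st <- reads_ch[reads_ch$protocol == st, ]
      if (nrow(s_st) == 0 || nrow(r_st) == 0) next
      cnt <- pileup_counts(s_st$pos, r_st$pos, r_st$seq,
                           meth_base = if (st == "+") "C" else "G",
                           unmeth_base = if (st == "+") "T" else "A")
      keep <- cnt$n_total > 0
      if (!any(keep)) next
      res[[length(res) + 1]] <- tibble(
        chrom = ch, pos = s_st$pos[keep], strand = st,
        context = s_st$context[keep],
        n_meth = cnt$n_meth[keep], n_total = cnt$n_total[keep])
    }
  }
  calls <- if (length(res) > 0) bind_rows(res) else {
    tibble(chrom = character(), pos = integer(), strand = character(),
           context = character(), n_meth = integer(), n_total = integer())
  }
  if (pool_strands && nrow(calls) > 0) {
    cg <- calls[calls$context == "CG", ]
    other <- calls[calls$context != "CG", ]
    cg <- cg %>%
      mutate(pos = .data$pos - (.data$strand == "-")) %>%
      group_by(.data$chrom, .data$pos) %>%
      summarise(strand = "*", context = "CG",
                n_meth = sum(.data$n_meth), n_total = sum(.data$n_total),
                .groups = "drop")
    calls <- bind_rows(cg, other)
  }
  calls <- calls %>%
    mutate(ratio = .data$n_meth / .data$n_total) %>%
    arrange(.data$chrom, .data$pos, .data$strand)
  attr(calls, "n_skipped") <- n_skipped
  class(calls) <- c("meth_calls", class(calls))
  calls
}

# Count methylated / informative base calls over sorted site positions for
# one chromosome strand. `site_pos`, `read_pos` 0-based; reads ungapped.
pileup_counts <- function(site_pos, read_pos, read_seq,
                          meth_base, unmeth_base,
                          count_all_bases = FALSE) {
  len <- nchar(read_seq)
  i_lo <- findInterval(read_pos - 0.5, site_pos) + 1L
  i_hi <- findInterval(read_pos + len - 0.5, site_pos)
  cnt <- pmax(i_hi - i_lo + 1L, 0L)
  nsite <- length(site_pos)
  if (sum(cnt) == 0) {
    return(list(n_meth = integer(nsite), n_total = integer(nsite)))
  }
  keep <- cnt > 0
  si <- sequence(cnt[keep], from = i_lo[keep])
  ri <- rep(which(keep), cnt[keep])
  off <- site_pos[si] - read_pos[ri] + 1L
  base <- substring(read_seq[ri], off, off)
  meth <- base == meth_base
  informative <- if (count_all_bases) rep(TRUE, length(base)) else
    meth | base == unmeth_base
  list(n_meth = tabulate(si[meth], nbins = nsite),
       n_total = tabulate(si[informative], nbins = nsite))
}

#' Estimate the bisulfite conversion rate from non-CpG positions
#'
#' Counts cytosines called in all mapped reads at all non-CpG cytosine
#' positions of the reference (strand-aware: reverse-strand cytosines are
#' reference G positions, read as G/A in forward orientation), divides by
#' the number of all aligned base calls at those positions, and subtracts
#' the ratio from 1. Assumes non-CpG methylation is negligible, so every
#' retained C call reflects a conversion failure.
#'
#' @param reads A `bs_reads` tibble.
#' @param genome A `meth_genome`.
#' @return An object of class `conversion_estimate`: `n_c` (cytosine
#'   calls), `n_bases` (all aligned base calls at non-CpG cytosine
#'   positions), `rate` (`1 - n_c / n_bases`).
#' @export
estimate_conversion <- function(reads, genome) {
  assert_cols(reads, c("chrom", "pos", "protocol", "seq"), "reads")
  reads <- reads[!is.na(reads$protocol) & reads$protocol %in% c("+", "-"), ]
  sites <- genome$sites[genome$sites$context == "CH", ]
  n_c <- 0L
  n_bases <- 0L
  for (ch in intersect(unique(sites$chrom), unique(reads$chrom))) {
    sites_ch <- sites[sites$chrom == ch, ]
    reads_ch <- reads[reads$chrom == ch, ]
    for (st in c("+", "-")) {
      s_st <- sites_ch[sites_ch$strand == st, ]
      r_st <- reads_ch[reads_ch$protocol == st, ]
      if (nrow(s_st) == 0 || nrow(r_st) == 0) next
      cnt <- pileup_counts(s_st$pos, r_st$pos, r_st$seq,
                           meth_base = if (st == "+") "C" else "G",
                           unmeth_base = if (st == "+") "T" else "A",
                           count_all_bases = TRUE)
      n_c <- n_c + sum(cnt$n_meth)
      n_bases <- n_bases + sum(cnt$n_total)
    }
  }
  if (n_bases == 0) {
    abort("no aligned bases at non-CpG cytosine positions; conversion rate undefined")
  }
  structure(list(n_c = n_c, n_bases = n_bases, rate = 1 - n_c / n_bases),
            class = "conversion_estimate")
}

#' @export
print.conversion_estimate <- function(x, ...) {
  cat(sprintf(
    "<conversion_estimate> rate = %.4f (%d C calls / %d bases at non-CpG cytosines)\n",
    x$rate, x$n_c, x$n_bases))
  invisible(x)
}

#' @export
tidy.conversion_estimate <- function(x, ...) {
  tibble(n_c = x$n_c, n_bases = x$n_bases, rate = x$rate)
}

#' Average methylation ratio over called sites
#'
#' Arithmetic mean of per-site methylation ratios over all sites with
#' informative coverage (the genome-wide "average CpG methylation ratio").
#'
#' @param calls A `meth_calls` tibble.
#' @return A single numeric value.
#' @export
mean_methylation <- function(calls) {
  assert_cols(calls, c("ratio", "n_total"), "calls")
  x <- calls$ratio[calls$n_total > 0]
  if (length(x) == 0) abort("no called sites with coverage")
  mean(x)
}

#' Read and write per-cytosine call tables
#'
#' Stable TSV dialect: columns `chrom`, `pos` (0-based), `strand`,
#' `context`, `n_meth`, `n_total`, `ratio`. `calls_to_bedgraph()` converts
#' calls to a single-base bedGraph of methylation ratios.
#'
#' @param calls A `meth_calls` tibble.
#' @param path File path.
#' @return `read_calls()` returns a `meth_calls` tibble.
#' @export
write_calls <- function(calls, path) {
  readr::write_tsv(calls[, c("chrom", "pos", "strand", "context",
                             "n_meth", "n_total", "ratio")],
                   path, progress = FALSE)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  x <- readr::read_tsv(path, col_types = "cicciid", progress = FALSE)
  class(x) <- c("meth_calls", class(x))
  x
}

#' @rdname write_calls
#' @export
calls_to_bedgraph <- function(calls) {
  tibble(chrom = calls$chrom, start = calls$pos, end = calls$pos + 1L,
         value = calls$ratio)
}
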