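#' Read aligned bisulfite reads from SAM/BAM
#'
#' Loads aligned reads through Rsamtools (SAM input is converted to BAM in a
#' temporary directory first). Unmapped, secondary, duplicate and
#' supplementary alignments are dropped via SAM flags -- the caller's
#' equivalent of upstream unique-mapping filters. The bisulfite protocol
#' strand is taken from the `ZS` tag (`+` original-top, `-`
#' original-bottom); reads without the tag are kept with `protocol = NA` and
#' are skipped (and counted) by downstream calling. Reads with gapped
#' alignments (CIGAR operations other than M) are excluded here and counted
#' in the `n_gapped` attribute; the pileup supports ungapped alignments.
#'
#' @param path SAM or BAM file.
#' @param chrom Optional chromosome name(s) to restrict to.
#' @return A `bs_reads` tibble: `qname`, `chrom`, `pos` (0-based),
#'   `protocol`, `reverse`, `seq`, `qual`, with attribute `n_gapped`.
#' @export
read_bs_sam <- function(path, chrom = NULL) {
  is_bam <- grepl("\\.bam$", path, ignore.case = TRUE)
  bam <- if (is_bam) path else {
    dest <- tempfile(fileext = "")
    Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                     indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isDuplicate = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq", "qual"),
    tag = "ZS", flag = flag)
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  zs <- res$tag$ZS
  if (is.null(zs)) zs <- rep(NA_character_, length(res$pos))
  out <- tibble(
    qname = res$qname,
    chrom = as.character(res$rname),
    pos = res$pos - 1L,
    protocol = as.character(zs),
    reverse = bitwAnd(res$flag, 16L) > 0L,
    seq = as.character(res$seq),
    qual = as.character(res$qual),
    cigar = res$cigar
  )
  if (!is.null(chrom)) out <- out[out$chrom %in% chrom, ]
  gapped <- grepl("[^0-9M]", out$cigar)
  n_gapped <- sum(gapped)
  if (n_gapped > 0) {
    warn(sprintf("skipping %d gapped alignment(s); pileup is ungapped-only",
                 n_gapped))
  }
  out <- out[!gapped, setdiff(names(out), "cigar")]
  attr(out, "n_gapped") <- n_gapped
  class(out) <- c("bs_reads", class(out))
  out
}
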