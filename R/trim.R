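#' Trim aligned bisulfite reads by length and terminal base quality
#'
#' Each read is first truncated to `max_length` bases counted from its
#' sequencing 5' end (the left end of the stored sequence for
#' forward-oriented alignments, the right end for reverse-oriented ones),
#' then maximal terminal stretches of bases with Phred quality below
#' `min_quality` are removed. By default both ends are quality-trimmed; set
#' `both_ends = FALSE` to restrict trimming to the sequencing 3' end.
#' Alignment start positions are shifted by the number of bases removed from
#' the left (reference) end, so trimmed reads remain correctly anchored.
#'
#' Reads emptied by trimming, and reads without base qualities (`"*"` or
#' `NA`), are discarded; their counts are recorded in the `n_discarded` and
#' `n_no_quality` attributes.
#'
#' @param reads A `bs_reads` tibble (columns `pos`, `reverse`, `seq`,
#'   `qual`).
#' @param max_length Maximum retained read length (default 80).
#' @param min_quality Minimum terminal Phred quality (default 30).
#' @param both_ends Quality-trim both ends (default) or only the sequencing
#'   3' end.
#' @return The trimmed `bs_reads` tibble.
#' @examples
#' r <- tibble::tibble(qname = "r1", chrom = "chr1", pos = 10L,
#'                     protocol = "+", reverse = FALSE,
#'                     seq = strrep("ACGT", 25), qual = strrep("I", 100))
#' nchar(trim_reads(r)$seq)
#' @export
trim_reads <- function(reads, max_length = 80L, min_quality = 30L,
                       both_ends = TRUE) {
  assert_cols(reads, c("pos", "reverse", "seq", "qual"), "reads")
  no_qual <- is.na(reads$qual) | reads$qual == "*" | reads$qual == ""
  if (any(no_qual)) {
    warn(sprintf("discarding %d read(s) without base qualities",
                 sum(no_qual)))
  }
  r <- reads[!no_qual, ]
  len <- nchar(r$seq)

  # 1) cap at max_length from the sequencing 5' end
  keep <- pmin(len, max_length)
  left0 <- ifelse(r$reverse, len - keep, 0L)  # bases dropped on the left
  r$seq <- substr(r$seq, left0 + 1L, left0 + keep)
  r$qual <- substr(r$qual, left0 + 1L, left0 + keep)
  r$pos <- r$pos + left0

  # 2) terminal low-quality stretches; trim offsets depend only on the
  #    quality string, so compute once per distinct string
  uq <- unique(r$qual)
  thr <- min_quality + 33L
  trims <- vapply(uq, function(q) {
    qi <- utf8ToInt(q)
    low <- qi < thr
    n <- length(qi)
    left <- if (all(low)) n else which(!low)[1] - 1L
    right <- if (all(low)) n else n - max(which(!low))
    c(left, right)
  }, integer(2))
  m <- match(r$qual, uq)
  lt <- unname(trims[1, m])
  rt <- unname(trims[2, m])
  if (!both_ends) {
    # sequencing 3' end only: right end of stored string for forward reads,
    # left end for reverse reads
    lt <- ifelse(r$reverse, lt, 0L)
    rt <- ifelse(r$reverse, 0L, rt)
  }
  newlen <- nchar(r$seq) - lt - rt
  empty <- newlen <= 0L
  r$pos <- r$pos + lt
  r$seq <- substr(r$seq, lt + 1L, lt + pmax(newlen, 0L))
  r$qual <- substr(r$qual, lt + 1L, lt + pmax(newlen, 0L))
  out <- r[!empty, ]
  attr(out, "n_discarded") <- sum(empty)
  attr(out, "n_no_quality") <- sum(no_qual)
  class(out) <- unique(c("bs_reads", class(out)))
  out
}
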