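#' Simulate aligned bisulfite reads from a truth methylome
#'
#' Samples single-end reads uniformly from both protocol strands
#' (original-top reads inform forward-strand cytosines, original-bottom reads
#' inform reverse-strand cytosines), applies per-molecule bisulfite chemistry
#' -- a truly methylated cytosine is always read as C; a truly unmethylated
#' cytosine is read as T with probability `conversion_rate` and as C
#' (conversion failure) otherwise -- and adds independent substitution errors
#' at `error_rate`. Original-bottom reads are reported in forward reference
#' orientation (SAM convention): their cytosines appear at reference G
#' positions, methylated as G, converted as A.
#'
#' Base qualities follow a two-level profile: `qual_high` over the read
#' interior and `qual_tail` over the last `tail_len` sequenced cycles, so the
#' quality-trimming rule in [trim_reads()] is exercised. For reverse-oriented
#' reads the low-quality tail sits at the left end in reference orientation.
#'
#' @param genome A `meth_genome`.
#' @param truth A `truth_methylome` from [assign_truth_methylome()].
#' @param condition One of `"normal"`, `"wt"`, `"ko"`: selects the truth
#'   column and, when `conversion_rate` is `NULL`, the spec's per-condition
#'   conversion rate.
#' @param coverage Target mean genome coverage (> 0).
#' @param read_length Read length in bp (default 105).
#' @param conversion_rate Bisulfite conversion rate in \[0.9, 1\].
#' @param error_rate Per-base substitution error probability.
#' @param seed Integer seed; identical arguments and seed give identical
#'   read sets.
#' @param qual_high,qual_tail,tail_len Phred quality profile parameters.
#' @return Tibble of class `bs_reads`: `qname`, `chrom`, `pos` (0-based
#'   leftmost), `protocol` (`"+"` original-top / `"-"` original-bottom),
#'   `reverse` (alignment orientation), `seq`, `qual` (Phred+33).
#' @examples
#' g <- build_genome(genome_spec(chrom_lengths = c(chr1 = 5e4), seed = 2))
#' tr <- assign_truth_methylome(g)
#' reads <- simulate_bisulfite_reads(g, tr, "normal", coverage = 2, seed = 9)
#' @export
simulate_bisulfite_reads <- function(genome, truth,
                                     condition = c("normal", "wt", "ko"),
                                     coverage,
                                     read_length = 105L,
                                     conversion_rate = NULL,
                                     error_rate = 0.001,
                                     seed = 1L,
                                     qual_high = 38L, qual_tail = 20L,
                                     tail_len = 5L) {
  condition <- match.arg(condition)
  if (!is.numeric(coverage) || coverage <= 0) abort("`coverage` must be > 0")
  if (read_length > min(genome$chrom_lengths)) {
    abort("`read_length` exceeds the shortest chromosome")
  }
  if (is.null(conversion_rate)) {
    conversion_rate <- unname(attr(truth, "conversion")[condition])
  }
  if (is.na(conversion_rate) || conversion_rate < 0.9 || conversion_rate > 1) {
    abort("`conversion_rate` must be in [0.9, 1]")
  }
  p_col <- paste0("p_", condition)
  rl <- as.integer(read_length)

  qual_fwd <- paste0(strrep(intToUtf8(qual_high + 33L), max(rl - tail_len, 0)),
                     strrep(intToUtf8(qual_tail + 33L), min(tail_len, rl)))
  qual_rev <- paste(rev(strsplit(qual_fwd, "")[[1]]), collapse = "")

  with_seed(seed, {
    chunks <- list()
    for (ch in names(genome$seq)) {
      L <- genome$chrom_lengths[[ch]]
      truth_ch <- truth[truth$chrom == ch, ]
      sites_ch <- genome$sites[genome$sites$chrom == ch, ]
      for (st in c("+", "-")) {
        # fully-converted template: every cytosine of this protocol strand
        # reads as converted (T on the forward strand, A at reverse-strand
        # cytosines, i.e. reference G positions)
        template <- if (st == "+") chartr("C", "T", genome$seq[[ch]])
                    else chartr("G", "A", genome$seq[[ch]])
        # informative cytosine sites for this protocol strand, with truth p
        cg <- truth_ch[truth_ch$strand == st, ]
        chs <- sites_ch[sites_ch$strand == st & sites_ch$context == "CH", ]
        site_pos <- c(cg$pos, chs$pos)
        site_p <- c(cg[[p_col]], rep(0, nrow(chs)))
        ord <- order(site_pos)
        site_pos <- site_pos[ord]
        site_p <- site_p[ord]

        n_reads <- rpois(1, L * coverage / (2 * rl))
        if (n_reads == 0) next
        starts <- sample.int(L - rl + 1L, n_reads, replace = TRUE) - 1L
        seqs <- simulate_strand_reads(template, starts, rl, st,
                                      site_pos, site_p,
                                      conversion_rate, error_rate)
        chunks[[length(chunks) + 1]] <- tibble(
          qname = sprintf("%s_%s%s_%d", condition, ch,
                          ifelse(st == "+", "t", "b"), seq_len(n_reads)),
          chrom = ch, pos = starts, protocol = st, reverse = st == "-",
          seq = seqs, qual = if (st == "+") qual_fwd else qual_rev)
      }
    }
    out <- bind_rows(chunks)
    class(out) <- c("bs_reads", class(out))
    out
  })
}

# Apply single-character edits to a character vector: element `idx[k]` gets
# `ch[k]` written at 1-based position `offset[k]`. Elements with several
# edits are handled in rounds so each round is one vectorised substr<-.
apply_string_edits <- function(x, idx, offset, ch) {
  if (length(idx) == 0) return(x)
  ord <- order(idx)
  idx <- idx[ord]
  offset <- offset[ord]
  ch <- ch[ord]
  rank <- sequence(rle(idx)$lengths)
  for (r in seq_len(max(rank))) {
    sel <- rank == r
    i <- idx[sel]
    y <- x[i]
    substr(y, offset[sel], offset[sel]) <- ch[sel]
    x[i] <- y
  }
  x
}

# Vectorised read construction for one chromosome / protocol strand: reads
# start as substrings of the fully-converted template; methylated or
# unconverted cytosines are then restored, and substitution errors applied,
# as sparse per-read string edits.
simulate_strand_reads <- function(template, starts, rl, strand,
                                  site_pos, site_p,
                                  conversion_rate, error_rate) {
  n <- length(starts)
  meth_base <- if (strand == "+") "C" else "G"
  bases <- c("A", "C", "G", "T")
  out <- substring(template, starts + 1L, starts + rl)
  # (read, site) incidences via interval lookup on sorted site positions
  if (length(site_pos) > 0) {
    i_lo <- findInterval(starts - 0.5, site_pos) + 1L
    i_hi <- findInterval(starts + rl - 0.5, site_pos)
    cnt <- pmax(i_hi - i_lo + 1L, 0L)
    if (sum(cnt) > 0) {
      keep <- cnt > 0
      si <- sequence(cnt[keep], from = i_lo[keep])
      ri <- rep(seq_len(n)[keep], cnt[keep])
      np <- length(si)
      meth <- runif(np) < site_p[si]
      call_c <- meth | (runif(np) < (1 - conversion_rate))
      out <- apply_string_edits(out, ri[call_c],
                                site_pos[si[call_c]] - starts[ri[call_c]] + 1L,
                                rep(meth_base, sum(call_c)))
    }
  }
  if (error_rate > 0) {
    n_err <- rbinom(1, n * rl, error_rate)
    if (n_err > 0) {
      epos <- sort(sample.int(n * rl, n_err))
      ri <- (epos - 1L) %/% rl + 1L
      off <- epos - (ri - 1L) * rl
      cur <- match(substring(out[ri], off, off), bases)
      new <- bases[(cur - 1L + sample.int(3L, n_err, replace = TRUE)) %% 4L + 1L]
      out <- apply_string_edits(out, ri, off, new)
    }
  }
  out
}

#' Write simulated reads as SAM
#'
#' Emits an unsorted SAM with `@SQ` header lines and a `ZS` tag recording the
#' bisulfite protocol strand (`ZS:Z:+` original-top, `ZS:Z:-`
#' original-bottom). Original-bottom reads carry FLAG 16 (reverse strand);
#' coordinates are 1-based in the file per the SAM standard.
#'
#' @param reads A `bs_reads` tibble.
#' @param chrom_lengths Named chromosome lengths for the header.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, chrom_lengths, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                       as.integer(chrom_lengths))), con)
  n <- nrow(reads)
  chunk <- 500000L
  for (lo in seq(1L, max(n, 1L), by = chunk)) {
    if (n == 0) break
    hi <- min(lo + chunk - 1L, n)
    r <- reads[lo:hi, ]
    writeLines(paste(r$qname,
                     ifelse(r$reverse, 16L, 0L),
                     r$chrom, r$pos + 1L, 42L,
                     paste0(nchar(r$seq), "M"), "*", 0L, 0L,
                     r$seq, r$qual,
                     paste0("ZS:Z:", r$protocol), sep = "\t"), con)
  }
  invisible(path)
}
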