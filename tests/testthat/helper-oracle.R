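# Independent brute-force pileup: plain per-read, per-base accumulation
# into per-position count arrays, written without reference to the
# package's interval-join implementation. Used as the exact oracle for
# methylation calling and conversion-rate counting on small fixtures.

brute_pileup <- function(reads, genome, contexts = c("CG", "CH")) {
  out <- list()
  for (ch in names(genome$chrom_lengths)) {
    L <- genome$chrom_lengths[[ch]]
    for (st in c("+", "-")) {
      meth_cnt <- integer(L)
      tot_cnt <- integer(L)
      rs <- reads[!is.na(reads$protocol) & reads$protocol == st &
                    reads$chrom == ch, ]
      if (nrow(rs) > 0) {
        for (i in seq_len(nrow(rs))) {
          bases <- strsplit(rs$seq[i], "")[[1]]
          for (j in seq_along(bases)) {
            p <- rs$pos[i] + j  # 1-based index for position pos0 + j - 1
            b <- bases[j]
            if (st == "+") {
              if (b == "C") {
                meth_cnt[p] <- meth_cnt[p] + 1L
                tot_cnt[p] <- tot_cnt[p] + 1L
              } else if (b == "T") {
                tot_cnt[p] <- tot_cnt[p] + 1L
              }
            } else {
              if (b == "G") {
                meth_cnt[p] <- meth_cnt[p] + 1L
                tot_cnt[p] <- tot_cnt[p] + 1L
              } else if (b == "A") {
                tot_cnt[p] <- tot_cnt[p] + 1L
              }
            }
          }
        }
      }
      sites <- genome$sites[genome$sites$chrom == ch &
                              genome$sites$strand == st &
                              genome$sites$context %in% contexts, ]
      idx <- sites$pos + 1L
      keep <- tot_cnt[idx] > 0L
      if (any(keep)) {
        out[[length(out) + 1]] <- tibble::tibble(
          chrom = ch, pos = sites$pos[keep], strand = st,
          context = sites$context[keep],
          n_meth = meth_cnt[idx][keep], n_total = tot_cnt[idx][keep])
      }
    }
  }
  res <- dplyr::bind_rows(out)
  res[order(res$chrom, res$pos, res$strand), ]
}

# Brute-force conversion-rate counting: every aligned base over CH-context
# reference cytosines enters the denominator, C (or G on the reverse
# strand) calls the numerator.
brute_conversion <- function(reads, genome) {
  n_c <- 0L
  n_bases <- 0L
  ch_sites <- genome$sites[genome$sites$context == "CH", ]
  keyset <- new.env(hash = TRUE)
  for (i in seq_len(nrow(ch_sites))) {
    assign(paste(ch_sites$chrom[i], ch_sites$pos[i], ch_sites$strand[i]),
           TRUE, envir = keyset)
  }
  rs <- reads[!is.na(reads$protocol) & reads$protocol %in% c("+", "-"), ]
  for (i in seq_len(nrow(rs))) {
    bases <- strsplit(rs$seq[i], "")[[1]]
    st <- rs$protocol[i]
    for (j in seq_along(bases)) {
      key <- paste(rs$chrom[i], rs$pos[i] + j - 1L, st)
      if (exists(key, envir = keyset, inherits = FALSE)) {
        n_bases <- n_bases + 1L
        if (bases[j] == (if (st == "+") "C" else "G")) n_c <- n_c + 1L
      }
    }
  }
  list(n_c = n_c, n_bases = n_bases, rate = 1 - n_c / n_bases)
}
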