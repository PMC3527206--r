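# Shared fixture builders. Everything is generated in code at test time;
# no data files are stored.

# A meth_genome built from explicit chromosome sequences, via the public
# FASTA loader so tests exercise the same path external references take.
genome_from_seq <- function(...) {
  seqs <- c(...)
  fa <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(seqs), function(nm) {
    c(paste0(">", nm), seqs[[nm]])
  })), fa)
  load_genome(fa)
}

# Small spec with no genes/repeats and a single neutral landscape unless
# stated otherwise; fast to build in unit tests.
bare_spec <- function(len = 2e5, seed = 1, ...) {
  genome_spec(
    chrom_lengths = c(chrA = len),
    domains = tibble::tibble(chrom = "chrA", start = 0L, end = as.integer(len),
                             type = "neutral", cpg_mult = 1,
                             shift_wt = 0, shift_ko = 0),
    genes = list(n_genes = 0),
    repeats = NULL,
    lamina = list(coupling = 0, outside_max = 0),
    seed = seed,
    ...)
}

# Hand-built read tibble in the bs_reads dialect.
mk_reads <- function(chrom, pos, seq, protocol = "+",
                     reverse = protocol == "-", qual = NULL) {
  n <- max(length(chrom), length(pos), length(seq), length(protocol))
  chrom <- rep_len(chrom, n)
  pos <- rep_len(as.integer(pos), n)
  seq <- rep_len(seq, n)
  protocol <- rep_len(protocol, n)
  reverse <- rep_len(reverse, n)
  if (is.null(qual)) qual <- strrep("I", nchar(seq))  # Q40
  tibble::tibble(qname = paste0("r", seq_len(n)), chrom = chrom, pos = pos,
                 protocol = protocol, reverse = reverse, seq = seq,
                 qual = rep_len(qual, n))
}

# Hand-built per-site call table.
mk_calls <- function(chrom, pos, ratio, strand = "+", context = "CG",
                     n_total = 10L) {
  n <- max(length(chrom), length(pos), length(ratio))
  n_total <- rep_len(as.integer(n_total), n)
  ratio <- rep_len(ratio, n)
  tibble::tibble(chrom = rep_len(chrom, n), pos = rep_len(as.integer(pos), n),
                 strand = rep_len(strand, n),
                 context = rep_len(context, n),
                 n_meth = as.integer(round(ratio * n_total)),
                 n_total = n_total, ratio = ratio)
}
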