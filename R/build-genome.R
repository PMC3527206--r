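#' Build a synthetic reference genome from a spec
#'
#' Emits chromosome sequences whose CpG placement follows the spec's density
#' plan (denser inside DPD-like intervals and CpG islands, sparser inside
#' PMD-like intervals), together with gene, subregion, repeat, CpG-island and
#' planted-domain annotations. Deterministic given the spec's seed.
#'
#' Sequences are built on a 4-bp lattice: each cell hosts at most one planted
#' dinucleotide (a CpG dyad, a plus-strand CH cytosine as `CT`, or a
#' minus-strand CH cytosine as `AG`) and is otherwise filled with A/T. The
#' lattice guarantees that every cytosine's context is exactly as planted --
#' no accidental CpGs arise at junctions -- so simulator truth and caller
#' context assignment agree by construction.
#'
#' @param spec A [genome_spec()].
#' @return A `meth_genome` list: `seq` (named character vector of chromosome
#'   sequences), `chrom_lengths`, `sites` (tibble of all reference cytosines:
#'   `chrom`, `pos` (0-based position of the cytosine on its strand; for
#'   minus-strand sites this is the G position on the forward strand),
#'   `strand`, `context` (`"CG"` or `"CH"`)), `annotations` (tibbles `genes`,
#'   `subregions`, `repeats`, `cgi`, `domains`), and the originating `spec`.
#' @examples
#' g <- build_genome(genome_spec(chrom_lengths = c(chr1 = 2e6), seed = 7))
#' nchar(g$seq[["chr1"]])
#' @export
build_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  validate_domain_plan(spec$domains, spec$chrom_lengths)
  with_seed(spec$seed, {
    lamina_field <- build_lamina_field(spec)
    repeats <- place_repeats(spec)
    genes <- place_genes(spec, repeats)
    seqs <- build_sequences(spec, genes$cgi, lamina_field)
    sites <- scan_cytosine_sites(seqs)
    structure(
      list(seq = seqs,
           chrom_lengths = spec$chrom_lengths,
           sites = sites,
           lamina = lamina_field,
           annotations = list(genes = genes$genes,
                              subregions = genes$subregions,
                              repeats = repeats,
                              cgi = genes$cgi,
                              domains = spec$domains),
           spec = spec),
      class = "meth_genome")
  })
}

#' @export
print.meth_genome <- function(x, ...) {
  cat("<meth_genome> ", length(x$seq), " chromosome(s), ",
      format(sum(x$chrom_lengths), big.mark = ","), " bp\n", sep = "")
  n_cg <- sum(x$sites$context == "CG" & x$sites$strand == "+")
  cat("  CpG dyads: ", format(n_cg, big.mark = ","),
      " | genes: ", nrow(x$annotations$genes),
      " | repeats: ", nrow(x$annotations$repeats),
      " | planted domains: ", nrow(x$annotations$domains), "\n", sep = "")
  invisible(x)
}

place_repeats <- function(spec) {
  plan <- spec$repeats
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  family = character(), copy = integer())
  if (is.null(plan) || nrow(plan) == 0) return(empty)
  lens <- spec$chrom_lengths
  out <- list()
  occupied <- lapply(lens, function(...) tibble(start = integer(), end = integer()))
  for (i in seq_len(nrow(plan))) {
    fam <- plan$family[i]
    cl <- plan$copy_length[i]
    cc <- plan$copy_count[i]
    if (cc == 0) next
    if (isTRUE(plan$tandem[i])) {
      ch <- names(which.max(lens))
      block <- cc * cl
      s <- place_nonoverlapping(1, block, lens[[ch]], occupied[[ch]])
      if (length(s) == 1) {
        occupied[[ch]] <- bind_rows(occupied[[ch]],
                                    tibble(start = s, end = s + block))
        out[[length(out) + 1]] <- tibble(
          chrom = ch, start = as.integer(s + (seq_len(cc) - 1) * cl),
          end = as.integer(s + seq_len(cc) * cl), family = fam,
          copy = seq_len(cc))
      }
    } else {
      # disperse copies across chromosomes proportional to length
      n_per <- as.vector(stats::rmultinom(1, cc, lens / sum(lens)))
      for (j in seq_along(lens)) {
        if (n_per[j] == 0) next
        ch <- names(lens)[j]
        s <- place_nonoverlapping(n_per[j], cl, lens[[j]], occupied[[ch]])
        if (length(s) == 0) next
        occupied[[ch]] <- bind_rows(occupied[[ch]],
                                    tibble(start = s, end = s + cl))
        out[[length(out) + 1]] <- tibble(
          chrom = ch, start = as.integer(s), end = as.integer(s + cl),
          family = fam, copy = seq_along(s))
      }
    }
  }
  if (length(out) == 0) return(empty)
  bind_rows(out) %>% arrange(.data$chrom, .data$start)
}

# Rejection-sample `n` non-overlapping interval starts of width `w` in
# [0, L - w], avoiding `occupied` (tibble start/end) and each other.
place_nonoverlapping <- function(n, w, L, occupied, max_tries = 50L) {
  starts <- integer()
  occ_s <- occupied$start
  occ_e <- occupied$end
  for (k in seq_len(n)) {
    for (t in seq_len(max_tries)) {
      s <- sample.int(L - w + 1, 1) - 1L
      if (!any(s < occ_e & s + w > occ_s)) {
        starts <- c(starts, s)
        occ_s <- c(occ_s, s)
        occ_e <- c(occ_e, s + w)
        break
      }
    }
  }
  sort(starts)
}

place_genes <- function(spec, repeats) {
  gp <- spec$genes
  empty_genes <- tibble(chrom = character(), start = integer(), end = integer(),
                        name = character(), score = double(), strand = character(),
                        tss = integer(), promoter_start = integer(),
                        promoter_end = integer(), cgi = logical())
  empty_sub <- tibble(chrom = character(), start = integer(), end = integer(),
                      name = character(), gene = character(),
                      category = character(), strand = character())
  empty_cgi <- tibble(chrom = character(), start = integer(), end = integer(),
                      name = character())
  if (is.null(gp) || (gp$n_genes %||% 0) == 0) {
    return(list(genes = empty_genes, subregions = empty_sub, cgi = empty_cgi))
  }
  n_exons <- length(gp$exon)
  span <- gp$five_utr + sum(gp$exon) + gp$intron * max(n_exons - 1, 0) +
    gp$three_utr
  lens <- spec$chrom_lengths
  pmds <- spec$domains[spec$domains$type == "PMD", ]
  dpds <- spec$domains[spec$domains$type == "DPD", ]
  # genes avoid PMD-like intervals (PMDs are gene-poor); a fraction is
  # targeted into DPD-like intervals (active domains are gene-rich)
  dpd_frac <- gp$dpd_fraction %||% 0.5
  n_in_dpd <- if (nrow(dpds) > 0) round(dpd_frac * gp$n_genes) else 0L
  slot <- span + 2000L  # gene plus 1-kb promoter margin on both sides
  occupied <- lapply(lens, function(L) tibble(start = integer(), end = integer()))
  for (j in seq_along(lens)) {
    ch <- names(lens)[j]
    pmd_ch <- pmds[pmds$chrom == ch, ]
    occupied[[ch]] <- tibble(
      start = c(pmd_ch$start - slot, -slot),
      end = c(pmd_ch$end, 0L))
    occupied[[ch]] <- bind_rows(occupied[[ch]],
                                tibble(start = lens[[j]] - slot,
                                       end = lens[[j]]))
  }
  placements <- list()
  # DPD-targeted genes: pick an interval weighted by length, place inside
  if (n_in_dpd > 0) {
    dpd_ok <- dpds[dpds$end - dpds$start >= slot, ]
    for (k in seq_len(if (nrow(dpd_ok) > 0) n_in_dpd else 0L)) {
      di <- sample.int(nrow(dpd_ok), 1,
                       prob = dpd_ok$end - dpd_ok$start)
      ch <- dpd_ok$chrom[di]
      lo <- dpd_ok$start[di]
      hi <- dpd_ok$end[di] - slot
      for (t in seq_len(50L)) {
        s0 <- lo + sample.int(hi - lo + 1L, 1) - 1L
        occ <- occupied[[ch]]
        if (!any(s0 < occ$end & s0 + slot > occ$start)) {
          occupied[[ch]] <- bind_rows(occ, tibble(start = s0, end = s0 + slot))
          placements[[length(placements) + 1]] <- list(chrom = ch, s0 = s0)
          break
        }
      }
    }
  }
  n_rest <- gp$n_genes - length(placements)
  if (n_rest > 0) {
    n_per <- as.vector(stats::rmultinom(1, n_rest, lens / sum(lens)))
    for (j in seq_along(lens)) {
      if (n_per[j] == 0) next
      ch <- names(lens)[j]
      starts <- place_nonoverlapping(n_per[j], slot, lens[[j]],
                                     occupied[[ch]])
      for (s0 in starts) {
        occupied[[ch]] <- bind_rows(occupied[[ch]],
                                    tibble(start = s0, end = s0 + slot))
        placements[[length(placements) + 1]] <- list(chrom = ch, s0 = s0)
      }
    }
  }
  genes <- list()
  subs <- list()
  gid <- 0L
  for (pl in placements) {
    {
      ch <- pl$chrom
      gid <- gid + 1L
      s <- pl$s0 + 1000L  # margin hosts the promoter whichever strand is drawn
      strand <- sample(c("+", "-"), 1)
      name <- sprintf("gene%03d", gid)
      # subregion lengths in transcription order
      cats <- c("five_utr",
                as.vector(rbind(rep("exon", n_exons),
                                rep("intron", n_exons)))[seq_len(2 * n_exons - 1)],
                "three_utr")
      lens_tx <- c(gp$five_utr,
                   as.vector(rbind(gp$exon, rep(gp$intron, n_exons)))[
                     seq_len(2 * n_exons - 1)],
                   gp$three_utr)
      offs <- cumsum(c(0, lens_tx))
      if (strand == "+") {
        sub_start <- s + offs[-length(offs)]
        sub_end <- s + offs[-1]
        tss <- s
        prom <- c(s - 1000L, s)
      } else {
        e <- s + span
        sub_start <- e - offs[-1]
        sub_end <- e - offs[-length(offs)]
        tss <- e
        prom <- c(e, e + 1000L)
      }
      genes[[gid]] <- tibble(
        chrom = ch, start = as.integer(s), end = as.integer(s + span),
        name = name, score = 0, strand = strand, tss = as.integer(tss),
        promoter_start = as.integer(prom[1]), promoter_end = as.integer(prom[2]))
      subs[[gid]] <- tibble(
        chrom = ch, start = as.integer(sub_start), end = as.integer(sub_end),
        gene = name, category = cats, strand = strand) %>%
        mutate(name = paste0(.data$gene, "|", .data$category), .after = "end")
    }
  }
  if (gid == 0) {
    return(list(genes = empty_genes, subregions = empty_sub, cgi = empty_cgi))
  }
  genes <- bind_rows(genes)
  subs <- bind_rows(subs) %>% arrange(.data$chrom, .data$start)
  n_cgi <- round((gp$cgi_fraction %||% 0) * nrow(genes))
  genes$cgi <- FALSE
  if (n_cgi > 0) {
    genes$cgi[sample.int(nrow(genes), n_cgi)] <- TRUE
  }
  cgi <- genes[genes$cgi, ]
  cgi <- tibble(chrom = cgi$chrom, start = cgi$promoter_start,
                end = cgi$promoter_end, name = paste0("cgi_", cgi$name))
  list(genes = arrange(genes, .data$chrom, .data$start), subregions = subs,
       cgi = cgi)
}

# Latent lamina-association score per block: 1 inside PMD-like intervals,
# a capped Beta draw outside. Shared by truth shifts, CpG-density grading
# and the simulated lamina track.
build_lamina_field <- function(spec) {
  lp <- spec$lamina
  tiles <- tile_windows(spec$chrom_lengths, lp$block)
  mid <- (tiles$start + tiles$end) %/% 2L
  lambda <- lp$outside_max * rbeta(nrow(tiles), lp$shape[1], lp$shape[2])
  pmds <- spec$domains[spec$domains$type == "PMD", ]
  for (ch in unique(tiles$chrom)) {
    sel <- tiles$chrom == ch
    d <- pmds[pmds$chrom == ch, , drop = FALSE]
    if (nrow(d) == 0) next
    hit <- !is.na(interval_index(mid[sel], d$start, d$end))
    lambda[sel][hit] <- 1
  }
  tiles$lambda <- lambda
  tiles[, c("chrom", "start", "end", "lambda")]
}

lambda_at <- function(lamina_field, chrom, pos) {
  out <- rep(0, length(pos))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    lf <- lamina_field[lamina_field$chrom == ch, ]
    if (nrow(lf) == 0) next
    i <- interval_index(pos[sel], lf$start, lf$end)
    out[sel][!is.na(i)] <- lf$lambda[i[!is.na(i)]]
  }
  out
}

build_sequences <- function(spec, cgi, lamina_field) {
  lens <- spec$chrom_lengths
  cells_per_kb <- 250  # 4-bp lattice
  out <- character(length(lens))
  names(out) <- names(lens)
  for (j in seq_along(lens)) {
    ch <- names(lens)[j]
    L <- lens[[j]]
    ncell <- L %/% 4L
    cell_start <- (seq_len(ncell) - 1L) * 4L
    dom <- spec$domains[spec$domains$chrom == ch, ]
    # outside planted domains, CpG density declines with lamina association
    lam <- lambda_at(lamina_field, rep(ch, ncell), cell_start)
    mult <- 1 - spec$lamina$density_coupling * lam
    idx <- interval_index(cell_start, dom$start, dom$end)
    mult[!is.na(idx)] <- dom$cpg_mult[idx[!is.na(idx)]]
    p_cpg <- pmin(spec$cpg_per_kb * mult / cells_per_kb, 0.95)
    cgi_ch <- cgi[cgi$chrom == ch, ]
    if (nrow(cgi_ch) > 0) {
      in_cgi <- !is.na(interval_index(cell_start, cgi_ch$start, cgi_ch$end))
      p_cpg[in_cgi] <- pmin(spec$cgi_cpg_per_kb / cells_per_kb, 0.95)
    }
    p_ch <- spec$ch_per_kb / cells_per_kb
    u <- runif(ncell)
    m <- matrix(sample(c("A", "T"), 4L * ncell, replace = TRUE), nrow = 4L)
    is_cpg <- u < p_cpg
    is_chp <- !is_cpg & u < p_cpg + p_ch / 2
    is_chm <- !is_cpg & !is_chp & u < p_cpg + p_ch
    m[1, is_cpg] <- "C"; m[2, is_cpg] <- "G"
    m[1, is_chp] <- "C"; m[2, is_chp] <- "T"
    m[1, is_chm] <- "A"; m[2, is_chm] <- "G"
    tail_len <- L - 4L * ncell
    tail_seq <- if (tail_len > 0) {
      paste(sample(c("A", "T"), tail_len, replace = TRUE), collapse = "")
    } else ""
    out[j] <- paste0(paste(m, collapse = ""), tail_seq)
  }
  out
}

# Scan a set of chromosome sequences for all cytosine sites on both strands.
# Minus-strand cytosines are reference G positions; their CpG context is a
# preceding C on the forward strand.
scan_cytosine_sites <- function(seqs) {
  rows <- lapply(names(seqs), function(ch) {
    x <- Biostrings::DNAString(seqs[[ch]])
    cg <- Biostrings::start(Biostrings::matchPattern("CG", x))
    cpos <- Biostrings::start(Biostrings::matchPattern("C", x))
    gpos <- Biostrings::start(Biostrings::matchPattern("G", x))
    ch_plus <- setdiff(cpos, cg)
    ch_minus <- setdiff(gpos, cg + 1L)
    tibble(
      chrom = ch,
      pos = as.integer(c(cg, cg + 1L, ch_plus, ch_minus) - 1L),
      strand = c(rep("+", length(cg)), rep("-", length(cg)),
                 rep("+", length(ch_plus)), rep("-", length(ch_minus))),
      context = c(rep("CG", 2L * length(cg)),
                  rep("CH", length(ch_plus) + length(ch_minus)))
    )
  })
  bind_rows(rows) %>% arrange(.data$chrom, .data$pos, .data$strand)
}

#' Write or load genome FASTA and annotation files
#'
#' `write_genome_fasta()` writes the simulated chromosomes as FASTA.
#' `write_genome_annotations()` writes `genes.bed`, `subregions.bed`,
#' `repeats.bed`, `cgi.bed` and `domains_truth.bed` (BED6, name field
#' carrying the category). `load_genome()` reconstructs a `meth_genome`
#' from any FASTA reference (annotations empty), scanning cytosine sites
#' with [Biostrings::matchPattern()].
#'
#' @param genome A `meth_genome`.
#' @param path,dir Output FASTA path / annotation directory.
#' @return Paths invisibly; `load_genome()` returns a `meth_genome`.
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome$seq)
  Biostrings::writeXStringSet(x, path, width = 70)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
write_genome_annotations <- function(genome, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  a <- genome$annotations
  write_bed(a$genes, file.path(dir, "genes.bed"))
  write_bed(a$subregions, file.path(dir, "subregions.bed"))
  if (nrow(a$repeats) > 0) {
    write_bed(tibble(chrom = a$repeats$chrom, start = a$repeats$start,
                     end = a$repeats$end, name = a$repeats$family),
              file.path(dir, "repeats.bed"))
  } else {
    write_bed(a$repeats[, c("chrom", "start", "end")],
              file.path(dir, "repeats.bed"))
  }
  write_bed(a$cgi, file.path(dir, "cgi.bed"))
  write_bed(tibble(chrom = a$domains$chrom, start = a$domains$start,
                   end = a$domains$end, name = a$domains$type),
            file.path(dir, "domains_truth.bed"))
  invisible(dir)
}

#' @rdname write_genome_fasta
#' @export
load_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  seqs <- setNames(as.character(x), names(x))
  empty <- tibble(chrom = character(), start = integer(), end = integer())
  structure(
    list(seq = seqs,
         chrom_lengths = setNames(nchar(seqs), names(seqs)),
         sites = scan_cytosine_sites(seqs),
         annotations = list(genes = empty, subregions = empty, repeats = empty,
                            cgi = empty, domains = empty),
         spec = NULL),
    class = "meth_genome")
}
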