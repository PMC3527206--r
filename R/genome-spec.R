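#' Specify a synthetic genome with planted methylation-domain architecture
#'
#' A `genome_spec` fixes everything the simulator needs: chromosome lengths,
#' background CpG density, a domain plan (megabase-scale partially methylated
#' domain (PMD)-like intervals that lose methylation in tumours, CpG-dense
#' Dnmt3a-protected domain (DPD)-like intervals that lose methylation only in
#' the knockout condition), gene and repeat plans, the three-component
#' methylation-state mixture, and a seed. Identical specs (same seed) yield
#' byte-identical simulated genomes, annotations and reads.
#'
#' CpG dinucleotides are placed on a 4-bp lattice so that realised density is
#' binomial around `cpg_per_kb` times the local domain multiplier. Non-CpG
#' cytosines (CH context, needed to estimate bisulfite conversion rates) are
#' planted at `ch_per_kb`, split evenly between strands.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths in bp.
#' @param cpg_per_kb Background CpG dyad density (dyads per kb) outside
#'   planted domains and islands.
#' @param ch_per_kb Density of non-CpG (CH-context) cytosines per kb,
#'   split evenly between the two strands.
#' @param domains Tibble with columns `chrom`, `start`, `end`, `type`
#'   (one of `"PMD"`, `"DPD"`, `"neutral"`), `cpg_mult` (CpG-density
#'   multiplier, > 0), `shift_wt`, `shift_ko` (additive truth-methylation
#'   shifts for the wildtype-tumour and knockout-tumour conditions).
#'   `NULL` lays out a regular 2-Mb cassette per chromosome: 500 kb PMD-like
#'   (multiplier 0.3, shift -0.3 in both tumour conditions), 300 kb neutral,
#'   300 kb DPD-like (multiplier 4, shift -0.3 in knockout only), 900 kb
#'   neutral. Intervals are window-aligned at 100 kb.
#' @param genes List: `n_genes`, subregion lengths `five_utr`, `exon`
#'   (vector, one entry per exon), `intron`, `three_utr`, and `cgi_fraction`
#'   (fraction of promoters carrying a CpG island). Genes are placed outside
#'   PMD-like intervals (PMDs are gene-poor).
#' @param repeats Tibble with columns `family`, `copy_length`, `copy_count`,
#'   `meth` (per-copy mean methylation), `tandem` (logical; tandem families
#'   are planted as one contiguous block).
#' @param meth_weights Length-3 numeric, mixture weights for the
#'   unmethylated / partially methylated / fully methylated truth components
#'   (must sum to 1). Default `c(0.17, 0.35, 0.48)`.
#' @param meth_shapes List of 3 Beta shape pairs for the components. The
#'   defaults concentrate the outer components inside the state-definition
#'   regions (< 0.05 and > 0.95) so planted state fractions remain
#'   recoverable after binomial read sampling at typical WGBS coverage.
#' @param lamina List controlling the latent lamina-association field
#'   lambda, a per-block score in \[0, 1\] shared by the truth methylome,
#'   the CpG-density plan and the simulated lamina track. Fields: `block`
#'   (bp, default 100000), `outside_max` (ceiling of lambda outside
#'   PMD-like intervals, default 0.4; lambda is 1 inside them),
#'   `shape` (Beta shape pair for the outside draw, default `c(2, 2)`),
#'   `coupling` (tumour methylation loss outside planted domains =
#'   `coupling * lambda`, default 0.3), `density_coupling` (CpG-density
#'   multiplier outside planted domains = `1 - density_coupling * lambda`,
#'   default 0.5). Set `coupling = 0, outside_max = 0` for a genome whose
#'   only methylation differences are the planted domains.
#' @param cgi_cpg_per_kb CpG density inside CpG islands.
#' @param conversion Named numeric, per-condition bisulfite conversion rate
#'   (fraction of unmethylated cytosines successfully converted).
#' @param coverage Named numeric, per-condition target mean coverage.
#' @param seed Integer seed controlling every random choice downstream.
#' @return A list of class `genome_spec`.
#' @examples
#' spec <- genome_spec(chrom_lengths = c(chr1 = 2e6), seed = 1)
#' @export
genome_spec <- function(chrom_lengths = c(chr1 = 1e7, chr2 = 1e7),
                        cpg_per_kb = 10,
                        ch_per_kb = 20,
                        domains = NULL,
                        genes = list(n_genes = 40, five_utr = 200,
                                     exon = c(300, 300, 300), intron = 1000,
                                     three_utr = 500, cgi_fraction = 0.4),
                        repeats = default_repeat_plan(),
                        meth_weights = c(0.17, 0.35, 0.48),
                        meth_shapes = list(c(0.05, 30), c(5, 5), c(30, 0.05)),
                        lamina = list(),
                        cgi_cpg_per_kb = 80,
                        conversion = c(normal = 0.982, wt = 0.992, ko = 0.989),
                        coverage = c(normal = 9.1, wt = 14.4, ko = 17.1),
                        seed = 1L) {
  if (is.null(names(chrom_lengths)) || any(names(chrom_lengths) == "")) {
    abort("`chrom_lengths` must be a named vector")
  }
  chrom_lengths <- setNames(as.integer(chrom_lengths), names(chrom_lengths))
  if (any(chrom_lengths <= 0)) abort("chromosome lengths must be positive")
  if (is.null(domains)) domains <- default_domain_plan(chrom_lengths)
  domains <- as_tibble(domains)
  assert_cols(domains, c("chrom", "start", "end", "type"), "domains")
  if (!"cpg_mult" %in% names(domains)) {
    domains$cpg_mult <- c(PMD = 0.3, DPD = 4, neutral = 1)[domains$type]
  }
  if (!"shift_wt" %in% names(domains)) {
    domains$shift_wt <- ifelse(domains$type == "PMD", -0.3, 0)
  }
  if (!"shift_ko" %in% names(domains)) {
    domains$shift_ko <- ifelse(domains$type %in% c("PMD", "DPD"), -0.3, 0)
  }
  validate_domain_plan(domains, chrom_lengths)
  if (abs(sum(meth_weights) - 1) > 1e-8) abort("`meth_weights` must sum to 1")
  if (any(meth_weights < 0)) abort("`meth_weights` must be non-negative")
  if (any(conversion < 0 | conversion > 1)) abort("conversion rates must be in [0, 1]")
  if (cpg_per_kb <= 0 || ch_per_kb < 0) abort("densities must be positive")
  repeats <- if (is.null(repeats)) default_repeat_plan()[0, ] else as_tibble(repeats)
  lamina_defaults <- list(block = 1e5, outside_max = 0.4, shape = c(2, 2),
                          coupling = 0.3, density_coupling = 0.5)
  lamina <- utils::modifyList(lamina_defaults, lamina)
  structure(
    list(chrom_lengths = chrom_lengths, cpg_per_kb = cpg_per_kb,
         ch_per_kb = ch_per_kb, domains = domains, genes = genes,
         repeats = repeats, meth_weights = meth_weights,
         meth_shapes = meth_shapes, lamina = lamina,
         cgi_cpg_per_kb = cgi_cpg_per_kb,
         conversion = conversion, coverage = coverage,
         seed = as.integer(seed)),
    class = "genome_spec")
}

#' @rdname genome_spec
#' @export
default_repeat_plan <- function() {
  tibble(
    family = c("LINE", "SINE", "satellite"),
    copy_length = c(500L, 150L, 300L),
    copy_count = c(40L, 60L, 50L),
    meth = c(0.9, 0.85, 0.95),
    tandem = c(FALSE, FALSE, TRUE)
  )
}

#' @rdname genome_spec
#' @export
default_domain_plan <- function(chrom_lengths) {
  plans <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    cassette_starts <- seq(0, L - 1, by = 2e6)
    cassette_starts <- cassette_starts[cassette_starts + 2e6 <= L]
    if (length(cassette_starts) == 0) {
      return(tibble(chrom = character(), start = integer(),
                    end = integer(), type = character()))
    }
    tibble(
      chrom = ch,
      start = as.integer(c(cassette_starts, cassette_starts + 8e5)),
      end = as.integer(c(cassette_starts + 5e5, cassette_starts + 11e5)),
      type = rep(c("PMD", "DPD"), each = length(cassette_starts))
    )
  })
  dplyr::bind_rows(plans) %>% arrange(.data$chrom, .data$start)
}

validate_domain_plan <- function(domains, chrom_lengths) {
  bad_chrom <- setdiff(domains$chrom, names(chrom_lengths))
  if (length(bad_chrom) > 0) {
    abort(sprintf("domain plan references unknown chromosome(s): %s",
                  paste(bad_chrom, collapse = ", ")))
  }
  if (any(domains$start < 0) ||
      any(domains$end > chrom_lengths[domains$chrom]) ||
      any(domains$start >= domains$end)) {
    abort("domain intervals must be non-empty and within chromosome bounds")
  }
  if (any(domains$cpg_mult <= 0)) abort("`cpg_mult` must be > 0")
  planted <- domains[domains$type %in% c("PMD", "DPD"), ]
  split_by_chrom <- split(planted, planted$chrom)
  for (d in split_by_chrom) {
    d <- d[order(d$start), ]
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)])) {
      abort("PMD-like and DPD-like intervals must be disjoint")
    }
  }
  invisible(domains)
}
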