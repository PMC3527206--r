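#' Default configuration for the end-to-end synthetic pipeline
#'
#' Returns the run configuration as a plain list (YAML-serialisable). The
#' defaults emulate the study design the package models: three conditions
#' (normal lung, Dnmt3a-wildtype tumour, Dnmt3a-knockout tumour) at
#' typical WGBS coverages of 9.1x / 14.4x / 17.1x with bisulfite conversion
#' rates of 98.2% / 99.2% / 98.9%, 105-bp reads trimmed to 80 bp at Q30,
#' 100-kb and 20-kb window tracks, and a hypomethylation cutoff of 0.15.
#'
#' @param outdir Output directory.
#' @param seed Integer seed driving every stage.
#' @param chrom_lengths Named chromosome lengths for the simulated genome.
#' @return A named list of class `run_config`.
#' @export
default_run_config <- function(outdir = tempfile("methrun"), seed = 1L,
                               chrom_lengths = c(chr1 = 1e7, chr2 = 1e7)) {
  structure(list(
    outdir = outdir,
    seed = as.integer(seed),
    genome = list(chrom_lengths = as.list(chrom_lengths),
                  cpg_per_kb = 10, ch_per_kb = 20),
    coverage = list(normal = 9.1, wt = 14.4, ko = 17.1),
    conversion = list(normal = 0.982, wt = 0.992, ko = 0.989),
    read_length = 105L,
    error_rate = 0.001,
    trim = list(max_length = 80L, min_quality = 30L),
    window_sizes = c(100000L, 20000L),
    delta = 0.15,
    fold = 2,
    alpha = 0.01,
    n_up = 8L, n_down = 10L,
    stages = list(simulate = TRUE, call = TRUE, stats = TRUE,
                  domains = TRUE, correlate = TRUE, expression = TRUE)
  ), class = c("run_config", "list"))
}

#' Run the full synthetic-methylome analysis pipeline
#'
#' Executes the enabled stages in order -- simulate, call, stats, domains,
#' correlate, expression -- for the three conditions and the three
#' condition pairs (tumour vs normal, knockout vs wildtype, knockout vs
#' normal), writing every stage output under `config$outdir` and a
#' `manifest.json` recording the package version, the full configuration,
#' the seed, and per-stage file checksums. Reruns with an identical
#' configuration reproduce byte-identical outputs. A stage failure aborts
#' with a stage-named error and leaves a `FAILED` marker next to the
#' partial outputs.
#'
#' @param config A list from [default_run_config()] (possibly modified), or
#'   the path to a YAML file holding one.
#' @return Invisibly, a list of class `meth_pipeline` with the manifest and
#'   the in-memory stage results (`conversion`, `mean_methylation`,
#'   `state_fractions`, `window_counts`, `pmds`, `dpds`, `correlations`,
#'   `de_genes`, `subregion_tests`).
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- config
  outdir <- cfg$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  failed_marker <- file.path(outdir, "FAILED")
  if (file.exists(failed_marker)) unlink(failed_marker)
  manifest <- list(package = "methdomains",
                   version = as.character(utils::packageVersion("methdomains")),
                   seed = cfg$seed, config = cfg, stages = list())
  results <- list()
  env <- new.env()
  stage_names <- c("simulate", "call", "stats", "domains", "correlate",
                   "expression")
  for (st in stage_names) {
    enabled <- isTRUE(cfg$stages[[st]])
    if (!enabled) {
      manifest$stages[[st]] <- list(status = "skipped", files = list())
      message("[", st, "] skipped")
      next
    }
    message("[", st, "] running")
    files <- tryCatch(
      switch(st,
             simulate = stage_simulate(cfg, env, outdir,
                                       fuse_call = isTRUE(cfg$stages$call)),
             call = stage_call(cfg, env, outdir),
             stats = stage_stats(cfg, env, outdir),
             domains = stage_domains(cfg, env, outdir),
             correlate = stage_correlate(cfg, env, outdir),
             expression = stage_expression(cfg, env, outdir)),
      error = function(e) {
        writeLines(paste0("stage: ", st, "\n", conditionMessage(e)),
                   failed_marker)
        abort(sprintf("pipeline stage '%s' failed: %s", st,
                      conditionMessage(e)))
      })
    md5 <- tools::md5sum(files)
    manifest$stages[[st]] <- list(
      status = "ok",
      files = as.list(setNames(unname(md5), basename(files))))
  }
  for (nm in c("conversion", "mean_methylation", "state_fractions",
               "window_counts", "pmds", "dpds", "correlations",
               "de_genes", "de_fraction_flagged", "subregion_tests")) {
    results[[nm]] <- env[[nm]]
  }
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  out <- structure(c(list(manifest = manifest,
                          manifest_path = manifest_path,
                          outdir = outdir), results),
                   class = "meth_pipeline")
  invisible(out)
}

stage_simulate <- function(cfg, env, outdir, fuse_call = FALSE) {
  spec <- genome_spec(
    chrom_lengths = unlist(cfg$genome$chrom_lengths),
    cpg_per_kb = cfg$genome$cpg_per_kb %||% 10,
    ch_per_kb = cfg$genome$ch_per_kb %||% 20,
    conversion = unlist(cfg$conversion),
    coverage = unlist(cfg$coverage),
    seed = cfg$seed)
  env$genome <- build_genome(spec)
  env$truth <- assign_truth_methylome(env$genome)
  files <- character()
  f <- file.path(outdir, "genome.fa")
  write_genome_fasta(env$genome, f)
  files <- c(files, f)
  write_genome_annotations(env$genome, outdir)
  files <- c(files, file.path(outdir, c("genes.bed", "subregions.bed",
                                        "repeats.bed", "cgi.bed",
                                        "domains_truth.bed")))
  f <- file.path(outdir, "truth.tsv")
  write_truth(env$truth, f)
  files <- c(files, f)
  env$tracks <- simulate_tracks(env$genome, seed = cfg$seed + 100L)
  for (nm in names(env$tracks)) {
    f <- file.path(outdir, paste0(nm, ".bedGraph"))
    write_bedgraph(env$tracks[[nm]], f)
    files <- c(files, f)
  }
  env$expression <- simulate_expression_table(
    env$genome, n_up = cfg$n_up %||% 8L, n_down = cfg$n_down %||% 10L,
    fold = cfg$fold %||% 2, seed = cfg$seed + 200L)
  f <- file.path(outdir, "expression.tsv")
  readr::write_tsv(env$expression, f, progress = FALSE)
  files <- c(files, f)
  # reads are simulated, written and (when the call stage is enabled)
  # called one condition at a time so only one read set is held in memory
  env$calls <- if (fuse_call) list() else NULL
  env$conversion <- if (fuse_call) list() else NULL
  for (i in seq_along(cfg$coverage)) {
    cond <- names(cfg$coverage)[i]
    reads <- simulate_bisulfite_reads(
      env$genome, env$truth, condition = cond,
      coverage = cfg$coverage[[cond]],
      read_length = cfg$read_length %||% 105L,
      conversion_rate = cfg$conversion[[cond]],
      error_rate = cfg$error_rate %||% 0.001,
      seed = cfg$seed + 300L + i)
    f <- file.path(outdir, paste0("reads_", cond, ".sam"))
    write_sam(reads, env$genome$chrom_lengths, f)
    files <- c(files, f)
    if (fuse_call) {
      trimmed <- trim_reads(reads,
                            max_length = cfg$trim$max_length %||% 80L,
                            min_quality = cfg$trim$min_quality %||% 30L)
      rm(reads)
      env$conversion[[cond]] <- estimate_conversion(trimmed, env$genome)
      env$calls[[cond]] <- call_methylation(trimmed, env$genome,
                                            context = "CG")
      rm(trimmed)
    } else {
      rm(reads)
    }
    gc(verbose = FALSE)
  }
  files
}

stage_call <- function(cfg, env, outdir) {
  if (is.null(env$genome)) {
    env$genome <- load_genome(file.path(outdir, "genome.fa"))
  }
  conds <- names(cfg$coverage)
  if (is.null(env$calls)) {
    # stand-alone call stage: read each SAM back, one condition at a time
    env$calls <- list()
    env$conversion <- list()
    for (cond in conds) {
      reads <- read_bs_sam(file.path(outdir, paste0("reads_", cond, ".sam")))
      trimmed <- trim_reads(reads,
                            max_length = cfg$trim$max_length %||% 80L,
                            min_quality = cfg$trim$min_quality %||% 30L)
      rm(reads)
      env$conversion[[cond]] <- estimate_conversion(trimmed, env$genome)
      env$calls[[cond]] <- call_methylation(trimmed, env$genome,
                                            context = "CG")
      rm(trimmed)
      gc(verbose = FALSE)
    }
  }
  files <- character()
  for (cond in conds) {
    f <- file.path(outdir, paste0("calls_", cond, ".tsv"))
    write_calls(env$calls[[cond]], f)
    files <- c(files, f)
    f <- file.path(outdir, paste0("calls_", cond, ".bedGraph"))
    write_bedgraph(calls_to_bedgraph(env$calls[[cond]]), f)
    files <- c(files, f)
  }
  conv_tab <- bind_rows(lapply(conds, function(cond) {
    tidy(env$conversion[[cond]]) %>% mutate(condition = cond, .before = 1)
  }))
  f <- file.path(outdir, "conversion.tsv")
  readr::write_tsv(conv_tab, f, progress = FALSE)
  files <- c(files, f)
  files
}

load_calls_if_needed <- function(cfg, env, outdir) {
  if (is.null(env$genome)) {
    env$genome <- load_genome(file.path(outdir, "genome.fa"))
  }
  if (is.null(env$calls)) {
    conds <- names(cfg$coverage)
    env$calls <- lapply(setNames(conds, conds), function(cond) {
      read_calls(file.path(outdir, paste0("calls_", cond, ".tsv")))
    })
  }
}

stage_stats <- function(cfg, env, outdir) {
  load_calls_if_needed(cfg, env, outdir)
  conds <- names(env$calls)
  files <- character()
  env$mean_methylation <- vapply(env$calls, mean_methylation, numeric(1))
  bins <- lapply(env$calls, bin_distribution)
  env$state_fractions <- bind_rows(lapply(conds, function(cond) {
    tidy(bins[[cond]]) %>% mutate(condition = cond, .before = 1)
  }))
  f <- file.path(outdir, "histograms.tsv")
  readr::write_tsv(bind_rows(lapply(conds, function(cond) {
    bins[[cond]]$histogram %>% mutate(condition = cond, .before = 1)
  })), f, progress = FALSE)
  files <- c(files, f)
  f <- file.path(outdir, "state_fractions.tsv")
  readr::write_tsv(env$state_fractions, f, progress = FALSE)
  files <- c(files, f)

  genes <- env$genome$annotations$genes
  feature_rows <- list()
  for (cond in conds) {
    calls <- env$calls[[cond]]
    if (nrow(genes) > 0) {
      promoters <- tibble(chrom = genes$chrom, start = genes$promoter_start,
                          end = genes$promoter_end, name = genes$name,
                          category = ifelse(genes$cgi, "cgi_promoter",
                                            "promoter"))
      fm <- feature_methylation(calls, promoters, min_cpgs = 3,
                                min_coverage = 3)
      fm_cgi <- feature_methylation(calls,
                                    promoters[promoters$category == "cgi_promoter", ],
                                    min_cpgs = 6, min_coverage = 3)
      feature_rows[[length(feature_rows) + 1]] <-
        bind_rows(glance(fm) %>% filter(.data$category == "promoter"),
                  glance(fm_cgi)) %>%
        mutate(condition = cond, .before = 1)
    }
    reps <- env$genome$annotations$repeats
    if (nrow(reps) > 0) {
      rep_feats <- tibble(chrom = reps$chrom, start = reps$start,
                          end = reps$end,
                          name = paste0(reps$family, "_", reps$copy),
                          category = reps$family)
      fm_rep <- feature_methylation(calls, rep_feats, min_cpgs = 1,
                                    min_coverage = 1)
      feature_rows[[length(feature_rows) + 1]] <-
        glance(fm_rep) %>% mutate(condition = cond, .before = 1)
    }
    if (nrow(genes) > 0) {
      part <- partition_genic(calls, genes, env$genome$annotations$subregions)
      feature_rows[[length(feature_rows) + 1]] <-
        bind_rows(part$compartments, part$subregions) %>%
        rename(n_features = "n_sites") %>%
        mutate(condition = cond, .before = 1)
    }
  }
  if (length(feature_rows) > 0) {
    f <- file.path(outdir, "feature_summary.tsv")
    readr::write_tsv(bind_rows(feature_rows), f, progress = FALSE)
    files <- c(files, f)
  }
  files
}

stage_domains <- function(cfg, env, outdir) {
  load_calls_if_needed(cfg, env, outdir)
  conds <- names(env$calls)
  lens <- env$genome$chrom_lengths
  files <- character()
  env$tracks_by_w <- list()
  env$diffs <- list()
  counts <- list()
  comparisons <- list(wt_vs_normal = c("wt", "normal"),
                      ko_vs_normal = c("ko", "normal"),
                      ko_vs_wt = c("ko", "wt"))
  for (w in cfg$window_sizes) {
    wt_tracks <- lapply(env$calls, window_track, chrom_lengths = lens, w = w)
    env$tracks_by_w[[as.character(w)]] <- wt_tracks
    for (cond in conds) {
      f <- file.path(outdir, sprintf("windows_%d_%s.bedGraph", w, cond))
      write_window_bedgraph(wt_tracks[[cond]], f)
      files <- c(files, f)
    }
    for (cmp in names(comparisons)) {
      pair <- comparisons[[cmp]]
      if (!all(pair %in% conds)) next
      d <- differential_windows(wt_tracks[[pair[1]]], wt_tracks[[pair[2]]],
                                delta = cfg$delta %||% 0.15)
      if (w == cfg$window_sizes[[1]]) env$diffs[[cmp]] <- d
      f <- file.path(outdir, sprintf("diff_%s_%d.bedGraph", cmp, w))
      write_bedgraph(tibble(chrom = d$chrom, start = d$start, end = d$end,
                            value = d$delta), f)
      files <- c(files, f)
      counts[[length(counts) + 1]] <- tibble(
        comparison = cmp, w = w, n_flagged = n_hypomethylated(d),
        n_incomparable = attr(d, "n_incomparable"))
    }
  }
  env$window_counts <- bind_rows(counts)
  f <- file.path(outdir, "window_counts.tsv")
  readr::write_tsv(env$window_counts, f, progress = FALSE)
  files <- c(files, f)
  # conserved PMDs: tumour-vs-normal comparisons supporting the same loss
  pmd_support <- env$diffs[intersect(c("wt_vs_normal", "ko_vs_normal"),
                                     names(env$diffs))]
  env$pmds <- call_conserved_pmds(pmd_support)
  f <- file.path(outdir, "pmds.bed")
  write_bed(tibble(chrom = env$pmds$chrom, start = env$pmds$start,
                   end = env$pmds$end, name = "PMD",
                   score = env$pmds$mean_delta), f)
  files <- c(files, f)
  w1 <- as.character(cfg$window_sizes[[1]])
  env$dpds <- call_dpds(env$tracks_by_w[[w1]][["wt"]],
                        env$tracks_by_w[[w1]][["ko"]],
                        delta = cfg$delta %||% 0.15)
  f <- file.path(outdir, "dpds.bed")
  write_bed(tibble(chrom = env$dpds$chrom, start = env$dpds$start,
                   end = env$dpds$end, name = "DPD",
                   score = env$dpds$mean_delta), f)
  files <- c(files, f)
  files
}

stage_correlate <- function(cfg, env, outdir) {
  if (is.null(env$tracks)) {
    env$tracks <- lapply(
      setNames(c("lamina", "h3k4me1", "expression"),
               c("lamina", "h3k4me1", "expression")),
      function(nm) read_bedgraph(file.path(outdir, paste0(nm, ".bedGraph"))))
  }
  d <- env$diffs[["wt_vs_normal"]]
  loss <- d %>% mutate(value = -.data$delta)
  dens <- cpg_density_track(env$genome, w = cfg$window_sizes[[1]])
  rows <- list(
    lamina = correlate_with_track(loss, env$tracks[["lamina"]]),
    h3k4me1 = correlate_with_track(loss, env$tracks[["h3k4me1"]]),
    cpg_density = correlate_with_track(loss, dens$value)
  )
  env$correlations <- bind_rows(lapply(names(rows), function(nm) {
    glance(rows[[nm]]) %>% mutate(track = nm, .before = 1)
  }))
  f <- file.path(outdir, "correlations.tsv")
  readr::write_tsv(env$correlations, f, progress = FALSE)
  f
}

stage_expression <- function(cfg, env, outdir) {
  files <- character()
  if (is.null(env$expression)) {
    env$expression <- readr::read_tsv(file.path(outdir, "expression.tsv"),
                                      show_col_types = FALSE, progress = FALSE)
  }
  de <- select_de_genes(env$expression, fold = cfg$fold %||% 2)
  env$de_genes <- de
  genes <- env$genome$annotations$genes
  de_set <- genes[genes$name %in% de$gene[de$direction != "unchanged"], ]
  deltas <- gene_window_delta(de_set, env$diffs[["ko_vs_wt"]])
  f <- file.path(outdir, "de_gene_deltas.tsv")
  readr::write_tsv(deltas, f, progress = FALSE)
  files <- c(files, f)
  env$de_fraction_flagged <- attr(deltas, "fraction_flagged")

  subs <- env$genome$annotations$subregions
  sm_wt <- gene_subregion_means(env$calls[["wt"]], subs)
  sm_ko <- gene_subregion_means(env$calls[["ko"]], subs)
  dir_map <- setNames(as.character(de$direction), de$gene)
  sm <- sm_wt %>%
    inner_join(sm_ko, by = c("gene", "category"),
               suffix = c("_wt", "_ko")) %>%
    mutate(set = dir_map[.data$gene]) %>%
    filter(.data$set %in% c("up", "down")) %>%
    select("gene", "set", "category",
           mean_wt = "mean_ratio_wt", mean_ko = "mean_ratio_ko")
  env$subregion_tests <- subregion_differential_test(
    sm, alpha = cfg$alpha %||% 0.01)
  f <- file.path(outdir, "subregion_tests.tsv")
  readr::write_tsv(env$subregion_tests, f, progress = FALSE)
  files <- c(files, f)
  files
}

#' @export
print.meth_pipeline <- function(x, ...) {
  cat("<meth_pipeline> outputs in ", x$outdir, "\n", sep = "")
  st <- vapply(x$manifest$stages, function(s) s$status, character(1))
  cat("  stages: ", paste(names(st), st, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
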