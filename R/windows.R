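#' Non-overlapping window methylation track
#'
#' Tiles each chromosome with fixed-width windows (stride = width, i.e. a
#' sliding window shifted non-overlappingly) and computes, per window, the
#' arithmetic mean methylation ratio over CG-context cytosines covered by at
#' least one read, plus the number of covered CpG sites. Windows with no
#' covered CpG carry `NA`, never 0. The trailing window of each chromosome
#' may be shorter than `w`; it is retained and marked `partial`.
#'
#' `pooled = TRUE` replaces the mean of per-site ratios with the
#' pooled-count ratio (sum of methylated calls over sum of informative
#' calls). A stride smaller than `w` produces overlapping windows for
#' exploration; downstream segmentation requires the default tiling.
#'
#' @param calls A `meth_calls` tibble.
#' @param chrom_lengths Named chromosome lengths in bp.
#' @param w Window width in bp (defaults used in this package: 100000 and
#'   20000).
#' @param stride Window stride; defaults to `w` (non-overlapping tiling).
#' @param pooled Use pooled-count window means (default FALSE).
#' @return Tibble of class `window_track`: `chrom`, `start`, `end`,
#'   `partial`, `n_cpgs`, `mean_meth`; attribute `w`.
#' @examples
#' calls <- tibble::tibble(chrom = "chr1", pos = c(10L, 150L), strand = "+",
#'                         context = "CG", n_meth = c(1L, 2L),
#'                         n_total = c(2L, 2L), ratio = c(0.5, 1))
#' window_track(calls, c(chr1 = 300L), w = 100)
#' @export
window_track <- function(calls, chrom_lengths, w = 100000L, stride = w,
                         pooled = FALSE) {
  assert_cols(calls, c("chrom", "pos", "context", "n_total", "ratio"), "calls")
  if (w <= 0) abort("`w` must be positive")
  if (w > max(chrom_lengths)) {
    warn("`w` exceeds the longest chromosome; tracks have a single window")
  }
  tiles <- tile_windows(chrom_lengths, w, stride)
  x <- calls[calls$context == "CG" & calls$n_total > 0, ]
  if (stride == w) {
    x <- x %>% mutate(.win = .data$pos %/% as.integer(w))
    stats <- x %>%
      group_by(.data$chrom, .data$.win) %>%
      summarise(n_cpgs = dplyr::n(),
                mean_meth = if (pooled) sum(.data$n_meth) / sum(.data$n_total)
                            else mean(.data$ratio),
                .groups = "drop")
    out <- tiles %>%
      mutate(.win = .data$start %/% as.integer(w)) %>%
      left_join(stats, by = c("chrom", ".win")) %>%
      select(-".win")
  } else {
    hits <- overlap_pairs(x, tiles %>% mutate(.fid = dplyr::row_number()))
    stats <- hits %>%
      group_by(.data$.fid) %>%
      summarise(n_cpgs = dplyr::n(),
                mean_meth = if (pooled) sum(.data$n_meth) / sum(.data$n_total)
                            else mean(.data$ratio),
                .groups = "drop")
    out <- tiles %>%
      mutate(.fid = dplyr::row_number()) %>%
      left_join(stats, by = ".fid") %>%
      select(-".fid")
  }
  out <- out %>%
    mutate(n_cpgs = dplyr::coalesce(.data$n_cpgs, 0L)) %>%
    arrange(.data$chrom, .data$start)
  attr(out, "w") <- w
  class(out) <- c("window_track", class(out))
  out
}

tile_windows <- function(chrom_lengths, w, stride = w) {
  bind_rows(lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    starts <- seq(0L, max(L - 1L, 0L), by = as.integer(stride))
    tibble(chrom = ch, start = as.integer(starts),
           end = as.integer(pmin(starts + w, L)),
           partial = starts + w > L)
  }))
}

#' CpG density per window
#'
#' Counts CpG dyads of the reference per non-overlapping window and divides
#' by window length (density per bp).
#'
#' @param genome A `meth_genome`.
#' @param w Window width in bp.
#' @return A `window_track`-tiled tibble with columns `chrom`, `start`,
#'   `end`, `partial`, `n_cpgs`, `value` (dyads per bp).
#' @export
cpg_density_track <- function(genome, w = 100000L) {
  tiles <- tile_windows(genome$chrom_lengths, w)
  dyads <- genome$sites %>%
    filter(.data$context == "CG", .data$strand == "+") %>%
    mutate(.win = .data$pos %/% as.integer(w)) %>%
    group_by(.data$chrom, .data$.win) %>%
    summarise(n_cpgs = dplyr::n(), .groups = "drop")
  tiles %>%
    mutate(.win = .data$start %/% as.integer(w)) %>%
    left_join(dyads, by = c("chrom", ".win")) %>%
    mutate(n_cpgs = dplyr::coalesce(.data$n_cpgs, 0L),
           value = .data$n_cpgs / (.data$end - .data$start)) %>%
    select(-".win") %>%
    arrange(.data$chrom, .data$start)
}

#' Resample a bedGraph signal onto a window tiling
#'
#' Computes the coverage-weighted mean of an interval signal within each
#' window. bedGraph gaps are missing data: windows with no overlapping
#' signal get `NA`, and partially covered windows weight by the covered
#' bases only.
#'
#' @param track bedGraph tibble (`chrom`, `start`, `end`, `value`).
#' @param windows Window tibble (`chrom`, `start`, `end`).
#' @return `windows` with a `value` column appended.
#' @export
resample_to_windows <- function(track, windows) {
  assert_cols(track, c("chrom", "start", "end", "value"), "track")
  out <- windows
  out$value <- NA_real_
  for (ch in intersect(unique(track$chrom), unique(windows$chrom))) {
    tr <- track[track$chrom == ch & !is.na(track$value), ]
    wi <- which(windows$chrom == ch)
    if (nrow(tr) == 0 || length(wi) == 0) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(start = tr$start + 1L, end = tr$end),
      IRanges::IRanges(start = windows$start[wi] + 1L, end = windows$end[wi]))
    if (length(ov) == 0) next
    q <- S4Vectors::queryHits(ov)
    s <- S4Vectors::subjectHits(ov)
    olap <- pmin(tr$end[q], windows$end[wi][s]) -
      pmax(tr$start[q], windows$start[wi][s])
    agg <- tibble(s = s, wsum = olap * tr$value[q], wt = olap) %>%
      group_by(.data$s) %>%
      summarise(value = sum(.data$wsum) / sum(.data$wt), .groups = "drop")
    out$value[wi[agg$s]] <- agg$value
  }
  out
}

#' @rdname window_track
#' @param track A `window_track`.
#' @param path Output bedGraph path (windows with defined means only).
#' @export
write_window_bedgraph <- function(track, path) {
  write_bedgraph(tibble(chrom = track$chrom, start = track$start,
                        end = track$end, value = track$mean_meth), path)
}
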