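#' Differential (hypomethylation) window track
#'
#' Compares a test condition against a baseline on an identical window
#' tiling and flags windows whose methylation loss -- baseline mean minus
#' test mean -- exceeds the cutoff `delta` (default 0.15). Windows missing
#' a mean in either track are incomparable: unflagged and counted in the
#' `n_incomparable` attribute. Trailing partial windows are never flagged in
#' genome-wide counts unless `include_partial = TRUE`.
#'
#' @param track_test `window_track` for the condition suspected of
#'   methylation loss (e.g. a tumour).
#' @param track_baseline `window_track` for the reference condition.
#' @param delta Hypomethylation cutoff on the per-window loss (default
#'   0.15).
#' @param include_partial Allow flagging of trailing partial windows.
#' @return Tibble of class `diff_track`: `chrom`, `start`, `end`,
#'   `partial`, `mean_test`, `mean_baseline`, `delta` (test - baseline, so
#'   loss is negative), `flagged`. Attributes `n_flagged`,
#'   `n_incomparable`, `cutoff`.
#' @examples
#' # see vignette("methdomains") for an end-to-end example
#' @export
differential_windows <- function(track_test, track_baseline, delta = 0.15,
                                 include_partial = FALSE) {
  for (tr in list(track_test, track_baseline)) {
    assert_cols(tr, c("chrom", "start", "end", "mean_meth"), "track")
  }
  if (nrow(track_test) != nrow(track_baseline) ||
      !all(track_test$chrom == track_baseline$chrom) ||
      !all(track_test$start == track_baseline$start) ||
      !all(track_test$end == track_baseline$end)) {
    abort("window tilings differ between tracks")
  }
  comparable <- !is.na(track_test$mean_meth) & !is.na(track_baseline$mean_meth)
  loss <- track_baseline$mean_meth - track_test$mean_meth
  eligible <- comparable & (include_partial | !track_test$partial)
  is_hypo <- eligible & !is.na(loss) & loss > delta
  out <- tibble(
    chrom = track_test$chrom, start = track_test$start,
    end = track_test$end, partial = track_test$partial,
    mean_test = track_test$mean_meth,
    mean_baseline = track_baseline$mean_meth,
    delta = -loss,
    flagged = is_hypo
  )
  attr(out, "n_flagged") <- sum(out$flagged)
  attr(out, "n_incomparable") <- sum(!comparable)
  attr(out, "cutoff") <- delta
  class(out) <- c("diff_track", class(out))
  out
}

#' @rdname differential_windows
#' @param diff A `diff_track`.
#' @export
n_hypomethylated <- function(diff) {
  sum(diff$flagged)
}

# Merge runs of flagged windows into domains. `gap` = tolerated unflagged
# windows between flagged ones; runs shorter than `min_windows` dropped.
merge_flagged <- function(diff, label, gap = 0L, min_windows = 1L) {
  flagged <- diff[diff$flagged, ]
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  n_windows = integer(), mean_delta = double(),
                  label = character())
  if (nrow(flagged) == 0) {
    out <- empty
  } else {
    w <- max(diff$end - diff$start)
    out <- flagged %>%
      arrange(.data$chrom, .data$start) %>%
      group_by(.data$chrom) %>%
      mutate(.new = c(TRUE, diff(.data$start) > (gap + 1L) * w)) %>%
      mutate(.run = cumsum(.data$.new)) %>%
      group_by(.data$chrom, .data$.run) %>%
      summarise(start = min(.data$start), end = max(.data$end),
                n_windows = dplyr::n(), mean_delta = mean(.data$delta),
                .groups = "drop") %>%
      filter(.data$n_windows >= min_windows) %>%
      mutate(label = label) %>%
      select("chrom", "start", "end", "n_windows", "mean_delta", "label") %>%
      arrange(.data$chrom, .data$start)
  }
  class(out) <- c("domain_set", class(out))
  out
}

#' Call conserved partially methylated domains (PMDs)
#'
#' Takes differential tracks from two or more independent comparisons
#' against the same baseline (e.g. replicate tumour pools vs normal tissue)
#' on a shared tiling, keeps the windows flagged in *all* comparisons, and
#' merges adjacent runs into domains (gap tolerance in windows, runs
#' shorter than `min_windows` dropped). With a single comparison the
#' function falls back to single-comparison domains with a warning.
#'
#' @param diffs List of `diff_track`s sharing one tiling.
#' @param gap Tolerated unflagged windows inside a domain (default 0).
#' @param min_windows Minimum run length in windows (default 1).
#' @return Tibble of class `domain_set`: `chrom`, `start`, `end`,
#'   `n_windows`, `mean_delta` (mean over the first comparison's deltas),
#'   `label = "PMD"`; attribute `provenance` names the comparisons.
#' @export
call_conserved_pmds <- function(diffs, gap = 0L, min_windows = 1L) {
  if (inherits(diffs, "diff_track")) diffs <- list(diffs)
  if (length(diffs) < 2) {
    warn("fewer than 2 comparisons; calling single-comparison domains")
  }
  base <- diffs[[1]]
  for (d in diffs[-1]) {
    if (nrow(d) != nrow(base) || !all(d$start == base$start) ||
        !all(d$chrom == base$chrom)) {
      abort("differential tracks must share one tiling")
    }
  }
  conserved <- Reduce(`&`, lapply(diffs, function(d) d$flagged))
  merged_in <- base
  merged_in$flagged <- conserved
  out <- merge_flagged(merged_in, "PMD", gap = gap, min_windows = min_windows)
  attr(out, "provenance") <- names(diffs) %||%
    paste0("comparison", seq_along(diffs))
  out
}

#' Call Dnmt3a-protected domains (DPDs)
#'
#' Flags windows where the knockout track's mean methylation falls more
#' than `delta` below the wildtype track's, and merges adjacent flagged
#' windows into DPD intervals.
#'
#' @param track_wt,track_ko `window_track`s for the wildtype-tumour and
#'   knockout-tumour conditions on the same tiling.
#' @param delta Hypomethylation cutoff (default 0.15).
#' @param gap,min_windows Merging parameters as in
#'   [call_conserved_pmds()].
#' @return A `domain_set` with `label = "DPD"`.
#' @export
call_dpds <- function(track_wt, track_ko, delta = 0.15, gap = 0L,
                      min_windows = 1L) {
  diff <- differential_windows(track_ko, track_wt, delta = delta)
  merge_flagged(diff, "DPD", gap = gap, min_windows = min_windows)
}

#' @export
print.domain_set <- function(x, ...) {
  lab <- if (nrow(x) > 0) x$label[1] else "domain"
  cat("<domain_set> ", nrow(x), " ", lab, " domain(s), ",
      format(sum(x$end - x$start), big.mark = ","), " bp total\n", sep = "")
  if (nrow(x) > 0) print(as_tibble(x))
  invisible(x)
}

#' Jaccard overlap between two interval sets
#'
#' Total intersection length divided by total union length, per the usual
#' interval-set similarity used to score domain recovery against planted
#' truth.
#'
#' @param a,b Interval tibbles (`chrom`, `start`, `end`).
#' @return A number in \[0, 1\].
#' @export
interval_jaccard <- function(a, b) {
  to_ir <- function(x, ch) {
    xx <- x[x$chrom == ch, ]
    IRanges::reduce(IRanges::IRanges(start = xx$start + 1L, end = xx$end))
  }
  chroms <- union(unique(a$chrom), unique(b$chrom))
  inter <- 0
  uni <- 0
  for (ch in chroms) {
    ia <- to_ir(a, ch)
    ib <- to_ir(b, ch)
    inter <- inter + sum(IRanges::width(IRanges::intersect(ia, ib)))
    uni <- uni + sum(IRanges::width(IRanges::union(ia, ib)))
  }
  if (uni == 0) return(NA_real_)
  inter / uni
}

#' Spearman correlation between a window signal and an external track
#'
#' Resamples an external bedGraph signal onto the window tiling
#' (coverage-weighted mean; see [resample_to_windows()]) when needed, then
#' computes Spearman's rank correlation over windows where both values are
#' defined, with the p-value for the two-sided alternative that the
#' correlation is non-zero.
#'
#' @param windows Window tibble with a `value` column (or a column named by
#'   `value_col`) -- e.g. a methylation-loss track.
#' @param track External signal: a bedGraph tibble, resampled onto the
#'   tiling, or a vector of per-window values.
#' @param value_col Column of `windows` holding the signal (default
#'   `"value"`).
#' @return Object of class `meth_cor`: `estimate` (rho), `p_value`, `n`
#'   (comparable windows). [tidy()] and [glance()] methods return one-row
#'   tibbles.
#' @export
correlate_with_track <- function(windows, track, value_col = "value") {
  x <- windows[[value_col]]
  if (is.null(x)) abort(sprintf("`windows` has no column '%s'", value_col))
  if (is.data.frame(track)) {
    y <- resample_to_windows(track, windows)$value
  } else {
    if (length(track) != nrow(windows)) {
      abort("per-window `track` vector must match the tiling")
    }
    y <- track
  }
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 10) abort("fewer than 10 comparable windows")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    abort("constant input; rank correlation undefined")
  }
  ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman",
                                  alternative = "two.sided", exact = FALSE))
  structure(list(estimate = unname(ct$estimate), p_value = ct$p.value,
                 n = sum(ok), method = "spearman"),
            class = "meth_cor")
}

#' @export
print.meth_cor <- function(x, ...) {
  cat(sprintf("<meth_cor> Spearman rho = %.3f, p = %.3g, n = %d windows\n",
              x$estimate, x$p_value, x$n))
  invisible(x)
}

#' @export
tidy.meth_cor <- function(x, ...) {
  tibble(estimate = x$estimate, p.value = x$p_value, method = x$method)
}

#' @export
glance.meth_cor <- function(x, ...) {
  tibble(estimate = x$estimate, p.value = x$p_value, n = x$n)
}
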