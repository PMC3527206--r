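# Internal helpers: seeded evaluation, interval utilities, and plain-text
# genomic format I/O (BED6, bedGraph, TSV dialects used across the pipeline).

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. Keeps simulator determinism self-contained.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

clip01 <- function(x) pmin(1, pmax(0, x))

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# First interval (by priority order of `starts`) containing each position;
# intervals are 0-based half-open. Returns NA for positions in no interval.
# Used for domain/feature lookups where interval sets are modest in size.
interval_index <- function(pos, starts, ends) {
  if (length(starts) == 0) return(rep(NA_integer_, length(pos)))
  ord <- order(starts)
  starts <- starts[ord]
  ends <- ends[ord]
  i <- findInterval(pos, starts)
  hit <- i >= 1 & pos < ends[pmax(i, 1L)]
  out <- rep(NA_integer_, length(pos))
  out[hit] <- ord[i[hit]]
  out
}

#' Read and write BED6 interval files
#'
#' Minimal BED6 dialect used for all annotations emitted by the simulator:
#' columns chrom, start, end, name, score, strand; 0-based half-open
#' coordinates. Missing score/strand columns are filled with `0` / `"."`.
#'
#' @param path File path.
#' @param x Tibble with at least `chrom`, `start`, `end`.
#' @return `read_bed()` returns a tibble with columns chrom, start, end,
#'   name, score, strand; `write_bed()` returns `path` invisibly.
#' @export
read_bed <- function(path) {
  x <- readr::read_tsv(path,
    col_names = c("chrom", "start", "end", "name", "score", "strand"),
    col_types = "ciicdc", progress = FALSE)
  x
}

#' @rdname read_bed
#' @export
write_bed <- function(x, path) {
  assert_cols(x, c("chrom", "start", "end"))
  out <- tibble(
    chrom = x$chrom,
    start = as.integer(x$start),
    end = as.integer(x$end),
    name = if ("name" %in% names(x)) x$name else ".",
    score = if ("score" %in% names(x)) x$score else 0,
    strand = if ("strand" %in% names(x)) x$strand else "."
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read and write bedGraph tracks
#'
#' Four-column genomic signal format (chrom, start, end, value), 0-based
#' half-open. Gaps between intervals are treated as missing data by all
#' consumers in this package, never as zero signal.
#'
#' @param path File path.
#' @param x Tibble with columns chrom, start, end, value.
#' @return `read_bedgraph()` returns a tibble; `write_bedgraph()` returns
#'   `path` invisibly.
#' @export
read_bedgraph <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                  col_types = "ciid", progress = FALSE)
}

#' @rdname read_bedgraph
#' @export
write_bedgraph <- function(x, path) {
  assert_cols(x, c("chrom", "start", "end", "value"))
  out <- x[, c("chrom", "start", "end", "value")]
  out <- out[!is.na(out$value), ]
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
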