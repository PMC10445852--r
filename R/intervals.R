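# Internal coordinate convention: 0-based half-open [start, end) everywhere.
# GFF3 and tabular hit files are 1-based inclusive and are converted at the
# I/O boundary only; BED is already 0-based half-open.

#' Build an interval table
#'
#' Intervals are plain data frames with integer `start` (0-based, inclusive)
#' and `end` (exclusive) columns, optionally `strand` and `name`. Every
#' genomic coordinate inside the package uses this convention.
#'
#' @param start,end integer vectors, `0 <= start < end` rowwise.
#' @param strand optional character vector over `+`, `-`, `.`.
#' @param name optional character vector of feature names.
#' @return a data frame with columns `start`, `end` (+ `strand`, `name`).
#' @export
intervals <- function(start = integer(), end = integer(), strand = NULL,
                      name = NULL) {
  start <- as.integer(start)
  end <- as.integer(end)
  df <- data.frame(start = start, end = end)
  if (!is.null(strand)) df$strand <- as.character(strand)
  if (!is.null(name)) df$name <- as.character(name)
  validate_intervals(df)
  df
}

validate_intervals <- function(df, what = "interval") {
  if (nrow(df) == 0L) return(invisible(df))
  bad <- which(!(df$start >= 0L & df$start < df$end))
  if (length(bad)) {
    stop(sprintf("invalid %s at row %d: start=%s end=%s (need 0 <= start < end)",
                 what, bad[1], df$start[bad[1]], df$end[bad[1]]))
  }
  if ("strand" %in% names(df) && !all(df$strand %in% c("+", "-", "."))) {
    stop(sprintf("invalid %s strand; allowed: + - .", what))
  }
  invisible(df)
}

iv_width <- function(df) if (nrow(df) == 0L) 0L else sum(df$end - df$start)

as_iranges <- function(df) {
  IRanges::IRanges(start = df$start + 1L, end = df$end)
}

from_iranges <- function(ir) {
  data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

#' Merge overlapping or bookended intervals
#'
#' @param df an interval data frame.
#' @return interval data frame with overlapping/adjacent rows unioned,
#'   sorted by start.
#' @export
merge_intervals <- function(df) {
  if (nrow(df) == 0L) return(data.frame(start = integer(), end = integer()))
  from_iranges(IRanges::reduce(as_iranges(df)))
}

# TRUE for each row of `a` overlapping (>= 1 shared base) any row of `b`
# (base arithmetic: called per gene on tiny inputs, where S4 dispatch
# overhead would dominate)
overlaps_any <- function(a, b) {
  if (nrow(a) == 0L) return(logical(0))
  if (nrow(b) == 0L) return(rep(FALSE, nrow(a)))
  vapply(seq_len(nrow(a)), function(i)
    any(a$start[i] < b$end & a$end[i] > b$start), logical(1))
}

# union of intervals by sort-and-sweep, without validation
union_base <- function(df) {
  if (nrow(df) <= 1L) return(df)
  df <- df[order(df$start), , drop = FALSE]
  out_s <- df$start[1]; out_e <- df$end[1]
  for (i in 2:nrow(df)) {
    k <- length(out_s)
    if (df$start[i] <= out_e[k]) out_e[k] <- max(out_e[k], df$end[i])
    else { out_s <- c(out_s, df$start[i]); out_e <- c(out_e, df$end[i]) }
  }
  data.frame(start = out_s, end = out_e)
}

# total bases of `a` covered by the union of `b`
covered_bases <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(0L)
  ua <- union_base(a[, c("start", "end")])
  ub <- union_base(b[, c("start", "end")])
  tot <- 0L
  for (i in seq_len(nrow(ua))) {
    tot <- tot + sum(pmax(0L, pmin(ua$end[i], ub$end) -
                            pmax(ua$start[i], ub$start)))
  }
  as.integer(tot)
}
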