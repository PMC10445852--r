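#' Round half away from zero
#'
#' Published assembly tables round percentages half away from zero
#' (e.g. 1360/1367 prints as 99.5%), unlike base `round()`'s banker's
#' rounding.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Rounded percentage of a count
#'
#' @param count numerator, `>= 0`.
#' @param total denominator, `> 0`.
#' @param decimals decimal places (half-away-from-zero).
#' @return `round(100 * count / total, decimals)`.
#' @export
percent_of <- function(count, total, decimals = 1) {
  if (any(total <= 0)) stop("percent_of: total must be > 0")
  if (any(count < 0)) stop("percent_of: count must be >= 0")
  round_half_up(100 * count / total, decimals)
}

#' Assembly contiguity and composition statistics
#'
#' NX is the length of the contig at which the descending cumulative length
#' first reaches X% of the assembly, LX its 1-based rank; auN is the
#' length-weighted mean contig length (sum of l^2 / sum of l, rounded to the
#' nearest integer); GC% ignores N bases in the denominator.
#'
#' @param records `seq_records()` data frame (non-empty). Composition stats
#'   need real sequences; pass records built from a length vector via
#'   [lengths_as_records()] to get contiguity stats only.
#' @return list with `n_contigs`, `cumulative_size`, `max_len`, `mean_len`,
#'   `n50`, `l50`, `n90`, `l90`, `auN`, `gc_percent`, `n_count`, `n_percent`.
#' @export
compute_stats <- function(records) {
  if (nrow(records) == 0L) stop("compute_stats: empty assembly")
  len <- nchar(records$seq)
  total <- sum(as.numeric(len))
  sorted <- sort(len, decreasing = TRUE)
  csum <- cumsum(as.numeric(sorted))
  nx <- function(x) {
    i <- which(csum >= total * x / 100)[1]
    c(n = sorted[i], l = i)
  }
  n50 <- nx(50); n90 <- nx(90)
  af <- Biostrings::alphabetFrequency(Biostrings::DNAStringSet(records$seq))
  base_counts <- colSums(af[, c("A", "C", "G", "T", "N"), drop = FALSE])
  acgt <- sum(base_counts[c("A", "C", "G", "T")])
  gc <- if (acgt > 0) round_half_up(100 * sum(base_counts[c("G", "C")]) / acgt, 2)
        else NA_real_
  list(n_contigs = length(len),
       cumulative_size = total,
       max_len = max(len),
       mean_len = round_half_up(total / length(len)),
       n50 = unname(n50["n"]), l50 = unname(n50["l"]),
       n90 = unname(n90["n"]), l90 = unname(n90["l"]),
       auN = round_half_up(sum(as.numeric(sorted)^2) / total),
       gc_percent = gc,
       n_count = unname(base_counts["N"]),
       n_percent = percent_of(unname(base_counts["N"]), total, 2))
}

#' Wrap a length vector as placeholder sequence records
#'
#' Contiguity statistics depend only on lengths; this builds all-A records
#' of the requested lengths so [compute_stats()] can be exercised (and
#' oracle-checked) on arbitrary length multisets.
#'
#' @param lengths positive integer vector.
#' @return `seq_records()` data frame.
#' @export
lengths_as_records <- function(lengths) {
  seq_records(paste0("ctg", seq_along(lengths)),
              vapply(lengths, function(l) strrep("A", l), character(1)))
}

#' Scaffold length filter
#'
#' Keeps scaffolds strictly longer than `min_len_bp` (a "larger than" cut),
#' preserving input order.
#'
#' @param records `seq_records()` data frame.
#' @param min_len_bp length threshold in bp; default 35 kb.
#' @return `list(kept = , discarded = )` of record data frames.
#' @export
filter_scaffolds <- function(records, min_len_bp = 35000) {
  keep <- nchar(records$seq) > min_len_bp
  list(kept = records[keep, , drop = FALSE],
       discarded = records[!keep, , drop = FALSE])
}
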