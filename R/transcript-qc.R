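# Post-processing of assembled transcript contigs: end trimming, DUST-style
# low-complexity masking, length/complexity filtering, six-frame ORF
# discovery, consistent read-pair coverage, chimera splitting at uncovered
# junctions, and strand orientation from read-pair votes.

#' Trim contig ends
#'
#' Removes the first and last `n` bases of each sequence (assembler ends are
#' unreliable); sequences shorter than `2n` become empty.
#'
#' @param seq character vector of DNA strings.
#' @param n bases to remove from each end (default 5).
#' @return trimmed character vector.
#' @export
trim_ends <- function(seq, n = 5L) {
  if (n == 0L) return(seq)
  len <- nchar(seq)
  out <- character(length(seq))
  ok <- len > 2L * n
  out[ok] <- substr(seq[ok], n + 1L, len[ok] - n)
  out
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

dna_codes <- function(seq) {
  # A=0 C=1 G=2 T=3, NA for N
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  unname(c(A = 0L, C = 1L, G = 2L, T = 3L, N = NA_integer_)[chars])
}

#' Low-complexity masking with a windowed symmetric DUST score
#'
#' Each window of `window` bases gets the symmetric DUST score
#' `S = 10 * sum_t c_t (c_t - 1) / 2 / (w - 2)` over its triplet counts
#' `c_t`; windows scoring strictly above `score_threshold` are masked and
#' overlapping masked windows merged. Triplets containing N are not counted
#' (the denominator is unchanged). Sequences shorter than the window are
#' scored as a single window.
#'
#' @param seq one DNA string.
#' @param window window width in bases (default 64).
#' @param score_threshold mask windows with score strictly above this
#'   (default 20).
#' @return interval data frame of merged masked regions (0-based half-open).
#' @export
dust_mask <- function(seq, window = 64L, score_threshold = 20) {
  L <- nchar(seq)
  empty <- data.frame(start = integer(), end = integer())
  if (L < 3L) return(empty)
  code <- dna_codes(seq)
  trip <- 16L * code[1:(L - 2L)] + 4L * code[2:(L - 1L)] + code[3:L]
  w <- min(window, L)
  tw <- w - 2L                      # triplets per window
  nwin <- L - w + 1L
  counts <- integer(64L)
  sum_pairs <- 0
  add <- function(t) {
    if (!is.na(t)) {
      sum_pairs <<- sum_pairs + counts[t + 1L]
      counts[t + 1L] <<- counts[t + 1L] + 1L
    }
  }
  drop1 <- function(t) {
    if (!is.na(t)) {
      counts[t + 1L] <<- counts[t + 1L] - 1L
      sum_pairs <<- sum_pairs - counts[t + 1L]
    }
  }
  for (j in 1:tw) add(trip[j])
  masked_start <- integer(0); masked_end <- integer(0)
  for (i in seq_len(nwin)) {
    if (10 * sum_pairs / tw > score_threshold) {
      masked_start <- c(masked_start, i - 1L)
      masked_end <- c(masked_end, i - 1L + w)
    }
    if (i < nwin) {
      drop1(trip[i])
      add(trip[i + tw])
    }
  }
  if (!length(masked_start)) return(empty)
  merge_intervals(data.frame(start = masked_start, end = masked_end))
}

#' Length and complexity filter for transcript contigs
#'
#' Keeps contigs strictly longer than `min_len` with an unmasked fraction
#' strictly above `min_unmasked`.
#'
#' @param records `seq_records()` data frame.
#' @param masks list of masked-interval data frames, parallel to `records`
#'   (e.g. from [dust_mask()]).
#' @param min_len minimum length in bp, exclusive (default 150).
#' @param min_unmasked minimum unmasked fraction, exclusive (default 0.75).
#' @return list with `kept` (record subset) and `report` (per-contig length,
#'   masked bases, unmasked fraction, kept flag).
#' @export
complexity_filter <- function(records, masks, min_len = 150L,
                              min_unmasked = 0.75) {
  stopifnot(length(masks) == nrow(records))
  len <- nchar(records$seq)
  masked <- vapply(masks, iv_width, integer(1))
  unmasked_frac <- ifelse(len > 0L, (len - masked) / len, 0)
  keep <- len > min_len & unmasked_frac > min_unmasked
  list(kept = records[keep, , drop = FALSE],
       report = data.frame(id = records$id, length = len, masked = masked,
                           unmasked_frac = unmasked_frac, kept = keep))
}

#' Find complete ORFs on six frames
#'
#' Reports every complete open reading frame (first in-frame ATG after the
#' previous stop, through the next in-frame stop codon) of at least `min_aa`
#' codons before the stop, on both strands, in contig coordinates.
#'
#' @param seq one DNA string.
#' @param min_aa minimum protein length in codons (default 100).
#' @return data frame `start`, `end` (0-based half-open, stop codon
#'   included), `strand`, `frame` (0-2 on the scanned strand); ORF widths
#'   are divisible by 3.
#' @export
find_orfs <- function(seq, min_aa = 100L) {
  L <- nchar(seq)
  rows <- list()
  for (str in c("+", "-")) {
    s <- if (str == "+") seq else revcomp(seq)
    for (frame in 0:2) {
      ncod <- (L - frame) %/% 3L
      if (ncod < min_aa + 1L) next
      pos <- frame + 3L * (seq_len(ncod) - 1L)
      codons <- substring(s, pos + 1L, pos + 3L)
      stops <- which(codons %in% STOP_CODONS)
      atgs <- codons == "ATG"
      prev <- 0L
      for (st in stops) {
        cand <- if (st - 1L >= prev + 1L) which(atgs[(prev + 1L):(st - 1L)])
                else integer(0)
        if (length(cand)) {
          atg <- prev + cand[1]
          if (st - atg >= min_aa) {
            a <- frame + 3L * (atg - 1L)      # 0-based on scanned strand
            b <- frame + 3L * st              # end incl. stop, exclusive
            if (str == "-") { tmp <- a; a <- L - b; b <- L - tmp }
            rows[[length(rows) + 1L]] <-
              data.frame(start = a, end = b, strand = str, frame = frame)
          }
        }
        prev <- st
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), frame = integer()))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$end, out$strand), , drop = FALSE]
}

#' Coverage from consistent read pairs
#'
#' A pair is consistent when its mates are convergent (the leftmost read on
#' the plus strand, the rightmost on the minus strand) and the outer span is
#' at most `max_insert`. Depth is incremented over the full outer span of
#' each consistent pair; strand votes are tallied from read-1 orientation.
#'
#' @param pairs data frame with columns `r1_start`, `r1_end`, `r1_strand`,
#'   `r2_start`, `r2_end`, `r2_strand` (intervals 0-based half-open, within
#'   the contig).
#' @param contig_len contig length in bp.
#' @param contig_id contig identifier for the track.
#' @param max_insert maximum outer span of a consistent pair (default 1000).
#' @return a [coverage_track()].
#' @export
pair_coverage <- function(pairs, contig_len, contig_id = "contig",
                          max_insert = 1000L) {
  delta <- numeric(contig_len + 1L)
  plus <- 0L; minus <- 0L
  if (nrow(pairs)) {
    bounds_ok <- pairs$r1_start >= 0L & pairs$r2_start >= 0L &
      pairs$r1_end <= contig_len & pairs$r2_end <= contig_len &
      pairs$r1_start < pairs$r1_end & pairs$r2_start < pairs$r2_end
    if (!all(bounds_ok)) {
      stop(sprintf("pair_coverage: read interval out of contig bounds at row %d",
                   which(!bounds_ok)[1]))
    }
    lo <- pmin(pairs$r1_start, pairs$r2_start)
    hi <- pmax(pairs$r1_end, pairs$r2_end)
    left_strand <- ifelse(pairs$r1_start <= pairs$r2_start,
                          pairs$r1_strand, pairs$r2_strand)
    right_strand <- ifelse(pairs$r1_start <= pairs$r2_start,
                           pairs$r2_strand, pairs$r1_strand)
    consistent <- left_strand == "+" & right_strand == "-" &
      (hi - lo) <= max_insert
    for (i in which(consistent)) {
      delta[lo[i] + 1L] <- delta[lo[i] + 1L] + 1
      delta[hi[i] + 1L] <- delta[hi[i] + 1L] - 1
    }
    plus <- sum(consistent & pairs$r1_strand == "+")
    minus <- sum(consistent & pairs$r1_strand == "-")
  }
  coverage_track(contig_id, cumsum(delta[seq_len(contig_len)]), plus, minus)
}

# maximal runs of depth 0 as an interval data frame
zero_runs <- function(depth) {
  if (!length(depth)) return(data.frame(start = integer(), end = integer()))
  r <- rle(depth == 0L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Split chimeric contigs at uncovered junctions
#'
#' Candidate junctions are maximal runs of zero consistent-pair coverage of
#' at least `min_gap` bases. A junction is actionable only when it overlaps
#' no ORF and no domain interval; the contig is cut there, the uncovered gap
#' bases are removed (the junction sequence is an assembly artefact), and
#' sub-contigs are renamed `id.1`, `id.2`, ... left to right. Abrupt
#' coverage shifts (>= 10-fold within 20 bp between non-zero depths) are
#' flagged in the report but never cut.
#'
#' @param record one-row `seq_records()` data frame.
#' @param track the contig's [coverage_track()].
#' @param orfs,domains interval data frames on this contig (may be empty).
#' @param min_gap minimum zero-coverage run length to consider (default 10).
#' @return list: `pieces` (record data frame, original record when no cut),
#'   `gaps` (per-candidate start/end/actionable), `n_cuts`,
#'   `abrupt_shifts` (positions flagged).
#' @export
split_chimeric <- function(record, track, orfs = NULL, domains = NULL,
                           min_gap = 10L) {
  stopifnot(nrow(record) == 1L)
  L <- nchar(record$seq)
  if (length(track$depth) != L) {
    stop(sprintf("coverage track length %d does not match contig %s (%d bp)",
                 length(track$depth), record$id, L))
  }
  blocked <- rbind(
    if (!is.null(orfs) && nrow(orfs)) orfs[, c("start", "end")],
    if (!is.null(domains) && nrow(domains)) domains[, c("start", "end")])
  if (is.null(blocked)) blocked <- data.frame(start = integer(), end = integer())
  gaps <- zero_runs(track$depth)
  gaps <- gaps[gaps$end - gaps$start >= min_gap, , drop = FALSE]
  gaps$actionable <- if (nrow(gaps)) !overlaps_any(gaps, blocked) else logical(0)
  cut <- gaps[gaps$actionable, , drop = FALSE]
  shifts <- abrupt_shifts(track$depth)
  if (!nrow(cut)) {
    return(list(pieces = record, gaps = gaps, n_cuts = 0L,
                abrupt_shifts = shifts))
  }
  bounds <- data.frame(start = c(0L, cut$end), end = c(cut$start, L))
  bounds <- bounds[bounds$end > bounds$start, , drop = FALSE]
  pieces <- seq_records(
    paste0(record$id, ".", seq_len(nrow(bounds))),
    substring(record$seq, bounds$start + 1L, bounds$end),
    record$desc)
  list(pieces = pieces, gaps = gaps, n_cuts = nrow(cut),
       abrupt_shifts = shifts)
}

# >= 10-fold change between non-zero depths 20 bp apart (reported, not cut)
abrupt_shifts <- function(depth, fold = 10, span = 20L) {
  L <- length(depth)
  if (L <= span) return(integer(0))
  a <- depth[1:(L - span)]
  b <- depth[(span + 1):L]
  which(a > 0L & b > 0L & (a / b >= fold | b / a >= fold))
}

#' Run the chimera splitter over a contig set and score recovery
#'
#' Applies [split_chimeric()] to every contig and, when planted-junction
#' truth is supplied, scores recovery: a planted splittable junction counts
#' as recovered when an actionable gap with exactly its interval is cut;
#' any cut without a matching planted junction is a false positive.
#'
#' @param contigs `seq_records()` data frame.
#' @param tracks named list of coverage tracks (by contig id).
#' @param orfs,domains BED-style data frames (`scaffold_id`, `start`,
#'   `end`).
#' @param truth optional truth data frame from
#'   [simulate_chimeric_contigs()].
#' @param min_gap passed to [split_chimeric()].
#' @return list: `pieces` (all output records), `cuts` (data frame
#'   contig_id/start/end of actionable gaps cut), and when truth is given
#'   `precision`, `recall`.
#' @export
split_contig_set <- function(contigs, tracks, orfs, domains, truth = NULL,
                             min_gap = 10L) {
  pieces <- list(); cuts <- list()
  for (i in seq_len(nrow(contigs))) {
    rec <- contigs[i, , drop = FALSE]
    res <- split_chimeric(
      rec, tracks[[rec$id]],
      orfs = orfs[orfs$scaffold_id == rec$id, , drop = FALSE],
      domains = domains[domains$scaffold_id == rec$id, , drop = FALSE],
      min_gap = min_gap)
    pieces[[i]] <- res$pieces
    g <- res$gaps[res$gaps$actionable, , drop = FALSE]
    if (nrow(g)) {
      cuts[[length(cuts) + 1L]] <-
        data.frame(contig_id = rec$id, start = g$start, end = g$end)
    }
  }
  cuts <- if (length(cuts)) do.call(rbind, cuts) else
    data.frame(contig_id = character(), start = integer(), end = integer())
  out <- list(pieces = do.call(rbind, pieces), cuts = cuts)
  if (!is.null(truth)) {
    planted <- truth[truth$splittable, , drop = FALSE]
    key <- function(id, s, e) paste(id, s, e)
    truth_keys <- key(planted$contig_id, planted$break_start,
                      planted$break_end)
    cut_keys <- key(cuts$contig_id, cuts$start, cuts$end)
    tp <- sum(cut_keys %in% truth_keys)
    out$precision <- if (nrow(cuts)) tp / nrow(cuts) else NA_real_
    out$recall <- if (nrow(planted)) tp / nrow(planted) else NA_real_
  }
  out
}

#' Orient a contig from read-pair strand votes
#'
#' Reverse-complements the contig when minus-strand votes outnumber plus;
#' ties keep the input orientation and are flagged ambiguous.
#'
#' @param record one-row `seq_records()` data frame.
#' @param track the contig's [coverage_track()] carrying the votes.
#' @return list: `record` (possibly reverse-complemented), `flipped`,
#'   `ambiguous`.
#' @export
orient_contig <- function(record, track) {
  stopifnot(nrow(record) == 1L)
  flip <- track$minus_pairs > track$plus_pairs
  if (flip) record$seq <- revcomp(record$seq)
  list(record = record, flipped = flip,
       ambiguous = track$minus_pairs == track$plus_pairs)
}
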