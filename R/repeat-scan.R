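# Satellite-monomer and reference-copy scanning by deterministic local
# alignment with iterative masking: align query vs scaffold, record the best
# local hit, mask it with N, realign, until the best score drops below a
# floor. Replaces seeded heuristic search with an exact method at desk
# scale; scoring is match +1, mismatch -1, gap open -2, gap extend -1
# (a gap of length L costs L + 1).

sw_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = FALSE)
}

# best local alignment of query vs subject; returns scaffold interval
# (0-based half-open), score, identity %, query coverage fraction
sw_best_hit <- function(query, subject) {
  p <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(subject),
    type = "local", substitutionMatrix = sw_submat(),
    gapOpening = 1, gapExtension = 1)
  qa <- Biostrings::pattern(p)
  sa <- Biostrings::subject(p)
  list(score = Biostrings::score(p),
       s_start = Biostrings::start(sa) - 1L,
       s_end = Biostrings::end(sa),
       identity = Biostrings::pid(p),
       q_coverage = (Biostrings::end(qa) - Biostrings::start(qa) + 1L) /
         nchar(query))
}

# iterative masked local alignment: per round, the best-scoring hit of any
# query (e.g. both strands of a monomer) is recorded and masked with N, so
# reported intervals never overlap across queries
iterate_masked_hits <- function(queries, scaffold_seq, min_score,
                                max_hits = 10000L) {
  queries <- as.list(queries)
  hits <- list()
  masked <- scaffold_seq
  repeat {
    if (length(hits) >= max_hits) break
    cand <- lapply(queries, sw_best_hit, subject = masked)
    scores <- vapply(cand, `[[`, numeric(1), "score")
    if (max(scores) < min_score) break
    best <- which.max(scores)
    h <- cand[[best]]
    h$query <- if (!is.null(names(queries))) names(queries)[best] else
      as.character(best)
    hits[[length(hits) + 1L]] <- h
    substr(masked, h$s_start + 1L, h$s_end) <-
      strrep("N", h$s_end - h$s_start)
  }
  hits
}

# approximate e-value for an ungapped-style +1/-1 local score via the
# Karlin-Altschul formula E = K m n exp(-lambda S), default parameters for
# the +1/-1 scoring system; marked approximate (no finite-size correction)
sw_evalue <- function(score, m, n, K = 0.711, lambda = 1.33) {
  K * as.numeric(m) * as.numeric(n) * exp(-lambda * score)
}

#' Scan scaffolds for a satellite monomer
#'
#' Finds all non-overlapping local-alignment occurrences of a satellite
#' monomer in each scaffold by iterative masking, keeping hits that cover
#' strictly more than `min_coverage` of the monomer at `min_identity`
#' percent identity or better (coverage strict, identity inclusive). Both
#' strands are scanned (the monomer and its reverse complement). With
#' `mode = "evalue"` the coverage/identity filter is replaced by an
#' approximate Karlin-Altschul e-value threshold on the alignment score
#' (the variant-search style of thresholding); this conversion is
#' approximate by design.
#'
#' @param scaffolds `seq_records()` data frame.
#' @param monomer monomer DNA string (>= 20 bp).
#' @param min_coverage monomer-coverage threshold, exclusive (default 0.80).
#' @param min_identity percent-identity threshold, inclusive (default 90).
#' @param min_score alignment-score floor ending the iteration; default
#'   half the monomer length, safely below any hit passing the thresholds.
#' @param mode `"coverage"` (default) or `"evalue"`.
#' @param max_evalue e-value ceiling used in `"evalue"` mode
#'   (default 1e-5).
#' @return list: `occurrences` (data frame `scaffold_id`, `start`, `end`,
#'   `identity`, `monomer_coverage`, `strand`), `summary`
#'   (`n_occurrences`, `n_scaffolds`, `total_bp`).
#' @export
scan_monomer <- function(scaffolds, monomer, min_coverage = 0.80,
                         min_identity = 90.0,
                         min_score = floor(nchar(monomer) / 2),
                         mode = c("coverage", "evalue"),
                         max_evalue = 1e-5) {
  if (nchar(monomer) < 20L) stop("scan_monomer: monomer shorter than 20 bp")
  mode <- match.arg(mode)
  rows <- list()
  queries <- c("+" = monomer, "-" = revcomp(monomer))
  for (i in seq_len(nrow(scaffolds))) {
    for (h in iterate_masked_hits(queries, scaffolds$seq[i], min_score)) {
      keep <- if (mode == "coverage") {
        h$q_coverage > min_coverage && h$identity >= min_identity
      } else {
        sw_evalue(h$score, nchar(monomer),
                  nchar(scaffolds$seq[i])) <= max_evalue
      }
      if (keep) {
        rows[[length(rows) + 1L]] <- data.frame(
          scaffold_id = scaffolds$id[i], start = h$s_start, end = h$s_end,
          identity = h$identity, monomer_coverage = h$q_coverage,
          strand = h$query)
      }
    }
  }
  occ <- if (length(rows)) do.call(rbind, rows) else
    data.frame(scaffold_id = character(), start = integer(),
               end = integer(), identity = numeric(),
               monomer_coverage = numeric(), strand = character())
  occ <- occ[order(occ$scaffold_id, occ$start), , drop = FALSE]
  rownames(occ) <- NULL
  list(occurrences = occ,
       summary = list(n_occurrences = nrow(occ),
                      n_scaffolds = length(unique(occ$scaffold_id)),
                      total_bp = if (nrow(occ)) sum(occ$end - occ$start) else 0L))
}

#' Count copies of a reference sequence in a scaffold
#'
#' Same iterative-masking local alignment, against a full-length reference
#' (e.g. a mitochondrial genome inside a nuclear scaffold): copies are hits
#' covering strictly more than `min_coverage` of the reference at
#' `min_identity` percent identity or better.
#'
#' @param scaffold one-row `seq_records()` data frame.
#' @param reference reference DNA string (not longer than the scaffold).
#' @param min_identity percent-identity threshold, inclusive (default 80).
#' @param min_coverage reference-coverage threshold, exclusive
#'   (default 0.80).
#' @param min_score alignment-score floor (default 0.4 x reference length).
#' @return list: `n_copies`, `intervals` (data frame with scaffold
#'   coordinates, identity, coverage).
#' @export
count_reference_copies <- function(scaffold, reference, min_identity = 80.0,
                                   min_coverage = 0.80,
                                   min_score = floor(0.4 * nchar(reference))) {
  stopifnot(nrow(scaffold) == 1L)
  if (nchar(reference) > nchar(scaffold$seq)) {
    stop("count_reference_copies: reference longer than scaffold")
  }
  hits <- iterate_masked_hits(reference, scaffold$seq, min_score)
  rows <- list()
  for (h in hits) {
    if (h$q_coverage > min_coverage && h$identity >= min_identity) {
      rows[[length(rows) + 1L]] <- data.frame(
        scaffold_id = scaffold$id, start = h$s_start, end = h$s_end,
        identity = h$identity, reference_coverage = h$q_coverage)
    }
  }
  iv <- if (length(rows)) do.call(rbind, rows) else
    data.frame(scaffold_id = character(), start = integer(),
               end = integer(), identity = numeric(),
               reference_coverage = numeric())
  iv <- iv[order(iv$start), , drop = FALSE]
  rownames(iv) <- NULL
  list(n_copies = nrow(iv), intervals = iv)
}
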