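# Retention rules applied to transcript and protein alignment evidence
# before gene prediction. All thresholds are strict (>), following the
# "higher than / more than" phrasing of each rule.

#' Retain transcript (mRNA) alignments
#'
#' Keeps aligned contigs whose aligned fraction of the contig length is
#' strictly above `min_overlap` and whose identity is strictly above
#' `min_identity`.
#'
#' @param ev data frame with columns `evidence_id`, `contig_len`,
#'   `aligned_len`, `identity` (percent).
#' @param min_overlap aligned fraction threshold, exclusive (default 0.80).
#' @param min_identity percent identity threshold, exclusive (default 95).
#' @return list `kept`, `dropped` (with a `reason` column on dropped rows).
#' @export
retain_transcript_alignments <- function(ev, min_overlap = 0.80,
                                         min_identity = 95.0) {
  frac <- ev$aligned_len / ev$contig_len
  keep <- frac > min_overlap & ev$identity > min_identity
  dropped <- ev[!keep, , drop = FALSE]
  dropped$reason <- ifelse(frac[!keep] <= min_overlap, "LOW_OVERLAP",
                           "LOW_IDENTITY")
  list(kept = ev[keep, , drop = FALSE], dropped = dropped)
}

#' Retain protein matches
#'
#' Two-stage rule: per protein, matches scoring strictly above
#' `score_frac * best score in the group` survive stage 1; then only
#' proteins with strictly more than `min_cov` of their length aligned keep
#' their surviving matches (aligned coverage taken as the maximum
#' `aligned_len` among stage-1 survivors).
#'
#' @param ev data frame with columns `protein_id`, `protein_len`,
#'   `aligned_len`, `score`.
#' @param score_frac fraction of the per-protein best score, exclusive
#'   (default 0.9).
#' @param min_cov aligned fraction of the protein length, exclusive
#'   (default 0.5).
#' @return list `kept`, `dropped` (with `reason`).
#' @export
retain_protein_matches <- function(ev, score_frac = 0.9, min_cov = 0.5) {
  if (!nrow(ev)) return(list(kept = ev, dropped = ev))
  best <- tapply(ev$score, ev$protein_id, max)
  stage1 <- ev$score > score_frac * unname(best[ev$protein_id])
  # a group's best match always scores above score_frac * itself
  surv_cov <- tapply(ifelse(stage1, ev$aligned_len, -Inf), ev$protein_id, max)
  covered <- unname(surv_cov[ev$protein_id]) / ev$protein_len > min_cov
  keep <- stage1 & covered
  dropped <- ev[!keep, , drop = FALSE]
  dropped$reason <- ifelse(!stage1[!keep], "LOW_SCORE", "LOW_COVERAGE")
  list(kept = ev[keep, , drop = FALSE], dropped = dropped)
}

#' Remove sample-specific single-exon transcripts
#'
#' A single-exon aligned transcript is removed when its genomic interval
#' overlaps (>= 1 base, same scaffold and strand) no transcript from a
#' different sample; multi-exon transcripts are always kept. Run before
#' combining transcript evidence into gene models.
#'
#' @param tx data frame with columns `transcript_id`, `sample`,
#'   `scaffold_id`, `start`, `end`, `strand`, `n_exons`.
#' @return list `kept`, `dropped`.
#' @export
drop_sample_specific_single_exon <- function(tx) {
  keep <- rep(TRUE, nrow(tx))
  single <- which(tx$n_exons == 1L)
  for (i in single) {
    others <- tx$scaffold_id == tx$scaffold_id[i] &
      tx$strand == tx$strand[i] & tx$sample != tx$sample[i]
    hit <- others & tx$start < tx$end[i] & tx$end > tx$start[i]
    keep[i] <- any(hit)
  }
  list(kept = tx[keep, , drop = FALSE], dropped = tx[!keep, , drop = FALSE])
}
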