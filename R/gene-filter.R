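# Sequential post-prediction filtering cascade. Each predicted gene is
# classified KEEP or REMOVE with a single reason code; rules are evaluated
# in order and the first match wins:
#
#   R1 (any gene)        highly repeat-covered (>90% of exonic bases) or
#                        TE-tagged, without any pfam/blastp hit -> REPEAT_TE
#   R2 (intronless only) no protein-species support, UTR ratio > 80%,
#                        no pfam/blastp hit                     -> UTR_RNA_ONLY
#   R3 (intronless only) none of (>=1 mRNA sample and >=1 protein species;
#                        >=2 mRNA samples; same-species curated protein),
#                        and no pfam/blastp hit                 -> WEAK_EVIDENCE
#   otherwise KEEP.

FILTER_REASONS <- c("KEPT", "REPEAT_TE", "UTR_RNA_ONLY", "WEAK_EVIDENCE")

validate_evidence_row <- function(ev) {
  need <- setdiff(EVIDENCE_COLS, "gene_id")
  bad <- vapply(need, function(f) {
    v <- ev[[f]]
    is.null(v) || (f != "utr_ratio" && is.na(v))  # utr_ratio may be NA
  }, logical(1))
  if (any(bad)) {
    stop(sprintf("evidence for gene %s lacks field(s): %s",
                 if (!is.null(ev$gene_id)) ev$gene_id else "?",
                 paste(need[bad], collapse = ", ")))
  }
  if (ev$repeat_cov < 0 || ev$repeat_cov > 1) {
    stop("repeat_cov must lie in [0, 1]")
  }
  invisible(ev)
}

#' Classify one predicted gene
#'
#' Applies the filtering cascade to one gene given its evidence record; see
#' the rule order in the package vignette. `utr_ratio` may be `NA` when the
#' model annotates no UTR/CDS, in which case the UTR rule cannot fire.
#'
#' @param intronless logical; does the model have exactly one exon?
#' @param ev one-row evidence record (list or data frame row) with fields
#'   `has_pfam`, `has_blastp`, `repeat_cov`, `te_tagged`, `n_mrna_samples`,
#'   `n_protein_species`, `has_self_uniprot`, `utr_ratio`.
#' @param repeat_cov_max repeat-coverage threshold, exclusive (default 0.90).
#' @param utr_ratio_max UTR-ratio threshold, exclusive (default 0.80).
#' @return list `verdict` ("KEEP"/"REMOVE"), `reason`, `rule_trace`.
#' @export
classify_gene <- function(intronless, ev, repeat_cov_max = 0.90,
                          utr_ratio_max = 0.80) {
  validate_evidence_row(ev)
  no_hits <- !ev$has_pfam && !ev$has_blastp
  trace <- character(0)

  trace <- c(trace, "R1:repeat_te")
  if ((ev$repeat_cov > repeat_cov_max || ev$te_tagged) && no_hits) {
    return(list(verdict = "REMOVE", reason = "REPEAT_TE", rule_trace = trace))
  }
  if (intronless) {
    trace <- c(trace, "R2:utr_rna_only")
    if (ev$n_protein_species == 0L && !is.na(ev$utr_ratio) &&
        ev$utr_ratio > utr_ratio_max && no_hits) {
      return(list(verdict = "REMOVE", reason = "UTR_RNA_ONLY",
                  rule_trace = trace))
    }
    trace <- c(trace, "R3:weak_evidence")
    supported <- (ev$n_mrna_samples >= 1L && ev$n_protein_species >= 1L) ||
      ev$n_mrna_samples >= 2L || isTRUE(ev$has_self_uniprot)
    if (!supported && no_hits) {
      return(list(verdict = "REMOVE", reason = "WEAK_EVIDENCE",
                  rule_trace = trace))
    }
  }
  list(verdict = "KEEP", reason = "KEPT", rule_trace = c(trace, "KEEP"))
}

#' Filter a predicted gene set
#'
#' Applies [classify_gene()] to every model and summarises the outcome the
#' way annotation tables report it: counts per removal reason, intronless
#' fraction of the kept set, and mean/median gene and CDS lengths (gene
#' length is the genomic span; CDS length is spliced).
#'
#' @param models list of [gene_model()] objects.
#' @param evidence evidence data frame with one row per gene
#'   (see [read_evidence()]).
#' @param ... thresholds passed on to [classify_gene()].
#' @return list: `decisions` (per-gene data frame with `gene_id`, `verdict`,
#'   `reason`), `kept`/`removed` (model sublists), `summary`.
#' @export
filter_gene_set <- function(models, evidence, ...) {
  ids <- vapply(models, function(m) m$gene_id, character(1))
  if (anyDuplicated(evidence$gene_id)) stop("duplicate gene_id in evidence")
  orphan_m <- setdiff(ids, evidence$gene_id)
  orphan_e <- setdiff(evidence$gene_id, ids)
  if (length(orphan_m) || length(orphan_e)) {
    stop(sprintf("model/evidence id mismatch; models without evidence: %s; evidence without model: %s",
                 paste(head(orphan_m, 5), collapse = ","),
                 paste(head(orphan_e, 5), collapse = ",")))
  }
  rownames(evidence) <- evidence$gene_id
  res <- lapply(models, function(m) {
    classify_gene(is_intronless(m), as.list(evidence[m$gene_id, ]), ...)
  })
  decisions <- data.frame(
    gene_id = ids,
    verdict = vapply(res, `[[`, character(1), "verdict"),
    reason = vapply(res, `[[`, character(1), "reason"))
  keep <- decisions$verdict == "KEEP"
  kept <- models[keep]
  gene_len <- vapply(kept, function(m) diff(gene_span(m)), numeric(1))
  cds_len <- vapply(kept, function(m) as.numeric(iv_width(m$cds)), numeric(1))
  summary <- list(
    n_total = length(models),
    n_kept = sum(keep),
    n_removed = sum(!keep),
    removed_by_reason = table(factor(decisions$reason[!keep],
                                     levels = FILTER_REASONS[-1])),
    intronless_fraction_kept =
      if (sum(keep)) mean(vapply(kept, is_intronless, logical(1))) else NA_real_,
    gene_length_mean = if (sum(keep)) round_half_up(mean(gene_len)) else NA,
    gene_length_median = if (sum(keep)) median(gene_len) else NA,
    cds_length_mean = if (sum(keep)) round_half_up(mean(cds_len)) else NA,
    cds_length_median = if (sum(keep)) median(cds_len) else NA)
  list(decisions = decisions, kept = kept, removed = models[!keep],
       summary = summary)
}
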