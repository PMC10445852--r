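#' Construct a gene model
#'
#' A gene model holds the spliced structure of one predicted gene: sorted,
#' pairwise-disjoint exons plus CDS and UTR segments, all as 0-based
#' half-open intervals on one scaffold. CDS and UTR must lie inside the exon
#' union and be mutually disjoint. A gene is intronless iff it has exactly
#' one exon.
#'
#' @param gene_id gene identifier.
#' @param scaffold_id scaffold the gene lies on.
#' @param strand `+` or `-`.
#' @param exons,cds,utr interval data frames (`start`, `end`).
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, scaffold_id, strand, exons,
                       cds = intervals(), utr = intervals()) {
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  rownames(exons) <- NULL
  gm <- structure(list(gene_id = gene_id, scaffold_id = scaffold_id,
                       strand = strand,
                       exons = exons,
                       cds = cds[, c("start", "end"), drop = FALSE],
                       utr = utr[, c("start", "end"), drop = FALSE]),
                  class = "gene_model")
  validate_gene_model(gm)
}

validate_gene_model <- function(gm) {
  stopifnot(inherits(gm, "gene_model"))
  if (!gm$strand %in% c("+", "-", ".")) stop("gene strand must be +, - or .")
  validate_intervals(gm$exons, paste0("exon of ", gm$gene_id))
  validate_intervals(gm$cds, paste0("CDS of ", gm$gene_id))
  validate_intervals(gm$utr, paste0("UTR of ", gm$gene_id))
  if (nrow(gm$exons) == 0L) stop(sprintf("gene %s has no exons", gm$gene_id))
  if (nrow(gm$exons) > 1L &&
      any(gm$exons$start[-1] < gm$exons$end[-nrow(gm$exons)])) {
    stop(sprintf("gene %s: exons overlap or are unsorted", gm$gene_id))
  }
  for (part in c("cds", "utr")) {
    df <- gm[[part]]
    if (nrow(df) && covered_bases(df, gm$exons) != iv_width(df)) {
      stop(sprintf("gene %s: %s extends outside exons", gm$gene_id,
                   toupper(part)))
    }
  }
  if (covered_bases(gm$cds, gm$utr) > 0L) {
    stop(sprintf("gene %s: CDS and UTR overlap", gm$gene_id))
  }
  gm
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d(%s) %d exon(s), CDS %d bp, UTR %d bp\n",
              x$gene_id, x$scaffold_id, gene_span(x)[1], gene_span(x)[2],
              x$strand, nrow(x$exons), iv_width(x$cds), iv_width(x$utr)))
  invisible(x)
}

#' Is a gene model intronless (single exon)?
#' @param gm a `gene_model`.
#' @return logical.
#' @export
is_intronless <- function(gm) nrow(gm$exons) == 1L

gene_span <- function(gm) c(min(gm$exons$start), max(gm$exons$end))

#' Spliced UTR ratio of a gene model
#'
#' `UTR / (UTR + CDS)` over spliced (exonic) lengths; `NA` when the model
#' annotates neither CDS nor UTR.
#' @param gm a `gene_model`.
#' @return numeric in `[0, 1]` or `NA`.
#' @export
utr_ratio <- function(gm) {
  u <- iv_width(gm$utr); k <- iv_width(gm$cds)
  if (u + k == 0L) return(NA_real_)
  u / (u + k)
}
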