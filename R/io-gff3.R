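# GFF3 gene models: gene -> mRNA -> exon/CDS/five_prime_UTR/three_prime_UTR
# linked by ID/Parent. GFF coordinates are 1-based inclusive and converted to
# the internal 0-based half-open convention here and nowhere else. When a gene
# has several mRNA children the first by file order is used (gene sets are
# reported without isoforms).

#' Read gene models from GFF3
#'
#' @param path GFF3 file with gene/mRNA/exon/CDS/UTR features.
#' @return list of [gene_model()] objects, one per gene, in file order.
#' @export
read_gff3 <- function(path) {
  g <- as.data.frame(rtracklayer::readGFF(
    path, columns = c("seqid", "type", "start", "end", "strand"),
    tags = c("ID", "Parent")))
  g$Parent <- vapply(g$Parent, function(p)
    if (length(p)) as.character(p[[1]]) else NA_character_, character(1))
  g$type <- as.character(g$type)
  genes <- g[g$type == "gene", , drop = FALSE]
  models <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    gid <- genes$ID[i]
    mrnas <- g[g$type == "mRNA" & !is.na(g$Parent) & g$Parent == gid, ,
               drop = FALSE]
    parent_id <- if (nrow(mrnas)) mrnas$ID[1] else gid
    kids <- g[!is.na(g$Parent) & g$Parent == parent_id, , drop = FALSE]
    part <- function(types) {
      k <- kids[kids$type %in% types, , drop = FALSE]
      intervals(k$start - 1L, k$end)  # 1-based inclusive -> 0-based half-open
    }
    gm <- tryCatch(
      gene_model(gene_id = gid,
                 scaffold_id = as.character(genes$seqid[i]),
                 strand = as.character(genes$strand[i]),
                 exons = part("exon"),
                 cds = part("CDS"),
                 utr = part(c("five_prime_UTR", "three_prime_UTR", "UTR"))),
      error = function(e) stop(sprintf("GFF3 validation failed for gene %s: %s",
                                       gid, conditionMessage(e))))
    models[[i]] <- gm
  }
  models
}

#' Write gene models to GFF3
#'
#' Emits gene, mRNA, exon, CDS and UTR lines (UTR segments upstream of the
#' first CDS base in transcription order as five_prime_UTR, the rest as
#' three_prime_UTR), converting back to 1-based inclusive coordinates.
#'
#' @param models list of [gene_model()] objects.
#' @param path output file.
#' @export
write_gff3 <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  fmt <- function(scaf, type, df, strand, attr) {
    sprintf("%s\tannotqc\t%s\t%d\t%d\t.\t%s\t.\t%s",
            scaf, type, df$start + 1L, df$end, strand, attr)
  }
  for (gm in models) {
    sp <- gene_span(gm)
    span <- data.frame(start = sp[1], end = sp[2])
    mid <- paste0(gm$gene_id, ".t1")
    writeLines(fmt(gm$scaffold_id, "gene", span, gm$strand,
                   paste0("ID=", gm$gene_id)), con)
    writeLines(fmt(gm$scaffold_id, "mRNA", span, gm$strand,
                   paste0("ID=", mid, ";Parent=", gm$gene_id)), con)
    writeLines(fmt(gm$scaffold_id, "exon", gm$exons, gm$strand,
                   paste0("Parent=", mid)), con)
    if (nrow(gm$cds)) {
      writeLines(fmt(gm$scaffold_id, "CDS", gm$cds, gm$strand,
                     paste0("ID=", mid, ".cds;Parent=", mid)), con)
    }
    if (nrow(gm$utr)) {
      cds_start <- if (nrow(gm$cds)) min(gm$cds$start) else Inf
      cds_end <- if (nrow(gm$cds)) max(gm$cds$end) else -Inf
      five <- if (gm$strand == "-") gm$utr$start >= cds_end
              else gm$utr$end <= cds_start
      writeLines(fmt(gm$scaffold_id,
                     ifelse(five, "five_prime_UTR", "three_prime_UTR"),
                     gm$utr, gm$strand, paste0("Parent=", mid)), con)
    }
  }
  invisible(path)
}
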