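HIT_COLS <- c("query_id", "subject_id", "pct_identity", "aln_len",
              "mismatches", "gap_opens", "qstart", "qend", "sstart", "send",
              "evalue", "bitscore")

#' Read a 12-column tabular similarity hit file
#'
#' The classic 12-column tab-separated dialect (query, subject, %identity,
#' alignment length, mismatches, gap opens, qstart, qend, sstart, send,
#' e-value, bitscore), no header, coordinates 1-based inclusive. Subject
#' coordinates of minus-strand hits arrive reversed (`sstart > send`); they
#' are kept as read and flagged in a `subject_strand` column.
#'
#' @param path hit file; an empty file yields a 0-row table.
#' @return data frame with the 12 standard columns plus `subject_strand`.
#' @export
read_hits <- function(path) {
  empty <- data.frame(query_id = character(), subject_id = character(),
                      pct_identity = numeric(), aln_len = integer(),
                      mismatches = integer(), gap_opens = integer(),
                      qstart = integer(), qend = integer(),
                      sstart = integer(), send = integer(),
                      evalue = numeric(), bitscore = numeric(),
                      subject_strand = character())
  if (file.size(path) == 0) return(empty)
  h <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, col.names = HIT_COLS,
               colClasses = "character", quote = "", comment.char = "#"),
    error = function(e) stop(sprintf("malformed hit table %s: %s", path,
                                     conditionMessage(e))))
  for (j in 3:12) h[[j]] <- suppressWarnings(as.numeric(h[[j]]))
  num <- h[, 3:12]
  if (anyNA(num)) {
    stop(sprintf("non-numeric field in hit table %s at line %d", path,
                 which(rowSums(is.na(num)) > 0)[1]))
  }
  if (any(h$qstart > h$qend)) {
    stop(sprintf("hit table %s: qstart > qend at line %d", path,
                 which(h$qstart > h$qend)[1]))
  }
  if (any(h$evalue < 0)) stop(sprintf("hit table %s: negative e-value", path))
  h$subject_strand <- ifelse(h$sstart <= h$send, "+", "-")
  h
}

#' Write hits in the 12-column tabular dialect
#' @param hits data frame as returned by [read_hits()].
#' @param path output file.
#' @export
write_hits <- function(hits, path) {
  write.table(format(hits[, HIT_COLS], trim = TRUE, scientific = NA,
                     digits = 15),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED4 interval file
#'
#' BED is natively 0-based half-open, matching the internal convention.
#' @param path BED file with >= 3 columns (chrom, start, end[, name]).
#' @return data frame `scaffold_id`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0) {
    return(data.frame(scaffold_id = character(), start = integer(),
                      end = integer(), name = character()))
  }
  b <- read.table(path, sep = "\t", header = FALSE, quote = "",
                  comment.char = "#")
  if (ncol(b) < 3L) stop(sprintf("BED file %s has fewer than 3 columns", path))
  out <- data.frame(scaffold_id = as.character(b[[1]]),
                    start = as.integer(b[[2]]), end = as.integer(b[[3]]),
                    name = if (ncol(b) >= 4L) as.character(b[[4]]) else ".")
  validate_intervals(out, paste0("BED record in ", path))
  out
}

#' Write intervals as BED4
#' @param bed data frame with `scaffold_id`, `start`, `end` and optional `name`.
#' @param path output file.
#' @export
write_bed <- function(bed, path) {
  nm <- if ("name" %in% names(bed)) bed$name else "."
  write.table(data.frame(bed$scaffold_id, bed$start, bed$end, nm),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a per-base coverage track
#'
#' Two tab-separated columns, 1-based position and integer depth, one row per
#' base. Consistent-pair strand votes are carried in `#plus_pairs=` /
#' `#minus_pairs=` comment headers.
#'
#' @param path coverage file.
#' @param contig_id contig the track belongs to.
#' @return a coverage track: `list(contig_id, depth, plus_pairs, minus_pairs)`.
#' @export
read_coverage <- function(path, contig_id) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  grab <- function(key) {
    m <- grep(paste0("^#", key, "="), meta, value = TRUE)
    if (length(m)) as.integer(sub(".*=", "", m[1])) else 0L
  }
  d <- if (length(body)) {
    f <- read.table(text = body, sep = "\t", col.names = c("pos", "depth"))
    stopifnot(identical(f$pos, seq_len(nrow(f))))
    as.integer(f$depth)
  } else integer()
  coverage_track(contig_id, d, grab("plus_pairs"), grab("minus_pairs"))
}

#' @rdname read_coverage
#' @param track a coverage track.
#' @export
write_coverage <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#plus_pairs=%d", track$plus_pairs),
               sprintf("#minus_pairs=%d", track$minus_pairs)), con)
  if (length(track$depth)) {
    writeLines(paste(seq_along(track$depth), track$depth, sep = "\t"), con)
  }
  invisible(path)
}

#' Construct a coverage track
#'
#' @param contig_id contig identifier.
#' @param depth non-negative integer depth per base (length = contig length).
#' @param plus_pairs,minus_pairs counts of consistent pairs voting for each
#'   transcript strand.
#' @return `list(contig_id, depth, plus_pairs, minus_pairs)`.
#' @export
coverage_track <- function(contig_id, depth, plus_pairs = 0L,
                           minus_pairs = 0L) {
  depth <- as.integer(depth)
  if (any(depth < 0L)) stop("coverage depth must be non-negative")
  list(contig_id = contig_id, depth = depth,
       plus_pairs = as.integer(plus_pairs),
       minus_pairs = as.integer(minus_pairs))
}

EVIDENCE_COLS <- c("gene_id", "has_pfam", "has_blastp", "repeat_cov",
                   "te_tagged", "n_mrna_samples", "n_protein_species",
                   "has_self_uniprot", "utr_ratio")

#' Read / write per-gene evidence tables
#'
#' Tab-separated with a header line; columns are exactly the evidence-record
#' fields used by the gene-filter cascade.
#' @param path file path.
#' @return data frame with the evidence columns.
#' @export
read_evidence <- function(path) {
  ev <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  missing <- setdiff(EVIDENCE_COLS, names(ev))
  if (length(missing)) {
    stop(sprintf("evidence table %s lacks column(s): %s", path,
                 paste(missing, collapse = ", ")))
  }
  ev$has_pfam <- as.logical(ev$has_pfam)
  ev$has_blastp <- as.logical(ev$has_blastp)
  ev$te_tagged <- as.logical(ev$te_tagged)
  ev$has_self_uniprot <- as.logical(ev$has_self_uniprot)
  ev
}

#' @rdname read_evidence
#' @param ev evidence data frame.
#' @export
write_evidence <- function(ev, path) {
  write.table(ev[, EVIDENCE_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
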