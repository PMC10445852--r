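# Sequence records are data frames with columns id, seq, desc. Sequences are
# stored as upper-case character strings over {A,C,G,T,N}; anything else is
# mapped to N on read with a warning.

#' Construct a sequence record table
#'
#' @param id character vector of identifiers (no whitespace).
#' @param seq character vector of DNA strings.
#' @param desc optional free-text descriptions.
#' @return data frame with columns `id`, `seq`, `desc`.
#' @export
seq_records <- function(id, seq, desc = "") {
  stopifnot(length(id) == length(seq))
  if (any(!nzchar(id)) || any(grepl("\\s", id))) {
    stop("sequence ids must be non-empty tokens without whitespace")
  }
  data.frame(id = as.character(id), seq = normalize_dna(seq),
             desc = rep_len(as.character(desc), length(id)))
}

# upper-case and map non-ACGTN letters to N (warn once per call)
normalize_dna <- function(seq) {
  seq <- toupper(as.character(seq))
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    warning(sprintf("%d sequence(s) contain letters outside {A,C,G,T,N}; mapped to N",
                    sum(bad)))
    seq[bad] <- gsub("[^ACGTN]", "N", seq[bad])
  }
  seq
}

#' Read a FASTA file
#'
#' Multi-line sequences are concatenated; the alphabet is normalized to
#' upper-case ACGTN (other letters become N with a warning). Records are
#' returned in file order.
#'
#' @param path FASTA file.
#' @return a `seq_records()` data frame (0 rows for an empty file).
#' @export
read_fasta <- function(path) {
  if (file.size(path) == 0) {
    return(data.frame(id = character(), seq = character(), desc = character()))
  }
  first <- readLines(path, n = 1L)
  if (!startsWith(first, ">")) {
    stop(sprintf("malformed FASTA %s: line 1 does not start with '>'", path))
  }
  x <- Biostrings::readBStringSet(path)
  headers <- names(x)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seq_records(id, as.character(x), desc)
}

#' Write sequence records to FASTA
#'
#' @param records a `seq_records()` data frame.
#' @param path output file.
#' @param width line-wrap width in bases.
#' @export
write_fasta <- function(records, path, width = 70L) {
  x <- Biostrings::BStringSet(records$seq)
  names(x) <- ifelse(nzchar(records$desc),
                     paste(records$id, records$desc), records$id)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Reverse-complement a DNA string
#'
#' @param seq character string over ACGTN.
#' @return the reverse complement, same alphabet.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
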