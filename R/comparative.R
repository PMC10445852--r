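# Two-genome comparative stage: reciprocal best-hit orthology, greedy
# macrosynteny chaining, circos-style link export, paralog clustering by
# connected components, family-expansion tables, and the ortholog CDS-length
# log-log regression.

#' Best hit per query
#'
#' Discards hits above `max_evalue`, then picks per query the hit with the
#' highest bitscore; ties broken by lower e-value, then lexicographic
#' subject id.
#'
#' @param hits hit data frame (see [read_hits()]).
#' @param max_evalue inclusive e-value ceiling (default 1e-10).
#' @return named character vector, query id -> subject id.
#' @export
best_hits <- function(hits, max_evalue = 1e-10) {
  h <- hits[hits$evalue <= max_evalue, , drop = FALSE]
  if (!nrow(h)) return(setNames(character(0), character(0)))
  h <- h[order(h$query_id, -h$bitscore, h$evalue, h$subject_id), ,
         drop = FALSE]
  h <- h[!duplicated(h$query_id), , drop = FALSE]
  setNames(h$subject_id, h$query_id)
}

#' Reciprocal best hits between two species
#'
#' A pair (a, b) is reported when a's best hit in B is b and b's best hit in
#' A is a, both at `max_evalue` or better.
#'
#' @param hits_ab,hits_ba hit tables in the two directions.
#' @param max_evalue inclusive e-value ceiling (default 1e-10).
#' @return data frame `gene_a`, `gene_b`, sorted by `gene_a`.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba, max_evalue = 1e-10) {
  ab <- best_hits(hits_ab, max_evalue)
  ba <- best_hits(hits_ba, max_evalue)
  a <- names(ab)
  mutual <- !is.na(ba[ab]) & ba[ab] == a
  out <- data.frame(gene_a = a[mutual], gene_b = unname(ab[mutual]))
  out[order(out$gene_a), , drop = FALSE]
}

#' Chain reciprocal best hits into macrosynteny blocks
#'
#' Within each (scaffold_a, chrom_b) pair, ortholog pairs are sorted by
#' position on genome A and chained greedily while positions on genome B
#' stay monotone (either direction, fixed by the first step) and adjacent
#' gaps stay within `max_gap` on both genomes. Chains shorter than
#' `min_genes` are discarded. Block orientation is `same` for b-increasing
#' chains, `inverted` for b-decreasing.
#'
#' @param pairs data frame with `gene_a`, `gene_b`, `scaffold_a`, `pos_a`,
#'   `chrom_b`, `pos_b` (positions = gene midpoints in bp).
#' @param min_genes minimum pairs per block (default 3).
#' @param max_gap maximum adjacent gap in bp on either genome
#'   (default 1e6).
#' @return data frame of blocks: `scaffold_a`, `chrom_b`, `n_genes`,
#'   `orientation`, `a_start`, `a_end`, `b_start`, `b_end`, plus a `genes`
#'   list-column of member gene_a ids.
#' @export
chain_synteny <- function(pairs, min_genes = 3L, max_gap = 1e6) {
  blocks <- list()
  for (key in unique(paste(pairs$scaffold_a, pairs$chrom_b, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    p <- pairs[pairs$scaffold_a == parts[1] & pairs$chrom_b == parts[2], ,
               drop = FALSE]
    p <- p[order(p$pos_a), , drop = FALSE]
    runs <- monotone_runs(p$pos_a, p$pos_b, max_gap)
    for (r in runs) {
      if (length(r$idx) < min_genes) next
      q <- p[r$idx, , drop = FALSE]
      blocks[[length(blocks) + 1L]] <- data.frame(
        scaffold_a = parts[1], chrom_b = parts[2],
        n_genes = nrow(q), orientation = r$orientation,
        a_start = min(q$pos_a), a_end = max(q$pos_a),
        b_start = min(q$pos_b), b_end = max(q$pos_b),
        genes = I(list(q$gene_a)))
    }
  }
  if (!length(blocks)) {
    return(data.frame(scaffold_a = character(), chrom_b = character(),
                      n_genes = integer(), orientation = character(),
                      a_start = numeric(), a_end = numeric(),
                      b_start = numeric(), b_end = numeric(),
                      genes = I(list())))
  }
  do.call(rbind, blocks)
}

# split indices 1..n into maximal greedy runs monotone in b (direction fixed
# by the first step of each run) with adjacent gaps <= max_gap on both axes
monotone_runs <- function(pos_a, pos_b, max_gap) {
  n <- length(pos_a)
  if (n == 0L) return(list())
  runs <- list()
  start <- 1L
  dir <- 0L   # 0 = undecided, +1 increasing in b, -1 decreasing
  for (i in seq_len(n - 1L)) {
    step_b <- pos_b[i + 1L] - pos_b[i]
    gap_ok <- (pos_a[i + 1L] - pos_a[i]) <= max_gap &&
      abs(step_b) <= max_gap
    new_dir <- sign(step_b)
    mono_ok <- dir == 0L || new_dir == 0L || new_dir == dir
    if (gap_ok && mono_ok) {
      if (dir == 0L && new_dir != 0L) dir <- new_dir
    } else {
      runs[[length(runs) + 1L]] <-
        list(idx = start:i,
             orientation = if (dir < 0L) "inverted" else "same")
      start <- i + 1L
      dir <- 0L
    }
  }
  runs[[length(runs) + 1L]] <-
    list(idx = start:n, orientation = if (dir < 0L) "inverted" else "same")
  runs
}

#' Write circos-style ortholog links
#'
#' One tab-separated line per ortholog pair: scaffold_a, start_a, end_a,
#' chrom_b, start_b, end_b, sorted by the A-side coordinates.
#'
#' @param pairs data frame with `scaffold_a`, `a_start`, `a_end`, `chrom_b`,
#'   `b_start`, `b_end` (gene spans or block spans).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_links <- function(pairs, path) {
  p <- pairs[order(pairs$scaffold_a, pairs$a_start), , drop = FALSE]
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d", p$scaffold_a,
                   as.integer(p$a_start), as.integer(p$a_end), p$chrom_b,
                   as.integer(p$b_start), as.integer(p$b_end))
  writeLines(lines, path)
  invisible(path)
}

#' Paralog clusters from within-species hits
#'
#' Self-pairs (query = subject) and hits above `max_evalue` are dropped; the
#' remaining hits form an undirected similarity graph whose connected
#' components are the paralog clusters. Genes of `universe` with no
#' surviving edge are reported as singletons.
#'
#' @param self_hits within-species all-vs-all hit table.
#' @param max_evalue inclusive e-value ceiling (default 1e-10).
#' @param universe optional character vector of all gene ids; defaults to
#'   the ids seen in `self_hits`.
#' @return list: `clusters` (list of >= 2-member id vectors, largest first),
#'   `singletons` (character vector).
#' @export
paralog_clusters <- function(self_hits, max_evalue = 1e-10,
                             universe = NULL) {
  h <- self_hits[self_hits$query_id != self_hits$subject_id &
                   self_hits$evalue <= max_evalue, , drop = FALSE]
  if (is.null(universe)) {
    universe <- unique(c(self_hits$query_id, self_hits$subject_id))
  }
  if (!nrow(h)) return(list(clusters = list(), singletons = sort(universe)))
  g <- igraph::graph_from_data_frame(
    h[, c("query_id", "subject_id")], directed = FALSE,
    vertices = data.frame(name = sort(unique(universe))))
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  clusters <- Filter(function(m) length(m) >= 2L, members)
  clusters <- lapply(clusters, sort)
  ord <- order(-vapply(clusters, length, integer(1)),
               vapply(clusters, `[`, character(1), 1))
  list(clusters = unname(clusters[ord]),
       singletons = sort(unlist(Filter(function(m) length(m) == 1L,
                                       members), use.names = FALSE)))
}

#' Family-expansion table across two species
#'
#' Counts, per family label, the clustered genes of each species, sorted by
#' the species-A count (descending). The ratio column reports A/B, `Inf`
#' when the family is absent from B.
#'
#' @param clusters_a,clusters_b outputs of [paralog_clusters()].
#' @param family_of_gene named character vector, gene id -> family label;
#'   unlabelled genes are ignored.
#' @return data frame `family`, `count_a`, `count_b`, `ratio`.
#' @export
expansion_table <- function(clusters_a, clusters_b, family_of_gene) {
  count_by_family <- function(cl) {
    genes <- unlist(cl$clusters, use.names = FALSE)
    fam <- family_of_gene[genes]
    table(fam[!is.na(fam)])
  }
  ta <- count_by_family(clusters_a)
  tb <- count_by_family(clusters_b)
  fams <- union(names(ta), names(tb))
  if (!length(fams)) {
    return(data.frame(family = character(), count_a = integer(),
                      count_b = integer(), ratio = numeric()))
  }
  out <- data.frame(
    family = fams,
    count_a = as.integer(ifelse(fams %in% names(ta), ta[fams], 0L)),
    count_b = as.integer(ifelse(fams %in% names(tb), tb[fams], 0L)))
  out$ratio <- ifelse(out$count_b == 0L, Inf, out$count_a / out$count_b)
  out <- out[order(-out$count_a, out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Log-log regression of ortholog CDS lengths
#'
#' Ordinary least squares of `log10(cds_len_b)` on `log10(cds_len_a)` over
#' ortholog pairs; slope and R-squared are log-base invariant, the
#' intercept is reported in base-10 units.
#'
#' @param pairs data frame with positive `cds_len_a`, `cds_len_b`
#'   (>= 3 rows).
#' @return list `a_intercept`, `b_slope`, `r_squared`, `n`.
#' @export
cds_length_regression <- function(pairs) {
  if (nrow(pairs) < 3L) stop("cds_length_regression: need at least 3 pairs")
  if (any(pairs$cds_len_a <= 0 | pairs$cds_len_b <= 0)) {
    stop("cds_length_regression: CDS lengths must be positive")
  }
  x <- log10(pairs$cds_len_a)
  y <- log10(pairs$cds_len_b)
  fit <- lm(y ~ x)
  list(a_intercept = unname(coef(fit)[1]),
       b_slope = unname(coef(fit)[2]),
       r_squared = summary(fit)$r.squared,
       n = nrow(pairs))
}
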