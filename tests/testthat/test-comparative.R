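mk_hits <- function(q, s, bit, ev = 1e-50) {
  k <- length(q)
  data.frame(query_id = q, subject_id = s, pct_identity = 90,
             aln_len = 100L, mismatches = 10L, gap_opens = 0L, qstart = 1L,
             qend = 100L, sstart = 1L, send = 100L,
             evalue = rep_len(ev, k), bitscore = bit)
}

test_that("best hits pick highest bitscore under the e-value ceiling", {
  h <- mk_hits(c("q1", "q1"), c("s1", "s2"), c(200, 150))
  expect_equal(best_hits(h), c(q1 = "s1"))

  late <- mk_hits("q1", "s1", 500, ev = 1e-9)   # above 1e-10 ceiling
  expect_equal(length(best_hits(late)), 0L)

  # ties: lower e-value, then lexicographic subject
  tie <- mk_hits(c("q1", "q1", "q1"), c("sC", "sB", "sA"), c(100, 100, 100),
                 ev = c(1e-30, 1e-40, 1e-40))
  expect_equal(unname(best_hits(tie)["q1"]), "sA")
})

test_that("best hits equal an exhaustive argmax oracle on random tables", {
  set.seed(53)
  for (rep in 1:10) {
    q <- sample(paste0("q", 1:8), 60, replace = TRUE)
    s <- sample(paste0("s", 1:8), 60, replace = TRUE)
    h <- mk_hits(q, s, round(runif(60, 50, 500), 3))
    h <- h[!duplicated(h[, c("query_id", "subject_id")]), ]
    got <- best_hits(h)
    for (qq in unique(h$query_id)) {
      sub <- h[h$query_id == qq, ]
      best <- max(sub$bitscore)
      cand <- sort(sub$subject_id[sub$bitscore == best])[1]
      expect_equal(unname(got[qq]), cand)
    }
  }
})

test_that("reciprocal best hits require mutual bests", {
  ab <- mk_hits(c("a1", "a2"), c("b1", "b2"), c(300, 300))
  ba <- mk_hits(c("b1", "b2"), c("a1", "a1"), c(300, 300))
  r <- reciprocal_best_hits(ab, ba)
  expect_equal(r$gene_a, "a1")   # b2's best is a1, so (a2,b2) is asymmetric
  expect_equal(r$gene_b, "b1")
})

test_that("RBH is symmetric under species swap", {
  set.seed(59)
  cfg <- sim_config(seed = 59, n_genes = 60, n_scaffolds = 3)
  hom <- simulate_homology(cfg)
  r1 <- reciprocal_best_hits(hom$hits_ab, hom$hits_ba)
  r2 <- reciprocal_best_hits(hom$hits_ba, hom$hits_ab)
  expect_setequal(paste(r1$gene_a, r1$gene_b), paste(r2$gene_b, r2$gene_a))
})

test_that("synteny chaining splits at monotonicity breaks", {
  # perfectly collinear
  p <- data.frame(gene_a = paste0("a", 1:10), gene_b = paste0("b", 1:10),
                  scaffold_a = "s1", chrom_b = "c1",
                  pos_a = (1:10) * 1e4, pos_b = (1:10) * 1e4)
  bl <- chain_synteny(p)
  expect_equal(nrow(bl), 1L)
  expect_equal(bl$orientation, "same")
  expect_equal(bl$n_genes, 10L)

  # planted inversion of 4 inside 12
  inv <- p <- data.frame(gene_a = paste0("a", 1:12), gene_b = paste0("b", 1:12),
                         scaffold_a = "s1", chrom_b = "c1",
                         pos_a = (1:12) * 1e4, pos_b = (1:12) * 1e4)
  inv$pos_b[5:8] <- rev(inv$pos_b[5:8])
  bl <- chain_synteny(inv, min_genes = 3)
  expect_equal(nrow(bl), 3L)
  expect_true("inverted" %in% bl$orientation)

  # scattered sub-threshold pairs give no blocks
  few <- data.frame(gene_a = paste0("a", 1:4), gene_b = paste0("b", 1:4),
                    scaffold_a = paste0("s", 1:4), chrom_b = paste0("c", 1:4),
                    pos_a = 1e4, pos_b = 1e4)
  expect_equal(nrow(chain_synteny(few)), 0L)
})

test_that("greedy chaining equals the literal-scan oracle on small inputs", {
  set.seed(61)
  for (rep in 1:30) {
    n <- sample(3:12, 1)
    p <- data.frame(gene_a = paste0("a", 1:n), gene_b = paste0("b", 1:n),
                    scaffold_a = "s", chrom_b = "c",
                    pos_a = sort(sample(1:100, n)) * 1e4,
                    pos_b = sample(1:100, n) * 1e4)
    bl <- chain_synteny(p, min_genes = 1)
    groups <- oracle_chain(p$pos_a, p$pos_b)
    expect_equal(nrow(bl), length(groups))
    expect_equal(sort(bl$n_genes), sort(lengths(groups)))
  }
})

test_that("every gene lands in at most one block with declared monotonicity", {
  set.seed(67)
  p <- data.frame(gene_a = paste0("a", 1:40), gene_b = paste0("b", 1:40),
                  scaffold_a = "s", chrom_b = "c",
                  pos_a = sort(sample(1:1000, 40)) * 1e3,
                  pos_b = sample(1:1000, 40) * 1e3)
  bl <- chain_synteny(p, min_genes = 1)
  members <- unlist(bl$genes)
  expect_equal(anyDuplicated(members), 0L)
  expect_equal(sort(members), sort(p$gene_a))
})

test_that("circos link files carry one sorted line per pair", {
  p <- data.frame(scaffold_a = "s1", a_start = 100L, a_end = 200L,
                  chrom_b = "c2", b_start = 5000L, b_end = 5100L)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_links(p, f)
  expect_equal(readLines(f), "s1\t100\t200\tc2\t5000\t5100")

  many <- data.frame(scaffold_a = c("s2", "s1"), a_start = c(5L, 9L),
                     a_end = c(6L, 10L), chrom_b = "c", b_start = 1L,
                     b_end = 2L)
  write_links(many, f)
  expect_equal(length(readLines(f)), 2L)
  expect_true(startsWith(readLines(f)[1], "s1"))

  write_links(many[0, ], f)
  expect_equal(length(readLines(f)), 0L)
})

test_that("paralog clusters are connected components minus self-pairs", {
  h <- mk_hits(c("a", "b", "a"), c("b", "c", "a"), c(100, 100, 999))
  cl <- paralog_clusters(h)
  expect_equal(cl$clusters, list(c("a", "b", "c")))

  none <- mk_hits(c("a", "b"), c("a", "b"), c(10, 10))  # only self-pairs
  cl <- paralog_clusters(none)
  expect_equal(length(cl$clusters), 0L)
  expect_setequal(cl$singletons, c("a", "b"))
})

test_that("cluster partition equals the union-find oracle on random graphs", {
  set.seed(71)
  for (rep in 1:15) {
    verts <- paste0("g", 1:30)
    ne <- sample(5:40, 1)
    e <- data.frame(q = sample(verts, ne, TRUE), s = sample(verts, ne, TRUE))
    h <- mk_hits(e$q, e$s, runif(ne, 100, 200))
    cl <- paralog_clusters(h, universe = verts)
    parts <- c(cl$clusters, as.list(cl$singletons))
    want <- oracle_components(e[e$q != e$s, ], verts)
    key <- function(p) sort(vapply(p, paste, "", collapse = "|"))
    expect_equal(key(parts), key(want))
  }
})

test_that("expansion table counts family members per species", {
  cl_a <- list(clusters = list(paste0("hA", 1:20), c("x1", "x2")),
               singletons = character())
  cl_b <- list(clusters = list(paste0("hB", 1:2)), singletons = character())
  fam <- setNames(rep("histone", 22), c(paste0("hA", 1:20), paste0("hB", 1:2)))
  tab <- expansion_table(cl_a, cl_b, fam)
  expect_equal(tab$count_a[tab$family == "histone"], 20L)
  expect_equal(tab$count_b[tab$family == "histone"], 2L)

  fam2 <- c(fam, setNames(rep("antifreeze", 2), c("x1", "x2")))
  tab2 <- expansion_table(cl_a, cl_b, fam2)
  expect_equal(tab2$ratio[tab2$family == "antifreeze"], Inf)

  empty <- list(clusters = list(), singletons = character())
  expect_equal(nrow(expansion_table(empty, empty, fam)), 0L)
})

test_that("CDS-length regression matches closed form and exact lines", {
  ident <- data.frame(cds_len_a = c(100, 500, 2000),
                      cds_len_b = c(100, 500, 2000))
  # perfect-fit fixtures make summary.lm warn about its R^2; that is the point
  r <- suppressWarnings(cds_length_regression(ident))
  expect_equal(r$a_intercept, 0, tolerance = 1e-10)
  expect_equal(r$b_slope, 1, tolerance = 1e-10)
  expect_equal(r$r_squared, 1, tolerance = 1e-10)

  tens <- data.frame(cds_len_a = c(1, 10, 100), cds_len_b = c(10, 100, 1000))
  r <- suppressWarnings(cds_length_regression(tens))
  expect_equal(r$a_intercept, 1, tolerance = 1e-10)
  expect_equal(r$b_slope, 1, tolerance = 1e-10)

  set.seed(73)
  sim <- sim_ortholog_cds_lengths(400)
  r <- cds_length_regression(sim)
  o <- oracle_ols_log10(sim$cds_len_a, sim$cds_len_b)
  expect_equal(r$a_intercept, o$a, tolerance = 1e-10)
  expect_equal(r$b_slope, o$b, tolerance = 1e-10)
  expect_equal(r$r_squared, o$r2, tolerance = 1e-10)

  expect_error(cds_length_regression(ident[1:2, ]), "3 pairs")
  expect_error(cds_length_regression(
    data.frame(cds_len_a = c(1, 2, 0), cds_len_b = c(1, 2, 3))), "positive")
})
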