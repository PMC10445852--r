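small_cfg <- function(seed = 5, satellite_array_counts = c(4L, 3L), ...) {
  sim_config(seed = seed, n_scaffolds = 3,
             scaffold_len_range = c(15000, 25000), n_genes = 40,
             mito_len = 1500, mito_copies = 3,
             satellite_array_counts = satellite_array_counts,
             n_contigs = 30, ...)
}

test_that("generators are byte-identical under a fixed seed", {
  cfg <- small_cfg()
  g1 <- simulate_genome(cfg); g2 <- simulate_genome(cfg)
  expect_identical(g1, g2)
  a1 <- simulate_annotation(cfg, g1); a2 <- simulate_annotation(cfg, g2)
  expect_identical(a1$evidence, a2$evidence)
  c1 <- simulate_chimeric_contigs(cfg); c2 <- simulate_chimeric_contigs(cfg)
  expect_identical(c1, c2)
  h1 <- simulate_homology(cfg); h2 <- simulate_homology(cfg)
  expect_identical(h1, h2)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(cfg, d1); write_simulation(cfg, d2)
  expect_identical(readLines(file.path(d1, "genome.fasta")),
                   readLines(file.path(d2, "genome.fasta")))
  expect_identical(readLines(file.path(d1, "truth.json")),
                   readLines(file.path(d2, "truth.json")))
})

test_that("planted satellite truth matches configuration", {
  cfg <- small_cfg(satellite_array_counts = integer(0))
  g <- simulate_genome(cfg)
  expect_equal(nrow(g$truth$satellite), 0L)

  cfg <- small_cfg()
  g <- simulate_genome(cfg)
  expect_equal(nrow(g$truth$satellite), 7L)  # 4 + 3 copies
  expect_true(all(g$truth$satellite$end - g$truth$satellite$start == 142L))
  # planted copies really sit in the sequence at the recorded identity
  exact <- g$truth$satellite[g$truth$satellite$identity == 100, ]
  for (i in seq_len(nrow(exact))) {
    scaf <- g$scaffolds$seq[g$scaffolds$id == exact$scaffold_id[i]]
    expect_equal(substr(scaf, exact$start[i] + 1, exact$end[i]),
                 g$truth$monomer)
  }
})

test_that("the mito-like region is planted in tandem at the host scaffold", {
  cfg <- small_cfg()
  g <- simulate_genome(cfg)
  mt <- g$truth$mito
  expect_equal(nrow(mt$intervals), 3L)
  expect_equal(mt$intervals$start[-1], mt$intervals$end[-3])  # tandem
  host <- g$scaffolds$seq[g$scaffolds$id == mt$scaffold_id]
  for (i in 1:3) {
    expect_equal(substr(host, mt$intervals$start[i] + 1, mt$intervals$end[i]),
                 mt$mito_seq)
  }
})

test_that("simulated annotation hits the configured intronless fraction", {
  cfg <- sim_config(seed = 7, n_scaffolds = 6,
                    scaffold_len_range = c(60000, 80000), n_genes = 300,
                    mito_len = 1500, satellite_array_counts = integer(0))
  ann <- simulate_annotation(cfg, simulate_genome(cfg))
  frac <- mean(ann$truth$intronless)
  expect_equal(frac, 0.27, tolerance = 0.25)
  # intronless_fraction = 0 means no intronless-only removals are possible
  cfg0 <- small_cfg(intronless_fraction = 0)
  ann0 <- simulate_annotation(cfg0, simulate_genome(cfg0))
  expect_false(any(ann0$truth$label %in% c("UTR_RNA_ONLY", "WEAK_EVIDENCE")))
  # every generated model passes validation (constructor enforces it)
  expect_true(all(vapply(ann0$models, inherits, logical(1), "gene_model")))
})

test_that("chimeric contig truth places junctions where coverage is zero", {
  cfg <- small_cfg()
  chi <- simulate_chimeric_contigs(cfg)
  tr <- chi$truth
  for (i in which(tr$is_chimera)) {
    d <- chi$tracks[[tr$contig_id[i]]]$depth
    expect_true(all(d[(tr$break_start[i] + 1):tr$break_end[i]] == 0L))
  }
  for (i in which(!tr$is_chimera)) {
    expect_true(all(chi$tracks[[tr$contig_id[i]]]$depth > 0L))
  }
  # unsplittable junctions are covered by a planted ORF
  uns <- tr[tr$is_chimera & !tr$splittable, ]
  for (i in seq_len(nrow(uns))) {
    o <- chi$orfs[chi$orfs$scaffold_id == uns$contig_id[i], ]
    expect_true(any(o$start < uns$break_end[i] & o$end > uns$break_start[i]))
  }
})

test_that("noise-free homology keeps planted best hits strictly best", {
  cfg <- small_cfg(bitscore_noise = 0)
  hom <- simulate_homology(cfg)
  rbh <- reciprocal_best_hits(hom$hits_ab, hom$hits_ba)
  truth <- hom$truth$ortholog_pairs
  expect_setequal(paste(rbh$gene_a, rbh$gene_b),
                  paste(truth$gene_a, truth$gene_b))
})

test_that("a written simulation directory passes the package readers", {
  cfg <- small_cfg()
  d <- withr::local_tempdir()
  write_simulation(cfg, d)
  genome <- read_fasta(file.path(d, "genome.fasta"))
  expect_equal(nrow(genome), 3L)
  models <- read_gff3(file.path(d, "genes.gff3"))
  expect_equal(length(models), 40L)
  ev <- read_evidence(file.path(d, "evidence.tsv"))
  expect_equal(nrow(ev), 40L)
  hits <- read_hits(file.path(d, "hits_ab.tsv"))
  expect_true(nrow(hits) > 0)
  expect_true(file.exists(file.path(d, "orfs.bed")))
  cov_files <- list.files(file.path(d, "coverage"))
  expect_equal(length(cov_files), 30L)
  tr <- read_coverage(file.path(d, "coverage", cov_files[1]),
                      sub("[.]tsv$", "", cov_files[1]))
  contigs <- read_fasta(file.path(d, "contigs.fasta"))
  expect_equal(length(tr$depth),
               nchar(contigs$seq[contigs$id == tr$contig_id]))
})
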