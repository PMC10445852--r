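base_ev <- function(...) {
  ev <- list(gene_id = "g", has_pfam = FALSE, has_blastp = FALSE,
             repeat_cov = 0, te_tagged = FALSE, n_mrna_samples = 0L,
             n_protein_species = 0L, has_self_uniprot = FALSE,
             utr_ratio = 0.3)
  mods <- list(...)
  ev[names(mods)] <- mods
  ev
}

test_that("the cascade applies rules in order with first match winning", {
  # multi-exon, highly repeat-covered, no hits -> repeat/TE removal
  d <- classify_gene(FALSE, base_ev(repeat_cov = 0.95))
  expect_equal(d$reason, "REPEAT_TE")

  # intronless, RNA-only, UTR-dominated -> UTR rule
  d <- classify_gene(TRUE, base_ev(utr_ratio = 0.85, n_mrna_samples = 1L))
  expect_equal(d$reason, "UTR_RNA_ONLY")

  # intronless with one mRNA and one protein evidence -> condition (i) keeps
  d <- classify_gene(TRUE, base_ev(n_mrna_samples = 1L,
                                   n_protein_species = 1L))
  expect_equal(d$verdict, "KEEP")

  # TE-tagged but with a pfam hit -> the no-hit guard keeps it
  d <- classify_gene(FALSE, base_ev(te_tagged = TRUE, has_pfam = TRUE))
  expect_equal(d$verdict, "KEEP")

  # intronless, unsupported, no hits -> weak-evidence removal
  d <- classify_gene(TRUE, base_ev(n_mrna_samples = 1L))
  expect_equal(d$reason, "WEAK_EVIDENCE")

  # two mRNA samples satisfy condition (ii)
  d <- classify_gene(TRUE, base_ev(n_mrna_samples = 2L))
  expect_equal(d$verdict, "KEEP")

  # curated same-species protein satisfies condition (iii)
  d <- classify_gene(TRUE, base_ev(has_self_uniprot = TRUE))
  expect_equal(d$verdict, "KEEP")
})

test_that("thresholds are strict and missing evidence errors", {
  expect_equal(classify_gene(FALSE, base_ev(repeat_cov = 0.90))$verdict,
               "KEEP")
  expect_equal(classify_gene(TRUE, base_ev(utr_ratio = 0.80,
                                           n_mrna_samples = 2L))$verdict,
               "KEEP")
  ev <- base_ev(); ev$repeat_cov <- NULL
  expect_error(classify_gene(FALSE, ev), "repeat_cov")
  expect_error(classify_gene(FALSE, base_ev(repeat_cov = 1.2)), "0, 1")
})

test_that("multi-exon genes can only be removed as repeat/TE", {
  set.seed(43)
  for (i in 1:300) {
    ev <- base_ev(repeat_cov = runif(1), te_tagged = runif(1) < 0.5,
                  has_pfam = runif(1) < 0.3, has_blastp = runif(1) < 0.3,
                  n_mrna_samples = sample(0:3, 1),
                  n_protein_species = sample(0:3, 1),
                  utr_ratio = runif(1))
    d <- classify_gene(FALSE, ev)
    expect_true(d$reason %in% c("KEPT", "REPEAT_TE"))
  }
})

test_that("adding a pfam or blastp hit never flips KEEP to REMOVE", {
  set.seed(47)
  for (i in 1:500) {
    ev <- base_ev(repeat_cov = runif(1), te_tagged = runif(1) < 0.5,
                  n_mrna_samples = sample(0:3, 1),
                  n_protein_species = sample(0:3, 1),
                  has_self_uniprot = runif(1) < 0.3, utr_ratio = runif(1))
    intronless <- runif(1) < 0.5
    before <- classify_gene(intronless, ev)$verdict
    ev$has_pfam <- TRUE
    after <- classify_gene(intronless, ev)$verdict
    expect_false(before == "KEEP" && after == "REMOVE")
    expect_equal(after, "KEEP")  # a hit disarms every removal rule
  }
})

toy_models <- function() {
  list(gene_model("gA", "s1", "+", intervals(0, 100),
                  cds = intervals(0, 100)),
       gene_model("gB", "s1", "+", intervals(c(200, 300), c(260, 440)),
                  cds = intervals(c(200, 300), c(260, 440))),
       gene_model("gC", "s1", "-", intervals(c(1000, 1500), c(1400, 2000)),
                  cds = intervals(c(1000, 1500), c(1400, 2000))))
}

test_that("gene-set filtering summarises kept models like Table-style stats", {
  models <- toy_models()
  ev <- data.frame(gene_id = c("gA", "gB", "gC"), has_pfam = TRUE,
                   has_blastp = FALSE, repeat_cov = 0, te_tagged = FALSE,
                   n_mrna_samples = 1L, n_protein_species = 1L,
                   has_self_uniprot = FALSE, utr_ratio = 0)
  out <- filter_gene_set(models, ev)
  expect_equal(out$summary$n_removed, 0L)
  expect_equal(out$summary$n_kept, 3L)
  # genomic spans 100, 240, 1000 -> median 240
  expect_equal(out$summary$gene_length_median, 240)
  expect_equal(out$summary$intronless_fraction_kept, 1 / 3)

  expect_error(filter_gene_set(models, ev[1:2, ]), "mismatch")
})

test_that("planted labels are recovered exactly on a synthetic set", {
  cfg <- sim_config(seed = 11, n_scaffolds = 4,
                    scaffold_len_range = c(30000, 50000), n_genes = 100,
                    mito_len = 2000, satellite_array_counts = integer(0))
  g <- simulate_genome(cfg)
  ann <- simulate_annotation(cfg, g)
  out <- filter_gene_set(ann$models, ann$evidence)
  called <- ifelse(out$decisions$reason == "KEPT", "KEEP",
                   out$decisions$reason)
  expect_equal(called, ann$truth$label)   # diagonal confusion matrix
})
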