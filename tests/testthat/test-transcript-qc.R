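test_that("end trimming removes n bases from each side", {
  expect_equal(trim_ends("AAAAACGTACGTTTTTT"), "CGTACGT")
  expect_equal(trim_ends("ACGTACGTAC"), "")       # 10 bp, degenerate
  expect_equal(trim_ends("ACGT", n = 0L), "ACGT") # identity
  expect_equal(trim_ends(c("AAAAACGTACGTTTTTT", "ACG")), c("CGTACGT", ""))
})

test_that("DUST masks homopolymers but not high-complexity sequence", {
  m <- dust_mask(strrep("A", 100))
  expect_equal(nrow(m), 1L)
  expect_gte(iv_width_test(m), 95)

  # all 64 distinct triplets once per window: score 0
  set.seed(5)
  hi <- random_dna_str(300)
  while (nrow(dust_mask(hi)) > 0) hi <- random_dna_str(300)
  expect_equal(nrow(dust_mask(hi)), 0L)
})

test_that("DUST equals the exhaustive window-score oracle on planted repeats", {
  set.seed(17)
  for (rep in 1:8) {
    s <- random_dna_str(500)
    at <- sample(50:350, 1)
    micro <- strrep("AT", 40)  # 80-bp microsatellite
    substr(s, at, at + 79) <- micro
    got <- dust_mask(s)
    want <- oracle_dust(s)
    expect_equal(got, want, ignore_attr = TRUE)
    expect_true(any(got$start <= at + 78 & got$end >= at))  # overlaps repeat
  }
})

test_that("complexity filter applies both strict thresholds", {
  recs <- seq_records(c("short", "masked", "ok"),
                      c(strrep("A", 150), strrep("A", 200), strrep("A", 200)))
  masks <- list(data.frame(start = integer(), end = integer()),
                data.frame(start = 0L, end = 60L),   # unmasked 0.70
                data.frame(start = 0L, end = 40L))   # unmasked 0.80
  out <- complexity_filter(recs, masks)
  expect_equal(out$kept$id, "ok")
  expect_false(out$report$kept[out$report$id == "short"])  # 150 is strict
})

test_that("ORF finder handles both strands and matches the brute-force scan", {
  s <- paste0("ATG", strrep("AAA", 100), "TAA")
  o <- find_orfs(s, min_aa = 50)
  expect_equal(nrow(o), 1L)
  expect_equal(o$start, 0L)
  expect_equal(o$end, 306L)
  expect_equal(o$strand, "+")

  o2 <- find_orfs(revcomp(s), min_aa = 50)
  expect_equal(nrow(o2), 1L)
  expect_equal(o2$strand, "-")
  expect_equal(c(o2$start, o2$end), c(0L, 306L))   # mirrored coordinates

  set.seed(23)
  for (rep in 1:5) {
    r <- random_dna_str(2000)
    expect_equal(find_orfs(r, min_aa = 20), oracle_orfs(r, min_aa = 20),
                 ignore_attr = TRUE)
  }
})

test_that("ORF widths are divisible by three and inside the contig", {
  set.seed(29)
  r <- random_dna_str(3000)
  o <- find_orfs(r, min_aa = 10)
  expect_true(nrow(o) > 0)
  expect_true(all((o$end - o$start) %% 3 == 0))
  expect_true(all(o$start >= 0 & o$end <= 3000))
})

test_that("pair coverage counts convergent pairs within the insert bound", {
  pr <- data.frame(r1_start = 10L, r1_end = 60L, r1_strand = "+",
                   r2_start = 150L, r2_end = 200L, r2_strand = "-")
  tr <- pair_coverage(pr, 300L, "c")
  expect_equal(unique(tr$depth[11:200]), 1L)
  expect_equal(sum(tr$depth), 190L)
  expect_equal(tr$plus_pairs, 1L)

  div <- data.frame(r1_start = 10L, r1_end = 60L, r1_strand = "-",
                    r2_start = 150L, r2_end = 200L, r2_strand = "+")
  expect_equal(sum(pair_coverage(div, 300L, "c")$depth), 0L)

  wide <- data.frame(r1_start = 0L, r1_end = 50L, r1_strand = "+",
                     r2_start = 1500L, r2_end = 1600L, r2_strand = "-")
  expect_equal(sum(pair_coverage(wide, 2000L, "c")$depth), 0L)

  oob <- data.frame(r1_start = 0L, r1_end = 50L, r1_strand = "+",
                    r2_start = 250L, r2_end = 400L, r2_strand = "-")
  expect_error(pair_coverage(oob, 300L, "c"), "bounds")
})

test_that("pair coverage equals brute-force interval stabbing", {
  set.seed(31)
  L <- 800L
  n <- 50L
  s1 <- sample(0:(L - 80L), n, replace = TRUE)
  s2 <- pmin(L - 40L, s1 + sample(20:700, n, replace = TRUE))
  pr <- data.frame(r1_start = s1, r1_end = s1 + 40L,
                   r1_strand = sample(c("+", "-"), n, TRUE),
                   r2_start = s2, r2_end = s2 + 40L,
                   r2_strand = sample(c("+", "-"), n, TRUE))
  expect_equal(pair_coverage(pr, L, "c")$depth, oracle_pair_depth(pr, L))
})

test_that("chimera splitting cuts only actionable gaps", {
  rec <- seq_records("ch1", random_dna_str(1000))
  depth <- rep(2L, 1000); depth[601:640] <- 0L
  tr <- coverage_track("ch1", depth)

  out <- split_chimeric(rec, tr)   # no ORFs/domains: gap is actionable
  expect_equal(out$n_cuts, 1L)
  expect_equal(out$pieces$id, c("ch1.1", "ch1.2"))
  expect_equal(nchar(out$pieces$seq), c(600L, 360L))
  expect_equal(sum(nchar(out$pieces$seq)) + 40L, 1000L)  # gap bases removed
  expect_equal(out$pieces$seq[1], substr(rec$seq, 1, 600))

  blocked <- split_chimeric(rec, tr, orfs = data.frame(start = 500L, end = 700L))
  expect_equal(blocked$n_cuts, 0L)
  expect_equal(blocked$pieces$id, "ch1")  # returned unchanged

  full <- split_chimeric(rec, coverage_track("ch1", rep(1L, 1000)))
  expect_equal(full$pieces, rec)

  # sub-min_gap dropouts are ignored
  d2 <- rep(2L, 1000); d2[500:504] <- 0L
  expect_equal(split_chimeric(rec, coverage_track("ch1", d2))$n_cuts, 0L)
})

test_that("splitting never cuts inside ORFs or domains on random fixtures", {
  set.seed(37)
  for (rep in 1:20) {
    L <- 1200L
    rec <- seq_records("x", random_dna_str(L))
    depth <- rep(1L, L)
    for (g in 1:sample(1:3, 1)) {
      at <- sample(50:(L - 100), 1)
      depth[at:(at + sample(10:60, 1))] <- 0L
    }
    orfs <- data.frame(start = sample(0:(L - 200), 2), end = 0L)
    orfs$end <- orfs$start + 150L
    doms <- data.frame(start = sample(0:(L - 120), 1), end = 0L)
    doms$end <- doms$start + 100L
    out <- split_chimeric(rec, coverage_track("x", depth), orfs, doms)
    cutg <- out$gaps[out$gaps$actionable, , drop = FALSE]
    if (nrow(cutg)) {
      for (i in seq_len(nrow(cutg))) {
        expect_false(any(cutg$start[i] < orfs$end & cutg$end[i] > orfs$start))
        expect_false(any(cutg$start[i] < doms$end & cutg$end[i] > doms$start))
      }
    }
    removed <- sum(cutg$end - cutg$start)
    expect_equal(sum(nchar(out$pieces$seq)) + removed, L)
  }
})

test_that("orientation follows majority strand votes with tie kept", {
  rec <- seq_records("c", "ACGTTT")
  keep <- orient_contig(rec, coverage_track("c", rep(1L, 6), 10L, 0L))
  expect_equal(keep$record$seq, "ACGTTT")
  expect_false(keep$flipped)

  flip <- orient_contig(rec, coverage_track("c", rep(1L, 6), 0L, 10L))
  expect_equal(flip$record$seq, revcomp("ACGTTT"))
  twice <- orient_contig(flip$record, coverage_track("c", rep(1L, 6), 0L, 10L))
  expect_equal(twice$record$seq, "ACGTTT")   # involution

  tie <- orient_contig(rec, coverage_track("c", rep(1L, 6), 5L, 5L))
  expect_equal(tie$record$seq, "ACGTTT")
  expect_true(tie$ambiguous)
})
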