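# Deterministic synthetic-data generators. Every input the pipeline
# consumes can be produced here with ground truth attached: scaffolds with
# planted satellite arrays and a tandem-multiplied mitochondrion-like
# region, gene models with controlled intronless fraction and UTR ratios
# plus planted keep/remove labels, chimeric transcript contigs with
# uncovered junctions, and within/between-species hit tables with planted
# orthologs, rearrangements and an expanded gene family. Background
# sequence is i.i.d. uniform ACGT so DUST behaviour stays predictable;
# low-complexity stretches are injected explicitly where wanted.

# fixed 142-bp synthetic satellite monomer (a frozen random sequence; real
# beetle satellite sequences are not redistributed here)
SATELLITE_MONOMER_142 <- paste0(
  "TGCATCGAGGTCTAGGACTCCATTTAAGCGTACGGATCAACTGTGCCATA",
  "GCTTTCAAGTGGTACCGAGCATTCGGACTAATCCGCTGATCAGGTTACGA",
  "CCTGAAGTCATTGGCAACGTATCCGGTATGACTTAGCACAGT")

#' Default synthetic satellite monomer
#'
#' A fixed 142-bp sequence (the length of the tandem satellite that
#' dominates the mealworm genome); synthetic, not a published satellite.
#' @return DNA string of length 142.
#' @export
sim_satellite_monomer <- function() SATELLITE_MONOMER_142

#' Simulation configuration
#'
#' Bundles every knob of the synthetic generators; `seed` fixes all random
#' draws. Defaults emulate the study conditions at desk scale: 27%
#' intronless predictions, a 142-bp satellite monomer planted as tandem
#' arrays with per-copy identity in 85-100%, and a 15,724-bp
#' mitochondrion-like sequence planted in tandem triplicate in one
#' scaffold.
#'
#' @param seed integer seed (< 2^31).
#' @param n_scaffolds number of nuclear-like scaffolds.
#' @param scaffold_len_range scaffold length range in bp.
#' @param n_genes number of gene models.
#' @param intronless_fraction fraction of single-exon models (default 0.27).
#' @param utr_ratio_range range the spliced UTR ratio is drawn from.
#' @param satellite_monomer monomer sequence to plant.
#' @param satellite_array_counts integer vector, tandem copies per planted
#'   array (one array per element; `integer(0)` plants none).
#' @param satellite_identity_range per-copy identity range (fractions;
#'   `c(1, 1)` plants exact copies).
#' @param mito_len length of the mitochondrion-like sequence (default
#'   15,724 bp).
#' @param mito_copies tandem copies planted in the host scaffold
#'   (default 3).
#' @param ortholog_fraction fraction of genes with a planted 1:1 ortholog.
#' @param n_expanded_family members of the expanded family in species A
#'   (2 in species B).
#' @param rearrangement_ops `list(inversions =, translocations =)` planted
#'   in the species-B gene order.
#' @param n_contigs transcript contigs to simulate.
#' @param chimera_fraction fraction of contigs built as two fused
#'   transcripts.
#' @param junction_len uncovered junction width in bp (default 40).
#' @param bitscore_noise half-width of additive uniform bitscore noise;
#'   0 = noise-free (planted best hits exactly best). Kept well below the
#'   planted true/background score margin.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_scaffolds = 8L,
                       scaffold_len_range = c(40000L, 120000L),
                       n_genes = 160L,
                       intronless_fraction = 0.27,
                       utr_ratio_range = c(0.05, 0.95),
                       satellite_monomer = sim_satellite_monomer(),
                       satellite_array_counts = c(10L, 6L, 4L),
                       satellite_identity_range = c(0.85, 1.0),
                       mito_len = 15724L,
                       mito_copies = 3L,
                       ortholog_fraction = 0.8,
                       n_expanded_family = 20L,
                       rearrangement_ops = list(inversions = 1L,
                                                translocations = 1L),
                       n_contigs = 200L,
                       chimera_fraction = 0.3,
                       junction_len = 40L,
                       bitscore_noise = 5) {
  cfg <- list(seed = as.integer(seed), n_scaffolds = as.integer(n_scaffolds),
              scaffold_len_range = as.integer(scaffold_len_range),
              n_genes = as.integer(n_genes),
              intronless_fraction = intronless_fraction,
              utr_ratio_range = utr_ratio_range,
              satellite_monomer = satellite_monomer,
              satellite_array_counts = as.integer(satellite_array_counts),
              satellite_identity_range = satellite_identity_range,
              mito_len = as.integer(mito_len),
              mito_copies = as.integer(mito_copies),
              ortholog_fraction = ortholog_fraction,
              n_expanded_family = as.integer(n_expanded_family),
              rearrangement_ops = rearrangement_ops,
              n_contigs = as.integer(n_contigs),
              chimera_fraction = chimera_fraction,
              junction_len = as.integer(junction_len),
              bitscore_noise = bitscore_noise)
  stopifnot(cfg$n_scaffolds >= 1L, cfg$n_genes >= 0L,
            cfg$intronless_fraction >= 0, cfg$intronless_fraction <= 1,
            all(cfg$satellite_array_counts >= 0L),
            cfg$ortholog_fraction >= 0, cfg$ortholog_fraction <= 1,
            cfg$chimera_fraction >= 0, cfg$chimera_fraction <= 1)
  class(cfg) <- "sim_config"
  cfg
}

random_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute bases to reach the requested identity fraction
degrade_to_identity <- function(seq, identity) {
  n_sub <- round((1 - identity) * nchar(seq))
  if (n_sub == 0L) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample(length(chars), n_sub)
  chars[pos] <- vapply(chars[pos], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
  paste0(chars, collapse = "")
}

plant <- function(scaffold_seq, insert, at) {
  # overwrite scaffold bases [at, at + nchar(insert)) (0-based) with insert
  end <- at + nchar(insert)
  if (at < 0L || end > nchar(scaffold_seq)) {
    stop("planted feature exceeds scaffold length")
  }
  paste0(substr(scaffold_seq, 1L, at), insert,
         substr(scaffold_seq, end + 1L, nchar(scaffold_seq)))
}

#' Simulate a genome with planted satellite arrays and a mito-like region
#'
#' Scaffolds are i.i.d. uniform ACGT at the configured lengths. Each
#' element of `satellite_array_counts` becomes one tandem array of monomer
#' copies (per-copy identity drawn from `satellite_identity_range`) planted
#' on scaffolds round-robin. The last scaffold hosts `mito_copies` tandem
#' copies of a freshly drawn mitochondrion-like sequence (its length is
#' grown if needed so the copies fit). All planted intervals are recorded.
#'
#' @param config a [sim_config()].
#' @return list: `scaffolds` (`seq_records()`), `truth` with `satellite`
#'   (per-copy data frame), `mito` (host scaffold, copy intervals,
#'   `mito_seq`), and the monomer used.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  lens <- sample(config$scaffold_len_range[1]:config$scaffold_len_range[2],
                 config$n_scaffolds, replace = TRUE)
  mito_total <- config$mito_len * config$mito_copies
  host <- config$n_scaffolds
  lens[host] <- max(lens[host], as.integer(ceiling(mito_total * 1.3)))
  ids <- sprintf("scaffold_%02d", seq_len(config$n_scaffolds))
  seqs <- vapply(lens, random_dna, character(1))

  mlen <- nchar(config$satellite_monomer)
  sat_rows <- list()
  occupied <- lapply(seq_len(config$n_scaffolds), function(i)
    data.frame(start = integer(), end = integer()))
  for (j in seq_along(config$satellite_array_counts)) {
    k <- config$satellite_array_counts[j]
    if (k == 0L) next
    tgt <- ((j - 1L) %% max(1L, config$n_scaffolds - 1L)) + 1L  # keep host clean
    arr_len <- k * mlen
    if (arr_len + 2000L > lens[tgt]) {
      stop(sprintf("satellite array %d (%d bp) exceeds scaffold %s", j,
                   arr_len, ids[tgt]))
    }
    at <- NA_integer_
    for (try in 1:100) {                   # avoid overlapping planted arrays
      cand <- sample.int(lens[tgt] - arr_len - 1000L, 1L) + 500L
      if (!any(overlaps_any(data.frame(start = cand, end = cand + arr_len),
                            occupied[[tgt]]))) { at <- cand; break }
    }
    if (is.na(at)) stop("could not place satellite array without overlap")
    occupied[[tgt]] <- rbind(occupied[[tgt]],
                             data.frame(start = at, end = at + arr_len))
    for (c in seq_len(k)) {
      idy <- runif(1, config$satellite_identity_range[1],
                   config$satellite_identity_range[2])
      n_sub <- round((1 - idy) * mlen)
      copy <- degrade_to_identity(config$satellite_monomer, 1 - n_sub / mlen)
      pos <- at + (c - 1L) * mlen
      seqs[tgt] <- plant(seqs[tgt], copy, pos)
      sat_rows[[length(sat_rows) + 1L]] <- data.frame(
        scaffold_id = ids[tgt], start = pos, end = pos + mlen,
        array = j, copy = c, identity = 100 * (1 - n_sub / mlen))
    }
  }
  satellite <- if (length(sat_rows)) do.call(rbind, sat_rows) else
    data.frame(scaffold_id = character(), start = integer(),
               end = integer(), array = integer(), copy = integer(),
               identity = numeric())

  mito_seq <- random_dna(config$mito_len)
  mito_at <- 500L
  mito_iv <- data.frame(
    scaffold_id = ids[host],
    start = mito_at + (seq_len(config$mito_copies) - 1L) * config$mito_len,
    end = mito_at + seq_len(config$mito_copies) * config$mito_len)
  for (c in seq_len(config$mito_copies)) {
    seqs[host] <- plant(seqs[host], mito_seq, mito_iv$start[c])
  }

  list(scaffolds = seq_records(ids, seqs),
       truth = list(satellite = satellite,
                    monomer = config$satellite_monomer,
                    mito = list(scaffold_id = ids[host], mito_seq = mito_seq,
                                intervals = mito_iv)))
}

# map a spliced interval [s, e) onto genomic intervals across sorted exons
spliced_to_genomic <- function(exons, s, e) {
  out <- list()
  off <- 0L
  for (i in seq_len(nrow(exons))) {
    w <- exons$end[i] - exons$start[i]
    lo <- max(s, off); hi <- min(e, off + w)
    if (lo < hi) {
      out[[length(out) + 1L]] <- data.frame(
        start = exons$start[i] + (lo - off), end = exons$start[i] + (hi - off))
    }
    off <- off + w
  }
  if (!length(out)) data.frame(start = integer(), end = integer()) else
    do.call(rbind, out)
}

# evidence templates guaranteeing each planted label under the cascade
evidence_for_label <- function(label, intronless, model_utr_ratio) {
  ev <- list(has_pfam = FALSE, has_blastp = FALSE, repeat_cov = runif(1, 0, 0.5),
             te_tagged = FALSE, n_mrna_samples = 1L, n_protein_species = 1L,
             has_self_uniprot = FALSE, utr_ratio = model_utr_ratio)
  if (label == "REPEAT_TE") {
    if (runif(1) < 0.5) ev$repeat_cov <- runif(1, 0.905, 1) else
      ev$te_tagged <- TRUE
    ev$n_mrna_samples <- sample(0:2, 1L)
    ev$n_protein_species <- 0L
  } else if (label == "UTR_RNA_ONLY") {      # intronless only
    ev$n_protein_species <- 0L
    ev$n_mrna_samples <- sample(1:3, 1L)
  } else if (label == "WEAK_EVIDENCE") {     # intronless only
    ev$n_mrna_samples <- 1L
    ev$n_protein_species <- 0L
  } else {                                   # KEEP
    pick <- sample(4L, 1L)
    if (pick == 1L) {                        # domain/protein hit
      ev$has_pfam <- runif(1) < 0.8
      ev$has_blastp <- !ev$has_pfam || runif(1) < 0.5
      if (runif(1) < 0.2) ev$te_tagged <- TRUE   # TE tag overridden by hit
    } else if (pick == 2L) {                 # one mRNA + one protein
      ev$n_mrna_samples <- 1L; ev$n_protein_species <- sample(1:3, 1L)
    } else if (pick == 3L) {                 # two mRNA samples
      ev$n_mrna_samples <- sample(2:4, 1L); ev$n_protein_species <- 0L
    } else {                                 # curated same-species protein
      ev$n_mrna_samples <- sample(0:1, 1L); ev$n_protein_species <- 0L
      ev$has_self_uniprot <- TRUE
    }
  }
  ev
}

#' Simulate gene models and evidence with planted filter labels
#'
#' Places gene models on the simulated scaffolds with the configured
#' intronless fraction and UTR-ratio range, then draws an evidence record
#' per gene from templates that guarantee a planted label (KEEP,
#' REPEAT_TE, UTR_RNA_ONLY, WEAK_EVIDENCE). The label is fixed by the
#' template construction, not by running the classifier: genes destined
#' for the UTR rule get a model UTR ratio above 0.8 and no protein
#' support, keepers that rely on transcript support get ratios clamped
#' below it, and so on.
#'
#' @param config a [sim_config()].
#' @param genome output of [simulate_genome()].
#' @return list: `models` (list of [gene_model()]), `evidence` (data
#'   frame), `truth` (`gene_id`, `label`, `intronless`).
#' @export
simulate_annotation <- function(config, genome) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  scaf <- genome$scaffolds
  n <- config$n_genes
  if (n == 0L) {
    return(list(models = list(), evidence = data.frame(), truth = data.frame()))
  }
  intronless <- runif(n) < config$intronless_fraction
  # planted labels: removal reasons need structure compatible with the rules
  label <- character(n)
  for (i in seq_len(n)) {
    label[i] <- if (intronless[i]) {
      sample(c("KEEP", "REPEAT_TE", "UTR_RNA_ONLY", "WEAK_EVIDENCE"), 1L,
             prob = c(0.55, 0.15, 0.15, 0.15))
    } else {
      sample(c("KEEP", "REPEAT_TE"), 1L, prob = c(0.85, 0.15))
    }
  }
  scaf_len <- nchar(scaf$seq)
  cursor <- rep(200L, nrow(scaf))
  models <- vector("list", n)
  evidence <- vector("list", n)
  for (i in seq_len(n)) {
    gid <- sprintf("gene_%04d", i)
    n_ex <- if (intronless[i]) 1L else sample(2:5, 1L)
    ex_w <- sample(80:300, n_ex, replace = TRUE)
    in_w <- if (n_ex > 1L) sample(40:200, n_ex - 1L, replace = TRUE) else integer()
    span <- sum(ex_w) + sum(in_w)
    s <- which(cursor + span + 200L < scaf_len)  # scaffolds with room
    if (!length(s)) stop("simulate_annotation: scaffolds too small for gene set")
    tgt <- s[(i - 1L) %% length(s) + 1L]
    at <- cursor[tgt]
    cursor[tgt] <- cursor[tgt] + span + sample(100:300, 1L)
    starts <- at + cumsum(c(0L, head(ex_w, -1L) + in_w))
    exons <- intervals(starts, starts + ex_w)
    S <- sum(ex_w)
    r <- runif(1, config$utr_ratio_range[1], config$utr_ratio_range[2])
    if (label[i] == "UTR_RNA_ONLY") r <- runif(1, 0.82, 0.95)
    else if (r > 0.78) r <- runif(1, 0.1, 0.78)  # keep other labels clear of the UTR rule
    utr_len <- round(S * r)
    cds_len <- S - utr_len
    # keep a minimal CDS; UTR-rule genes use a smaller floor so the clamp
    # cannot pull their spliced UTR ratio back under the 0.8 threshold
    cds_floor <- if (label[i] == "UTR_RNA_ONLY") 10L else 30L
    if (cds_len < cds_floor) { cds_len <- cds_floor; utr_len <- S - cds_floor }
    u5 <- floor(utr_len / 2)
    cds <- spliced_to_genomic(exons, u5, u5 + cds_len)
    utr <- rbind(spliced_to_genomic(exons, 0L, u5),
                 spliced_to_genomic(exons, u5 + cds_len, S))
    gm <- gene_model(gid, scaf$id[tgt], sample(c("+", "-"), 1L), exons,
                     cds = cds, utr = utr)
    models[[i]] <- gm
    ev <- evidence_for_label(label[i], intronless[i], utr_ratio(gm))
    evidence[[i]] <- data.frame(gene_id = gid, has_pfam = ev$has_pfam,
                                has_blastp = ev$has_blastp,
                                repeat_cov = ev$repeat_cov,
                                te_tagged = ev$te_tagged,
                                n_mrna_samples = ev$n_mrna_samples,
                                n_protein_species = ev$n_protein_species,
                                has_self_uniprot = ev$has_self_uniprot,
                                utr_ratio = ev$utr_ratio)
  }
  list(models = models,
       evidence = do.call(rbind, evidence),
       truth = data.frame(gene_id = vapply(models, `[[`, character(1),
                                           "gene_id"),
                          label = label, intronless = intronless))
}

#' Simulate transcript contigs with planted chimeric junctions
#'
#' Non-chimeric contigs are fully covered by consistent-pair depth.
#' Chimeric contigs fuse two transcripts with a `junction_len`-bp run of
#' zero coverage starting at the fusion point; planted ORF and domain
#' intervals stay clear of splittable junctions. A configurable share of
#' chimeras get an ORF laid across the junction and are recorded as
#' unsplittable (breaks are only allowed outside ORFs and domains).
#'
#' @param config a [sim_config()].
#' @param unsplittable_fraction share of chimeras whose junction is covered
#'   by an ORF (default 0.2).
#' @return list: `contigs` (`seq_records()`), `tracks` (list of coverage
#'   tracks by contig id), `orfs`/`domains` (BED-style data frames),
#'   `truth` (per contig: chimera flag, junction interval, `splittable`).
#' @export
simulate_chimeric_contigs <- function(config, unsplittable_fraction = 0.2) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  n <- config$n_contigs
  jl <- config$junction_len
  ids <- sprintf("contig_%04d", seq_len(n))
  is_chim <- runif(n) < config$chimera_fraction
  unsplit <- is_chim & runif(n) < unsplittable_fraction
  contigs <- character(n)
  tracks <- vector("list", n)
  orf_rows <- list(); dom_rows <- list(); truth_rows <- list()
  for (i in seq_len(n)) {
    if (is_chim[i]) {
      l1 <- sample(400:1200, 1L); l2 <- sample(400:1200, 1L)
      seqi <- random_dna(l1 + l2)
      depth <- rep(2L, l1 + l2)
      gap <- c(l1, l1 + jl)                 # junction gap [l1, l1 + jl)
      depth[(gap[1] + 1L):gap[2]] <- 0L
      if (unsplit[i]) {
        # ORF across the junction blocks the cut
        orf <- c(max(0L, gap[1] - 150L), min(l1 + l2, gap[2] + 150L))
        orf_rows[[length(orf_rows) + 1L]] <-
          data.frame(scaffold_id = ids[i], start = orf[1], end = orf[2],
                     name = "orf_spanning")
      } else {
        orf_rows[[length(orf_rows) + 1L]] <-
          data.frame(scaffold_id = ids[i], start = 50L,
                     end = min(l1 - 60L, 50L + 300L), name = "orf_t1")
        orf_rows[[length(orf_rows) + 1L]] <-
          data.frame(scaffold_id = ids[i], start = gap[2] + 60L,
                     end = gap[2] + 60L + 300L, name = "orf_t2")
      }
      truth_rows[[length(truth_rows) + 1L]] <-
        data.frame(contig_id = ids[i], is_chimera = TRUE,
                   break_start = gap[1], break_end = gap[2],
                   splittable = !unsplit[i])
      contigs[i] <- seqi
      tracks[[i]] <- coverage_track(ids[i], depth,
                                    plus_pairs = sample(5:30, 1L),
                                    minus_pairs = sample(0:4, 1L))
    } else {
      l <- sample(300:1500, 1L)
      contigs[i] <- random_dna(l)
      depth <- rep(2L, l)
      if (runif(1) < 0.3) {                  # occasional domain annotation
        d0 <- sample.int(max(1L, l - 200L), 1L)
        dom_rows[[length(dom_rows) + 1L]] <-
          data.frame(scaffold_id = ids[i], start = d0,
                     end = min(l, d0 + 150L), name = "domain")
      }
      flip <- runif(1) < 0.3                 # some minus-strand contigs
      tracks[[i]] <- coverage_track(
        ids[i], depth,
        plus_pairs = if (flip) sample(0:4, 1L) else sample(5:30, 1L),
        minus_pairs = if (flip) sample(5:30, 1L) else sample(0:4, 1L))
      truth_rows[[length(truth_rows) + 1L]] <-
        data.frame(contig_id = ids[i], is_chimera = FALSE,
                   break_start = NA_integer_, break_end = NA_integer_,
                   splittable = FALSE)
    }
  }
  names(tracks) <- ids
  bind_or_empty <- function(rows) {
    if (length(rows)) do.call(rbind, rows) else
      data.frame(scaffold_id = character(), start = integer(),
                 end = integer(), name = character())
  }
  list(contigs = seq_records(ids, contigs),
       tracks = tracks,
       orfs = bind_or_empty(orf_rows),
       domains = bind_or_empty(dom_rows),
       truth = do.call(rbind, truth_rows))
}

#' Simulate ortholog CDS-length pairs from a log-log linear model
#'
#' Draws `log10(len_a) ~ N(3, 0.3)` (CDS lengths centred near 1 kb) and
#' `log10(len_b) = intercept + slope * log10(len_a) + N(0, sigma)`.
#'
#' @param n number of pairs.
#' @param intercept,slope generating coefficients (defaults 0.508, 0.939).
#' @param sigma residual s.d. on log10 scale (default 0.2).
#' @return data frame `cds_len_a`, `cds_len_b` (bp, positive).
#' @export
sim_ortholog_cds_lengths <- function(n, intercept = 0.508, slope = 0.939,
                                     sigma = 0.2) {
  la <- rnorm(n, mean = 3, sd = 0.3)
  lb <- intercept + slope * la + rnorm(n, sd = sigma)
  data.frame(cds_len_a = 10^la, cds_len_b = 10^lb)
}

#' Simulate two-species homology with planted orthologs, rearrangements
#' and an expanded family
#'
#' Species A genes sit on `n_scaffolds` scaffolds at regular spacing;
#' species B mirrors the layout gene for gene (collinear), then the
#' configured rearrangements are applied to the B order: each inversion
#' reverses an interior run of 4 genes (adding 2 monotonicity breakpoints
#' to that scaffold/chromosome pair), each translocation moves a run of 3
#' genes to another chromosome (a new pair with a single block). A share
#' `ortholog_fraction` of genes get a planted 1:1 ortholog whose hits are
#' mutually best (true bitscore 500, background 300, additive uniform
#' noise `bitscore_noise` within a margin that cannot reorder them);
#' remaining genes are species-specific. One family of
#' `n_expanded_family` species-A genes (2 in B) is connected inside the
#' self-hit tables. Ortholog pairs carry CDS lengths drawn from
#' [sim_ortholog_cds_lengths()].
#'
#' @param config a [sim_config()].
#' @return list: hit tables `hits_ab`, `hits_ba`, `hits_aa`, `hits_bb`,
#'   gene position tables `genes_a`, `genes_b`, `family_of_gene`, and
#'   `truth` (`ortholog_pairs`, `expected_blocks`, `family_a`,
#'   `family_b`).
#' @export
simulate_homology <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  n <- config$n_genes
  per <- ceiling(n / config$n_scaffolds)
  scaffold_a <- sprintf("scaffold_%02d", ((seq_len(n) - 1L) %/% per) + 1L)
  idx_on <- ((seq_len(n) - 1L) %% per) + 1L
  spacing <- 20000
  genes_a <- data.frame(gene_id = sprintf("tmA_g%04d", seq_len(n)),
                        scaffold_id = scaffold_a,
                        pos = idx_on * spacing)
  # B mirrors A: chrB_k carries the partners of scaffold_k genes, in order
  genes_b <- data.frame(gene_id = sprintf("tcB_g%04d", seq_len(n)),
                        chrom_id = sub("scaffold", "chrB", scaffold_a),
                        ord = idx_on)
  breakpoints <- list()
  bump <- function(scaf, chrom, k) {
    key <- paste(scaf, chrom)
    breakpoints[[key]] <<- (if (is.null(breakpoints[[key]])) 0L else
      breakpoints[[key]]) + k
  }
  scafs <- unique(scaffold_a)
  for (s in scafs) bump(s, sub("scaffold", "chrB", s), 0L)

  n_inv <- config$rearrangement_ops$inversions %||% 0L
  n_tra <- config$rearrangement_ops$translocations %||% 0L
  used <- character(0)
  for (v in seq_len(n_inv)) {
    s <- setdiff(scafs, used)[1]
    if (is.na(s)) break
    used <- c(used, s)
    on_s <- which(genes_a$scaffold_id == s)
    if (length(on_s) < 10L) next
    seg <- on_s[4:7]                       # interior run of 4
    genes_b$ord[seg] <- rev(genes_b$ord[seg])
    bump(s, sub("scaffold", "chrB", s), 2L)
  }
  for (v in seq_len(n_tra)) {
    s <- setdiff(scafs, used)[1]
    if (is.na(s)) break
    used <- c(used, s)
    on_s <- which(genes_a$scaffold_id == s)
    if (length(on_s) < 8L) next
    seg <- tail(on_s, 3L)                  # terminal run of 3 moves away
    dest <- sub("scaffold", "chrB", setdiff(scafs, s)[1])
    genes_b$chrom_id[seg] <- dest
    genes_b$ord[seg] <- per + seq_along(seg)  # appended at dest end
    bump(s, dest, 0L)
  }
  genes_b$pos <- genes_b$ord * spacing

  is_ortho <- runif(n) < config$ortholog_fraction
  lens <- sim_ortholog_cds_lengths(sum(is_ortho))
  pairs <- data.frame(gene_a = genes_a$gene_id[is_ortho],
                      gene_b = genes_b$gene_id[is_ortho],
                      cds_len_a = lens$cds_len_a,
                      cds_len_b = lens$cds_len_b)

  eps <- config$bitscore_noise
  jitter <- function(k) if (eps > 0) runif(k, -eps, eps) else rep(0, k)
  hit_row <- function(q, s, score, ev) {
    k <- length(q)
    data.frame(query_id = q, subject_id = s,
               pct_identity = rep(90, k), aln_len = rep(300L, k),
               mismatches = rep(30L, k), gap_opens = rep(0L, k),
               qstart = rep(1L, k), qend = rep(300L, k),
               sstart = rep(1L, k), send = rep(300L, k),
               evalue = rep_len(ev, k), bitscore = score)
  }
  empty_hits <- hit_row(character(0), character(0), numeric(0), numeric(0))
  m <- nrow(pairs)
  ab <- list(); ba <- list()
  if (m) {
    ab[[1]] <- hit_row(pairs$gene_a, pairs$gene_b, 500 + jitter(m), 1e-50)
    ba[[1]] <- hit_row(pairs$gene_b, pairs$gene_a, 500 + jitter(m), 1e-50)
    # background: each ortholog also weakly hits the next gene's partner
    nxt <- c(seq_len(m)[-1], 1L)
    ab[[2]] <- hit_row(pairs$gene_a, pairs$gene_b[nxt], 300 + jitter(m), 1e-20)
    ba[[2]] <- hit_row(pairs$gene_b, pairs$gene_a[nxt], 300 + jitter(m), 1e-20)
    # high-bitscore hits above the e-value ceiling must be ignored
    ab[[3]] <- hit_row(pairs$gene_a[1], pairs$gene_b[min(2L, m)], 900, 1e-9)
  }
  hits_ab <- if (length(ab)) do.call(rbind, ab) else empty_hits
  hits_ba <- if (length(ba)) do.call(rbind, ba) else empty_hits

  # expanded family: n_expanded_family members in A, 2 in B
  fam_a <- sprintf("tmA_hist%03d", seq_len(config$n_expanded_family))
  fam_b <- sprintf("tcB_hist%03d", seq_len(min(2L, config$n_expanded_family)))
  ring <- function(ids, ev = 1e-30) {
    if (length(ids) < 2L) return(empty_hits)
    hit_row(ids, ids[c(2:length(ids), 1L)], 400 + jitter(length(ids)), ev)
  }
  hits_aa <- rbind(ring(fam_a),
                   hit_row(fam_a[1], fam_a[1], 600, 1e-80),      # self-pair, dropped
                   if (n >= 2L) hit_row(genes_a$gene_id[1], genes_a$gene_id[2],
                                        150, 1e-3) else NULL)     # above ceiling
  hits_bb <- ring(fam_b)
  family_of_gene <- setNames(rep("histone_like", length(c(fam_a, fam_b))),
                             c(fam_a, fam_b))

  expected_blocks <- data.frame(
    scaffold_a = sub(" .*", "", names(breakpoints)),
    chrom_b = sub(".* ", "", names(breakpoints)),
    breakpoints = unlist(breakpoints, use.names = FALSE))
  expected_blocks$expected <- 1L + expected_blocks$breakpoints

  list(hits_ab = hits_ab, hits_ba = hits_ba, hits_aa = hits_aa,
       hits_bb = hits_bb, genes_a = genes_a, genes_b = genes_b,
       family_of_gene = family_of_gene,
       truth = list(ortholog_pairs = pairs,
                    expected_blocks = expected_blocks,
                    family_a = fam_a, family_b = fam_b))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a full simulated dataset to disk
#'
#' Runs all four generators and writes genome.fasta, genes.gff3,
#' evidence.tsv, contigs.fasta, coverage/<contig>.tsv, orfs.bed,
#' domains.bed, hits_{ab,ba,aa,bb}.tsv and truth.json under `dir`.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_simulation <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "coverage"), showWarnings = FALSE)
  genome <- simulate_genome(config)
  ann <- simulate_annotation(config, genome)
  chi <- simulate_chimeric_contigs(config)
  hom <- simulate_homology(config)
  write_fasta(genome$scaffolds, file.path(dir, "genome.fasta"))
  write_gff3(ann$models, file.path(dir, "genes.gff3"))
  write_evidence(ann$evidence, file.path(dir, "evidence.tsv"))
  write_fasta(chi$contigs, file.path(dir, "contigs.fasta"))
  for (tr in chi$tracks) {
    write_coverage(tr, file.path(dir, "coverage",
                                 paste0(tr$contig_id, ".tsv")))
  }
  write_bed(chi$orfs, file.path(dir, "orfs.bed"))
  write_bed(chi$domains, file.path(dir, "domains.bed"))
  write_hits(hom$hits_ab, file.path(dir, "hits_ab.tsv"))
  write_hits(hom$hits_ba, file.path(dir, "hits_ba.tsv"))
  write_hits(hom$hits_aa, file.path(dir, "hits_aa.tsv"))
  write_hits(hom$hits_bb, file.path(dir, "hits_bb.tsv"))
  truth <- list(satellite = genome$truth$satellite,
                mito = genome$truth$mito["intervals"],
                genes = ann$truth,
                chimeras = chi$truth,
                ortholog_pairs = hom$truth$ortholog_pairs,
                expected_blocks = hom$truth$expected_blocks,
                family_a = hom$truth$family_a,
                family_b = hom$truth$family_b)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(dir)
}
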