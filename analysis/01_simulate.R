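#!/usr/bin/env Rscript
# Generate the synthetic study dataset: a genome with planted satellite
# arrays and a tandem-triplicated mitochondrion-like region, gene models
# with evidence and planted filter labels, chimeric transcript contigs with
# coverage tracks, and two-species homology tables. Everything downstream
# (02-06) reads from results/simdata.

library(annotqc)

cfg <- sim_config(seed = 20260920L)
dir <- "results/simdata"
write_simulation(cfg, dir)

genome <- read_fasta(file.path(dir, "genome.fasta"))
contigs <- read_fasta(file.path(dir, "contigs.fasta"))
models <- read_gff3(file.path(dir, "genes.gff3"))

cat("Simulated dataset written to", dir, "\n")
cat(sprintf("  scaffolds: %d (%.1f kb total)\n", nrow(genome),
            sum(nchar(genome$seq)) / 1e3))
cat(sprintf("  gene models: %d (%.0f%% intronless)\n", length(models),
            100 * mean(vapply(models, is_intronless, logical(1)))))
cat(sprintf("  transcript contigs: %d\n", nrow(contigs)))
cat("  hit tables: hits_ab/ba/aa/bb.tsv; ground truth: truth.json\n")
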