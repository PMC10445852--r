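#!/usr/bin/env Rscript
# Satellite and mitochondrial-like copy scanning: local-alignment scan of
# the 142-bp monomer over the simulated scaffolds at the >80% coverage /
# >=90% identity thresholds, and tandem-copy counting of the planted
# mitochondrion-like sequence in its host scaffold.

library(annotqc)

dir <- "results/simdata"
genome <- read_fasta(file.path(dir, "genome.fasta"))
truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                             simplifyVector = TRUE)

res <- scan_monomer(genome, sim_satellite_monomer(),
                    min_coverage = 0.80, min_identity = 90)
cat(sprintf("Satellite scan: %d occurrences on %d scaffolds, %d bp total\n",
            res$summary$n_occurrences, res$summary$n_scaffolds,
            res$summary$total_bp))
planted <- truth$satellite
cat(sprintf("Planted: %d copies (%d at identity >= 90%%)\n", nrow(planted),
            sum(planted$identity >= 90)))
write_bed(data.frame(scaffold_id = res$occurrences$scaffold_id,
                     start = res$occurrences$start,
                     end = res$occurrences$end,
                     name = sprintf("sat_%.1f", res$occurrences$identity)),
          "results/satellite_occurrences.bed")

# the generator's mito-like sequence is re-derived from the same seed
cfg <- sim_config(seed = 20260920L)
g <- simulate_genome(cfg)
host <- genome[genome$id == g$truth$mito$scaffold_id, , drop = FALSE]
mito <- count_reference_copies(host, g$truth$mito$mito_seq,
                               min_identity = 80)
cat(sprintf("Mito-like copies in %s: %d (planted %d)\n", host$id,
            mito$n_copies, nrow(g$truth$mito$intervals)))
print(mito$intervals, row.names = FALSE)
write.table(mito$intervals, "results/mito_copies.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
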