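---
title: "Methods: annotation QC, chimera splitting and comparative analyses"
author: "annotqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotation QC, chimera splitting and comparative analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annotqc)
```

# Scope and data model

`annotqc` re-implements, as a tested pipeline, the computations that turn a
draft insect genome assembly and its raw annotation evidence into a curated
gene set and two-genome comparative results: assembly contiguity metrics
and the scaffold length cut, transcript-contig post-processing (trimming,
low-complexity masking, ORF discovery, read-pair coverage, chimeric-contig
splitting, strand orientation), evidence-based retention rules, the
sequential gene-model filtering cascade, reciprocal best-hit (RBH)
orthology with macrosynteny chaining, paralog clustering with a
family-expansion table, an ortholog CDS-length regression, and
satellite/mitochondrial copy scanning. Heavy external tools (assemblers,
aligners, RepeatMasker, HMMER, BUSCO, gene predictors) are out of scope:
their *tabular outputs* are this package's inputs.

All coordinates are **0-based half-open** internally. GFF3 and 12-column
hit files are 1-based inclusive and converted exactly once, at the I/O
boundary; BED already matches the internal convention. A single convention
everywhere is the cheapest way to kill off-by-one drift. Sequences are
normalized to upper-case `{A,C,G,T,N}` on read; unknown letters become `N`
with a warning rather than an error, so imperfect inputs keep flowing.
When a gene has several mRNA isoforms the first in file order is used:
gene sets here are counted without isoforms.

# Assembly metrics

`compute_stats()` reports contig counts, cumulative size, max/mean length,
N50/L50 and N90/L90, auN, GC% and N counts. NX is the length of the contig
at which the descending cumulative length first *reaches* X% of the total;
LX is its 1-based rank; auN is the length-weighted mean contig length
$\sum_i \ell_i^2 / \sum_i \ell_i$. GC% excludes N from the denominator.
Percentages and means are rounded **half away from zero**
(`round_half_up()`), because that is the rounding that reproduces
published assembly tables exactly (e.g. 1360/1367 → 99.5%,
28,500/287,931,689 → 0.01%); base R's banker's rounding does not.
`reference_assembly_counts()` ships the published numerator/denominator
pairs for the mealworm (*Tenebrio molitor*) and red flour beetle
(*Tribolium castaneum*) assemblies, and `check_reference_arithmetic()`
re-derives every printed mean and percentage from them.

The scaffold filter keeps scaffolds **strictly longer** than 35 kb. The
source phrasing ("larger than") implies a strict cut and the published
scaffold counts cannot disambiguate it; strict is the package's choice and
the threshold is a parameter.

# Transcript-contig QC

*Trimming.* The first and last 5 bases of each contig are removed
(assembler ends are unreliable); contigs shorter than 10 bp become empty.

*DUST masking.* Each 64-bp window gets the symmetric DUST score
$S = 10 \cdot \frac{\sum_t c_t(c_t-1)/2}{w-2}$ over its triplet counts;
windows with $S > 20$ are masked and overlapping masked windows merged.
Window, threshold and the mask are all exposed. This is the windowed
variant of the DUST family, not a byte-for-byte clone of NCBI
`dustmasker`'s perfect-interval algorithm; masked-base counts can differ
slightly from that tool, which is acceptable because the downstream filter
only needs a stable low-complexity fraction. Triplets containing `N` are
not counted; the denominator is unchanged. The complexity filter then
keeps contigs strictly longer than 150 bp with strictly more than 75%
unmasked bases.

*ORFs.* `find_orfs()` reports complete ORFs only — first in-frame ATG
after the previous stop, through the next in-frame stop — on all six
frames, with a 100-codon minimum by default. The upstream tool named for
this step reports longest complete ORFs with this structure; the exact
minimum is a parameter.

*Pair coverage.* A read pair is *consistent* when its mates are convergent
(leftmost read on the plus strand, rightmost on minus) and the outer span
is at most 1,000 bp. The insert bound is not stated by the source
protocol; 1 kb is a standard short-insert RNA-seq library bound and is
configurable. Depth is incremented over the full outer span; read-1
orientation votes for the transcript strand.

*Chimera splitting.* Candidate junctions are maximal runs of **exactly
zero** consistent-pair depth of at least 10 bp (`min_gap` avoids
single-base dropouts). A junction is cut only when it intersects no ORF
and no domain interval; the uncovered gap bases are removed entirely
(junction sequence in a mis-joined contig is artefactual) and pieces are
renamed `id.1`, `id.2`, … left to right. Splitting at *abrupt but
non-zero* coverage shifts is deliberately not performed — the magnitude
that should trigger it is unknowable without the original data — but
≥10-fold shifts within 20 bp are flagged in the report so a user can
inspect them.

*Orientation.* A contig is reverse-complemented when minus-strand votes
outnumber plus; ties keep the input orientation and are flagged
ambiguous.

# Evidence retention and the gene-filter cascade

Transcript alignments are kept when aligned fraction of the **contig
length** exceeds 0.80 and identity exceeds 95% (both strict, following
"higher than"/"more than" phrasing; the overlap base is the contig because
the rule is stated for aligned contigs). Protein matches pass two stages:
score strictly above 0.9× the per-protein best (the best match always
survives), then proteins with strictly more than half their length
aligned. Per-protein aligned coverage is taken as the maximum aligned
length among surviving matches, since per-base alignment coordinates are
not part of the evidence table. Single-exon aligned transcripts seen in
only one sample (no overlapping transcript from any other sample, same
scaffold and strand, ≥1 shared base) are removed before gene building;
multi-exon transcripts are never removed by this rule.

The post-prediction cascade classifies every gene with the first matching
rule:

1. **REPEAT_TE** (any gene): >90% of exonic bases covered by repeats *or*
   a transposon-library tag, and no pfam/blastp hit. The no-hit guard
   applies to both branches: the combined phrasing ("either highly covered
   … or TE tagged … without any blastp/pfam hit") supersedes the earlier
   blanket "automatically classified as repeats", so a repeat-covered gene
   with a domain hit survives. Repeat coverage is computed over the union
   of the gene's exonic bases (a per-exon maximum is a configurable
   alternative).
2. **UTR_RNA_ONLY** (intronless only): no protein-species support, spliced
   UTR ratio UTR/(UTR+CDS) strictly above 0.80, no hits. The ratio uses
   spliced (exonic) lengths, not genomic span.
3. **WEAK_EVIDENCE** (intronless only): fails all of (i) ≥1 mRNA sample
   and ≥1 protein species, (ii) ≥2 mRNA samples, (iii) a same-species
   curated protein — and has no hits.
4. otherwise **KEEP**.

The decision is a pure per-gene function, so it is deterministic and
order-independent, and adding a pfam or blastp hit can only flip
REMOVE→KEEP (every removal rule carries the no-hit guard). Multi-exon
genes can only be removed by rule 1. Whether rules 2–3 were originally
evaluated on all genes or only the no-hit subset is not decidable from the
source description; first-match-wins per gene is the package's reading and
gives identical results on the no-hit subset.

# Comparative stage

*RBH.* Hits above e-value 1e-10 are discarded; per query the best hit is
the highest bitscore, ties broken by lower e-value then lexicographic
subject id (a deterministic, logged tie-break). A pair is orthologous when
it is mutually best. RBH operates on one sequence per gene; where inputs
are isoform-level, collapse to the best isoform score per gene first.

*Macrosynteny.* Within each (scaffold, chromosome) pair, ortholog
midpoints are sorted by the A genome and chained greedily while B
positions stay monotone (direction fixed by the first step) and adjacent
gaps stay within 1 Mb on both genomes; chains under 3 genes are dropped.
Greedy monotone-run splitting, rather than dynamic-programming longest
increasing subsequence chaining, is adequate at this scale and is
oracle-checked against a literal scan on small inputs. Gene position is
the midpoint of the genomic span (no anchor is prescribed by the source).
`write_links()` emits the circos-style six-column link file.

*Paralogs.* Self-pairs and hits above the e-value ceiling are dropped; the
remaining undirected similarity graph's connected components (via igraph)
are the clusters, singletons reported separately. The expansion table
counts labelled members per family and species, with an `Inf` ratio when a
family is absent from species B.

*CDS-length regression.* Ordinary least squares of
$\log_{10}(\mathrm{len}_B)$ on $\log_{10}(\mathrm{len}_A)$ over ortholog
pairs. Slope and $R^2$ are invariant to the log base; the intercept is
reported in base-10 units (the source plot states only "log-scaled";
base 10 is this package's convention and is configurable upstream by
transforming the inputs).

# Repeat and mitochondrial scanning

`scan_monomer()` and `count_reference_copies()` replace a seeded heuristic
search with deterministic Smith–Waterman local alignment (match +1,
mismatch −1, gap open −2, gap extend −1; a gap of length $L$ costs
$L+1$) and **iterative masking**: the best hit is recorded, masked with
`N`, and the scaffold realigned until the best score falls below a floor
(half the monomer length by default — safely under any hit that could
pass the reporting thresholds). Masking guarantees reported intervals
never overlap, and raising the identity threshold can only shrink the
occurrence set. Satellite occurrences are kept at monomer coverage
strictly above 80% and identity at or above 90% (the stated "> / ≥"
asymmetry is preserved); coverage is measured on the monomer (query)
because satellite variants are described by how much of the satellite
they cover. Per-masked-hit counting is used (whether the original count
merged intervals is unknown). Both strands are scanned against a shared
mask. Copy counting against a full reference (the mitochondrion-in-a-
scaffold case) uses the same loop with an 80% identity floor.

# The synthetic-data generator

The generators produce every input with ground truth attached, under full
determinism (`seed` plus fixed per-generator offsets). Background sequence
is i.i.d. uniform ACGT so DUST behaviour is predictable; low-complexity
stretches are planted explicitly where a test wants them. Defaults encode
the study conditions: a 27% intronless fraction among predictions, a
fixed 142-bp satellite monomer planted as tandem arrays with per-copy
identity drawn from 85–100%, and a 15,724-bp mitochondrion-like sequence
planted in tandem triplicate in one scaffold. The shipped monomer is a
frozen random sequence, not a published satellite (no such sequence is
redistributed here). Bitscore noise is additive uniform within ±5 by
default, far below the 200-point margin between planted-best and
background hits, so noise can never reorder bests; `bitscore_noise = 0`
gives the exact mode used by the recovery tests.

Planted gene-filter labels are fixed by evidence-template construction,
not by running the classifier: UTR-rule genes are built with a model UTR
ratio in 0.82–0.95 and no protein support; keepers that rely on transcript
support have their ratio clamped below 0.78 so no removal rule can reach
them; a small CDS floor (10 bp for UTR-rule genes, 30 bp otherwise)
prevents rounding from crossing the 0.8 boundary. Chimeric contigs fuse
two transcripts with a 40-bp zero-coverage junction at the fusion point;
a configurable share get an ORF across the junction and are recorded as
unsplittable. Rearrangements in the species-B gene order are interior
4-gene inversions (2 monotonicity breakpoints each) and terminal 3-gene
translocations (a new scaffold/chromosome pair with one block), so the
expected block count per pair is exactly 1 + breakpoints.

What the generator does **not** emulate: sequencing error and read-level
artefacts, repeat-induced mis-assembly, alignment-length/identity
heterogeneity of real hit tables, paralogy interference with RBH, and
GC/codon structure of real genes. Passing the planted-truth suites
therefore demonstrates correctness of the *rules and algorithms*, not
field performance on real data.

# Problem sizes and numerical choices

The shipped analysis (`analysis/01–06`) and the acceptance script run at
desk scale chosen to exercise every code path while keeping each stage in
seconds to a couple of minutes: an 8-scaffold ~0.7 Mb genome, 160–2,000
gene models, 200 transcript contigs, 500 planted orthologs, and the
full-length 15,724-bp mitochondrion-like reference (its Smith–Waterman
pass is the single most expensive step). The regression-recovery check
uses 10,000 pairs with residual SD 0.2 on the log10 scale, which
determines coefficient recovery to well within ±0.02. Ties are broken
deterministically everywhere (documented in each function); degenerate
inputs (empty files, empty contigs, genes without UTR/CDS, groups without
matches) return empty results or `NA` rather than failing, except where a
contract is violated (negative depth, CDS outside exons, id mismatches),
which raises an error naming the offender.

# Known limitations

- The DUST variant is windowed, not the suffix-perfect interval
  algorithm; masked boundaries can differ from NCBI `dustmasker` by a few
  bases.
- Greedy synteny chaining absorbs the first element after a monotone run
  into the preceding block when the step happens to continue its
  direction; block *counts* are unaffected, memberships at breakpoints
  can differ from an LIS-based chainer.
- The e-value-threshold mode of the satellite scan converts SW scores
  with default Karlin–Altschul parameters and is approximate by design.
- `filter_gene_set()` summaries assume one evidence row per gene;
  isoform-level evidence must be collapsed first.
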