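---
title: "Attributing gut-microbiome reads after a habitat exchange: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributing gut-microbiome reads after a habitat exchange}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A host transplanted between two aquatic habitats reorganises its gut
microbiome within weeks. Given 16S amplicon libraries from native-habitat
guts, exchanged guts, and the water and sediment of both habitats, the
analysis asks, for every read in an exchanged gut that belongs to a taxon
whose abundance changed substantially: is it *indigenous* (shared with the
native-habitat gut community, G), acquired from the new habitat's *water* (W)
or *sediment* (S), a combination (GS, GW, SW, GSW), or *Specific* to the
exchanged hosts? `gutswap` implements that inference and a synthetic
experiment generator that makes it verifiable: because no public re-analysis
can reproduce the original field study's numbers without its raw archive and
the exact reference databases and tool versions, this package's validation is
property-based against simulated ground truth instead.

# The attribution procedure

The chain is: QC/demultiplexing, 97% OTU clustering, family-level
aggregation, log2 fold-change targeting, pooled 99% re-clustering, core
filtering, and class assignment by cluster co-membership.

**Identity.** All clustering uses global Needleman–Wunsch alignment with
match +1, mismatch −1 and a linear gap penalty of −2 per column; identity is
matching columns over *all* alignment columns, including gap columns. This
definition must be pinned for "97%" and "99%" to be meaningful; the chosen
one is the common usearch-style convention. Among score-tied alignments a
deterministic traceback (diagonal over gap-in-second over gap-in-first, with
the lexicographically smaller sequence first) fixes the reported identity,
and the test suite re-verifies scores and identities against an independent
plain-R dynamic program and an exhaustive alignment enumerator on small
cases.

**Greedy clustering.** Reads are dereplicated; unique sequences are processed
in decreasing abundance (ties: lexicographic sequence, then smallest read
id), each joining the *first* centroid in creation order whose identity meets
the threshold, else founding a centroid. First-match rather than best-match
keeps the procedure order-canonical and reproducible; with the simulator's
identity bands (cross-family ≈ 0.85, within-family ≈ 0.93, within-taxon reads
≥ 0.99 in expectation) the two coincide in practice. A sound shared-8-mer
bound prunes hopeless centroid comparisons: if identity ≥ t is achievable,
the shared 8-mer count must be at least t·Lmax − (d+1)·7 with
d = ⌊Lmin(1−t)/t⌋, so failing that bound proves the pair is below threshold.

**Targeting.** Fold changes are computed on *family-level group-mean relative
abundances* (families, not 97% OTUs, because the aggregation rank is what
makes replicate means comparable), with the inclusive boundary |log2| ≥ 1.
Zero means are replaced by half the smallest nonzero mean of the same group —
without an epsilon, families absent from one group would have infinite
ratios; half-minimum keeps them ranked above every observed contrast without
dominating. Families absent from both groups are dropped with a notice.

**Core filtering and classes.** Targeted-family reads from the exchanged
group are pooled with the native-gut group's reads and the new habitat's
water and sediment reads (same families) and clustered once at 99%. A single
pooled clustering, with per-read community tags, is what "assigning reads to
new OTUs and judging their origin per community" operationally means; tags
preserve the per-community bookkeeping. Clusters whose exchanged reads span
fewer than 50% of the exchanged replicates (inclusive at exactly half) are
dropped, as are single-replicate clusters — the single-replicate exclusion is
applied at cluster level because at read level it would be vacuous. Each
surviving exchanged read's class is the set of source communities with at
least one read in the same cluster, or Specific if none.

# The synthetic experiment

The generator emulates the study design: two habitats (lake C, river K), gut
groups C (3 replicates), K (6), lake-to-river CK (5), river-to-lake KC (5),
and water/sediment communities per habitat with 3 samples each; 2,000 reads
per sample of ~303 nt (V1–V2-like lengths drawn per family from 295–311 nt).

**Reference pool.** 20 families × 5 taxa descend from one root by
substitution-only mutation. Per-branch rates are calibrated through the
per-site Markov eigenvalue λ = 1 − (4/3)q, so that expected pairwise identity
is 0.93 within families and 0.85 across families (the family-branch rate
accounts for the taxon branches on top of it). Divergence is enforced in
expectation only; occasional closer pairs are legitimate and must be handled
by the clustering tie-breaks.

**Communities and individuals.** Master profiles draw taxa uniformly with
log-normal (σ = 1) abundances; richness encodes the habitat-diversity
gradient with river sources twice as rich as lake ones (C gut 25, K gut 50,
water 20/40, sediment 25/50). Individuals realize a master through a
*colonization bottleneck*: a gut carries at most 20 taxa, drawn
abundance-weighted with log-normal jitter (σ = 0.5). This is the mechanism by
which a richer source community produces more divergent individuals — two
draws of 20 from 50 taxa overlap far less than two draws of 20 from 25 —
which is what lets the simulated data reproduce the qualitative dispersion
pattern (exchange toward the richer habitat increases within-group
Bray–Curtis dispersion, exchange toward the poorer one decreases it).
Environmental samples instead retain 90% of their master (a bulk water or
sediment sample integrates far more material than one gut).

**Exchanged guts.** Each exchanged individual mixes four pools: an indigenous
profile drawn from the *realized* native-gut community (the mean of the
native replicates' profiles), water and sediment acquisitions drawn from the
realized environmental communities, and a group-specific pool of taxa absent
from all three sources. Acquisition draws are uniform with fresh log-normal
weights — founder and priority effects make what establishes in a new gut
largely independent of source abundance, and this stochasticity is what
propagates habitat richness into between-individual divergence. Mixing
weights are per group (CK 0.50/0.25/0.15/0.10 indigenous/water/sediment/
specific; KC 0.75/0.08/0.07/0.10): colonization pressure scales with the
diversity of the new habitat, which is the asymmetry the field observation
reports (many environment-associated candidate taxa after moving to the
river, almost none after moving to the lake). A single weight vector can be
supplied to apply symmetric mixing.

**Truth definition.** A read's origin class is computed from the taxon sets
the three source communities *realize in the experiment* (union of the
native replicates' profiles; union of the environmental samples' profiles),
not from the latent master pools: "indigenous" operationally means *shared
with the sampled native-habitat hosts*, which is exactly the estimand the
cluster-co-membership method measures. Reads are the taxon sequence mutated
i.i.d. per base at 0.5% (no indels, fixed length per taxon), so identity
thresholds remain analytically predictable; quality strings are constant
Q38 so QC is exercised by dedicated crafted fixtures rather than every
simulation. Sequencing depth is not reported by field studies of this kind
at a per-sample level that would pin it; 2,000 reads/sample is a deliberate,
documented default that keeps per-class counts deep enough for binomial
recovery checks.

**What the generator does not emulate.** Chimeras, indel/homopolymer errors,
paired-end merging, variable read lengths within a taxon, abundance-dependent
PCR bias, and contamination. Passing tests therefore demonstrate the
*logic* of the pipeline — threshold behaviour, bookkeeping, recovery of a
known mixing structure — not robustness to real MiSeq error profiles.

# Other numerical and design choices

- **Quality threshold** is the *mean* Phred over the trimmed read (a per-base
  minimum of 30 would discard nearly all real reads); the check order
  barcode → primer → length → quality is fixed so rejection logs are
  reproducible, and each rejected read carries exactly the first failing
  reason.
- **Barcodes** are matched by Hamming distance on the leading 10 bases;
  a barcode map is rejected at load time if two barcodes sit within twice the
  mismatch tolerance. The reverse primer is matched at the 3′ end as given —
  the simulator writes reads in that orientation, and strand inference is out
  of scope.
- **Chao1** defaults to the bias-corrected form (the classic form divides by
  F2 and is undefined without doubletons); Shannon uses natural log. The
  group comparison is Welch's t-test — the choice of test is a documented
  default, not a claim about which test produced any particular published
  P value.
- **NMDS** minimises Kruskal stress-1 by alternating pool-adjacent-violators
  monotone regression (via `isoreg`) with steepest-descent updates under step
  halving, so the accepted-stress trace is non-increasing by construction;
  stress-1 is bounded in [0, 1] because the isotonic fit can do no worse than
  a constant. The default start is the classical metric MDS configuration;
  only the *rank order* of the input dissimilarities enters the fit, so a
  strictly monotone transform of the distances leaves the trajectory from a
  fixed start unchanged. Bray–Curtis on family-level relative abundance is
  the ordination dissimilarity (the standard community choice when none is
  dictated), Spearman uses average ranks on ties, and UPGMA input samples are
  pre-sorted lexicographically so equal-height merges resolve predictably.
- **Heatmap filter:** family-level group means, >1% in at least one member of
  a native/exchanged pair and strictly >2-fold between them (either
  direction; a zero against a positive counts as infinite fold). The
  abundance filter reads "more than 1%", hence strict; the targeting filter
  reads "≥ 2.00", hence inclusive — the two thresholds are deliberately kept
  independent.
- **Degenerate inputs** are contracts, not crashes: empty targeted sets,
  all-zero abundance vectors, zero-variance Welch groups (statistic 0/p 1 on
  equal means, ±Inf/p 0 otherwise), empty FASTQ files, and constant-valued
  samples in Spearman clustering all have defined behaviour and tests.

# Problem sizes

The shipped analyses and checks use the default scenario: 31 samples × 2,000
reads (62,000 reads, ~100 reference taxa), which one pipeline run processes
in well under a minute of clustering time thanks to dereplication and the
k-mer prescreen. The test suite validates estimators on dozens of random
abundance vectors (rarefaction against 100,000-replicate Monte-Carlo
subsampling), clustering on 50 random instances of up to 30 reads against
the brute-force aligner, attribution recovery on five full default-scenario
runs, and the dispersion pattern on ten seeds.

# Known limitations

Attribution accuracy is measured against the simulator's own truth labels;
on real data the native-gut and environmental libraries are themselves
samples, so "Specific" conflates genuinely host-specific taxa with
undersampled source taxa. The best-hit centroid classifier assumes the
reference pool contains the true taxa (true here by construction; on real
data a naive-Bayes classifier against a curated database would replace it).
The fold-change targeting operates on compositional proportions and inherits
their usual caveats; no multiple-testing machinery is attached because the
threshold rule, not inference, defines the targeted set.
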