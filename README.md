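# gutswap

Habitat-exchange gut-microbiome analysis with ground-truth validation.

When an aquatic host is transplanted between habitats — say a freshwater
shrimp moved from a lake to a river — its gut community reorganises within
weeks. The analytical question is *where the new community comes from*: did a
bloomed taxon expand from the **indigenous** gut community of native-habitat
conspecifics (G), or colonise from the new habitat's **water** (W) or
**sediment** (S), or some combination (GW, GS, SW, GSW), or is it **Specific**
to the exchanged hosts? `gutswap` implements the full 16S rRNA amplicon
pipeline that answers this, plus a synthetic-community generator that makes
the answer checkable: every simulated read carries its true taxon, generating
pool, and origin class, so the whole analysis can be validated end to end
without any sequencing data.

## Method at a glance

1. **QC/demultiplexing** — barcode assignment (Hamming ≤ 1 on 10-nt barcodes),
   IUPAC-aware primer matching (≤ 2 errors, 27F/355R defaults), trimmed length
   200–600 nt, mean Phred ≥ 30; each rejected read logged with the first
   failing criterion.
2. **OTU clustering** — greedy centroid clustering of dereplicated reads in
   decreasing abundance order at 97% identity, where identity is
   matches / alignment columns of an optimal Needleman–Wunsch global alignment
   (match +1, mismatch −1, linear gap −2; Rcpp with a sound shared-*k*-mer
   prescreen). Centroids are classified by best-hit identity against the
   reference pool.
3. **Diversity** — Chao1 (classic S_obs + F1²/2F2 and bias-corrected
   S_obs + F1(F1−1)/(2(F2+1))), Shannon H = −Σ pᵢ ln pᵢ, analytic rarefaction
   E[S(d)] = Σᵢ (1 − C(N−Nᵢ, d)/C(N, d)), Welch tests between groups.
4. **Community comparison** — family-level aggregation, Bray–Curtis
   dissimilarity, NMDS (Kruskal stress-1 via monotone regression with a
   non-increasing accepted-stress trace), Spearman/UPGMA sample clustering,
   Venn-region accounting, and the >1% abundance & >2-fold-change heatmap
   filter.
5. **Source attribution** — families whose group-mean relative abundance
   changed ≥ 2-fold (|log2 ratio| ≥ 1) after exchange are targeted; their
   reads are pooled with native-gut, new-water and new-sediment reads and
   re-clustered at 99% identity; clusters spanning < 50% of exchanged
   replicates (or a single replicate) are dropped; each remaining exchanged
   read is classed G/S/W/GS/GW/SW/GSW/Specific by which source communities
   co-occur in its cluster.

## Worked example

The numbered scripts under `analysis/` run the whole study on the default
simulated scenario (seed 1); `run_pipeline()` does the same in one call:

```r
library(gutswap)
res <- run_pipeline(run_config(scenario_config(seed = 1)), "out")
```

On this scenario the pipeline reports (as printed by `analysis/0*.R`):

```
simulated 62000 reads over 31 samples (100 taxa, 20 families)
62000 reads in, 62000 accepted, 0 rejected
62000 reads -> 94 OTUs at 97%; mean cluster purity vs. true taxa: 1.0000
lake-to-river vs native lake: 0.349 vs 0.240 (diverging)
river-to-lake vs native river: 0.266 vs 0.461 (converging)
CK: 8 targeted families, 11 core OTUs, 1509 attributed reads
KC: 3 targeted families, 3 core OTUs, 820 attributed reads
attribution accuracy vs truth: 100.00% over 2329 reads
```

Reading these numbers: all simulated reads pass QC (clean Q38 reads by
design), the 97% clusters recover the true taxa essentially perfectly, and
the two dispersion lines show the habitat-diversity signature — the group
moved *to the richer river* diverges between individuals (mean within-group
Bray–Curtis 0.349 vs 0.240 in its native group) while the group moved *to the
poorer lake* converges (0.266 vs 0.461). Attribution then classifies every
targeted-family read in the exchanged guts, and 100% of those classes match
the generator's truth table. Stage tables land under `results/`.

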