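# satconnect

Satellite DNA — tandem arrays of a short repeated monomer at centromeres
and heterochromatin — is expected to evolve by *concerted evolution*:
molecular drive homogenizes repeat copies within a species while species
diverge, so identity within a species should exceed identity between
species. A satellite family that instead stays near-identical across a
genus ("frozen") is evidence that drive alone does not govern its
evolution. `satconnect` is a toolkit for putting that question to
low-coverage shotgun sequencing data, built for researchers comparing a
specific satellite family (e.g. a ~345-bp centromeric monomer) across
related species.

## What it computes

The pipeline mirrors the classic satellite-mining workflow:

1. **Merge** paired-end reads over their best 3' overlap
   (`merge_pairs()`): all overlaps ≥ 10 bp are scored as
   matches − mismatches; the per-base consensus keeps the higher-quality
   base.
2. **Screen** merged reads against a satellite clone library
   (`filter_reads()`): iterative Smith–Waterman masking, retaining reads
   whose repeat fraction is ≥ 0.99 — reads wholly inside tandem arrays.
3. **Cluster** retained reads at 95/97/99% identity
   (`cluster_greedy()`): greedy incremental clustering against cluster
   representatives, identity measured over the shorter sequence's full
   alignment span. Each cluster gets per-species composition, raw and
   normalized counts, and Shannon's H (nats).
4. **Graph** the clusters (`cluster_graph()`): pairwise representative
   similarity (local alignment percent), a Kruskal minimum spanning tree
   over distance 100 − similarity, and a species-mixing summary — the
   fraction of clusters containing reads from ≥ 2 species. Species-specific
   clusters are the drive prediction; intermingled clusters the frozen
   pattern. Exportable as GraphML/DOT.

Companion statistics: consensus monomers (`build_consensus()`),
intra-/inter-specific identity matrices and the
interspecific-exceeds-intraspecific flag rule
(`identity_matrix()`, `concerted_evolution_test()`), CENP-B box scanning
by critical-base counts (`scan_cenpb()`), and in-silico restriction
digestion of tandem arrays with monomer-ladder summaries
(`digest_array()`, `ladder_summary()`).

A simulator (`sim_config()`, `evolve_library()`, `build_array()`,
`simulate_reads()`) evolves monomer libraries along a species tree under
a molecular-drive regime (gene-conversion-like homogenization) or a
frozen regime (constrained sites, no homogenization), assembles tandem
arrays, and emits paired FASTQ — so the entire pipeline can be exercised,
and its regime discrimination tested, with no external data.

## Worked example

Simulate both regimes and run the pipeline at the 97% rate:

```r
library(satconnect)

for (mode in c("drive", "frozen")) {
  cfg <- sim_config(mode, seed = 11, n_pairs = 60L)
  ds  <- simulate_dataset(cfg)
  rep <- run_pipeline(ds$runs, ds$library, thresholds = 0.97)
  cat("==", mode, "==\n"); print(rep$mixing)
}
```

Output:

```
== drive ==
  threshold multi_source_fraction weighted_mean_shannon_h n_clusters
1      0.97                     0                       0         32
== frozen ==
  threshold multi_source_fraction weighted_mean_shannon_h n_clusters
1      0.97                     1                1.366487          7
```

Under drive, every one of the 32 clusters is single-species
(`multi_source_fraction = 0`): satellites sort by species, the concerted
signature. Under the frozen regime all clusters mix species
(`multi_source_fraction = 1`) with a mean within-cluster source diversity
of 1.37 nats — species-specific clusters are not identifiable, which is
the pattern a conserved satellite leaves in real data.

The same contrast at the monomer level:

```r
cfg  <- sim_config("frozen", seed = 11)
lib  <- evolve_library(cfg)
identity_matrix(lib, "intra")          # per-species mean pairwise identity (%)
concerted_evolution_test(identity_matrix(lib, "intra"),
                         identity_matrix(lib, "inter"))
```

In frozen mode intraspecific and interspecific identities sit within a
couple of points of each other and many species pairs are flagged
(interspecific > intraspecific); in drive mode the flags vanish.

A thin command-line front end is included:

```sh
Rscript inst/scripts/satconnect.R simulate --mode drive --seed 1 --outdir sim/
Rscript inst/scripts/satconnect.R digest --array sim/arrays.fasta --monomer 345
```

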