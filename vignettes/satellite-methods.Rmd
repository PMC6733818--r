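---
title: "Methods: satellite repeat discovery, clustering and regime simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: satellite repeat discovery, clustering and regime simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Satellite DNA — long tandem arrays of a short monomer, typically at
centromeres and heterochromatin — is expected to evolve by concerted
evolution: molecular drive (unequal crossover, gene conversion, rolling-circle
reinsertion) homogenizes copies within a species while species drift apart,
so intraspecific identity should exceed interspecific identity. A satellite
that instead stays near-identical across a genus ("frozen") argues that
drive alone is not the whole story, e.g. that the repeat is conserved by
function or that the ancestral repeat library was simply of low diversity.

`satconnect` asks this question of low-coverage shotgun data. It screens
paired-end reads for a satellite of interest, clusters the surviving reads
by sequence identity across species, and inspects whether clusters are
species-specific (the drive prediction) or species-intermingled (the frozen
pattern). A built-in simulator generates data under both regimes, so the
whole chain of reasoning is testable without any sequencing download.

## Pipeline stages and their models

### Read merging

`merge_pair()` reverse-complements the reverse mate and scores every
ungapped 3' overlap of length at least `min_overlap` (default 10) as
`matches − mismatches`; the best-scoring overlap with mismatch rate at most
`max_mismatch_rate` (default 0.1) wins, ties going to the longer overlap
(the parsimonious one-fragment interpretation). Within the overlap the base
with the higher Phred quality is kept (ties keep the forward base). Scoring
is count-based by design — no quality-weighted likelihoods — because the
count scores can be checked exactly against an exhaustive-offset oracle;
quality enters only through the per-base consensus. Pairs with no
qualifying overlap are a normal, counted outcome.

### Repeat screening

`mask_read()` replaces a general repeat-masking engine with direct local
alignment (Smith–Waterman; match +1, mismatch −1, linear gap −2) of every
library monomer, both strands, against the read. Alignments with identity
at least `min_local_identity` (default 0.7) over at least 25 columns
contribute intervals; the found interval is hard-masked with `N` (which
mismatches everything, including itself) and the search repeats, so several
monomer copies along a merged read are all recovered. The repeat fraction
is the length of the interval union over the read length, which matches
the masked-base semantics of conventional maskers. `filter_reads()` keeps
reads with repeat fraction at least 0.99 — a deliberately harsh cut that
focuses the analysis on reads wholly inside tandem arrays rather than solo,
degenerate monomers at array margins. The 0.7 identity floor is this
toolkit's declared stand-in for a masking engine's internal defaults; it is
low enough to catch monomers ~25% diverged from the library, i.e. anything
that would still be recognized as the same satellite family.

### Identity and clustering

`pairwise_identity()` is the workhorse definition: the shorter sequence is
aligned end to end (match +1, mismatch −1, gap open −2, gap extend −1, a
gap of length L costing 2 + L), terminal gaps on the longer sequence are
free, and identity is matched columns over alignment columns, maximized
over strands. The denominator choice — the shorter-sequence alignment
span — matters: a fully ends-free alignment would collapse, on divergent
pairs, to a short perfect overlap and report near-100% identity for
sequences that are 15% diverged. Covering the shorter sequence end to end
removes that degeneracy and is the closest deterministic analog of how
greedy clustering tools measure identity.

`cluster_greedy()` is a transparent re-statement of greedy incremental
clustering: sequences sorted by length (descending, ties by id) are scanned
once; each sequence is compared to existing cluster representatives whose
length ratio is at least `length_diff_cutoff` (default 0.8) and joins the
highest-identity representative at or above the threshold (best-assignment
mode), else founds a new cluster. No word-filter heuristics are used —
inputs here are desk-scale and the exact scan is what makes a brute-force
oracle test possible. The thresholds 0.95/0.97/0.99 are the conventional
rates for satellite-variant resolution.

Cluster summaries report raw member counts, counts normalized per source
library by its initial read number and by its post-filter read number
(summed over the libraries present in the cluster, so the normalized totals
over all clusters are bounded by the library count), and Shannon's H of the
composition. H is reported in natural-log units (nats); that choice is
declared here and in the output header because conventions differ.

### The cluster graph

`cluster_similarity()` scores representative pairs by their best local
alignment (match +1, mismatch −1, linear gap −2, both strands), reported as
`100 × matches / alignment columns`. The minimum spanning tree over
distance `100 − similarity` is built by Kruskal's algorithm with a full
deterministic tie-break (distance, then smaller node id, then larger); on a
complete similarity graph the MST always exists. Edges may be pruned below
85% similarity for display, but only after the MST is built.
`mixing_summary()` condenses the question the graph answers into two
numbers: the fraction of clusters drawing members from two or more source
libraries, and the size-weighted mean Shannon H.

### Companion statistics

`build_consensus()` aligns clones progressively — most-central clone first
(highest mean pairwise identity), each next clone aligned globally against
the running majority consensus, profile columns re-expanded as needed.
Columns with more than 50% gaps are dropped; per column the majority base
is called and ties become the IUPAC code of the tied set. A dedicated
multiple aligner would differ in detail; the published identity statistics
this feeds carry a ±1.5 percentage-point tolerance for exactly that reason.

`identity_matrix()` computes intraspecific identity as the mean over all
unordered clone pairs within a species (the definition is not universal;
mean-pairwise was chosen as the least model-laden) and interspecific
identity between species consensuses, with an ambiguity code counting as a
match when its base set contains the other base.
`concerted_evolution_test()` applies the asterisk rule: flag every ordered
species pair whose interspecific identity exceeds the first species'
intraspecific identity — each flag is a point against unchecked concerted
evolution.

`scan_cenpb()` scores every 17-bp window on both strands of a consensus by
how many of the nine binding-critical positions of the human CENP-B box it
matches (ties: more total motif matches, then smaller offset, then +
strand). The motif and its critical positions are configuration data
(`inst/extdata/cenpb_motif.txt`), not constants, because the motif model is
exactly the thing a user may want to vary.

`digest_array()` models complete restriction digestion: a cut at every
exact site occurrence, with the MspI convention C^CGG (cut offset 1 into
the site) as the declared default. `ladder_summary()` bins fragments at
`round(length / monomer length)` — the in-silico counterpart of the
monomer-periodic ladder that tandem arrangement produces on a blot. For an
array whose copies lose their site independently with probability `q`, the
expected fraction of fragments spanning `k` monomers is
`(1 − q)² q^(k−1)`, which the tests check at `q = 0.3` over 10,000 copies.

## The simulator: what it emulates and what it does not

`sim_config()` describes a five-species clade (tree branch lengths in
substitutions per site, on the order of a few percent — a satellite
evolving fast relative to single-copy DNA) with a 345-bp monomer carrying
one MspI site, per-species libraries of 8 monomers, tandem arrays of 40
copies, and 2×150-bp read pairs on 260-bp inserts with 0.5% substitution
error at constant Q30.

Substitutions follow a Jukes–Cantor-like model (uniform over the three
alternative bases, no indels by default — consistent with the narrow
344–346-bp monomer-length band real clone sets show). The two regimes:

* **drive** — every site free; homogenization events, each copying a
  random donor monomer over a random recipient within the species (the
  simplest gene-conversion analog), occur at `homogenization_rate` events
  per monomer per branch-unit. Under these Moran-like dynamics the expected
  intra-library pairwise divergence is approximately
  `n_monomers × rate / homogenization_rate`; the default rate of 400 was
  chosen from this calculation to put intraspecific identity near 98%
  against interspecific identities of roughly 82–94% on the default tree —
  the concerted-evolution signature.
* **frozen** — no homogenization and 95% of sites constrained (drawn once
  at the root, immutable everywhere), so all identities stay near 99% and
  intra ≈ inter: the conserved-satellite pattern.

Site ablation during array assembly redraws its substitution if the
flanking context would recreate a shifted recognition site, so the
geometric ladder model holds exactly.

What the simulator does **not** emulate: quality-score profiles and
indel/chimera artifacts of real sequencers; higher-order repeat structure;
array-length variation among chromosomes; selection or centromere-drive
fitness dynamics; library-preparation biases. Passing the regime-contrast
tests therefore shows that the pipeline's statistics separate the two
evolutionary regimes under clean, known conditions — it does not show that
any particular real dataset is one or the other.

## Numerical choices and degenerate inputs

* Coordinates are 0-based, half-open throughout; FASTQ is Phred+33 with no
  dialect autodetection (the common emission format of SRA tooling).
* `N` is allowed in reads and scores as a universal mismatch, so masked or
  ambiguous stretches can never seed an alignment.
* Alignment ties inside the dynamic program are resolved by the alignment
  engine; every user-facing tie (merge overlap length, cluster assignment,
  MST edge order, motif window, anchor window) has a declared deterministic
  tie-break, tested explicitly.
* Empty reads, empty libraries, unpaired mates, disconnected graphs and
  sub-minimum clone sets are errors with named offenders, not silent
  results; an unmergeable pair and a read with zero repeat content are
  normal outcomes, counted in run statistics.
* All simulator outputs are byte-identical under a fixed seed; every
  stochastic default in the tests and the acceptance script derives from a
  single supplied seed.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline on 60
read pairs per species across the five-species default tree (300 pairs per
regime), cluster a few hundred retained reads, and digest a 10,000-copy
array for the ladder statistics. These sizes were chosen so the complete
analysis — both regimes end to end — finishes in minutes on one core while
keeping every Monte-Carlo tolerance tight; all counts scale linearly if a
user raises `n_pairs` or the library sizes.

## Known limitations

* The greedy scan is quadratic in the number of retained reads against
  cluster representatives; tens of thousands of reads will be slow. The
  exactness that enables oracle testing was deliberately preferred over
  word-filter speed.
* Identity under heavy indel divergence is only as good as the affine-gap
  model; the toolkit targets monomer families within ~25% divergence.
* The CENP-B scan counts critical-base matches; it deliberately does not
  assign motif-model p-values.
* Intraspecific identity from PCR-derived clone sets is biased toward the
  most amplifiable variant; the simulator does not model that bias, so
  comparisons of absolute identity levels between simulated and clone-based
  data should be read qualitatively.
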