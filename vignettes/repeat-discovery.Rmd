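---
title: "Reference-free repeat discovery and abundance phylogenetics with kchainr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free repeat discovery and abundance phylogenetics with kchainr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kchainr)
```

## The model

kchainr treats repeat discovery as dense-subgraph detection in a
bipartite incidence graph. The two vertex classes are k-mers (V1) and
sequencing reads (V2); a k-mer and a read are joined by an edge when the
k-mer occurs in the read (strands are collapsed: each k-mer is
represented by the lexicographic minimum of itself and its reverse
complement). For subsets Vs of k-mers and Vt of reads, the density

$$ d(V_s, V_t) \;=\; \frac{|E_{st}|}{|V_s|\,|V_t|} \in [0, 1] $$

is the fraction of possible k-mer–read incidences that are realised;
it equals 1 exactly when the subgraph is a biclique. The premise is
statistical: a single-copy locus contributes each of its k-mers to only
the handful of reads covering that locus, while a repeat family with
hundreds of genomic copies concentrates the *same* k-mers into
*many* reads — its k-mers and reads form a dense bicluster. Detecting
dense biclusters therefore finds repeats without a reference genome, an
assembly, or a curated repeat database. The k-mers of a bicluster are
then chained along exact (k−1)-overlaps into consensus sequences
(kChains), and downstream analysis works entirely on the
repeats-by-samples abundance matrix.

Abundance of a repeat in a sample is defined as the **median of
per-position read coverage** across the repeat's sequence after mapping
all of the sample's reads ("one best alignment" per read). The median is
robust to partial hits and edge effects; the per-position mean is
available as an alternative (`statistic = "mean"`).

## The search procedure

The published description of the dense-bicluster objective does not fix
a search algorithm, so the package documents its own, chosen for
determinism and auditability:

1. **Seed** at the unused k-mer with the highest remaining degree,
   starting from its full read neighbourhood (density 1 by
   construction).
2. **Grow** by alternately adding the k-mer, then the read, whose
   inclusion maximises the resulting density, accepting additions while
   density stays at or above `min_density` (default 0.5).
3. **Prune** by repeatedly removing the vertex whose removal most
   increases density, until no removal improves it.
4. **Accept** the cluster if it still meets `min_kmers` (5), `min_reads`
   (10) and the density floor; remove its edges from the working graph
   and repeat.

Ties everywhere resolve to the lexicographically smallest k-mer or read
id, so the search is bit-reproducible; the `seed` argument of
`find_biclusters()` exists only for interface symmetry. Every k-mer
absorbed into a grown candidate — accepted or rejected — is marked used
and never seeds again: a genomic locus is examined once, which bounds
the search at one growth per locus without losing qualifying clusters
(any cluster's best seed is its own highest-degree k-mer, and seeds are
taken in degree order, so true repeat clusters are grown before their
fringes are marked). The inner search runs in C++ with lazy max-heaps
over candidate gains.

Two properties of this procedure are worth knowing. First, the pruning
step drives clusters toward their densest core, often a near-biclique
considerably smaller than the full repeat; a 120-bp family is typically
recovered as several overlapping 30–60-bp chains rather than one
full-length consensus. This fragmentation is harmless for abundance
profiling (fragments of one family have proportional coverage) and the
optional `extend_kchains()` pass — a greedy unique-successor extension
against the full read set, off by default — can lengthen chains when a
full-length consensus is wanted. Second, cluster-count monotonicity in
`min_density` holds on clean planted structure but is not guaranteed on
arbitrary noisy graphs: lowering the floor can merge what a higher floor
splits.

## Chain assembly

Within one bicluster the k-mers are arranged on the (k−1)-overlap
(de Bruijn) graph, considering each canonical k-mer in both
orientations. Every maximal non-branching path is emitted as one chain;
a walk never reuses a k-mer in either orientation, which terminates
cycles and prevents a path from sliding onto its own reverse-complement
strand at palindromic k-mers (possible for even k). Divergent copies
produce branch points; each branch continues as its own chain rather
than being collapsed into an ambiguity consensus, so chains are always
exact k-mer paths supported by reads. Chains shorter than `min_length`
(30 bp, matching the short-repeat regime the method targets) are
discarded and reverse-complement duplicates merged. Discovery runs for
each k in `k_values` (12 and 15) and the union is deduplicated; the two
scales behave differently (k = 12 saturates faster on random sequence,
k = 15 is more specific) and keeping both costs only duplicates that the
reverse-complement dedup removes.

## Parameters that matter

| parameter | default | units / range | role |
|---|---|---|---|
| `k_values` | 12, 15 | bp | k-mer scales for the incidence graph |
| `discovery_fraction` | 0.10 | of pooled reads | subsample used for discovery |
| `min_kmer_reads` | 2 | reads | degree floor for V1 membership |
| `min_density` | 0.5 | — | bicluster density floor |
| `min_kmers`, `min_reads` | 5, 10 | vertices | bicluster size minima |
| `min_length` | 30 | bp | shortest reported kChain |
| `seed_k`, `min_identity` | 12, 0.9 | bp, fraction | mapper seed length and running-identity floor |
| `min_score` | 25 | matched bases | mapper score floor, the analogue of a local aligner's minimum score; keeps bare seed coincidences from depositing coverage |
| `pseudo` | 1 | coverage units | log-transform offset, ln(x + 1) keeps zeros at zero |
| `abundance_threshold` | 665 (150 for known-repeat libraries) | raw coverage | keep rows with max over samples strictly greater |
| `containment_threshold` | 0.5 | fraction of k-mers | contamination call floor |
| `metric` | euclidean | — | sample distance for the tree |

The high-abundance filter thresholds are expressed in raw
reads-per-base-pair coverage units, so the filter is applied to the
**raw** matrix before the log transform by default; `filter_stage =
"normalized"` applies it after normalization instead, for workflows that
state their threshold on the normalized scale.

## Normalization and ordination

The raw matrix is transformed elementwise to ln(x + pseudo) and
quantile-normalized (classic rank-mean normalization, ties receiving the
mean of their tied-rank targets; delegated to
`limma::normalizeQuantiles`), after which every sample has the identical
value distribution — appropriate because between-sample differences in
sequencing yield are nuisance here, relative repeat composition is the
signal.

PCA treats repeats as observations and samples as variables
(column-mean centring, exact SVD). Signs are fixed by making each
loading vector's largest-magnitude entry positive, so results are
deterministic. For the biplot the package uses a dual scaling with equal
per-component energy: repeat coordinates are U·diag(d) and sample
coordinates V·diag(d). Under this convention both clouds span the same
scale per component, so the distance from a repeat to the centroid of a
species' samples (`biplot_association()`) is meaningful, and repeats
land in the region of the species they are most abundant in. A
unit-norm-loading display was considered and rejected because it makes
cross-cloud distances scale-incommensurate.

`assign_max_species()` implements the repeat–species association: each
repeat goes to the species with the highest replicate-mean abundance,
exact ties to the lexicographically first species, all-zero rows flagged.
`profile_summary()` gives the per-sample mean abundance of one species'
assigned repeats — the bar-profile view that reveals asymmetric sharing
between related species.

## Distances and the tree

No distance metric is canonical for abundance profiles; the package
defaults to Euclidean distance on the normalized log matrix (Manhattan
and correlation distance are selectable — correlation because abundance
profiles are composition-like). Neighbor joining is implemented in the
package following Saitou–Nei with the Studier–Keppler Q-criterion:

- pair choice minimises Q(i,j) = (n−2)·d(i,j) − r(i) − r(j);
- branch lengths l(i) = d(i,j)/2 + (r(i) − r(j))/(2(n−2));
- reduction d(u,k) = (d(i,k) + d(j,k) − d(i,j))/2;
- ties resolve by label order; trees are returned as `ape` `phylo`
  objects with a basal trifurcation (unrooted).

On additive inputs the tree's path-length matrix reproduces the input to
numerical precision (the test suite verifies < 1e−9 on random additive
matrices up to 10 taxa, and agreement with `ape::nj`, which serves as an
independent oracle, never as the implementation). Negative branch-length
estimates — expected for non-additive data — are clamped to zero with a
warning reporting the clamped total. Trees are built over samples (one
tip per replicate), so replicate cohesion is itself a visible result.

## What the synthetic studies emulate — and what they do not

`simulate_study()` generates per-species genomes as i.i.d. uniform
background with planted repeat families: each family has one consensus
(drawn once per study, so shared families are genuinely shared),
inserted `copy_number[species]` times at random non-overlapping
positions, each copy independently mutated at the per-copy divergence
rate (2% by default — typical satellite-scale divergence). Replicates of
a species re-sequence the same genome. Reads are uniform-start,
uniform-strand, substitution-only (0.5% by default at the
quality-trimmed short-read error scale).

The default validation study (`default_study()`) fixes the conditions
used throughout the tests and the acceptance script: 4 species × 3
replicates, 100-kb backgrounds, 100-bp reads at 20× depth, three 120-bp
nuclear families with hierarchical sharing — {A, B} share one (300/100
copies), {A, B, C} share another (60/260/300), one is private to D
(300) — and optionally a chloroplast-derived family (40 copies
everywhere) cut verbatim from a simulated 3-kb cpDNA reference that
also serves as the contamination index. The shared families amplify in
opposite directions in A and B (A carries far more of the first, B far
more of the second) so that the two species differ in *rank* space, not
just in magnitudes: quantile normalization is rank-based and maps
columns with identical within-column orderings to identical vectors, so
species that differ only by proportional amplification of the same
repertoire are indistinguishable after it — a property of the
normalization worth remembering with small repeat panels. The cpDNA family is planted
without per-copy divergence because organellar DNA is effectively
clonal; this matters for the k-mer containment classifier, whose
containment drops steeply when a short chain carries even one
non-reference base (a single substitution removes k consecutive
k-mers), a sensitivity to keep in mind when screening diverged
contaminants. Copy numbers were chosen to span 0–300
while keeping every genome under the simulator's repeat-saturation
guard (planted bases ≤ half the background).

What passing on these studies shows: the discovery kernel finds
heavily amplified families and assembles faithful (≥ 90% identity)
chains; abundance ranks track planted copy numbers; species structure
(replicate cohesion, shared-family clades, contamination screening)
survives the full pipeline. What it does not show: behaviour under
indels and structural variants (the error model is substitution-only by
design — the k-mer stage tolerates substitutions naturally and gains
nothing from indel realism), nested or tandem higher-order repeat
structure, GC-biased coverage, diploid heterozygosity, or library
artifacts other than exact adapter sequences. Real-data thresholds
(e.g. the 665 filter) are coverage-scale-dependent and should be chosen
relative to the sequencing depth at hand.

## Numerical and degenerate-input choices

- All internal coordinates are 0-based half-open; SAM input/output is
  1-based per the standard, converted at the boundary.
- Only primary alignments count in SAM ingestion (`M`/`=`/`X` consume
  depth; clips, insertions and deletions never do), matching the
  one-alignment-per-read quantification.
- `subsample_reads()` visits reads in seeded random order and keeps each
  read that still fits the base budget — exact for equal-length reads,
  maximal along the visiting order otherwise; reads are never split.
- The mapper extends seeds without gaps while the running identity of
  the whole matched region stays ≥ `min_identity`; per-read ties break
  by score, then reference order, then strand (+ first).
- Empty inputs degrade explicitly: empty FASTA parses to zero reads,
  k larger than every read yields an empty graph with a warning, an
  empty bicluster list yields an empty kChain table, a constant matrix
  refuses PCA, fewer than two samples refuse distances, a single taxon
  refuses neighbor joining.
- Matrix state (`raw` → `log` → `quantile_normalized`) is carried on the
  object and enforced, so a matrix cannot be normalized twice or
  ordinated on the raw scale by accident.

## Problem sizes

The bundled studies are desk-scale by design: the default validation
study is ~35 Mb of reads (345k reads across 12 samples), on which
discovery takes a few minutes and mapping a similar time on one CPU;
the unit-test studies are 10–50× smaller. The same code paths accept
arbitrarily larger read sets and externally produced SAM alignments; the
mapper and the search kernel scale linearly in reads and edges
respectively.

## Known limitations

- The greedy search is a documented stand-in for an unspecified
  published search; it is deterministic and locally optimal but carries
  no global guarantee (the tests bound it against exhaustive enumeration
  on small graphs and pin its results as regressions).
- Chains are dense-core fragments rather than full-length repeat
  consensi; lengths near `min_length` are common.
- The built-in mapper is gapless and substitution-oriented; indel-rich
  divergence requires an external local aligner and SAM import.
- Repeat classification (LTR/LINE/satellite superfamilies) is out of
  scope; the contamination classifier separates classes only as far as
  user-supplied reference sets do.
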