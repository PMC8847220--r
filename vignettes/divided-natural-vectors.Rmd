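---
title: "Divided natural vectors: model, pipeline and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Divided natural vectors: model, pipeline and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnv)
library(dplyr)
```

## The model

The natural vector (NV) maps a nucleotide sequence of length $n$ to a point
in $\mathbb{R}^{12}$ without any alignment. For each base $k \in \{A, C, G,
T\}$, with $n_k$ occurrences at 0-based offsets $s_k[1], \dots, s_k[n_k]$
from the first residue, the descriptor records

$$
n_k,\qquad
\mu_k = \frac{1}{n_k}\sum_i s_k[i],\qquad
D_2^k = \frac{\sum_i (s_k[i] - \mu_k)^2}{n_k\, n},
$$

serialized in the fixed order $(n_A, n_C, n_G, n_T, \mu_A, \dots, \mu_T,
D_2^A, \dots, D_2^T)$. The counts capture composition, the means capture
where each base sits along the sequence, and the normalized second central
moments capture how spread out it is. Higher central moments shrink rapidly
under this normalization, which is why the descriptor is truncated at the
second moment: 12 numbers per sequence. The map is position-sensitive —
`ACGT` and `TGCA` have identical composition but different vectors — and
similarity between sequences is simply Euclidean distance between their
vectors.

The divided natural vector (DNV) sharpens the local signal: the sequence is
cut into $k$ contiguous segments left-to-right, the 12-dimensional NV of
each segment is computed with offsets restarting at 0, and the segment
vectors are concatenated into $12k$ numbers. With $k = 1$ the DNV *is* the
NV; larger $k$ trades global smoothness for local resolution. The pipeline
default is $k = 4$, a setting at which segment-level information separates
closely related groups that the plain NV merges, while the vector stays
short enough that centroid averaging remains stable.

```{r}
nv_vec("AATT")
```

## From genotypes to population distances

Human cohorts enter the pipeline as a reference sequence plus phased VCF
genotypes. `reconstruct_cohort()` splices each sample's alleles into the
reference: for every non-reference call the reference window
`[POS, POS + nchar(REF) - 1]` is replaced by the called allele, applied in
descending position order so indels never invalidate upstream coordinates.
Structural records (symbolic ALTs such as `<CN0>`, or records with an
SVTYPE key) are excluded: their leftmost-position convention is ambiguous
in duplicated regions, so splicing them would inject noise rather than
signal.

Diploidy is handled by averaging. The two haplotype vectors of a chromosome
pair cannot be assigned to a parent from phased data alone, so they carry
equal weight: their coordinate-wise mean is the individual's *personal
vector*. Haploid input (a Y chromosome) passes through unchanged. The
unweighted mean of a population's personal vectors is its *centroid*, and
the distance between two populations is the Euclidean distance between
centroids. Per-chromosome distance matrices are summed entrywise into a
total matrix; summation versus averaging differs only by the constant
factor `1/22`, which every distance-based tree topology is invariant to.

Trees are built from the total matrix with BIONJ by default (NJ and UPGMA
are selectable), optionally rooted with an outgroup. The layered
nearest-neighbor *natural graph* offers a complementary view: layer 1 links
each population to its closest population, the connected components of
those links are groups, and layer 2 links each group to its nearest group.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `k` | 4 | DNV segment count; 1 recovers the plain NV |
| `tree_method` | `"bionj"` | distance tree builder (`nj`, `upgma` selectable) |
| `group_distance` | `"min"` | natural-graph group linkage (`mean` selectable) |
| `min_length`, `max_length` | 16,564–16,574 bp | mitogenome length window around the 16,569 bp reference |
| `max_n` | 1 | maximum literal `N` symbols per mitogenome |
| `min_group_size` | 2 | minimum surviving sequences per country |

Offsets are 0-based ("distance from the first residue"); a 1-based
convention would shift every $\mu_k$ by the same constant, which cancels in
all pairwise Euclidean distances, so the choice is cosmetic but is fixed
and documented here. The $D_2$ denominator uses the *total* length $n$,
including ambiguous symbols: reconstructed genomes contain `N` runs, and
dropping them would shift every downstream offset. Ambiguous symbols
therefore occupy positions and count toward $n$ but join no base class.
Bases absent from a segment get $\mu_k = D_2^k = 0$, a convention needed
for short segments. When $n = qk + r$, the first $r$ segments get length
$q + 1$; this balanced, left-to-right split is deterministic and
order-preserving.

## What the simulators emulate — and what they do not

`simulate_vcf_cohort()` emulates the variant-call route: a uniform-random
reference, phased diploid genotypes over spaced positions (so reference
spans never overlap), cohort-wide SNPs at frequency 0.5, population-private
SNPs at frequency 0.9 inside the owning population and 0 elsewhere,
optional small indels, and a fraction of symbolic structural records that
the reconstruction step must ignore. Private-allele frequencies of 0.9/0.0
make structure recoverable at small cohort sizes, which is what a
desk-scale test needs; real human populations differ mostly by allele
*frequency shifts*, not near-fixed private alleles, so this generator is a
stress test of the machinery, not a demographic model.

`simulate_population_sequences()` emulates hierarchical divergence
directly: a common ancestor is mutated along a known two-level tree
(superpopulation, then population, then individual), with substitution
counts proportional to branch lengths. The defaults — 2 superpopulations x
2 populations x 20 samples, 10 kb sequences, 2 independent chromosomes,
and 150/60/25 substitutions on the superpopulation/population/individual
branches — put the population-level signal well above the individual-level
noise after centroid averaging ($25/\sqrt{20} \approx 5.6$ effective noise
against a 60-substitution signal). Under these conditions the DNV(k=4) →
centroid → summed-matrix → BIONJ pipeline recovers the generating topology
in effectively every replicate (`structure_recovery()` measures this; the
test suite requires at least 95 of 100 seeded replicates). The generator is
substitution-only by default so that Hamming-distance oracles stay exact;
it has no recombination, drift dynamics, or realistic mutation spectra, so
a passing recovery test demonstrates that the machinery extracts planted
hierarchical signal — not that it would resolve any particular real
demography.

## Numerical and design choices

- **Tree builders are delegated** to the standard implementations (`ape`'s
  NJ/BIONJ, `phangorn`'s UPGMA) rather than re-derived; the package's
  contribution is the vector representation and the averaging pipeline
  around them. Matrix labels are sorted before building, which makes the
  output invariant to input row order and pins down tie resolution
  deterministically.
- **Negative NJ/BIONJ branch lengths** (possible on non-additive input) are
  clamped to zero with the deficit transferred to the sibling edge, the
  standard repair, and reported via a message.
- **BIONJ distance cap**: the underlying implementation rejects distances
  above 100, so matrices are rescaled below the cap and branch lengths
  scaled back — exact, because topology is invariant to positive scaling
  and branch lengths are linear in it.
- **Overlapping applied variants are a hard error**, not a silent
  precedence rule: overlap is exactly the ambiguity that motivates
  excluding structural variants, and silently picking a winner would hide
  it.
- **Missing genotype alleles (`.`) act as reference** — the conservative
  reading, since a missing call carries no evidence of departure.
- **Group-to-group distance** in the natural graph is single linkage by
  default (`mean` is selectable); a centroid option is not offered because
  the graph is built from a distance matrix alone, where member vectors
  are no longer available.
- Pipeline outputs serialize floating point at 12 significant digits so
  manifests and golden files are stable across platforms.

## Worked example

```{r}
ref <- read_fasta(system.file("extdata", "worked_example_ref.fa",
                              package = "dnv"))
recs <- read_vcf(system.file("extdata", "worked_example.vcf",
                             package = "dnv"))
cohort <- reconstruct_cohort(ref, recs)
cohort %>% mutate(length = nchar(seq)) %>% select(sample, hap, length)
```

Sample `HG00096` carries no variants, so both its haplotypes equal the
reference; `HG01992` and `HG02230` both carry the second alternative
(`CATTTT`) at position 55 and reconstruct identically, three bases longer
than the reference.

```{r}
vecs <- divided_natural_vector(cohort, k = 4)
vecs$sample <- cohort$sample
pers <- personal_vectors(vecs)
round(as.matrix(dist(as.matrix(pers[, -1]))), 2)
```

## Problem sizes and limitations

The shipped tests and the acceptance script run the full pipeline at
desk scale: 10 kb sequences, 80 samples, 100 replicates — sizes chosen so
the whole battery completes in minutes while still exercising every stage
end to end. The vector computation itself is linear in sequence length and
handles chromosome-scale input; only the simulation sizes are small.

Known limitations: no structural-variant or copy-number reconstruction (by
design), no phase-set handling, no higher central moments beyond $D_2$,
and no maximum-likelihood tree refinement — the trees are purely
distance-based, and on real data their branch lengths should be read as
vector-space distances, not substitution rates.
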