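---
title: "Alignment-free k-mer phylogenomics with kmerphylo"
author: "kmerphylo authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-free k-mer phylogenomics with kmerphylo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmerphylo)
```

## The problem and the approach

Conventional phylogenetics aligns a handful of marker genes and infers a
tree from the alignment. For taxa such as the dinoflagellate family
Symbiodiniaceae — coral symbionts with enormous, repeat-rich genomes,
subtle morphology and extensive sequence divergence — marker genes cover a
tiny fraction of the genome, and multiple sequence alignment breaks down
across whole assemblies because of rearrangement and non-homologous
content. Alignment-free methods sidestep both problems: every genome is
reduced to its multiset of length-`k` subsequences (k-mers), and the
similarity of two genomes is measured from their shared word content.

`kmerphylo` implements that pipeline end to end on annotated assemblies:

1. **Region curation** — from each genome plus its GFF3 annotation, six
   sequence sets are built: the whole assembly (WGS), the repeat-masked
   assembly (rmWGS), strand-specific coding sequences (CDS), introns,
   annotated repeats, and the encoded proteins. Comparing trees inferred
   from each region asks whether different parts of the genome carry
   different phylogenetic signal.
2. **k-mer profiling and choice of k** — words are counted per region;
   the proportions of *distinct* (each different word once) and *unique*
   (multiplicity exactly one) words guide the choice of `k`.
3. **D2S distances** — a centred, self-normalised count statistic turns
   shared word content into a bounded pairwise distance.
4. **Trees and networks** — neighbour joining on the distance matrix;
   species-aware normalised Robinson–Foulds comparison against a
   reference topology; and a thresholded genome-relatedness network.
5. **Core k-mers** — words present in every genome of a target group,
   located exactly on a reference genome and classified against
   annotated repeats and known/dark genes.
6. **Repeat enrichment** — per repeat type, differential abundance and
   Kimura-divergence conservation between lifestyle groups (symbiotic
   vs free-living), with a Shapiro → transform → Levene →
   Student/Welch decision tree and per-metric multiple-testing
   adjustment.

A first-class simulator generates annotated genome collections with
known truth so that every stage is testable without external data.

## The D2S statistic and its distance transform

For genomes $A$ and $B$ profiled at word length $k$, let $X_w$ and $Y_w$
be the observed counts of word $w$, and let $\tilde X_w = X_w - T_A
p_w^{(A)}$ be the count centred by its expectation under a zero-order
(independent-letter) background model estimated from that genome's own
region sequences ($T$ is the number of counted windows and $p_w$ the
product of letter probabilities). Then

$$\mathrm{D2S}(A,B) \;=\; \sum_{w}
  \frac{\tilde X_w\, \tilde Y_w}{\sqrt{\tilde X_w^2 + \tilde Y_w^2}},$$

summed over words observed in at least one of the two genomes, skipping
terms where both centred counts are exactly zero. Restricting the sum to
observed words is what makes `k = 23` tractable (the full $4^{23}$
lattice is unusable); unobserved words contribute almost nothing because
their expectations are minute, and the package's exhaustive small-`k`
oracle quantifies the agreement (tests assert equality to `1e-9` at
`k ≤ 3`).

The similarity is normalised geometrically and mapped to a distance

$$a = \frac{\mathrm{D2S}(A,B)}{\sqrt{\mathrm{D2S}(A,A)\,\mathrm{D2S}(B,B)}},
\qquad d = \min(10,\, \max(0,\, -\ln a)),$$

with $a \le 0$ mapped to $d = 10$. The clamp to $[0, 10]$ is a design
choice: it makes the network similarity $S = 10 - d$ span exactly the
threshold slider range $t \in [0, 10]$, so $t = 0$ yields a clique and
$t = 10$ isolates every genome whenever all pairwise distances are
positive. Identical genomes get $a = 1$, hence $d = 0$ exactly.

Two further conventions matter. Counting is strand-as-given by default,
because the CDS and intron sets are deliberately strand-specific;
canonical (reverse-complement-merged) counting is available as an option
for whole-genome work. And the background model is zero-order per genome
per region; the interface accepts any model that supplies letter
frequencies, but higher-order Markov models are out of scope.

## Word-length optimisation

`sweepK()` evaluates a grid of `k` values (the standard nucleotide grid
is 11–25 in steps of 2; repeat sets escalate to 11–51 because short
words are insufficiently distinct there; proteins use 3, 5, 7, 9) and
`selectOptimalK()` picks, among values whose mean proportion of distinct
words reaches a floor of 0.5, the `k` maximising the mean of the two
proportions, breaking ties toward the smaller `k`. When nothing passes
the floor the largest grid value is returned with a warning — the
behaviour a repeat-rich data set triggers. The two proportions are
defined as `D/T` (distinct over total windows) and `U/D` (unique over
distinct); the literature leaves the denominators implicit, so they are
fixed and documented here.

## Trees and their comparison

`neighborJoining()` is a from-scratch Saitou–Nei implementation kept
deliberately simple: exact on additive matrices (verified to `1e-9`
against path-length metrics of random trees), deterministic under
Q-criterion ties (the pair whose representative leaf labels sort first
is joined), and tolerant of negative branch lengths, which are retained
but reported, since downstream use is topology-only. `ape::nj` serves as
an independent cross-check in the test suite, never as the
implementation.

`normalizedRF()` divides the raw Robinson–Foulds distance (symmetric
difference of non-trivial bipartition sets) by its maximum $2(N-3)$ for
$N$ leaves, so 0 means identical topologies and 1 means no shared
bipartitions. Because the data include multiple isolates of the same
species whose branching order is biologically uninteresting, the
comparison first collapses every species that is monophyletic in *both*
trees to a single species-level leaf; species whose isolates are not
monophyletic keep their isolate leaves in both trees, preserving equal
leaf sets. Collapsing is applied before bipartition extraction, and
multifurcating reference trees are accepted (the normalisation still
uses $2(N-3)$).

## Core k-mers and feature classification

Core k-mers of a group are the words present (multiplicity ≥ 1) in every
member — presence-based, with no multiplicity threshold. The
pairwise-shared-then-overlap construction used with counter dump files
and the direct n-way intersection are provably the same set; both are
implemented and compared in tests. Per-node annotation of a tree with
the core count of each node's leaf set is anti-monotone toward the root,
which the tests check exhaustively.

Because k-mers are exact words, placement on the reference genome uses
exact two-strand substring search rather than approximate alignment —
an intentional strengthening over seed-based search tools, whose
near-exact hits would change the semantics. A word's feature flags are
the union over all of its hits; a hit counts against a feature when the
intervals intersect by at least one base and, under strand-specific
classification, the strands are compatible. Gene regions are the full
gene spans (introns included), split into *known* and *dark* genes by
the annotation's `gene_status` attribute (dark genes lack any
functional-database hit). Words hitting no annotated feature are
`unclassified`; words absent from the reference entirely are tallied
separately, since the two cases mean different things.

## Repeat enrichment between lifestyle groups

For each repeat type shared by every genome of both groups, two metrics
are tested: the proportional length of the type relative to the
assembly, and the mean Kimura divergence of its copies (percent, as
repeat annotators report it). The decision tree follows the standard
practice for such screens: Shapiro–Wilk on pooled within-group residuals
at α = 0.05 decides whether values are log-transformed (zeros replaced
by half the smallest positive value of the metric); median-centred
Levene decides between Student's and Welch's two-sided t-test; and
p-values are adjusted per metric across all tested types. The adjustment
method is Benjamini–Hochberg by default (appropriate for a many-type
screen) with Bonferroni exposed as an option, since the choice is a
genuine free parameter of such analyses. The 7-versus-2 design the
symbiotic/free-living comparison implies is explicitly supported:
normality is assessed on the pooled residuals (n ≥ 4), so the two-genome
group never faces Shapiro's n ≥ 3 requirement alone. Identical values
across both groups give p = 1; zero variance in both groups with
differing means is reported as skipped rather than given an infinite
test statistic.

Under null simulations (both groups drawn from the same normal
distribution) the full decision tree's raw-p type-I error stays within
the binomial sampling band of its nominal 5% over 1,000 types, and a
planted two-fold abundance shift at 20% within-type noise is detected
with well over 80% power after adjustment — both properties are asserted
in the test suite with fixed seeds.

## What the simulator emulates — and what it does not

`simulationConfig()` defaults describe an 18-genome panel shaped like a
Suessiales-style study system: 16 ingroup genomes in five clades — one
large clade of nine (seven symbiotic/opportunistic genomes across four
species, two of them multi-isolate, plus two free-living species), a
single-species clade, a three-species clade, a two-isolate species, and
another singleton — plus a two-isolate free-living outgroup attached by
a long stem. Key regimes:

* **Repeat content** spans 20–40% of assembly length in the ingroup and
  69–70% in the outgroup, realised as copies of 12 repeat families
  (consensus 300 bp) whose per-copy divergence follows a Kimura
  two-parameter process to per-family targets of 10–35% — the divergence
  range repeat annotators typically report. Three families are planted
  at two-fold copy number in the symbiotic group; one family is planted
  at half divergence there.
* **Genic fraction** stays under 10% (ten genes of three 99-bp exons and
  two 80-bp introns on a 45 kb backbone), with 30% of genes labelled
  dark.
* **Branch lengths** separate clades much more deeply (0.035–0.05
  substitutions/site) than species within a clade (0.002–0.005), with
  0.01 species terminals, 0.002 isolate terminals and a 0.06 outgroup
  stem — genus-level structure, under which the relatedness network
  exhibits a threshold at which the components are exactly the clades.
* **Planted conserved elements** (150 bp) are written verbatim into a
  reserved gene-free backbone slot of every genome and of the large
  clade only, giving the core-k-mer stage exact ground truth.

Substitution is Jukes–Cantor per branch with the exact per-site
transition probability, so branch composition is exact and the JC
formula inverts observed differences back to the simulated distance.
There are **no indels** (a deliberate choice: D2S is indel-tolerant and
indels would complicate lifting annotation coordinates), no codon-usage
or GC-skew structure, no tandem gene arrays, and no assembly artefacts
such as gaps or chimeric scaffolds. Repeats are appended after the
genic backbone rather than interleaved with genes, so region-extraction
truth is clean; spacers of 25–40 random bases keep adjacent copies from
merging into one annotation interval. Passing the end-to-end tests
therefore demonstrates correctness of the pipeline's logic under the
modelled regime, not robustness to real-assembly pathologies.

The default problem size — 45 kb backbones, hence roughly 60–150 kb
genomes — is chosen so a full 18-genome analysis at `k = 23` runs in
seconds while still leaving every statistical regime (word uniqueness,
repeat saturation, divergence gradients) where the method operates in
real data.

## Numerical choices and degenerate inputs

* Distance matrices must be symmetric with zero diagonal; asymmetry
  beyond `1e-8` is an error, not a repair.
* NJ ties are broken lexicographically by representative leaf label;
  branch lengths are written at 15 significant digits so write/read
  round trips preserve additivity to `1e-9`.
* Three identical genomes give an all-zero distance matrix; NJ and the
  network tolerate it (a star tree; a clique at every `t < 10`).
* Windows containing ambiguity codes are skipped in counting, excluded
  from background frequencies and from G+C content.
* A `k` exceeding every sequence length yields an empty profile with a
  warning; empty profiles are rejected by the D2S stage with a clear
  error.
* In `d2sToDistance`, a non-positive normalised similarity (possible
  for unrelated sequences once centred) maps to the maximal distance 10
  rather than propagating `NaN`.
* Repeat copy numbers are allocated by largest-remainder rounding so the
  realised repeat fraction tracks the configured target to within a
  single copy, with a minimum of one copy per family per genome so
  every family is annotated everywhere (the enrichment screen's
  shared-type rule depends on it).

## Design decisions that were genuinely open

* **Internal coordinates.** Annotation intervals live in `GRanges`
  (1-based, closed), the Bioconductor convention, delegating all
  interval arithmetic to `IRanges`; the BED-like k-mer hit export
  converts to 0-based half-open at the boundary.
* **Repeat deletion semantics.** Removing a repeat *splits* the
  scaffold into separate fragments rather than concatenating the
  flanks. Concatenation would manufacture chimeric junction k-mers that
  exist in no real molecule; splitting only loses the (at most `k - 1`)
  windows that straddled the repeat. The `< 1 kb` fragment filter is
  applied after splitting.
* **Multi-transcript genes.** The transcript with the longest total CDS
  represents its gene, so no coding k-mer is double-counted.
* **Distance transform.** The clamped `-ln` of the geometrically
  normalised D2S is this package's documented transform; it guarantees
  the `[0, 10]` range the network threshold semantics require, and is
  flagged for revision if a different original definition is ever
  adopted.
* **PHYLIP dialect.** Distance matrices serialise in square (full)
  format at 17 significant digits; the square form avoids the
  lower/upper-triangle ambiguity of the triangular dialects.
* **Isolate collapsing order.** Collapsing happens before bipartition
  extraction, and a species collapses only if monophyletic in both
  trees under comparison, which keeps the two leaf sets identical by
  construction.

## Limitations

Counting stores words as R character vectors: ideal for transparency
and the genome sizes the simulator produces, but not for multi-gigabase
assemblies, which would want 2-bit packing or disk-backed counting
(explicitly out of scope, as are probabilistic counters). The D2S
variance is not estimated, so no significance is attached to individual
distances. Kimura divergences are consumed from annotations (or the
simulator), never recomputed from alignments. The reference topology
for RF comparison is consumed as Newick; maximum-likelihood inference
of that reference is out of scope.

## A worked micro-example

```{r example, eval = FALSE}
ds <- simulateDataset(simulationConfig(seed = 1))
regions <- lapply(ds$genomes, extractWGS)
profiles <- lapply(regions, countKmers, k = 23)
dm <- distanceMatrix(profiles, regionSets = regions)
tree <- rootWithOutgroup(neighborJoining(dm), c("O1_i1", "O1_i2"))
normalizedRF(tree, ds$tree, ds$speciesMap)   # 0: topology recovered
net <- buildNetwork(dm, ds$metadata)
networkBreakpoints(net)                      # component structure vs t
```

The same flow, stage by stage with artefacts and a hash manifest, is
available as `runPipeline()`.
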