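---
title: "Comparative karyotype evolution with ancestral elements"
author: "karyevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative karyotype evolution with ancestral elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Moths and butterflies carry some of the most conserved chromosome-scale
synteny in animals: despite well over one hundred million years of
divergence, most extant chromosomes are recognizable shuffles of a small
set of ancestral chromosomes, here called *elements* (the lepidopteran
analogue of *Drosophila* Muller elements and nematode Nigon elements).
Because genome assemblies number chromosomes by size, orthologous
chromosomes get unrelated names in different species, and the history of
fusions and fissions is invisible in the naming. `karyevo` implements the
comparative machinery to fix that: it assigns extant chromosomes to
numbered ancestral elements by shared orthologous gene content, decomposes
each chromosome into ordered element segments, derives evolution-aware
names in an `f`/`d` grammar, places independent fusion and fission events
on a species tree, accounts for single-gene movements, losses and
duplications (with special attention to the Z sex chromosome), chains
collinear blocks to define synteny breakpoints, and tests
transposable-element (TE) enrichment at those breakpoints by permutation.

Every stage is testable against ground truth: the package ships a
karyotype-evolution simulator whose truth logs record each event with all
random choices resolved.

## Ancestral elements and chromosome assignment

An element set is either supplied (`read_elements()`) or inferred
(`infer_elements()`) from *backbone* species judged to retain the
ancestral karyotype. Inference builds a graph over backbone chromosomes
with an edge whenever two chromosomes of different species share at least
8 orthogroups; connected components become elements, orthogroups join by
majority vote of their backbone placements (ties are reported, never
guessed), and elements are numbered by descending gene count. One element
is flagged Z: ancestrally the system is female-Z0, so a single Z element
suffices, and in the default simulated conditions it sits at size rank 20.

A chromosome is *orthologous* to an element when they share at least 8
orthologous genes (`assign_chromosomes()`). The same constant governs
segment calling: `decompose()` labels each conserved gene with its
element and reports maximal same-element runs of at least
`min_segment_genes = 8` genes as segments. The two uses of the constant
are deliberately coupled (both configurable): groups of at least eight
co-relocating genes are rearrangements, anything smaller is a candidate
single-gene movement, which keeps the two definitions mutually exclusive.

Two decisions in `decompose()` deserve explanation because no published
rule fixes them:

* **Bridging.** Orphan genes (no element) never interrupt a run, and a
  foreign interruption shorter than `min_segment_genes` is bridged: its
  genes are set aside as movement candidates. Under the alternative
  (foreign interruptions always split runs), a single inserted gene would
  manufacture two spurious rearrangements.
* **Part splitting.** A contiguous run of one element can contain two
  different ancestral parts lying side by side (a fission followed by a
  fusion of non-adjacent parts). The run is split between two
  neighbouring genes when at least `min_segment_genes` orthogroups of the
  element lie strictly between them in ancestral order *and* are retained
  elsewhere in the same species. Requiring retention elsewhere makes the
  rule robust to plain gene loss (which also creates rank gaps) and to
  within-part inversions (whose displaced genes remain inside the run).

## The f/d nomenclature

Chromosome names follow the grammar `token ("f" token)*` with
`token := element ("d" part)?`: `1f2` is a fusion of whole elements 1 and
2; a fission of element 3 yields chromosomes `3d1` and `3d2` and is
denoted `3d-2` as an event; `5d1f6d1f6d3` is a fusion of the first part
of element 5 with the first and third parts of element 6. d-indices are
numbered along the ancestral chromosome (part 1 is ancestral-first), not
by extant position or size, and count only retained parts, so indices
stay dense when internal material was lost. When an element lacks an
internal gene order the parts fall back to descending size with a
warning. Because assembly orientation is arbitrary, a name and its
reversal are the same chromosome; `canonicalize_name()` keeps the
numerically smaller reading, and `parse_name()`/`format_name()` are exact
inverses (property-tested on random names). W chromosomes are never
renamed: they carry no ancestral orthologs to name them by.

## Placing events on the tree

Per species, each adjacent segment pair is a fusion junction and each
element split over several segments is a fission. Observations are
identified across species structurally, not by label: junctions match
when their element pairs agree and both flanking segments share
orthogroup content; fission part-partitions match when no shared
orthogroup pair is split differently. This withstands per-species gene
loss, which would defeat identification by part sizes or indices.

`place_events()` runs presence/absence small parsimony with equal gain
and loss costs (a fission really can dissolve an earlier fusion, so
irreversibility would be wrong). Every feature is absent from the
ancestral karyotype, but a feature carried by all tips may arise by a
single stem gain reported at the root. Among minimum-change solutions,
ties resolve toward gains over losses — scattered carriers count as
independent gains, matching how convergent fusions are counted as
independent events — and then toward deeper (older) gains. Multi-way
fusions count pairwise: a chromosome fusing three elements carries two
junctions, so each fusion gain increments exactly two element tallies in
`count_by_element()`. Species whose compositions exceed configurable
complexity bounds (default 5 segments on one chromosome or 60 in total)
are flagged unresolvable and excluded from event counting.

## Gene dynamics

A conserved gene whose element is absent from its host chromosome's
segments is a movement (`detect_movements()`) — exactly the complement of
segment calling. The movement is `copy`-type (retrotransposition
candidate) when a same-species orthogroup member remains on a chromosome
housing the source element (the parental gene), else `cut`-type.
Movements classify into A→A, A→Z, Z→A, A→W and Z→W; with one Z element,
Z→Z cannot arise. Per-orthogroup and per-gene-copy summaries are both
emitted because a two-copy orthogroup moved off-element is one event or
two depending on the convention.

Loss and duplication are counted per extant species from copy numbers
under the low-copy filter (`filter_low_copy()`, at most 2 copies per
species): zero copies is a loss, two copies a duplication. No tree
correction is applied — a loss shared by a clade counts once per
descendant. This matches the per-species definition the counts mirror
but biases totals upward for clade-shared losses; treat the totals as
per-species event sums, not as parsimony event counts. A gene is
lineage-specific when no other analyzed species has a homolog.

## Synteny blocks and breakpoints

Blocks are chained from orthogroup anchors: within a chromosome pair,
anchors sort by gene rank and a chain must be strictly monotone in both
rank spaces (orientation `+`/`-`) with consecutive anchors at most
`max_gap = 25` gene ranks apart. Chains grow greedily left to right from
the first unused anchor; the longer of the two orientations is committed
(ties prefer `+`) and the scan repeats. This greedy pass provably returns
the lexicographically smallest maximal chain from each start, so it is
exactly checkable against exhaustive chain enumeration — the test suite
asserts set equality on hundreds of random chromosome pairs. Chaining
runs in a canonical frame for the unordered chromosome pair, making the
block set symmetric under swapping the genomes. Tandem duplicate anchors
collapse to the first copy. Defaults: `min_block_genes = 5` for general
scans, 7 for W-network edges, mirroring common practice for collinearity
tools at these scales.

Breakpoint regions are the bp gaps between merged block extents on a
focal chromosome; chromosome ends are excluded (they are gaps by
construction, not rearrangement evidence) and non-positive gaps are
skipped with a log entry. Block extents, breakpoint regions and the two
end gaps tile the chromosome exactly — an invariant the suite asserts on
simulated genomes.

The W-chromosome network (`w_network()`) connects two W chromosomes
whenever some block holds at least 7 collinear genes; connected
components carry the common-origin argument, because transitive
connectivity does not require any single segment shared by all W
chromosomes.

## TE enrichment at breakpoints

`te_permutation_test()` draws, per simulation, one random region per
observed region with the same length: a chromosome is chosen with
probability proportional to its number of valid start positions and the
start is uniform. Placed regions may overlap each other and the observed
regions — the null constrains only the size distribution; a
rejection-sampling `no_overlap` mode and a `per_chromosome` mode are
flags. Each TE counts once per class when it overlaps any region by at
least 1 bp (half-open). The one-sided p-value is the fraction of
simulations with a class count at least the observed count (`k/n`, which
can be 0; a `(k+1)/(n+1)` pseudocount mode is labelled in the output).
Enrichment only: depletion is reported descriptively via the null
quantiles. Identical seeds give bit-identical results.

Two practical notes from the calibration study in the test suite. First,
seeds for data generation and for the permutation test must be unrelated
integers; seeding both stages with nearby values visibly correlates R's
generator streams and biases the null. Second, with overlap-permitted
placement the null is exactly calibrated only when the observed regions
are themselves disjoint and the region set is a small fraction of the
genome; at high region densities the random regions' mutual overlaps
shrink their distinct-TE catch relative to disjoint observed regions.
Real breakpoint regions are disjoint by construction and typically a few
percent of the genome, inside the calibrated regime; the suite's
calibration check uses 10 disjoint interior regions covering about 2% of
a 1.8 Mb genome, 400 permutations per replicate and 200 replicates, and
its power check plants a 5x TE density inside regions covering about 7%
of a 600 kb genome at 10,000 permutations.

## Statistics

`wilcoxon_rank_sum()` reports the Mann-Whitney U statistic; with both
groups at most 8 and no ties the p-value is exact (the full permutation
distribution; the suite checks it against brute-force enumeration of all
group assignments), otherwise midranks with the tie-corrected normal
approximation, without continuity correction, with the branch recorded in
the `method` tag. `pearson_cor_test()` computes r from the covariance
formula with the two-sided p from the t transform on n-2 degrees of
freedom. `z_autosome_tests()` pools chromosomes across species for the
Z-versus-autosome contrasts (a per-species aggregation is a one-liner on
the feature table); no multiple-testing correction is applied, matching
how such panels are conventionally reported.

## The simulator and what passing tests mean

`simulate_karyotypes()` evolves an ancestral genome of `n_elements = 31`
elements along a tree (default: a 16-taxon coalescent tree). Element
gene counts are sampled uniformly on 14-259 — the observed span of
ancestral chromosome sizes in deeply conserved lepidopteran karyotypes —
giving roughly 4,000 ancestral genes; the Z element sits at size rank
20. Per branch, event counts are Poisson: fusions (random end-to-end
orientation, exercising name canonicalization), fissions (cut uniform
among inter-gene points, constrained so every split element keeps at
least 8 genes per side — smaller parts would be undetectable by
definition), movements (uniform destination; source copy retained with
probability `copy_fraction = 0.5`), losses and duplications (single-copy
genes only, keeping copy numbers within the low-copy filter), and
lineage-specific births (optionally Z-biased via `z_ls_multiplier` for
the sex-chromosome power scenario). Default rates are 0.3 fusions, 0.1
fissions, 0.5 movements, 1 loss, 0.5 duplications and 1 birth per
branch — a regime of order a few rearrangements per lineage, consistent
with karyotypes that mostly retain the ancestral state. Tip coordinates
are laid out at constant 2 kb gene spacing; TE tracks are uniform per
class with an optional density multiplier within a window around
historical fusion junctions.

Truth logs record every event with its resolved choices; `replay_truth()`
re-applies them from the ancestral genome and must reproduce each tip
gene table exactly (asserted across seeds). Three bookkeeping conventions
matter when scoring recovery:

* A movement whose destination already houses the gene's element is
  undetectable under the movement definition (the gene is consistent
  with its host); truth flags per-event detectability at the tips and
  recovery is scored against detectable events.
* A copy-type movement leaves two copies, indistinguishable from an
  in-place duplication by the two-copy counting rule, so truth
  duplication totals include copy-movements.
* A W chromosome is carried from the root when `with_w = TRUE` so that
  movements and births can target it, a simplification of the secondary
  W acquisition seen in real systems; it never fuses or fissions in v1.

The simulator emulates rearrangement and gene-content dynamics, not
sequence: no inversions (the element-level analyses are inversion-blind),
no intra-element order scrambling beyond fission/fusion, constant gene
spacing, and GC values drawn independently of content. Passing recovery
tests therefore demonstrates that the inference machinery is correct
under the stated event model — not that real genomes satisfy that model.
Assembly errors, missing orthologs, annotation noise and deep
orthogroup-inference artifacts are all outside what these tests can show.

## Problem sizes and numerical choices

The shipped test suite runs 20 replicate 16-taxon simulations at the
default conditions for event and gene-dynamics recovery, 200 random
chromosome pairs (up to 30 genes) for the chaining oracle, 200 replicate
datasets for enrichment calibration and 20 runs of 10,000 permutations
for power, and 20 seeds for replay identity — sizes chosen so a desk
machine reproduces everything in minutes while the statistics remain
discriminating. Determinism is enforced throughout: mandatory seeds on
all stochastic entry points, a stated tie-break (start, end, gene id) in
gene ranking, lexicographic tie-breaks in chain selection and parsimony,
and exact set arithmetic (no floating-point coordinates are compared for
equality anywhere).

Known limitations: no intra-chromosomal nomenclature, no ancestral
gene-order reconstruction (intra-element order is consumed, not
inferred), loss/duplication totals are per-species sums without
phylogenetic deduplication, and the enrichment null is uniform — not
GC- or gap-aware.
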