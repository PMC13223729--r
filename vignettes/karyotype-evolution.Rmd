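---
title: "Painting chromosomes and reconstructing the Cypriniformes ancestral karyotype"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Painting chromosomes and reconstructing the Cypriniformes ancestral karyotype}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyopaint)
```

## The problem

Cypriniform fishes (zebrafish, carps, minnows, cavefish) are a model system
for chromosome evolution: the family spans diploids with 24 or 25 chromosome
pairs and tetraploids with 48 or 50, the latter produced by lineage-specific
whole-genome duplications (WGD). Comparative genomics reconstructs how these
karyotypes arose from the teleost ancestor: 13 proto-chromosomes
(conventionally lettered `a`-`m`) that, after the teleost-specific third
round of WGD and 8 major rearrangements, left a 24-chromosome ancestral
complement.

`karyopaint` implements the full analytical chain used in such studies:

1. **Painting** — each gene on a modern chromosome is assigned the identity
   of the ancestral chromosome carrying its best protein hit (BLASTP
   tabular input, E-value threshold `1e-10`, best hit by bit score).
2. **Filtering** — on each chromosome, colors represented by fewer than 20
   genes are erased; sparse, noisy assignments never form "regions".
3. **Segmentation** — consecutive same-color genes become color blocks;
   uncolored genes are transparent.
4. **WGD collapsing** — for tetraploid lineages, homoeologous chromosomes
   are paired by cosine similarity of their color compositions and merged
   into ploidy units, so events are counted once per ancestral chromosome.
5. **Event classification** — fusions, fissions, translocations and complex
   rearrangements are read off the per-unit color compositions.
6. **Dollo placement** — event signatures shared by all members of a clade
   and absent outside it are assigned to the clade's stem branch.
7. **Reconstruction** — the ancestral karyotype is the set of unit
   compositions whose distribution across species implies presence at the
   ingroup root.

A built-in genome-evolution simulator generates painted gene tables under a
declared event history, providing ground truth for end-to-end validation.
Assembly-level helpers cover the two common QC computations of such genome
papers: k-mer genome-size estimation and telomere detection.

## Painting identities versus display colors

Painting is performed at the resolution of *ancestral chromosome ids* (the
24 teleost chromosomes `T01`-`T24`), not the 13 display letters. Two
post-duplication copies of proto-chromosome `a` are different ancestral
chromosomes; distinguishing them is what allows a 25-chromosome cypriniform
ancestor to be resolved. The letters `a`-`m` are retained as display colors
for rendering (`render_karyotype_svg()` maps each ancestral chromosome to
its dominant letter).

## The classification rules

The thresholds live in `event_params()`; all fractions refer to colored
genes only.

* A color is **present** on a unit with `>= min_genes` genes (default 20,
  the same constant as the painting filter).
* **Fusion**: a unit carries two present colors, each holding at least
  `major_frac` (default 0.25) of the unit's genes. The 0.25 default
  separates whole-arm fusion partners from segmental translocations.
* **Fission**: a color has two or more carriers, each holding at least
  `split_frac` (default 0.30) of the color's genes. The 0.30 default
  suppresses fission calls driven by translocated slivers or noise.
* **Translocation**: a present color below `major_frac` on a unit whose
  majority color differs, while at least `home_frac` (default 0.5) of the
  color's genes remain on its home unit.
* **Complex**: a unit with three or more major colors, or a color
  satisfying the fusion and the fission signature simultaneously.
  Overlapping complex calls (sharing a unit or color) merge into one
  record, absorbing the primitive calls they subsume.

Ties are broken deterministically: the majority color of a unit is the
first column at the maximum; homoeolog pairing resolves equal similarities
in lexicographic chromosome order.

Events are compared across species by `(type, sorted color set)` signature
only. Painting is gene-level, so breakpoint coordinates are not matched;
two species sharing `fusion:T16,T17` are taken to share the event. WGD
itself is never emitted as an event record — it is declared per branch and
consumed as the ploidy expectation.

## Dollo parsimony, placement and reconstruction

Chromosome fusions and fissions are essentially never reversed exactly, so
placement uses Dollo (single-origin, losses allowed) rather than Fitch
parsimony: a signature present in every sampled descendant of a node and
absent elsewhere is assigned to the node's stem branch; a signature carried
by a non-clade species set is assigned to each maximal clade in which it is
universal.

Reconstruction applies the same logic to chromosomes instead of events. A
candidate ancestral chromosome is a distinct major-color composition of the
collapsed units. A candidate copy enters the ancestor when its carriers
either span at least two child clades of the ingroup root (so a single
origin forces presence at the root) or reach the `quorum` fraction
(default 0.75) of ingroup species. The span rule matters in practice: an
event on the stem of a two-species subclade (for example a fusion shared by
two sibling domesticated variants) removes its operand chromosomes from two
species at once, and a raw 0.75 quorum over seven ingroup species would
then wrongly drop those chromosomes from the ancestor even though every
other lineage — on both sides of the root — still carries them. Copy
numbers are per-signature: a fissioned ancestral chromosome contributes two
units with the same major-color set, and a second ancestral copy is
admitted only if the species carrying two such units themselves satisfy the
support rule.

Whether a published 25-chromosome cypriniform ancestor should be read as a
consensus over all sampled cypriniforms or as anchored on the n=25 diploids
is not decidable from event counts alone; the `quorum` parameter lets users
test both readings (1.0 demands unanimity; 0.75 with the span rule is the
default).

## The simulator and the packaged scenario

`simulate_karyotypes()` evolves an `ancestor_def` along a tree: on each
branch a declared WGD doubles every chromosome (homoeologs get `_A`/`_B`
suffixes), then the branch's events apply in order. Events on post-WGD
branches may name pre-WGD chromosomes; they are then applied mirrored to
every homoeologous copy and logged once — matching how comparative studies
count one fusion in a tetraploid, not two. Gene loss and mis-coloring are
applied per gene, independently, at tip emission only; they stand in for
annotation incompleteness and best-hit assignment error, the two dominant
error modes of real painting. One seeded generator drives everything and
the previous RNG state is restored, so fixed seeds give byte-identical
output without touching global state.

`cypriniformes_scenario()` packages the canonical study design (also shipped as
`inst/extdata/cypriniformes_scenario.yaml`): the 24-chromosome teleost
ancestor, an 8-taxon tree (7 cypriniforms + medaka outgroup), 9 stem
events (2 fusions, 1 fission with a 60/40 split, 4 translocations moving
~15% slivers, 2 complex events each composed of two fissions whose distal
parts fuse), a terminal grass-carp fusion, a WGD on the carp lineage with a
small fusion on the koi stem, and a WGD plus 2 fusions and 2 fissions on
the *Sinocyclocheilus* branch. Published event lists name the types but not
the operand chromosomes; the operands here are a concrete, recorded choice
that reproduces the published type counts.

Default marker density is 400 genes per color segment (~10,400 genes per
diploid genome), the order of real cyprinid gene counts per chromosome and
comfortably above the 20-gene filter, so threshold behavior is far from
boundary effects. The event geometry is chosen inside the classifier's
detection envelope: translocated slivers are `max(21, 0.15 x density)`
genes — above `min_genes` yet under 25% of the acceptor — and fission
splits are 60/40. Below a density of roughly 120 genes per segment the
default thresholds are no longer guaranteed to detect every event type;
scale `event_params()` accordingly for sparser data.

Simulated chromosome counts follow the event algebra exactly; they can
disagree with published terminal counts where a published event list is
itself not arithmetically closed (e.g. a tetraploid reported with both a
WGD-doubled complement and additional net-negative fusions). Event
multisets, not terminal counts, are the validated surface.

What the simulator does *not* emulate: gene-order divergence between
homoeologs, inversions (painting is orientation-blind), segmental
duplications, spatially clustered annotation error, and breakpoint reuse.
Passing round-trip tests therefore demonstrates the internal consistency
of painting, classification and placement — not robustness to every
real-data pathology.

## Assembly-level computations

`estimate_genome_size()` implements *size = total k-mers / depth
expectation*, with the expectation taken as the modal depth after the first
local minimum of the histogram (error k-mers occupy the low-depth slope;
they are excluded from the mode search but included in the total, per the
formula — `exclude_error = TRUE` drops them, `mean_mode = TRUE` replaces
the mode by the weighted mean). A monotonically non-increasing histogram
has no separable coverage peak and is rejected.

`find_telomeres()` counts non-overlapping copies of the vertebrate telomere
motif `TTAGGG` (forward at left ends, reverse-complement at right ends)
within a 10 kb terminal window, calling a hit at 50 or more copies. The
published analyses this mirrors used external software whose motif and
thresholds are not stated, so counts on real assemblies are a
reproduction-with-caveat: the defaults are exposed (`motif`, `window_bp`,
`min_copies`) and may need tuning to match a specific tool.

## Numerical and design choices

* Internal coordinates are 0-based half-open; GFF3 converts on read, BED is
  native. Gene ids, not sequences, are the join keys everywhere.
* The painting filter is strict `< 20` removal: exactly 20 genes survive.
* Smoothing (`segment_blocks(smoothing_window = w)`) is off by default
  (`w = 1`) because the count filter alone matches the published method;
  `w = 5` is recommended when mis-coloring noise is expected.
* Homoeolog pairing is greedy on cosine similarity (deterministic,
  auditable, exact for the clean doublings it faces at n <= 25); pairs
  below similarity 0.2 stay singletons.
* Only the species-to-ancestor best-hit direction is used, matching the
  published protocol; reciprocal-best-hit filtering can be layered on by
  intersecting two `resolve_best_hits()` maps.
* Validation problem sizes: the packaged scenario runs ~10^4-10^5 genes per
  species in seconds; the seeded recovery suite uses 200 random scenarios
  at 18 chromosomes x 120 genes. These sizes were chosen so the full suite
  exercises every rule at realistic densities while staying quick to run.

## Worked example

```{r example, eval = FALSE}
fs <- cypriniformes_scenario(seed = 1)
res <- run_scenario_pipeline(fs$ancestor, fs$scenario)

res$summary[res$summary$total > 0, ]
#>              branch fusion fission translocation complex total
#> 3        grass_carp      1       0             0       0     1
#> 7  sinocyclocheilus      2       2             0       0     4
#> 9     cypriniformes      2       1             4       2     9
#> 14              koi      1       0             0       0     1

length(res$reconstruction$chromosomes)
#> [1] 25
```

The stem of Cypriniformes carries 9 events (2 fusions, 1 fission, 4
translocations, 2 complex), grass carp one private fusion, the koi stem one
small post-WGD fusion, and *Sinocyclocheilus* two fusions and two fissions
— and the reconstruction returns a 25-chromosome cypriniform ancestor.

## Known limitations

* Breakpoint-resolution scenarios (DCJ/GRIMM-style sorting) and inversion
  detection are out of scope; painting resolution is the gene, and
  orientation is ignored.
* Ancestral gene *order* within chromosomes is not reconstructed, only
  karyotype composition.
* The classifier assumes filtered input; it warns and auto-filters
  otherwise.
* Telomere and genome-size results on real assemblies depend on upstream
  k-mer counting and assembly quality, which are inputs here, not outputs.
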