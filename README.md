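# karyopaint

In-silico chromosome painting and ancestral karyotype reconstruction for
fishes with lineage-specific whole-genome duplications (WGD) — built for
the comparative genomics of Cypriniformes (zebrafish, carps, minnows,
cavefish), whose karyotypes descend from the 13 teleost proto-chromosomes
`a`–`m` (24 chromosomes after the teleost-specific duplication and 8
rearrangements).

## What it does

Given per-species gene coordinates (BED/GFF3) and gene-to-ancestral-protein
best hits (BLAST outfmt 6), or direct color assignments:

1. **paint** — each gene takes the identity of the ancestral chromosome
   carrying its best hit (E ≤ 1e-10, best bit score);
2. **filter** — colors with fewer than 20 genes on a chromosome are erased;
3. **segment** — consecutive same-color genes become color blocks
   (uncolored genes are transparent; optional majority smoothing);
4. **collapse** — tetraploid homoeologs are paired by cosine similarity of
   color composition and merged into ploidy units;
5. **classify** — fusions, fissions, translocations and complex
   rearrangements are read off unit compositions:
   a *fusion* is two co-major colors on one unit (each ≥ 25% of its genes),
   a *fission* is one color split over ≥ 2 units (each holding ≥ 30% of
   it), a *translocation* is a minor sliver away from a color's home
   (≥ 50% staying home), and *complex* is ≥ 3 majors on one unit or a
   color with both fusion and fission signatures;
6. **place** — event signatures `(type, color set)` are placed on a Newick
   phylogeny by Dollo parsimony (clade-universal ⇒ stem branch);
7. **reconstruct** — the ancestral karyotype is the set of unit
   compositions whose species distribution implies presence at the ingroup
   root (Dollo span of the root's child clades, or a quorum of species).

A genome-evolution **simulator** emulates all of this end to end: it
evolves a colored ancestor along a tree under declared fusions, fissions,
translocations, complex composites, WGDs, gene loss and mis-coloring, and
returns the ground-truth event log. Assembly QC utilities implement k-mer
genome-size estimation (`size = total k-mers / modal coverage depth`) and
telomere detection (`TTAGGG` arrays in 10 kb terminal windows, ≥ 50
copies).

## Worked example

The packaged scenario reproduces the canonical Cypriniformes design: a
24-chromosome teleost ancestor, 7 cypriniforms plus medaka, two
independent WGDs (carp lineage, *Sinocyclocheilus*).

```r
library(karyopaint)
fs  <- cypriniformes_scenario(seed = 1)                     # ancestor + scenario
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

Reading: the Cypriniformes stem carries 9 rearrangements — 2 fusions,
1 fission, 4 translocations, 2 complex — turning 24 teleost chromosomes
into the 25-chromosome cypriniform ancestor; grass carp adds one private
fusion (n = 24), the koi stem one small post-WGD fusion, and
*Sinocyclocheilus* two fusions plus two fissions after its WGD. The
reconstruction recovers all 25 ancestral chromosomes from the simulated
tips alone.

A shell interface wraps the same functions:

```sh
exec/karyopaint run-all \
  --scenario inst/extdata/cypriniformes_scenario.yaml \
  --seed 1 --out-dir out/
# out/: per-species gene tables (TSV + BED), events.json,
#       event_summary.tsv, reconstructed_ancestor.yaml, SVG ideograms,
#       manifest.json
```

## Notes

- Painting identity is the ancestral *chromosome id* (`T01`–`T24`), not
  the display letter; the letters color the SVG output.
- Telomere counts on real assemblies depend on the motif/threshold choices
  of the external tools used by genome papers; the defaults here are
  explicit and adjustable (`motif`, `window_bp`, `min_copies`).
- See `vignettes/karyotype-evolution.Rmd` for the model, thresholds,
  design decisions and limitations.
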