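---
title: "Methods: windowed population genomics of homozygous-diploid yeasts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed population genomics of homozygous-diploid yeasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eubpop)
```

## Scope and model assumptions

`eubpop` analyzes panels of wild yeast strains that live predominantly as
homozygous diploids (a consequence of haploselfing and intratetrad mating).
That biology licenses the package's central simplification: after
heterozygous calls are masked, **each strain contributes one haplotype**,
and every statistic (π, θ~W~, Tajima's D, F~ST~, LD, divergence) is
computed on a 0/1 haplotype matrix. Strains that are genuinely
heterozygous are handled upstream: `het_summary()` quantifies and
classifies heterozygosity, `apply_masks(drop_het = TRUE)` removes HET
calls per strain (keeping other strains' information at the site), and
`phase_split()` turns a *phased* heterozygous strain into two
pseudo-haplotypes so each phase can be assigned to a population. No
internal phasing is attempted — phasing is an input contract.

Coordinates are 0-based half-open everywhere internally (the BED
convention); VCF positions are converted on read. Multi-allelic records
are dropped, never decomposed, because all downstream statistics assume a
biallelic matrix.

## Windowed statistics

All windowed quantities use non-overlapping 50-kbp windows tiling each
contig (`make_windows()`; only the terminal window of a contig may be
short). Per-site normalization always divides by the window's **callable
bp** — window length minus the union of mask intervals — not by the SNP
count, so diversity is comparable across windows with different masking.
Windows with callable bp below `min_callable_fraction` (default 0.5) of
the window length are reported as no-data rather than as zeros.

- π uses the unbiased per-site form 2p̂(1−p̂)·n/(n−1) with n the called
  haplotypes at the site; on complete data this equals the average of all
  pairwise divergences exactly (a test asserts the identity to 1e-12).
- Tajima's D follows the standard 1989 constants; it is reported only
  when the window has at least `S_min = 3` segregating sites (near-invariant
  windows give numerically meaningless D) and at least 4 called
  haplotypes. With missing data, the haplotype count entering the
  constants is the median called count over segregating sites.
- F~ST~ is **Hudson's estimator**, 1 − π~within~/π~between~ with the
  unweighted mean of the two panels' diversities (symmetric and
  determinate under unequal sample sizes). Multi-window aggregation is a
  ratio of summed components, never a mean of window ratios. Small-sample
  values can be slightly negative; they are reported as-is. F~ST~
  estimators differ slightly in absolute value, so comparisons with
  values computed by other tools' defaults should expect small shifts.
- LD decay computes r² on jointly called haplotypes for within-contig
  pairs up to 25 kbp apart with both MAFs ≥ 0.05, bins by distance
  (500 bp), and smooths the bin means with a monotone non-increasing
  isotonic fit; the half-decay distance is the first bin midpoint whose
  smoothed mean falls to half of the first bin's. Because strains are
  haploidized, no EM phasing enters LD.

## Ancestry painting

For a query genome and two parental panels A and B, each window gets
d~A~ and d~B~ — the minimum pairwise divergence from the query to any
panel member — and the statistic r = log₂((d~A~+ε)/(d~B~+ε)).

- **Sign convention.** r < 0 means closer to panel A (PA), r > 0 closer
  to panel B (PB). The statistic is sometimes presented in the opposite
  orientation (log₂ of d~B~ over d~A~); the implementation fixes
  r = log₂(d~A~/d~B~) so that negative values always indicate PA, and
  states the convention in every output.
- **ε pseudocount.** ε = 1/callable-bp, one SNP-equivalent: a window in
  which the query is identical to a panel member (d = 0, common for
  clones) never takes log of zero, and the magnitude of r still reflects
  the divergence contrast. Clamping was rejected because it hides
  magnitude.
- **Informative sites.** A window is classified only if the nearest A
  member and nearest B member differ at ≥ `min_sites = 5` jointly called
  sites; fewer informative sites make the window's sign essentially
  noise. Windows failing callable or informative thresholds are NODATA;
  r exactly 0 is AMBIG. Ancestry fractions are taken over classified
  windows only, so PA + PB fractions sum to 1 and match two-way
  percentage reporting.
- Strain labels derive from the minor-ancestry fraction m: pure
  (m < 0.02), introgressed (0.02 ≤ m ≤ 0.12 — the band in which small
  cross-population tracts are detectable), admixed (m > 0.12). Bounds are
  configurable.
- `profile_identity()` declares strains clonal when their window-class
  vectors are identical (class-level identity; finer r-level identity
  would be broken by private SNPs that shift magnitudes without changing
  signs) and then counts the SNPs at which any two group members differ.

## Introgression scanning from dual-reference depth

Read depth against the recipient and a candidate donor reference is
normalized per strain by the **strain's sequencing depth**, estimated as
the larger of the two per-reference genome-wide median depths. A
per-reference median (the naive choice) fails for the donor reference:
when only a ~150-kbp tract maps, that reference's median is pure
cross-mapping leakage, and normalizing by it would inflate every leakage
window to ~1. With the sequencing-depth denominator, the reference the
strain derives from has median normalized depth ≈ 1 and leakage windows
sit near the leakage rate. A window is donor-present when donor
normalized depth ≥ θ_hi = 0.5 **and** recipient normalized depth
≤ θ_lo = 0.25; adjacent donor-present windows merge into tracts with no
gap bridging. The thresholds are config defaults chosen to be robust
under Poisson depth ~30 with modest cross-mapping; coverage evidence of
this kind is often judged visually, so the thresholded rule is an
explicit, reproducible operationalization. Tracts are window-resolved; per-base breakpoints are
out of scope, matching the resolution of the evidence. Homologous-contig
alignment between the references is an input, not computed.

## Biogeography

Distances are haversine on a sphere of radius 6371.0088 km; subpopulation
"range" is the maximum pairwise distance and "area" the spherical area of
the coordinate convex hull (degenerate hulls give 0). The Mantel test
correlates geographic distance with log₁₀-transformed genome-wide
pairwise divergence; the pseudocount is 0.1 × the smallest positive
observed divergence because clonal pairs can be at d = 0. The test is
one-sided (isolation **by** distance is a directional hypothesis), with
p = (1 + #{permuted r ≥ observed})/(B + 1) under whole-row/column
permutations, B = 10,000 by default and seeded for reproducibility. The
latitude split defaults to −43°, the Patagonian glacial boundary.

## The synthetic-data generator

The generator is first-class, tested code: its truth records are the
reference against which every estimator is scored.

- **Nested Balding–Nichols drift** replaces coalescent simulation:
  ancestral frequency per site, population frequency
  Beta(p(1−F)/F, (1−p)(1−F)/F) with F~pop~ = 0.45, then subpopulation
  frequency likewise with F~sub~ = 0.15. This gives closed-form control
  of differentiation targets at trivial runtime with no external
  simulator. Defaults encode the reference conditions: a 12-Mbp genome in
  240 windows of 50 kbp, 24,000 SNP sites, two populations (PA, PB) split
  into six subpopulations (PA-1, PA-2, PB-1, PB-2, PB-3, Holarctic), six
  homozygous diploid strains per subpopulation.
- The default ancestral-frequency spectrum is uniform on (0.05, 0.95).
  That spectrum yields a uniform site-frequency spectrum, which biases
  Tajima's D positive (≈ +0.8 at n = 10); a `spectrum = "neutral"` option
  draws frequencies with density ∝ 1/p, reproducing the ~1/k neutral SFS,
  and is what the D-calibration test uses (mean D ≈ 0 there).
- **Admixture scenarios** operate at window resolution — ancestry is
  constant within a 50-kbp window, matching the resolution of the
  painting statistic; sub-window breakpoints are below its resolution
  anyway. The NoAm scenario clones one PA-2/PB-1 mosaic 21 times across
  four geographic sites and adds 571 site-private SNPs (fixed within a
  site, so the variants also delineate geography); the SoAm scenario
  draws PA windows with probability 0.45 with the PA donor an equal
  PA-1/PA-2 mix and PB-1 elsewhere; the type-strain scenario replaces a
  0.04 window fraction of a PB-1 background with PA-1.
- **Dual-depth scenario**: Poisson(30) where the strain's genome carries
  a reference's material, Poisson(0.05 × 30) elsewhere; one 150-kbp donor
  tract at [300000, 450000) on a 2-Mbp contig.
- **Geography scenario**: sites on a 400-km north–south transect; all
  strains are clones of one founder plus (i) *distance-ordered* derived
  alleles — a site at transect distance d carries the first
  round(0.5 × d) loci of a shared ladder, so pairwise divergence grows
  with |d_i − d_j|, which is what isolation by distance means (strictly
  site-private alleles would instead make divergence grow with
  d_i + d_j) — and (ii) per-strain Poisson(30) private noise loci so the
  null (slope 0) has non-degenerate, exchangeable distances. This
  emulates a recently dispersed clonal lineage accumulating
  location-specific variants.
- All randomness flows from one master seed through named substreams
  (one per scenario block), so adding a scenario never perturbs another
  and all outputs are bit-identical across runs.

What the generator does **not** emulate: recombination maps and genuine
linkage (sites are exchangeable, so LD structure beyond duplicated sites
is absent), selection, indels, sequencing errors, reference bias, and
realistic SFS shape under the default spectrum. Passing tests therefore
demonstrate estimator correctness and calibration under controlled
structure — not robustness to every artifact of real short-read data.

## Host-association testing

Contingency tables keep subpopulations with ≥ 3 isolates and hosts with
≥ 5 isolates, after excluding strains with unknown collection
information; strains isolated from a fungus growing on a tree carry both
hosts and enter both the tree-level and mushroom-level analyses. Each
(subpopulation, host) cell is collapsed one-vs-rest to a 2×2 and tested
with the two-sided Fisher's exact test; Bonferroni multiplies by the
number of cells tested within the axis (per-level families). An omnibus
R×C exact test is deliberately not implemented because results are
reported per pair. The descriptive percentage reported first is the cell
count over the *subpopulation's* total (the reading that describes a
subpopulation's host preference); the share of the host's isolates is
also emitted since the other reading is occasionally wanted.

## Numerical and degenerate-input conventions

- Zero callable bp yields NA (no-data), never 0, for divergence and π.
- A strain with zero variant calls has het fraction 0 (class low) with a
  warning.
- Hudson F~ST~ with zero between-panel diversity is NA (undefined), not 0.
- Constant distance matrices make the Mantel r undefined (NA).
- An all-zero 2×2 table has Fisher p = 1.
- Empty mask files produce empty mask sets; masks merge within label;
  interval ends are validated against contig lengths when known.
- VCFs without contig header lines get lengths inferred from the maximum
  position rounded up to a window multiple, with a warning.

## Problem sizes in the test suite

The suite scales simulations to what the statistics need, as the
package's own choice of experiment size: full 240-window genomes for the
headline recovery checks (ancestry fractions, clonal grouping, tract
length over 20 seeds), 60-window genomes across 50 seeds for the
fraction-unbiasedness property, 1,000 replicates at 199 permutations for
the Mantel type-I calibration, and exhaustive enumeration up to n = 60
for Fisher's exact test.

## Known limitations

- Painting has no HMM smoothing; isolated misclassified windows are not
  corrected by their neighbors.
- Tract detection assumes the two references' window grids align by
  index on homologous contigs.
- The absolute 20,000-call high-heterozygosity flag is calibrated to a
  ~12-Mbp genome at typical wild-yeast SNP density; it must be
  reconfigured for toy genomes.
- Spherical convex-hull areas are adequate for relative comparisons, not
  for survey-grade geography.
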