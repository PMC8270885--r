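---
title: "Methods: stress-granule quantification and founder-haplotype dating"
author: "sgfound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stress-granule quantification and founder-haplotype dating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgfound)
```

# Scope

`sgfound` implements the quantitative arms of a study design in which an
epitope-tagged, aggregation-prone muscle protein is characterised by
(i) automated stress-granule (SG) image analysis in transfected cells,
(ii) repeated-measures statistics across independent experiments,
(iii) founder-haplotype detection and dating in hemizygous male carriers,
(iv) rare-variant prioritization, and (v) solubility fractionation
statistics.  Every stage consumes either real tabular/imaging inputs or
output of the package's synthetic generators, which plant a known ground
truth so each algorithm can be validated end to end.

# Image analysis

## Cell model and segmentation

Cells are detected from the nuclei channel by Otsu thresholding,
connected-component labelling, and an area filter
(`nucleus_min_area_px`, default 30 px, which removes debris at the
16-bit scales the generator emulates).  Cytoplasm is defined
operationally, in the CellProfiler tradition, as every non-nuclear pixel
within `cytoplasm_radius_px` (default 30 px at 20x magnification) of a
nucleus, each pixel assigned to its nearest nucleus by distance
transform.  Cells touching the image border are discarded entirely:
their truncated cytoplasm would bias per-cell granule counts downward.

Transfected (tag-positive) cells are separated from untransfected
neighbours on mean cytoplasmic V5 intensity, either by a global 1-D Otsu
split (`otsu_global`, appropriate when both populations are present in
numbers) or by a k-sigma rule over a reference untransfected population
(`k_sigma_over_untransfected`, appropriate for all-or-none wells).  The
self-calibrated fallback of the k-sigma rule floors the threshold at 1.5
times the median cell intensity so that pure geometric variation among
untransfected cells is never called positive.

## Granule detection

SGs are compact, bright TIAL1 foci.  A pixel is a candidate spot pixel
when (i) its intensity strictly exceeds `spot_threshold_k` (default 3)
times the cell's cytoplasmic background — the median TIAL1 intensity
over that cell's cytoplasm — and (ii) its difference-of-Gaussians
response at `spot_detection_sigma_px` (default 2 px, matching the
2–4 px granule radii the generator plants) is positive, which suppresses
flat or edge-like structure and splits adjacent foci.  Connected
components are kept inside an area band
(`spot_min_area_px` = 4 to `spot_max_area_px` = 400 px, `>=`/`<=`
conventions) and assigned to the cell containing their centroid.  The
median is used for all photometry because granules are small and a
single hot pixel should not flip a classification.

## Donut-ratio enrichment

Whether the tagged protein is concentrated in a granule is scored by the
annulus ("donut") statistic: the granule's median V5 intensity divided
by the median V5 intensity of the ring of local background around it.
The donut is obtained by dilating the spot by
`donut_gap_px + donut_width_px` (defaults 0 and 5 px — a 5-px-wide
annulus immediately surrounding the spot) and removing the spot itself,
any other granule's pixels, and anything outside the owning cell's
cytoplasm.  These exclusions keep neighbouring granules and background
from contaminating the local reference.  A granule is V5-enriched when
the ratio strictly exceeds `enrichment_ratio_threshold` = 1.2; the
inequality is strict, so a ratio of exactly 1.2 is not enriched.  The
wording "donut of 5 pixels" admits two geometries (width vs radius); we
implement a 5-px-wide annulus with a configurable gap and expose both
parameters rather than asserting either reading.

Degenerate cases: a granule whose donut is empty (e.g. fully enclosed by
other granules) keeps its place in total granule counts but is excluded
from enrichment tallies; a zero donut median yields ratio `Inf`, an
enriched flag, and a logged warning.

# Repeated-measures statistics

The unit of inference is the independent experiment (replicate): image
summaries are first aggregated per (construct, treatment, replicate)
with cell-weighted means, so an image contributes in proportion to the
cells it holds.  The two-way repeated-measures ANOVA treats construct
and treatment as within-subject factors and the replicate as the
subject.  The design must be complete and balanced; incomplete subjects
are named in the error rather than silently dropped, and mixed-model
fallbacks are deliberately out of scope so that every number the package
reports is reproducible by a closed-form decomposition.

Sphericity is never assumed: each effect's p-value is corrected with the
Greenhouse–Geisser epsilon estimated from the sample covariance of the
effect's orthonormal within-subject contrast scores
(`epsilon = tr(M)^2 / (d * tr(M^2))`, clamped to `[1/d, 1]`).  A
two-level factor has a single contrast and epsilon exactly 1.  The
corrected p can only be larger than the uncorrected one.  With few
subjects the epsilon estimate is biased downward and the corrected test
is conservative — this is a documented property of the correction, not
of this implementation — so the package's null-calibration simulations
use 80 subjects with a 2 x 3 within-subject layout and 2000 data sets,
a scale at which the estimate is stable and the test attains its
nominal 5% size; the imaging experiments themselves remain at the
4-replicate scale of the emulated study.

Many-to-one comparisons against wild type use Dunnett's procedure on
the block design: the error variance is the block-residual mean square,
contrasts share the control and are equicorrelated at 1/2, and adjusted
p-values and simultaneous confidence limits come from a Monte-Carlo
reference sample of the maximum absolute multivariate-t contrast (1e5
draws under a fixed internal seed; the induced tolerance on p is about
±0.002, and the reference sample is cached per (m, df)).  With a single
comparison the procedure reduces to the paired t-test; with zero
residual variance a zero difference is reported at p = 1 rather than
NaN.

# Founder-haplotype detection and dating

Carriers of an X-linked founder mutation are hemizygous males, so their
genotypes are single alleles and identity-by-state along a marker run is
direct evidence of identity-by-descent.  `find_shared_segment()` walks
outward from the marker nearest the mutation and returns the maximal run
of consecutive markers at which all carriers agree; it fails loudly if
the carriers already disagree at the core marker.  The reported interval
runs between the outermost concordant markers (1-based, inclusive), and
the physical span is `(end - start) / 1e6` rounded to 2 decimals — the
convention that reproduces both published spans (5.35 and 19.79 Mb) from
their printed coordinates.  Genotyping error tolerance defaults to zero
mismatches (array calls on hemizygous X are high-confidence);
`max_mismatch` exists for noisier inputs.

Genetic lengths interpolate a `(bp, cM)` map piecewise-linearly,
extrapolating with a warning outside the map.  The founder age is a
point estimate calibrated as `generations = 200 / length_cm`, the unique
simple inverse-length rule consistent with both published anchor pairs
(8.07 cM at ~25 generations, 25.5 cM at ~8 generations), with years
obtained from the rounded generation count at 25 years per generation
(the value implied by 25 generations = 625 years).  This is a
calibration to the published numbers, not a re-derivation of the cited
dating methods; no confidence interval is attached because the sharing
is observed in only two carrier lineages per haplotype.

# Variant prioritization

Filtering follows standard rare-disease practice: a variant passes when
its allele frequency is strictly below 0.001 in every provided
population database, with absence from a database treated as frequency
zero, and when its gene symbol (case-normalized) is on the
muscle-expressed gene list.  The two filters commute on the set of
passing variants.  External predictor scores are pass-through
annotations only — the package applies no thresholds to them.  HGVS
coding arithmetic is exact: `codon = ceiling(cds_pos / 3)`, and only the
single-nucleotide substitution grammar is parsed; anything else is
rejected explicitly rather than guessed at.

# Solubility statistics

Band intensities are divided by their lane's total-protein loading and
then by the wild-type mean of the same experiment and fraction, which
cancels between-experiment detection gain exactly and maps wild type to
1.  Replicates are pooled across experiments (three triplicate
experiments give n = 9 per construct and fraction).  Mutant-vs-wild-type
comparisons use a two-tailed Mann–Whitney U test whose p-value is exact
— computed by a shift-algorithm dynamic program over doubled midranks,
so ties are handled exactly — for groups up to 12 each, with a
tie-corrected normal approximation beyond.  Bonferroni correction uses
m = the number of mutant constructs, applied per fraction (the two
fractions are annotated independently, mirroring how such figures are
read); m is configurable for users who prefer the stricter
mutants-times-fractions family.

# Synthetic generators: what they emulate, and what they do not

The scene generator produces adherent-cell fields: elliptical nuclei,
irregular star-convex cytoplasms (two low-order harmonics over a 24-px
base radius), uniform channel baselines, and granules as truncated
Gaussian bumps, with V5 enrichment as a co-located bump that multiplies
the local cytoplasmic V5 level by `enrichment_factor` at the peak.
Noise is additive Gaussian clipped at zero.  Defaults mirror the
emulated study where it states them — enrichment threshold 1.2, donut
width 5 px, four replicate experiments, treatments
{NT, MG, ARS, R1, R3} — and otherwise use values a microscopist would
call typical at 20x (cell and granule sizes, ~20 cells per field,
transfection rate 0.5).  Placement is rejection-sampled with bounded
retries and fails naming the violated constraint rather than degrading
silently.

What the generator does not model: Poisson shot noise, point-spread
blur, 3-D structure, photobleaching, uneven illumination, cell-to-cell
expression variability beyond the binary transfected/untransfected
split, and female (diploid) genotypes.  Passing the package's
round-trip tests therefore demonstrates correctness of the measurement
code under the stated geometry and photometry, not robustness to every
artefact of real acquisitions; segmentation parameters remain the
user's responsibility on real data.

The genotype generator always places markers exactly at the planted
segment boundaries and forces discordance at the first marker outside
each end, so the planted interval is recoverable exactly; real data
offer no such guarantee, and there the reported boundaries are
outermost-concordant-marker approximations whose resolution is the
local marker spacing.  The densitometry generator moves a planted
fraction of wild-type supernatant signal to the pellet, conserving the
total per construct, with multiplicative noise and a per-experiment
gain; `noise_cv = 0` reproduces expectations exactly, which the tests
exploit.

# Numerical choices and problem sizes

Tie-breaking and threshold conventions: strict `>` for the enrichment
ratio (as printed), `>=` for area minima, strict `<` for the allele
frequency cut-off.  Otsu thresholds use a 256-bin histogram.  The exact
Mann–Whitney branch covers groups up to 12 (the DP is O(n1 * sum of
ranks), trivially fast there); the brute-force enumeration oracle in
the test suite covers sizes up to 6 + 6, as enumeration beyond that is
wasteful.  Validation problem sizes were chosen to make each check
sharp but quick: ~650 planted granules across 13 noisy scenes for the
enrichment-recovery check (binomial 99% interval), 2000 null data sets
for the ANOVA size calibration, 5000 for Dunnett familywise error, and
40 simulated tables for solubility-shift recovery.  All generator
randomness flows through per-call seeds, and library code restores the
caller's RNG state.

# Known limitations

Mixed models for incomplete designs, diploid/phased haplotype analysis,
IBD detection at population scale, confidence intervals on founder age,
annotation transfer, and densitometry from raw blot images are out of
scope.  The Dunnett procedure assumes the block design's homoscedastic
exchangeable structure; with strong variance heterogeneity across
constructs its error control is approximate.
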