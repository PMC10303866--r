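---
title: "Methods: quantifying cohesin vermicelli phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying cohesin vermicelli phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vermicelli)
```

When the cohesin kleisin RAD21 is strongly over-expressed, chromatin-bound
cohesin redistributes into thread-like axial structures ("vermicelli") with
regularly spaced bright foci, and the genome-wide contact map changes in a
characteristic way: contacts gain at sub-megabase separations and thin out at
long range, A/B compartments blur, contacts pile up at TAD corners and
inter-TAD contact rises, while TAD positions themselves barely move. This
package implements the quantitative read-outs of that phenotype — image
statistics, FRAP kinetics, 3D shape, and Hi-C statistics — together with
synthetic-data generators that plant known truth for every read-out, so each
estimator can be validated end to end without any external data.

This vignette records the models, the parameters that matter, and the design
choices made where the procedure is not fully pinned down by convention.

## Image heterogeneity

The heterogeneity level quantifies how strongly nuclear signal accumulates
into dense structures. The procedure is:

1. `mask_and_rescale()` — nucleolar and extranuclear pixels are set to 0 and
   the remaining nuclear pixels rescaled to a common mean (default 100), so
   expression-level differences between cells drop out. Heterogeneity is
   therefore invariant to global intensity scaling.
2. `compute_box_intensities()` — a 5 × 5-pixel box traverses the image and
   the mean intensity of each box is recorded; any box containing a zero
   (masked) pixel is discarded. The default traversal is non-overlapping
   (stride = box size): "traversing" is ambiguous, and disjoint tiles give
   approximately independent samples for the mixture fit; the stride is
   configurable for sensitivity analysis. Box *mean* rather than box *sum*
   is used so the statistic is in intensity units; with a fixed box size the
   two differ only by a constant factor. A box is discarded if it contains
   *any* zero pixel, not only when its total is zero — partially masked boxes
   would bias the low mode downward.
3. `fit_double_gaussian()` — the box values are decomposed into two Gaussian
   populations (sparse and dense regions) by nonlinear least squares on the
   density-normalized histogram (Freedman–Diaconis bin width), initialized
   from the 25th/75th percentiles with two fallback quantile splits (skewed
   distributions can defeat the primary start). The heterogeneity level is
   the peak distance `mu2 - mu1`. A two-component EM mixture fit on the raw
   values (via **mclust**) serves as an independent cross-check in the test
   suite, guarding against histogram-binning artifacts; it is never the
   implementation. When the fitted separation is below one pooled standard
   deviation the result is flagged `unimodal` — note that a genuinely normal
   sample can still be *decomposed* into two half-populations with larger
   nominal separation; the flag reports the fit's own geometry, and
   degenerate inputs return a near-zero separation rather than an error.

## Beads and spacing along fibers

The generator (`simulate_nucleus_image()`) draws smoothed random-walk fibers
confined to a circular nucleus and places beads at fixed arc-length intervals
(default 0.34 µm, the regular inter-bead distance characteristic of cohesin
fibers), renders them with a Gaussian PSF over a uniform background, and adds
Poisson and optional Gaussian noise. Fibers avoid one another and their own
older path by about one bead spacing: distinct chromatin axes do not
superimpose, and without this the planted truth would contain bead pairs
closer than the optical resolution limit, which no detector could separate.
The per-step angular diffusion (0.08 rad at an eighth of a bead spacing) keeps
fibers gently curved, so the Euclidean distance between consecutive beads
stays close to their arc-length spacing — the quantity the spacing histogram
actually measures.

`detect_beads()` band-passes the image with a difference of Gaussians
(σ and 2σ at the PSF scale), takes local maxima above a relative threshold,
enforces a minimum pairwise separation, and refines positions to sub-pixel
accuracy by quadratic interpolation. Fibers are reconstructed by linking
mutually nearest maxima within twice the expected spacing; each linked
component's ordered chain is the weighted geodesic between its two farthest
members, and side-branch beads become singletons so they never contribute
spurious spacings. The measurement procedure behind the published spacing
histograms is not described anywhere; this is the simplest pipeline that
reproduces planted truth exactly on noise-free fibers, and spacings are
measured in 2D.

Colocalization (`pearson_colocalization()`) is the whole-ROI Pearson
correlation over the nucleus-minus-exclusion mask with no intensity
threshold, matching the default behavior of the standard Coloc2-style
analysis. Cluster segmentation (`segment_clusters()`) is thresholding
(default 25 intensity units) plus 8-connected labeling with an equivalent-
diameter filter (default 0.492 µm) — a deliberate re-specification of a
commercial surface-segmentation tool as threshold + size filter.

## FRAP and iFRAP kinetics

The recovery model is the double exponential
\(F(t) = A\,(1-e^{-t/\tau_A}) + B\,(1-e^{-t/\tau_B})\), with the slower
constant reported as the chromatin residence time. Processing follows the
standard chain: `correct_photobleaching()` divides the bleached-ROI signal
by the reference-ROI decay (relative to its pre-bleach mean),
`normalize_frap()` maps the pre-bleach mean to 1 and the first post-bleach
frame to 0 (time zero is that frame), and `fit_double_exponential()` runs
bounded Levenberg–Marquardt least squares (amplitudes in [0, 1.5], time
constants in (0, 10⁵] s), reordering components so τ_A ≤ τ_B.

Initialization matters for sums of exponentials: a log-linear fit to the
recovery deficit over the last third of the trace seeds τ_B, but that fit
degenerates when recovery completes early, so a log-spaced grid of τ_B
candidates (max t divided by 100…1) is also tried and the lowest-RSS fit
kept. When the two constants differ by less than 2× the result carries a
`poorly_separated` flag (the classic identifiability limit), and a vanishing
component is flagged `degenerate` — flags, never silent failures. iFRAP
traces are normalized to the first pre-bleach frame; the generator's decay
`a·e^{-t/τ} + plateau` with `a = 1 − plateau` makes the stably-bound limit a
flat trace at 1.

## Radius of gyration

Segmented 3D territories are labeled by connectivity (26-neighborhood by
default, configurable to 6) via the voxel adjacency graph, and each
component's intensity-weighted radius of gyration is
\(R_g = \sqrt{\sum_i I_i\,\lVert r_i - r_c\rVert^2 / \sum_i I_i}\) with
\(r_c\) the intensity-weighted centroid. Distances are computed in physical
units with per-axis voxel size, so anisotropic z-spacing is honored by
default (an uncorrected mode is a one-line change of `voxel_size`). Raw
intensities are used as weights; background subtraction is left to the
caller since the appropriate background is instrument-specific. The uniform
ball of radius R has the continuum value \(R\sqrt{3/5}\), which the discrete
sum matches within 2% at R = 20 voxels — one of the acceptance checks.

## The contact-map generator

`simulate_contact_map()` builds an expected matrix

\[ E_{ij} \;=\; s\,(|i-j|+1)^{-\alpha}\; c_{ij}\; t_{ij}\; a_{ij}\; p_{ij} \]

with a power-law distance decay ((s+1) rather than s so the diagonal is
finite), a compartment factor \(c_{ij} = 1\pm\varepsilon\) for matching /
mismatching A/B labels, a TAD block factor \(t_{ij} = 1+\beta\) within a
domain, an adjacent-domain leakage factor \(a_{ij} = 1+\delta\) for pairs in
neighboring TADs (extruded loops crossing a boundary), and a corner factor
\(p_{ij} = 1+\gamma\) within `corner_width` bins of the (left boundary,
right boundary − 1) pair of each TAD. The scale fixes the expected total;
Poisson counts are drawn on the upper triangle and mirrored, or the expected
matrix itself is returned (`sample = FALSE`, "expected-value mode") so
estimator correctness can be separated from sampling error. The compartment
factor can be restricted to separations beyond `compartment_min_dist` bins:
the plaid is a long-range feature of real maps, and applying it at
intra-domain range would couple compartment strength into every short-range
statistic.

Two presets (`hic_preset()`) encode a paired control vs RAD21-over-expressed
contrast on identical 40-kb bins, identical TAD boundaries (20-bin = 800-kb
domains) and a shared compartment pattern whose blocks span 1–3 whole
domains (compartment transitions coincide with domain boundaries, as they
mostly do in real genomes, while blocks of varying size keep labels mixed at
domain-scale separations):

| parameter | control | OE-like | read-out it drives |
|---|---|---|---|
| decay α | 1.0 | 1.15 | long-range P(s) loss |
| compartment ε | 0.4 | 0.2 | mixing ratio up, saddle corners down |
| TAD block β | 1.0 | 1.2 | short-range gain |
| adjacent leakage δ | 0 | 0.6 | inter-TAD contact up, TAD score down |
| corner γ | 0.2 | 1.0 | corner/ATA enrichment up |
| label flips | — | 6% B→A, 2% A→B | asymmetric compartment switching |

ε and γ follow the natural strength ordering of the two conditions; α, β and
δ are the package's own design, chosen once so that the eight contact-map
contrasts all move in the physiological direction — in particular the
leakage term, not a global decay change, is what carries the inter-TAD
signal, mirroring the over-extrusion mechanism. The planted label flips are
contiguous blocks centered in the longest run of the source label, because
switching is regional; isolated single-bin flips would create artificial
coverage dips at the flip sites. The flipped fractions are exact by
construction, so expected-value-mode recovery of 6%/2% is a sharp test.

## Hi-C statistics

*Balancing.* `ice_balance()` is the standard iterative marginal equalization,
converged when the coefficient of variation of unmasked marginals falls
below 10⁻⁵ (at most 200 iterations), then scaled to unit mean per valid
pixel. Low-coverage bins are masked beforehand using the MAD-max convention
on log marginals (default 3 MADs below the median, plus all zero bins):
coverage outliers are multiplicative, so the filter operates on the log
scale. The filter is a dropout guard for real data; synthetic maps contain
no unmappable bins, so the demo and expected-value analyses disable it
(`min_coverage_mad = Inf`) rather than let it clip the structured tail of a
noiseless coverage distribution.

*Expected and O/E.* `expected_by_distance()` averages over valid pairs per
separation; `observed_over_expected()` divides by it, leaving per-distance
means at exactly 1. Both match O(n²) brute-force loops in the tests.

*P(s).* `contact_probability()` averages contact per geometrically spaced
distance bin (factor 1.12, configurable), excludes the s = 0 diagonal,
normalizes the curve to unit sum, and reports a least-squares log-log slope
over a requested range. On the pure-decay generator with α = 1 the fitted
slope is −0.96: the model decays as (s+1)^(−α), whose local log-log slope is
−α·s/(s+1), so slopes slightly shallower than −α are the correct behavior,
within the ±0.05 band used in the tests.

*Compartments.* `compute_pc1()` takes, per chromosome, the leading
eigenvector of the Pearson correlation matrix of the O/E map, oriented so it
correlates positively with a gene-density-like track (A is gene dense) and
scaled by the square root of its eigenvalue. Bins with PC1 exactly zero or
masked are `undetermined` — the zero cutoff is a strict sign test.
Eigenvector degeneracy (no plaid, or leading eigenvalues separated by less
than 10⁻⁸ relative) raises a flag instead of returning noise. PC1 is
computed per whole chromosome; arm-level splitting is not performed.
`compartment_switches()` classifies bins co-determined in two conditions
into stable A/B and A→B/B→A fractions (bin fractions, summing to 1), and
`mixing_ratio()` is the sum of balanced contacts over unordered A–B pairs
divided by the sum over same-class pairs, diagonal excluded, per chromosome
with an optional exclusion list (e.g. the X chromosome); sums rather than
means are used, with the per-pair-mean variant one line away since the two
differ only by class-size factors. `saddle()` ranks determined bins into
five equal-count PC1 groups (group count configurable) and averages O/E over
group pairs.

*TADs.* `insulation_score()` slides a w × w square along the diagonal
(window 500 kb by default, rounded to whole bins — 12 bins at 40 kb) over
the contacts crossing each bin's left edge, reporting log2 of the ratio to
the chromosome mean; masked bins get no score, since a balanced matrix
carries no information there. `call_boundaries()` finds
positive-to-negative zero crossings of the left-minus-right delta vector
(100-kb half-windows) that are score valleys, with boundary strength the
delta swing and a 0.1 minimum; valleys immediately flanking a masked bin
are discarded as balancing artifacts. On noise-free maps the planted
boundaries are recovered exactly, and at 5 × 10⁵ contacts over 100 bins
recall and precision stay above 0.9. `tad_score()` is mean intra-TAD
contact over mean contact with the two adjacent domains (TADs under 3 bins
skipped; the bounded-distance "inter" definition is robust to the P(s)
decay, with an all-pairs variant possible downstream). `aggregate_tads()`
rescales each TAD window (±50% flanks) on the O/E map to a 90 × 90 grid by
bilinear interpolation and averages; masked pixels carry zero weight so a
handful of filtered bins do not discard whole windows.

## Problem sizes and determinism

Every generator is a pure function of its parameter object including the
seed (the global RNG state is restored on exit). The default study
conditions are 200-bin (8-Mb) chromosomes at 2 × 10⁶ contacts for the
paired demo, 160 × 160-pixel nuclei at 0.034 µm/pixel with 4 fibers, 300
post-bleach frames at 1 s, and 20-seed replication for stochastic checks
(100 seeds for the noisy-FRAP hit rate) — sizes at which every statistic is
stable while a full pipeline run takes seconds.

## What the synthetic data does and does not show

The generators emulate the *statistical structure* the estimators consume:
multiplicative plaid and block factors on a power-law decay with Poisson
counting noise; Gaussian-PSF beads on smooth fibers with shot noise;
exponential kinetics with acquisition bleaching. They do not model polymer
dynamics, loop extrusion trajectories, optical aberrations, chromatic
shifts, coverage bias beyond masking, or replication timing. Passing tests
therefore demonstrate that the estimators recover known truth under the
stated noise models — not that the biological conclusions of any particular
experiment are correct, and thresholds tuned here (e.g. boundary strength
0.1) should be re-examined on real data with its heavier-tailed artifacts.
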