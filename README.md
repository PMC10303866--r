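# vermicelli

Quantitative analysis of the chromatin phenotypes caused by excess
chromatin-bound cohesin. When the kleisin subunit RAD21 is over-expressed,
cohesin accumulates on chromatin in thread-like axial "vermicelli"
structures with regularly spaced beads, and the Hi-C contact map shifts in a
stereotyped way: contacts gain at sub-megabase range and thin out at long
range, A/B compartments mix, contacts pile up at TAD corners and inter-TAD
contact rises, while TAD positions, lengths and counts stay put.

The package implements every quantitative read-out of that phenotype for
people analysing super-resolution nuclear images, photobleaching kinetics
and binned contact matrices:

- **Image statistics** — heterogeneity level via a two-Gaussian
  decomposition of 5 × 5-pixel box intensities
  (`heterogeneity_level()`), bead detection and inter-bead spacing along
  fibers (`detect_beads()`, `bead_spacings()`), whole-ROI Pearson
  colocalization, cluster segmentation, line profiles.
- **Kinetics** — FRAP/iFRAP trace normalization and double-exponential
  fitting, `F(t) = A(1 − e^(−t/τ_A)) + B(1 − e^(−t/τ_B))`, with the slower
  constant reported as the chromatin residence time (`fit_frap_trace()`).
- **3D shape** — connected-component labeling of segmented territories and
  the intensity-weighted radius of gyration
  `Rg = sqrt(Σ I_i (r_i − r_c)² / Σ I_i)` (`radius_of_gyration()`).
- **Hi-C statistics** — ICE balancing, contact probability P(s),
  observed-over-expected, PC1 compartment calling with switch accounting,
  AB/(AA+BB) mixing ratio, saddle enrichment, insulation-score TAD calling,
  TAD score (intra/inter), aggregate TAD analysis, trans-contact fraction.
- **Synthetic generators** — contact maps with power-law decay,
  checkerboard compartments, TAD blocks and corner peaks under Poisson
  noise; vermicelli-like bead images; biexponential FRAP traces; voxel
  clouds — each returning its planted ground truth, so every estimator is
  testable end to end.

## Worked example

The paired synthetic presets encode a control vs RAD21-over-expressed
contrast with identical TAD truth. One call runs the full contact-map
pipeline on both and reports each statistic with its direction of change:

```r
library(vermicelli)
demo <- demo_contrast(seed = 1)
```

```
ps_short           control  0.01235   rad21_oe  0.01297   up
ps_long            control 0.002655   rad21_oe  0.00147   down
mixing_ratio       control   0.1743   rad21_oe   0.3119   up
saddle_corner      control    1.305   rad21_oe     1.21   down
ata_corner         control    1.375   rad21_oe    1.637   up
tad_score          control    5.888   rad21_oe    5.116   down
tad_count          control       10   rad21_oe       10   unchanged
tad_median_length  control    8e+05   rad21_oe    8e+05   unchanged
```

Reading the rows: contact probability rises around the TAD scale
(0.55–1.1 Mb) and falls beyond 2 Mb; inter- vs intra-compartment mixing
AB/(AA+BB) nearly doubles while saddle corner enrichment (mean O/E of the
extreme PC1 quantile pairs) drops — compartments blur; the aggregate-TAD
corner enrichment rises (corner peaks strengthen) while the TAD score
(intra-TAD over adjacent-TAD contact) falls — boundaries leak; and the
called TAD count and median length are unchanged. All eight directions
match the over-extrusion phenotype.

Individual estimators print their fits directly:

```r
radius_of_gyration(simulate_territory(territory_sim_params("ball", radius = 20)))
#> rg_result: Rg 15.48 um over 33401 voxels        # R*sqrt(3/5) = 15.49

fit_frap_trace(simulate_frap_trace(frap_sim_params(noise_sd = 0.02, seed = 8)))
#> frap_fit: A 0.306 (tauA 2.48 s), B 0.486 (tauB 30.7 s), residence 30.7 s
```

(the trace was simulated with A = 0.3, τ_A = 2 s, B = 0.5, τ_B = 30 s).

Pipeline stages are also callable by name — `run_pipeline("tads", config,
seed, out_dir)` writes insulation bedGraph, boundary/TAD BED and score CSV
files; `inst/scripts/vermicelli-cli.R` is a thin shell wrapper over the same
registry.

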