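# telostorm

Quantitative analysis of telomere structure and protection for
experiments that manipulate telomeric chromatin — the readouts used
when, for example, heterochromatin protein HP1α is tethered to
telomeres through a TRF1 fusion and the consequences are measured by
super-resolution imaging, damage-focus scoring, Southern blot
densitometry and ChIP dot blots.

The package is aimed at microscopists and molecular biologists who have
3D STORM molecule lists, two-channel nuclear foci images, gel lane
profiles or dot-blot grids, and want the full measurement chain —
including a seeded synthetic-data generator so every stage can be
validated against known ground truth without any external dataset.

## What it computes

**Telomere shape from STORM localizations.** A telomere imaged by 3D
STORM is a cluster of hundreds of localizations. Its spatial extent is
the radius of gyration

    Rg² = (1/N) Σₖ ( r⃗ₖ − r⃗_com )²,

the RMS distance of the N localization points from the cluster's
center of mass. The pipeline is: drift correction by image correlation
(`correct_drift`), density-based telomere clustering
(`cluster_localizations`), quality filtering — strictly more than 200
localizations and a center of mass near the focal plane
(`filter_clusters`) — then `radius_of_gyration`, principal-axis
anisotropy (`cluster_anisotropy`), per-group summaries
(`summarize_shape_distribution`), and the fraction of irregular
telomeres with Rg **equal to or greater than** the reference group's
mean Rg, recomputed from the data (`fraction_irregular`). Group means
are compared by ANOVA with Tukey's multiple comparisons
(`anova_tukey`).

**Foci colocalization / TIF scoring.** Connected-component focus
detection under one shared threshold per channel (`detect_foci`),
% area per nucleus (`percent_area`), % of reference-channel foci
overlapping a partner channel (`percent_colocalized`), %TIF per
telomere (`percent_tif`), and a random-placement permutation null that
quantifies coincidental overlap (`tif_permutation_null`).

**TRF densitometry.** Ladder calibration, log-linear in molecular
weight (`calibrate_migration`), and the intensity-weighted mean
fragment length `Σ(Intᵢ) / Σ(Intᵢ/MWᵢ)` (`mean_telomere_length`).

**ChIP dot blots.** Normalization to the input spot per replicate,
mark-per-histone ratios (e.g. H3K9me3 per H3), fold changes against
pooled controls with s.e.m. (`normalize_dot_blot`).

**Statistics.** Two-tailed unpaired t test, one-way ANOVA with Dunnett
contrasts, ANOVA with Tukey comparisons, all at 95% confidence
(`ttest_two_tailed`, `anova_dunnett`, `anova_tukey`).

**Simulators.** `simulate_localizations` (spheres, ellipsoids,
segmented paths; geometric blinking; ~30 nm XY / ~30 nm Z localization
error; Poisson background; injectable drift), `simulate_rg_sample`
(vectorized group-scale Rg sampling calibrated through the
noise-additivity law E[Rg²_obs] = Rg²_struct + 2σ²xy + σ²z),
`simulate_foci_image`, `simulate_gel_profile`, `simulate_dot_blot` —
all seeded and all returning their ground truth.

## Worked example

Simulate a two-group experiment (a reference and a group whose target
mean Rg is 8% larger), run the full pipeline, and read the report:

```r
library(telostorm)

cfg <- experiment_config(
  groups = list(
    list(label = "reference", n_nuclei = 4, telomeres_per_nucleus = 10,
         mean_rg_nm = 84),
    list(label = "tethered", n_nuclei = 4, telomeres_per_nucleus = 10,
         mean_rg_nm = 90.7)),
  acquisition = acquisition_params(n_frames = 5000),
  filter = cluster_filter_policy(min_points = 200, focal_window = 5000),
  seed = 1)

report <- run_shape_experiment(cfg)
print(report)
#> Shape experiment (seed 1, telostorm 0.1.0)
#>   2 group(s), 8 nuclei, 80 telomeres after filtering
#>   localizations simulated: 39642; clusters found: 80; kept: 80
#>   reference cutoff: 79.6 nm
#>      group n_telomeres mean_rg_nm median_rg_nm fraction
#>  reference          40       79.6         73.8    0.400
#>   tethered          40       86.0         84.7    0.575
#>   Tukey-adjusted pairwise p-values:
#>          comparison estimate  p_adj
#>  tethered-reference     6.42 0.0891
```

Every planted telomere was recovered by clustering and survived the
filters (80 of 80). The cutoff (79.6 nm) is the reference group's mean
Rg recomputed from this run — per-telomere Rg is dispersed (lognormal
structural radii, CV 0.35), so a realized mean can sit a few nm from
its calibration target at n = 40. The tethered group's mean Rg is
6.4 nm larger and 57.5% of its telomeres lie at or above the cutoff
versus 40% in the reference; at only 40 telomeres per group the Tukey
comparison does not reach 0.05 — at the ~450 telomeres per group of a
full imaging study the same effect is detected in ~99% of replicates
(that power calculation is part of the acceptance script below).

`plot(report$shape_table)` draws the per-nucleus dot display (one dot
per telomere, nuclei along the x axis) used to check that group
differences are not driven by outlier nuclei.

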