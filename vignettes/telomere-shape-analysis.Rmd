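---
title: "Quantifying telomere shape, damage foci and chromatin enrichment with telostorm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying telomere shape, damage foci and chromatin enrichment with telostorm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telostorm)
```

## The problem

Telomeres are far smaller than the ~250 nm diffraction limit, so their
shape can only be resolved by single-molecule localization microscopy
(3D STORM). A labeled telomere appears as a cluster of hundreds of
localizations -- fitted molecular positions accumulated over tens of
thousands of camera frames -- and its spatial extent is summarized by
the radius of gyration

$$R_g^2 = \frac{1}{N}\sum_{k=1}^{N}\left(\vec r_k - \vec r_\mathrm{com}\right)^2,$$

the root-mean-square distance of the $N$ localization points from the
cluster's center of mass. Experiments that perturb telomeric chromatin
(for instance by tethering the heterochromatin protein HP1α to
telomeres through a TRF1 fusion) compare the $R_g$ distributions of
experimental and control groups, and summarize the shift as the
fraction of "irregular" telomeres whose $R_g$ is equal to or greater
than the mean $R_g$ of a reference group. The same studies score
telomere protection with damage-focus colocalization (%TIF), telomere
length with restriction-fragment densitometry, and chromatin
composition with ChIP dot blots. `telostorm` implements that entire
quantitative chain, together with a synthetic-data generator so every
stage can be validated against a known ground truth.

## The localization pipeline

**Input.** A molecule list: one row per localization with `x, y, z` in
nm, the frame of appearance and the photon count
(`read_molecule_list()` / `loc_table()`).

**Drift correction** (`correct_drift()`). Stage drift over a long
acquisition is estimated by image correlation analysis: localizations
are binned into frame intervals (500 frames by default at the scales we
simulate), each bin is rendered as a 2D histogram image, and the
displacement of every bin relative to the first is located at the
cross-correlation peak with parabolic sub-pixel interpolation. A light
Gaussian smoothing (1 px s.d.) of the binned images widens the
correlation peak so the three-point parabolic fit remains stable under
counting noise; without it, per-bin errors of ~8--9 nm occur at a few
thousand localizations per bin, with it the per-bin RMSE stays below
5 nm at 50 nm of injected drift. Only lateral (XY) drift is corrected;
axial drift is typically controlled by hardware focus locks and the
axial component of residual drift is small compared with the ~30 nm
axial localization error. An empty bin gets its displacement
interpolated from its neighbours with a warning.

**Cluster identification** (`cluster_localizations()`). The original
workflows selected telomeres manually; `telostorm` substitutes
density-based clustering (DBSCAN) with a 75 nm linkage radius and a
10-point core threshold. Telomere foci sit micrometres apart while
their own extent is ~80 nm $R_g$, so the result is insensitive to these
defaults over a wide range; both are configurable. Neighbour counting
includes the point itself.

**Filtering** (`filter_clusters()`). Three quality-control rules:
strictly more than `min_points` localizations (default 200 -- a cluster
of exactly 200 points is excluded), center of mass within
`focal_window` of the focal plane (default 250 nm about the centre of
the z-depth window; the underlying acceptance criterion is qualitative
in practice, so the window is explicit and configurable), and
optionally an XY reference mask derived from the conventional-image
overlay to exclude nontelomeric background.

**Shape statistics.** `radius_of_gyration()` computes $R_g$ in 3D by
default; a 2D projected mode is exposed because some published
pipelines work on projected coordinates. `cluster_anisotropy()`
returns the principal-axis spreads (square roots of the covariance
eigenvalues, population normalization), whose squares sum to $R_g^2$;
irregular telomeres are spread out in two dimensions but compact in
one, which shows as a small third spread. `fraction_irregular()`
recomputes the cutoff as the reference group's mean on the data at
hand -- a printed value like 84 nm is one study's realized cutoff, not
a constant -- and counts ties as irregular ("equal or greater").
`summarize_shape_distribution()` reports the violin-plot annotation
(mean over telomeres, median, IQR, 95% CI of the mean) plus a
per-nucleus breakdown, and `rg_count_correlation()` checks that $R_g$
is not driven by localization count.

**Statistics** (`anova_tukey()`, `anova_dunnett()`,
`ttest_two_tailed()`). Group means of per-telomere $R_g$ are compared
by one-way ANOVA with Tukey's multiple comparisons; focus percentages
and ChIP ratios by ANOVA with Dunnett contrasts against a control or by
two-tailed unpaired t tests, all at 95% confidence with s.e.m. error
bars. Telomeres from the same nucleus are treated as independent
observations, following the convention of the imaging literature this
package serves; that is a caveat, not a recommendation -- a
nucleus-level mixed model is out of scope here.

## What the simulator emulates (and what it does not)

`simulate_localizations()` draws emitter positions uniformly within a
sphere, a triaxial ellipsoid, or along a segmented path with a Gaussian
tube; each emitter blinks $1 + \mathrm{Geometric}$ times (mean
`blink_mean`), and each localization adds independent Gaussian error
with $\sigma_{xy} = 30$ nm and $\sigma_z = 70/2.355 \approx 29.7$ nm.
The defaults mirror typical telomere STORM acquisitions: 35,000 frames,
a 700 nm z-depth window, and ~500 localizations per telomere from 100
emitters at `blink_mean = 5` (published per-group means run 420--664).
Quoted "precision" and "resolution" figures are not standardized: we
read the lateral figure as a 1σ error and the axial figure as a FWHM;
both are plain parameters if a different reading is wanted.

Key modelling choices:

* **Blinking** is a shifted geometric count -- simple, heavy-tailed
  enough to reproduce the broad spread of localizations per telomere.
  Real photoswitching kinetics (dark-state lifetimes, bleaching) are
  not modelled.
* **Background** is a homogeneous Poisson process over the imaged
  volume; real nontelomeric background is structured, which is why the
  pipeline also supports overlay-mask gating.
* **Per-telomere size heterogeneity** is a lognormal structural radius
  with CV 0.35, chosen once to reproduce the broad, right-skewed
  per-telomere $R_g$ spread seen in telomere STORM violin plots. With
  this CV, groups calibrated 8% apart in mean $R_g$ at ~450 telomeres
  per group are separated by Tukey's procedure in essentially every
  replicate, matching how clearly the corresponding real effect is
  detected.
* **Group calibration.** `simulate_rg_sample()` is parameterized by the
  target *observed* mean $R_g$: the structural radius distribution is
  solved from the noise-additivity law
  $E[R_{g,\mathrm{obs}}^2] = R_{g,\mathrm{struct}}^2 + 2\sigma_{xy}^2 + \sigma_z^2$
  so the *quadratic* mean of observed $R_g$ matches the target. Because
  $R_g$ is dispersed, the arithmetic mean lands 2--3% below the target
  at CV 0.35 (Jensen's inequality); group *differences* on the
  quadratic scale are preserved exactly, which is what the comparison
  stage consumes.
* **Irregular structures** default to triaxial ellipsoids with one
  semi-axis several-fold smaller ("compact in one dimension"); a
  segmented-path generator is available as an alternative irregular
  family. Neither is a chromatin polymer model.

The foci, gel and dot-blot generators are bookkeeping fixtures: Gaussian
spots with a planted overlap plan, Gaussian bands placed through the
ladder's log-linear migration map, and lognormal multiplicative spot
noise with a recorded ground-truth ratio. Passing tests on these
fixtures demonstrates that the *scoring arithmetic* is exact and stable
under noise; it says nothing about segmentation of real images, where
deconvolution artifacts, uneven illumination and touching nuclei
dominate and thresholds must be chosen by the analyst (and then held
identical across all groups -- the package enforces reuse of one
configuration per experiment).

## Numerical choices and degenerate inputs

* $R_g$ of a single point is 0; an empty cluster is an error. The
  pairwise-distance identity
  $R_g^2 = \frac{1}{2N^2}\sum_i\sum_j |\vec r_i - \vec r_j|^2$ is used
  as an independent test oracle, never as the implementation.
* Anisotropy needs $N \ge 3$ and non-collinear points; degenerate
  clusters are flagged rather than silently dropped.
* The filter boundary is strict (`N > min_points`) and the cutoff
  comparison inclusive (`Rg >= cutoff`), matching the stated rules of
  the source workflow; both appear as exact boundary tests.
* Drift estimation uses circular FFT cross-correlation; fields are
  padded by 4 pixels and drifts are far smaller than the field, so
  wrap-around is immaterial. Sub-pixel refinement is a three-point
  parabola per axis; ties at the peak fall back to the integer peak.
* Gel calibration interpolates $\log_{10}$(MW) piecewise-linearly
  between anchors, reproduces anchors exactly, and extrapolates beyond
  them from the terminal segments with a warning; calibration is a
  required input because gels run without size markers cannot be
  calibrated post hoc.
* The TRF mean length is evaluated exactly as the printed sum over
  profile samples, $\sum Int_i / \sum (Int_i/MW_i)$, with no bin-width
  reweighting; merging adjacent bins moves the result by well under
  0.5% on smooth smears. (The source describes this formula as the
  mean average length; it is labeled mean fragment length here.)
* Dot-blot fold changes against several controls use the mean of the
  control-group means ("pooled controls"); input normalization is per
  replicate, then averaged with s.e.m.
* A constant-vs-constant t test with equal means returns $t = 0, p = 1$
  by convention; with unequal means it is an error rather than a
  spurious infinity.
* Equal-variance t tests are the default (the source procedures say
  only "unpaired"); Welch is an option.

## Problem sizes used by the tests

The bundled tests and the acceptance script run entirely on simulated
data at reduced scale: 5,000-frame acquisitions for drift recovery
(50 nm injected drift, 25 clusters), 100 replicates of the four-group
design at ~450 telomeres per group for the discrimination check, 1,000
null replicates for type-I calibration, and $10^4$ resamples for the
permutation cross-check of the t test. These sizes were chosen so the
whole suite completes in a few minutes on one CPU while leaving every
statistical tolerance a multiple of its Monte-Carlo error.

## Known limitations

* The pipeline starts at the molecule list; raw-frame spot fitting,
  astigmatic z calibration and reconstruction rendering are out of
  scope.
* Foci analysis is 2D (projected); 3D foci and sub-pixel spot
  localization are not attempted.
* The per-nucleus hierarchy is reported but not modelled; inference
  treats telomeres as independent.
* The irregular-shape generators are geometric stand-ins, not polymer
  physics; recovery tests certify the measurement chain, not any
  biological mechanism.

## A worked end-to-end run

```{r, eval = FALSE}
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
plot(report$shape_table)
```

The report embeds the resolved configuration and seed, the per-stage
record counts (localizations, clusters found, clusters kept -- always
non-increasing along the filter chain), the per-group and per-nucleus
summaries, the recomputed reference cutoff with the irregular
fractions, and the Tukey comparisons.
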