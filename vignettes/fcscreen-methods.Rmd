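---
title: "Methods: models, parameters, and design choices in fcscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and design choices in fcscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`fcscreen` implements a two-group, multi-modality screening pipeline for
small-animal studies: edge-wise inference on ROI functional-connectivity
matrices, an effect-size screen and per-region summary, seed-based voxel
maps, behaviour coupling, EMG spectral statistics, g-ratio morphometry, and
skeleton-based fiber metrics. This vignette documents the statistical model
behind each stage, the parameters that matter, the numerical conventions,
and the design decisions taken where more than one reasonable reading
existed.

## Connectivity model and edge-wise inference

Each animal contributes an ROI-averaged time-series matrix (volumes ×
ROIs). The per-animal connectivity matrix is the Pearson correlation of
every ROI pair; with the shipped 31-region atlas and 300 volumes this is
the usual 31 × 31 symmetric matrix with unit diagonal. All group-level
computation happens in Fisher-z space, \(z = \operatorname{atanh}(r)\),
because z is approximately variance-stabilised
(\(\operatorname{var}(\hat z) \approx 1/(T-3)\) for \(T\) volumes) and
group averages and t-tests behave much better there than on raw r.
Averages are converted back with \(r = \tanh(z)\) for presentation. A
config switch (`average_domain = "r"`) restores literal r-averaging for
comparison.

Numerical conventions: the diagonal is masked (set `NA`) before any
z-domain computation rather than letting \(\operatorname{atanh}(1)\)
diverge, and \(|r| \ge 1 - 10^{-7}\) is clipped to \(1 - 10^{-7}\) before
the transform. The clip bounds z at ≈ 8.4, far beyond any empirical
correlation at realistic T, so estimates are not materially biased.

Edge-wise inference is a two-sample t-test per unordered ROI pair on the
animals' z values. The default is the pooled-variance (Student) test —
the conventional reading of "two-sample t-test" with near-equal group
sizes — with Welch available via `screen_config(test_variant = "welch")`.
Multiplicity is handled by Benjamini–Hochberg FDR by default at
α = 0.01, with Bonferroni available for a family-wise reading. Edges with
zero pooled variance (possible only in degenerate fixtures) get t = 0 and
p = 1 with a warning; edges with zero pooled SD have undefined Cohen's D
and are masked out of the effect screen while remaining in the
significance screen. Groups with fewer than two animals are refused.

The effect-size screen keeps edges with \(|D| > 0.8\) ("large" by Cohen's
convention), where \(D = (\bar z_A - \bar z_B)/s_{pooled}\), positive
meaning stronger connectivity in the treated group. At n = 9/8 the
sampling SD of \(\hat D\) under the null is ≈ 0.5, so the effect screen
alone is permissive by design; the multi-parameter screen intersects it
with the FDR-significant set.

## Node Modulation Index

For each region the NMI is the mean signed D over its top
\(k = \lceil f\,(n-1) \rceil\) connections ranked by \(|D|\), with
\(f = 0.10\) by default (3 connections per region at n = 31). Design
choices: `ceiling` keeps \(k \ge 1\) for any atlas size; ties in \(|D|\)
break toward the smaller partner index so the selection is deterministic;
signed averaging is the default because the index is meant to carry the
direction of the change, with `absolute = TRUE` available since a
magnitude-only reading is also defensible. Ranking is by \(|NMI|\)
descending with an alphabetical tie-break. `fraction = 1` reduces the NMI
to the plain row mean, a closed-form identity used in the tests.

## The synthetic cohort: what it emulates, and what it does not

The generator plants effects in the space the test operates in. A planted
edge with target effect d separates the group-mean z values by
\(d\,\sigma_z\), where \(\sigma_z\) (default 0.15) is the between-animal
SD of z at planted edges — so the target Cohen's D is exact by
construction *in the latent animal-level z*. Observed D is mildly
attenuated because finite recordings add estimation noise: the observed
between-animal spread is \(\sqrt{\sigma_z^2 + 1/(T-3)}\) (≈ 0.16 at
T = 300 against σ_z = 0.15). The verification script measures a mean
empirical D ≈ 1.47 for a planted 1.5.

Animal-level variability is two-level: per-animal z values are drawn
Gaussian around the group mean, and the time series are then drawn
multivariate normal matching that animal's correlation matrix. One
geometric constraint shapes the implementation: independent jitter of SD
0.15 on *all* 465 edges of a 31-dimensional correlation matrix almost
never yields a positive-definite matrix (the spectral radius of the
perturbation, ≈ \(2\sigma\sqrt{n}\) ≈ 1.7, exceeds the smallest baseline
eigenvalue ≈ 0.9). Full-strength jitter is therefore applied only at
planted edges — which is exactly where the d ↔ σ_z calibration needs it —
and a reduced background jitter (`sigma_z_background`, default 0.03)
covers the remaining edges, keeping matrices comfortably PD. Each
animal's matrix is Cholesky-checked, redrawn up to 25 times on failure,
and rejected with the offending edge reported if the group-level
construction itself is infeasible (e.g. planted correlations violating
the triangle inequality). Behavioural scores couple to the *latent*
animal-level z of a chosen edge at a target correlation, so the observed
edge–behaviour correlation is attenuated by the same estimation-noise
factor (≈ 0.93 at T = 300).

Defaults mirror the study conditions the package is built around: 31
ROIs, 300 volumes at 1 s sampling, 9 treated + 8 control animals,
baseline inter-regional correlation 0.1 (a modest positive resting-state
baseline; the value is a generator choice, not an estimate from any
dataset, as no animal-level variance figures are published to estimate
σ_z from).

What the generator does not emulate: hemodynamics and autocorrelation in
time (volumes are i.i.d. in time), spatial autocorrelation between ROIs
beyond the compound-symmetric baseline, motion artefacts, and non-Gaussian
heavy tails. Passing tests therefore demonstrate statistical correctness
of the pipeline under a well-specified model, not robustness to every
artefact of real rsfMRI.

## Calibration of the screen, and a caveat on family-wise error

Per-edge p-values are calibrated: pooled over thousands of null cohorts,
the fraction of raw p below any threshold matches the nominal value,
including in the far tail relevant to multiplicity correction (verified
down to p < α/m). BH-adjusted selection matches `stats::p.adjust` and a
brute-force step-up oracle exactly.

The probability that a null cohort yields *any* BH-selected edge at
α = 0.01, however, is measurably about 1.2–1.4 % rather than exactly 1 %.
This is a real property of BH on this kind of data, not an implementation
artefact: edges sharing an ROI have positively correlated estimation
errors (an outlying animal time series perturbs many edges at once), so
extreme p-values arrive in clusters, and two-sided p-values from
positively dependent statistics fall outside the PRDS conditions under
which BH's false-discovery guarantee transfers to the global-null
any-rejection rate. FDR itself remains controlled; the any-rejection
probability under the global null — where FDR and FWER coincide only
under independence — is mildly inflated. The acceptance check of this
rate against a 500-replicate binomial interval around 1 % is therefore
sensitive to the draw; the package reports the measured rate as a
first-class output of the verification script rather than adjusting the
screen to force it to 1 %.

## Seed-based maps

The seed time course is the unweighted mean over the seed mask (matching
the ROI-averaging convention; no PCA eigenvariate). Maps are voxel-wise
Pearson correlations, Fisher-z transformed for the group stage;
zero-variance voxels are masked. Group t-maps are voxel-wise two-sample
tests on z with an optional BH mask — no cluster-extent correction is
applied, and display thresholds are left to the user. Voxel indices are
array indices; world coordinates live in the NIfTI affine and are passed
through, never computed.

The voxel generator plants a region whose voxels share a latent signal
with the seed at a target correlation. Its `noise_share` parameter
controls how much of the region's noise is common across voxels: with
independent voxel noise (default), averaging the r-map over a region and
correlating the region-averaged time course are *structurally different*
quantities (the average time course cancels noise); with `noise_share`
near 1 — emulating spatially smoothed data, where neighbouring voxels
carry common noise — the two averaging orders agree, and the package's
consistency check between the voxel-level and ROI-level pipelines is run
in that regime.

## EMG analysis

Recordings are 1 kHz signals with a wake/sleep label track; all
statistics are computed on wake samples, concatenated with segment
boundaries preserved so no analysis window straddles a gap. A 50 Hz mains
notch (2nd-order Butterworth band-stop, ±2 Hz, zero-phase) is the default
pre-processing step; a low-pass reading of mains filtering would destroy
the 50–150 Hz analysis band, so the notch interpretation is used and the
filter can be detached in config. The RMS envelope uses non-overlapping
1 s windows; "maximum amplitude" and "average amplitude" are the max and
mean of that envelope (a rectified-raw-mean variant of the average is a
documented alternative the envelope mean stands in for).

Welch PSD uses 4 s Hann segments at 50 % overlap — 0.25 Hz resolution at
1 kHz, a standard choice balancing variance against resolution; segments
are mean-removed so offsets do not leak into the density. The density
satisfies Parseval (integrated density ≈ signal variance; verified to
well under 5 %). Band power is a trapezoidal integral with edge
interpolation, so contiguous bands partition total power exactly. The
scalogram uses an analytic Morlet wavelet with centre parameter
ω₀ = 6 (the common default balancing time and frequency localisation).
Group comparisons aggregate to one band-power value per animal before the
t-test — the animal is the experimental unit, avoiding pseudo-replication
across windows; the test is run on log power, since gains act
multiplicatively.

The EMG generator sums band-limited Gaussian noise components (unit
variance each, scaled by per-band gains, so expected band power equals
gain²) plus a mains sinusoid, and attenuates sleep-labelled blocks. It
does not emulate realistic sleep architecture, movement artefacts, or
electrode drift.

## g-ratio morphometry

Areas are converted to circular-equivalent diameters
\(d = 2\sqrt{A/\pi}\); the g-ratio is inner (axonal) diameter over outer
(fiber incl. myelin) diameter, lower meaning thicker myelin. Axon tables
may carry areas or diameters but never mixed per row. Stratification is
on the *inner* diameter at 400 nm — the axon's own calibre, which is the
quantity the g-ratio's numerator measures. Rows violating
0 < inner < outer are rejected per-row with a count. Strata with fewer
than two axons in a group are skipped with a warning rather than erroring
the whole table. The diameter trend is ordinary least squares of g on
inner diameter per group. The axon generator draws log-normal inner
diameters (median 400 nm, σ_log = 0.4), applies the treated-group g shift
only below threshold, and clips g into (0, 1); an optional linear
g-versus-diameter slope is available and defaults to 0.

## Fiber skeletons

Grayscale images are Otsu-thresholded (256-bin between-class variance
maximiser); binary images pass through. Thinning is Zhang–Suen, which
preserves topology and is idempotent; its deletion order is slightly
orientation-dependent, so rotation/reflection invariance of measured
length holds to about 1 %, and the tests assert it at that tolerance.
Length uses the chain-code convention — 1 per axis-aligned inter-pixel
step, √2 per diagonal, with diagonals that shortcut an axis-aligned
two-step path not double-counted — times the pixel size; a 100-pixel
straight line measures 99. Branch points are skeleton pixels with ≥ 3
skeleton neighbours, merged 8-connectedly into single junctions to avoid
thinning artefacts; endpoints have exactly one neighbour. Node degree is
defined on the junction/endpoint graph (edges are traced skeleton paths),
the reading of "network connectivity" used throughout; a per-pixel degree
variant is not provided. Isolated pixels and pure closed loops contribute
no nodes. The curve generator records the analytic chain length of each
rasterised polyline and the count of crossing clusters between distinct
curves, giving the skeleton metrics a ground truth (recovered within
10 %; ≈ 4 % in the shipped verification run).

## Orchestration and reproducibility

`run_pipeline()` executes the stages in dependency order from a config
list or YAML file, runs partial pipelines for partial configs, records
failed stages while completing independent ones, and stamps every report
with the config hash and seed. One global integer seed drives everything;
all generators derive child seeds deterministically from it
(`derive_seed()`), so identical configs are bit-identical across runs.
Degenerate inputs follow one rule throughout: generation is permissive
(one animal per group can be simulated), inference is strict (every test
refuses n < 2 per group).

## Verification problem sizes

The shipped verification (test suite and `scripts/acceptance.R`) runs at
the package's default study conditions: 500 null cohorts and 200
planted-effect cohorts at 31 ROIs × 300 volumes × 9/8 animals; 20
seed-map replicates on a 20³ grid (300 volumes for correlation recovery,
100 per animal for the group t-maps); 100 EMG replicates at n = 6/5 with
20 s recordings; 200 axon-table replicates at 500 axons per group; and
fixed geometric fixtures for the skeleton stage. These sizes give the
Monte-Carlo checks enough resolution for the tolerances they assert while
keeping a full run in the minutes range on one CPU.

## Known limitations

* Time series are i.i.d. over volumes; no autocorrelation or hemodynamic
  model, so variance of \(\hat z\) in real data will exceed \(1/(T-3)\).
* No partial correlation, regularised precision, or sliding-window FC.
* No cluster-extent inference on voxel maps.
* The BH any-rejection caveat above: the screen controls FDR, and its
  global-null any-rejection rate runs slightly above α under edge
  dependence.
* Skeleton metrics assume 2-D images; confocal stacks must be projected
  upstream.
* The shipped atlas reproduces a 9-division / 31-subregion hierarchy with
  standard abbreviations, but several subregion names are documented
  placeholders rather than a published table.
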