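---
title: "Methods: resting-state connectivity, regional homogeneity and mediation with ground-truth cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resting-state connectivity, regional homogeneity and mediation with ground-truth cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`restfc` implements a complete resting-state fMRI analysis chain that links
executive function (EF) and episodic memory (EM) through functional
connectivity (FC), together with a synthetic-data generator whose planted
structure makes every stage verifiable. This vignette explains the models,
the tunable parameters, the numerical choices, and what the package's tests
do and do not establish.

## The analysis chain

The pipeline mirrors the standard single-site aMCI-versus-control design:

1. **Temporal preprocessing** per subject: discard the first 10 volumes
   (T1 equilibration), per-voxel linear detrending, 0.01–0.08 Hz band-pass,
   and nuisance regression of the six head-motion parameters, the global
   mean, and WM and CSF mean signals. The order is fixed and the operations
   are mask-respecting.
2. **Motion quality assurance**: framewise RMS displacement (dRMS) is the
   root mean square of the six backward-differenced realignment parameters,
   rotations mapped to arc length on a 50 mm sphere. Transitions with
   dRMS > 0.5 mm flag the later volume plus one back and two forward;
   flagged volumes are deleted before connectivity analysis. Subjects with
   any cumulative parameter beyond 2 mm or 2 degrees are excluded, and the
   groups' mean dRMS values are compared with a two-sample t-test.
3. **Regional homogeneity (ReHo)**: Kendall's coefficient of concordance
   (KCC) of each voxel's time series with its 26 neighbours,
   `W = 12 S / (k^2 (n^3 - n))` over within-series time ranks. Maps are
   divided by their whole-brain mean and then smoothed (8 mm FWHM). Seeds
   are discovered as clusters of the covariate-adjusted ReHo group
   difference; which discovered regions to carry forward is a user
   judgement, with the DLPFC-like and RSC-like regions the intended pair.
4. **Seed-based FC**: on the scrubbed series, the data are smoothed (8 mm),
   the seed's mean time course extracted, every in-mask voxel correlated
   with it, and correlations Fisher z-transformed. ReHo, by contrast, is
   computed on *unsmoothed* data and the map smoothed afterwards: smoothing
   data before ranking would manufacture local concordance.
5. **Group statistics**: one-sample t maps per group with Bonferroni
   familywise control (p < 0.01) and a positive-connectivity restriction;
   a per-voxel GLM of FC on group with age, gender, education and the
   voxel's (half-logit, smoothed) gray-matter value as covariates; cluster
   tabulation at voxel p < 0.005 with a 74-voxel (1,998 mm^3) extent rule;
   behaviour–FC regressions in patients at {p < 0.05, 389 voxels
   (10,503 mm^3)} with an EM-by-EF conjunction (voxelwise intersection).
6. **Cluster-extent calibration**: an AlphaSim-style Monte-Carlo that
   smooths unit white noise to the nominal FWHM, standardizes it exactly
   (the per-voxel variance of separable Gaussian smoothing is the product
   of per-dimension sums of squared kernel weights, so standardization is
   analytic rather than empirical), thresholds two-sided, and records the
   largest per-sign 26-connected cluster. The extent threshold is one voxel
   above the (1 − alpha) order statistic of the null maxima. The mm^3
   values above depend on the mask and true smoothness of the original
   study and are kept as configurable defaults, not as quantities this
   package can re-derive.
7. **Composites and mediation**: raw test scores are z-scored against the
   pooled mean and sample SD of all subjects; EM is the mean of the three
   delayed-recall z-scores, EF of the three timed z-scores (no sign flip:
   a higher EF composite means slower, worse performance, which is why the
   EM–EF association is negative). Mediation of the EF→EM effect through
   extracted FC strength uses the three-step OLS system
   `Y = cX`, `M = aX`, `Y = c'X + bM` (intercepts always included);
   mediation requires c significant, a and b significant, and either c'
   insignificant (full) or |c'| < |c| (partial); the mediated fraction is
   `(a b)/c`, suppressed when c is insignificant because the ratio is
   unstable near c = 0. A Sobel z for `a b` is reported as a supplementary
   statistic only.

## The synthetic cohorts

The generator works on a 24 × 28 × 24 grid at 3 mm (an ellipsoidal brain of
~5,700 voxels) with two seed boxes, six target regions named for the two
networks (MCC, caudate, ACG/SMA, bilateral IPL, PCC/precuneus), and WM/CSF
compartments. Design choices that matter:

* **Signals.** Latent series are white noise band-pass filtered into
  0.01–0.08 Hz, so preprocessing is approximately transparent to them.
  Seed voxels carry their seed latent with a group-specific "hotspot gain"
  (default 0.7 in controls, 0.35 in patients): the gain is the shared
  fraction of voxel variance and is what the ReHo group difference
  recovers. Target voxels mix the parent seed latent with weight
  `tanh(z_i)`, where `z_i` is the subject's planted Fisher-z coupling
  (group value + N(0, sd_fc) noise), a region-wide band-limited signal
  carrying the rest of the shared variance, and voxel-private white noise
  sized by the region-coherence parameter (default 0.8). Smoothing averages
  the private noise away, so the planted correlation is recovered at region
  interiors. All brain voxels additionally share a global fluctuation
  (amplitude 0.4) and WM/CSF carry their own compartment signals, giving
  the nuisance regression real work to do.
* **Phenotypes.** EF is drawn per group from the calibration targets
  (patients 0.44 ± 0.95, controls −0.27 ± 0.52 on the pooled-z scale);
  the mediator is the planted seed→MCC coupling, `FC = a·EF + noise`; and
  `EM = c'·EF + b·FC + noise`, with group baselines and residual SDs solved
  so the EM composites hit their targets (−0.74 ± 0.71 / 0.50 ± 0.51).
  Defaults `a = 0.15`, `b = −0.858`, `c' = −0.1713` give a total effect
  `c = −0.3` and a mediated fraction `(a b)/c = 0.429`, with within-patient
  EM–EF correlation ≈ −0.40 (R² ≈ 0.16). `sd_fc = 0.25` was chosen so the
  b-path is estimable at a realistic patient-group size (n = 79), the
  regime in which this design is actually fielded.
* **Raw test scores.** The member tests of each composite are the latent
  factor plus zero-sum triplet noise mapped to plausible raw units (words
  recalled, seconds). Zero-sum noise makes pooled z-averaging reconstruct
  the latent composite exactly, so mediation recovery is not diluted by
  test unreliability; the marginal distributions of single tests are
  generator conventions, not calibrated quantities. Because pooled
  z-scoring centres composites on the cohort mean, the printed group
  targets (whose weighted mean is ~0.01, not 0) are reachable only up to
  that offset.
* **Motion.** Baselines are low-amplitude random walks; a spike is a
  sustained step of `spike_mm` on all three translation axes, so one spike
  produces exactly one large transition (dRMS = spike_mm/√2) and the
  {one back, flagged, two forward} scrub set. A 3 mm step trips the 2 mm
  exclusion rule.
* **Gray matter.** Smooth logistic-scale random fields with tissue-typical
  levels, clamped inside (0, 1) so the half-logit transform is finite;
  patients lose `atrophy_effect` probability mass over the seed regions.

## What the tests show — and what they cannot

Recovery checks compare pipeline output against generative parameters:
results from real cohorts depend on the subjects' raw images and on
mask and smoothness properties that a phantom cannot reproduce. The planted
Δz = 0.3 seed→MCC difference is detected at the {p < 0.005, 74-voxel} rule
with the planted effect inside the peak's 95% CI (n = 30/group,
200 volumes); the mediated fraction 0.429 is recovered as the mean fitted
`(a b)/c` over 200 phenotype cohorts of 79 patients; and null cohorts stay
clean at the package's own Monte-Carlo extent threshold. Two caveats are
worth stating plainly. First, global-signal regression in a small phantom
brain (where coherent regions are a sizeable fraction of the mask) shifts
recovered correlations down by roughly 0.1 and attenuates group differences
by ~10–15%; this is the familiar GSR anticorrelation effect, exaggerated by
the phantom's geometry, and it is why wide confidence intervals rather than
point equality are the right acceptance currency at image level. Second,
the phantom has no anatomy, no physiological noise spectra, and no
motion-image interaction (motion traces are generated independently of the
volumes), so passing tests validate the *statistical machinery*, not its
robustness to real-scanner artefacts.

## Numerical choices

* Band-pass: zero-phase order-5 Butterworth applied in the frequency domain
  (squared magnitude response) after odd-reflection padding. A rectangular
  FFT filter was rejected: on 230-volume series its spectral leakage passes
  ~11% of a 0.005 Hz sinusoid's amplitude, while the Butterworth keeps the
  0.04 Hz response above 0.99 and the 0.005 Hz response near 0.025.
* KCC uses first-occurrence ranking with no tie correction (BOLD values are
  continuous; constant series warn). Edge voxels use the in-mask
  neighbourhood with k = actual series count, requiring k ≥ 2.
* Smoothing is mask-respecting (ratio-of-convolutions), so no intensity
  bleeds across the mask boundary; FWHM 0 is the identity.
* Cluster formation is 26-connective by default (6/18 available), per-sign,
  with extents reported in voxels and mm^3 (27 mm^3 per voxel at 3 mm).
* Fisher z clamps |r| ≥ 1 to 1 − 1e−7 with a warning; zero-variance voxels
  yield r = 0 and are flagged.
* The one-sample familywise rule is Bonferroni over in-mask voxels:
  conservative, deterministic, and independent of smoothness assumptions.
* All randomness flows from one integer seed; per-subject seeds are derived
  linearly modulo a 32-bit prime, so any subject's volume can be
  regenerated in isolation and a fixed seed makes pipeline summaries
  byte-identical.
* Desk-scale problem sizes (default cohorts of 12/12 at 120 volumes for
  interactive runs; 30/group at 200 volumes for the recovery studies;
  5,000 iterations for extent calibration) keep a full validation run in
  the tens of minutes on one core.

## Open choices made here

The exclusion rule is applied to cumulative (not framewise) motion,
reading "throughout the scan" as a bound on total excursion. ReHo runs on
unscrubbed (motion-regressed) data, keeping neighbourhood rank structure
intact, while FC uses scrubbed series with deleted volumes and degrees of
freedom from the retained count. Behavioural regressions enter EM and EF
in separate models by default. The mediation model is unadjusted
(covariate adjustment is available and preserves the OLS identity
`c = c' + a b`, which holds to 1e−10 whenever the three fits share one
design). Discovered seed ROIs are full surviving clusters rather than
spheres; sphere seeds remain available.
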