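---
title: "Simulating and measuring diffusion along the perivascular space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and measuring diffusion along the perivascular space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtialps)
```

## The measurement model

The glymphatic system is the brain's hypothesised waste-clearance
pathway: cerebrospinal fluid enters the perivascular spaces around
penetrating vessels, exchanges with interstitial fluid through
astrocytic AQP4 water channels, and drains toward the lymphatics.  The
DTI-ALPS technique probes this indirectly with diffusion MRI.  At the
level of the lateral ventricle bodies, the deep medullary veins — and
the perivascular spaces around them — run right–left (the x axis),
while the dominant white-matter fibers of the neighbouring *projection*
region run inferior–superior (z) and those of the *association* region
run anterior–posterior (y).  The x direction is therefore perpendicular
to the fibers of both regions, and any *excess* x diffusivity there is
attributed to water movement along the perivascular channels.

The ALPS index condenses this into a ratio of ROI means:

$$\mathrm{ALPS} \;=\;
  \frac{\mathrm{mean}(D_{xx,\mathrm{proj}},\, D_{xx,\mathrm{assoc}})}
       {\mathrm{mean}(D_{yy,\mathrm{proj}},\, D_{zz,\mathrm{assoc}})}$$

A value near 1 means x diffuses no faster than the fiber-perpendicular
reference directions (minimal perivascular flow); larger values mean
increased diffusivity along the perivascular axis.  The index is
computed per hemisphere from four spherical ROIs (projection and
association, left and right) and the two hemisphere indices are
averaged arithmetically.  Whether to average indices or to pool the
underlying diffusivities across hemispheres is genuinely ambiguous in
the method literature; this package averages indices, and implements
the pooled-diffusivity alternative only as a cross-check oracle inside
the test suite, where the two conventions are shown to differ on
asymmetric phantoms.

## The synthetic cohort

No subject-level data are distributed with the method, so the package
is built around a generator whose defaults encode the published study
conditions: 30 subjects with normal glucose metabolism (NGM), 22 with
prediabetes (Pre-DM) and 18 with type 2 diabetes (T2DM); true ALPS
distributions of 1.58 ± 0.20, 1.43 ± 0.08 and 1.36 ± 0.14; and the
published covariate profiles (age, sex, education, hypertension and
hyperlipidemia prevalence, total Fazekas scale, HOMA-IR and the three
glycemic markers).  One ambiguity is worth noting: the study abstract
reports 33 NGM controls while the cohort table reports 30; the
generator follows the table.  Intracranial volume is not part of the
published profile, so its default (1.45 × 10⁶ ± 1.4 × 10⁵ mm³) is a
typical older-adult distribution, identical across groups.

Three generator choices deserve explanation:

* **Label-consistent glycemic markers.**  Group labels must survive
  reclassification by the diagnostic thresholds (T2DM if FPG ≥ 126
  mg/dL, 2-h OGTT ≥ 200 mg/dL or HbA1c ≥ 6.1 %; NGM only if FPG < 110
  *and* OGTT < 140 *and* HbA1c < 5.4; Pre-DM otherwise).  Markers are
  drawn from the group's normal distribution truncated to a
  label-consistent range: NGM subjects are truncated into the NGM
  ranges, Pre-DM subjects have HbA1c pinned to its 5.6–6.0 band (which
  alone guarantees the label, and lets FPG and OGTT stay below the
  T2DM thresholds without being forced into their nominal Pre-DM
  bands — the published Pre-DM group has mean FPG 99, well inside the
  NGM range), and T2DM subjects have HbA1c ≥ 6.1 with FPG and OGTT
  free.  Truncated normals are sampled by inverse-CDF, so draws are
  exact and reproducible.  The diagnostic table leaves narrow bands
  uncovered (HbA1c 5.4–5.6, FPG 125–126, OGTT 199–200); the generator
  never emits values there, and the classifier assigns such values to
  Pre-DM with a warning.

* **A one-parameter ALPS family.**  Ground truth fixes
  $D_{yy,\mathrm{proj}} = D_{zz,\mathrm{assoc}} = 1.0\times10^{-3}$
  mm²/s and sets $D_{xx,\mathrm{proj}} = D_{xx,\mathrm{assoc}} =
  \mathrm{ALPS}\times10^{-3}$, so the index is exactly invertible from
  the stored diffusivities and recovery errors are attributable to the
  imaging chain alone.

* **Calibrated insulin-resistance coupling.**  HOMA-IR is generated as
  $\mu_H(g) + c\,s_H(g)\,z_A + s_H(g)\sqrt{1-c^2}\,\varepsilon$, where
  $z_A$ is the subject's standardised within-group ALPS deviation.
  The target is a *population partial correlation* of ALPS with
  HOMA-IR given the seven model covariates (default −0.35).  Because
  the groups differ in both ALPS and HOMA-IR means, and the covariates
  only partly track group membership, the partial correlation is not
  simply $c$: it contains a between-group component.  The calibration
  computes the exact population moment structure implied by the
  configuration — mixture over groups, covariates independent of ALPS
  within group, the Fazekas integer distribution handled by its exact
  discretised-normal probability mass function — and solves the
  resulting linear equation for $c$.  Targets outside the achievable
  range raise an error naming the variance parameters that constrain
  it.  Two approximations are documented rather than corrected: the
  true ALPS distribution is truncated at zero (immaterial at the
  default parameters, where the truncation probability is below
  10⁻¹⁰), and HOMA-IR is left untruncated, so a T2DM subject
  (1.7 ± 1.3) can in principle draw a small negative value; truncating
  would distort the calibrated correlation, and the linear-Gaussian
  emulation is anyway only an approximation to the right-skewed
  distribution of real HOMA-IR.

## The digital phantom

The phantom is a 64³ grid of 1.8 mm isotropic voxels (RAS, pure
scaling affine) holding an idealised periventricular geometry: a
CSF-like ventricle slab on the midline (isotropic
3.0 × 10⁻³ mm²/s), flanked per hemisphere by a projection band
(diagonal tensor, principal eigenvalue 1.7 × 10⁻³ mm²/s on z) and an
association band (principal eigenvalue on y), embedded in isotropic
parenchyma (0.8 × 10⁻³ mm²/s).  The bands are slabs at fixed
millimetre offsets, so the four 5.4 mm ROIs — centred on voxel centres
at ±14.4 mm (projection) and ±28.8 mm (association) from the midline —
lie strictly inside their bands on any grid of at least 44 voxels per
axis.  The main text of the method describes 5.4 mm ROIs while a
figure caption says 5 mm; the package defaults to 5.4 and exposes the
diameter as a parameter.  Spheres are voxelised by voxel-centre
inclusion with no partial volumes (at this grid ratio a 5.4 mm sphere
is a 19-voxel quasi-sphere); ROI means are unweighted voxel averages.

Realism deliberately stops here: there is no brain-shaped anatomy, no
partial-volume mixing, no crossing fibers, and no susceptibility or
motion artifacts.  The published workflow removes those artifacts with
external preprocessing tools before tensor fitting, so the simulation
generates data as if that preprocessing had already succeeded, and the
corresponding pipeline stage is an explicit no-op.  Registration to a
standard FA template is likewise replaced by simulating directly in
template space with known ROI coordinates (a per-ROI centre shift is
available to mimic manual placement adjustments).  Consequently,
passing recovery tests demonstrate correctness of the estimator chain
under the stated signal and noise model — not robustness to anatomy,
registration error, or artifact residue in real data.

## Acquisition, noise and tensor estimation

The simulated acquisition mirrors the published protocol: one b = 0
volume plus 64 gradient directions at b = 1000 s/mm², with directions
spread by a deterministic golden-angle spiral.  Signals follow the
monoexponential Stejskal–Tanner model
$S = S_0\exp(-b\,g^\top D g)$, and magnitude noise is Rician:
$\sqrt{(S+\varepsilon_1)^2 + \varepsilon_2^2}$ with
$\varepsilon_i \sim N(0, \sigma S_0)$.  The default σ of 0.01 (SNR 100
at b = 0) matches the noise level at which recovery is assessed.  Each
subject's noise stream is seeded as `master_seed + subject index`, so
a cohort is a pure function of its configuration and seed, and
re-running a simulation reproduces byte-identical files.

Tensor fitting is plain ordinary least squares on log-signals — the
estimator named by the published workflow — with the design row
$[-b g_x^2, -2b g_x g_y, -2b g_x g_z, -b g_y^2, -2b g_y g_z, -b g_z^2, 1]$
matching the stored element order (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz,
log S₀).  Two numerical choices are package decisions, as the source
workflow does not state its internals: non-positive signals (possible
under Rician noise) are clamped to 10⁻⁶ of the voxel's b = 0 signal
before the log, with the clamp count logged as a QC counter, and
voxels with non-positive b = 0 signal are dropped from the mask.  No
weighted least squares and no positive-definiteness projection are
applied; negative eigenvalues are clamped to zero only inside the FA
computation, which keeps FA within [0, 1].  Eigenvalues come from the
closed-form trigonometric solution for symmetric 3 × 3 matrices,
vectorised over voxels and verified against LAPACK in the tests.

## Statistics

The statistical layer reproduces the study's analysis plan:

* **Group comparison** — one GLM of the bilateral ALPS index on group
  dummies (NGM reference) plus seven covariates (sex, age,
  intracranial volume, education years, hypertension and
  hyperlipidemia history, total Fazekas scale), two-sided t tests on
  the three pairwise contrasts, Bonferroni family-wise correction
  (`min(1, 3p)`; the published corrected p of exactly 1.00 is only
  attainable under Bonferroni-style capping, which motivated the
  choice — the correction method itself is not stated at the source).
* **Cohen's d** — computed from raw group means and SDs with the
  n-weighted pooled SD, $S_c = \sqrt{(n_1 s_1^2 + n_2 s_2^2)/(n_1 +
  n_2)}$, exactly as printed (no $n-2$ correction), with strict
  magnitude bounds 0.2/0.5/0.8.  Adjusted contrasts and unadjusted
  effect sizes intentionally coexist in one table, mirroring the
  source analysis.
* **Partial correlation** — residualise ALPS and HOMA-IR on the seven
  covariates and correlate the residuals, with $t = r\sqrt{df/(1-r^2)}$
  and $df = n - k - 2$; the identity with the GLM coefficient t
  statistic is asserted to 10⁻⁸ in the tests.  The df convention is
  not stated at the source; the chosen one is documented and
  oracle-tested for internal consistency.
* **Screening and demographics** — variance inflation factors by the
  $1/(1-R^2)$ definition (perfect collinearity reported as infinite
  with a flag), Kruskal–Wallis for continuous demographic comparisons
  (applied pairwise for the two-group table entries, where it reduces
  to a rank-sum-style comparison; whether the source used pairwise
  rank tests or post-hoc procedures is not stated, so both the omnibus
  and pairwise modes are exposed), and Fisher's exact test for
  categorical ones.  These standard tests are delegated to base R
  (`kruskal.test`, `fisher.test`); the test suite checks them against
  hand-ranked and exhaustive-enumeration oracles.

## Problem sizes and runtime choices

The full pipeline on the default 64³ grid takes a few seconds per
subject, dominated by drawing the ~34 million Gaussian variates of the
noise field.  The test suite therefore runs its imaging checks on a
44³ grid — the smallest that contains the association ROIs with
margin — which changes nothing about the estimator chain (ROI voxel
counts and noise statistics are identical; only the amount of
background differs).  Recovery checks use 100 noiseless subjects for
the exactness bound (≤ 10⁻⁴ relative error, in practice ~10⁻¹²
in-memory and ~10⁻⁷ through 32-bit NIfTI files), the full 70-subject
cohort at 1 % noise for parameter recovery (group means within 2 SEM),
500 cohorts of n = 40 for coupling recovery (mean within 0.03 of the
target), and 2000 null replicates for type-I calibration
(5 % ± 1.5 %).

## Known limitations

Beyond the phantom simplifications above: the generator's covariates
are mutually independent within group (real cohorts correlate age,
hypertension and Fazekas burden), so covariate adjustment is easier
here than in practice; HOMA-IR is Gaussian rather than right-skewed;
the acquisition is single-shell with a single b = 0; and the published
group-mean reproduction targets population parameters read from a
table of a 70-subject study, so its check is inherently a
parameter-recovery statement about the simulator, not a replication of
the original subjects.
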