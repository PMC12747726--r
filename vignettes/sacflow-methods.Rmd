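---
title: "Aneurysmal hemodynamics, velocity informatics and rupture modeling with sacflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aneurysmal hemodynamics, velocity informatics and rupture modeling with sacflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sacflow)
```

# Scope and model of the data

`sacflow` post-processes time-resolved flow in intracranial aneurysm (IA)
sacs. It does not solve the Navier-Stokes equations: the expected upstream
producer of its inputs is a CFD solver (or 4-D flow imaging), and a seeded
synthetic generator stands in for those inputs so every downstream method is
testable without patient data. All analyses are confined to the isolated
sac. Units are mm, mm/s, Pa and seconds throughout, with one cardiac cycle
sampled by default at 20 equispaced frames over 1 s.

Three containers carry the data:

* `AneurysmDomain` — a voxelized sac (an idealised sphere truncated by the
  ostium plane), plus a near-uniform Fibonacci tiling of the sac surface
  into wall nodes with outward normals and area weights.
* `FlowSeries` — per-frame 3-D velocity vector fields on the domain grid.
* `WallShearSeries` — per-node wall shear-stress vector time series with
  area weights.

# Blood rheology

Four viscosity laws are implemented in `viscosity()`:

* Newtonian: constant $\mu = 0.004$ Pa s (density $\rho = 1050$ kg/m$^3$).
* Carreau-Yasuda:
  $\eta(\dot\gamma) = \eta_\infty + (\eta_0-\eta_\infty)\,
  [1+(\lambda\dot\gamma)^a]^{(n-1)/a}$ with $\eta_0 = 0.16$ Pa s,
  $\eta_\infty = 0.004$ Pa s, $\lambda = 8.2$ s, $a = 0.64$, $n = 0.2128$.
  The law is continuous, non-increasing and bounded by its two asymptotes;
  at high shear it converges to the Newtonian value, which is why
  high-shear regions differ negligibly between the two models while
  low-shear regions diverge.
* Herschel-Bulkley:
  $\eta = \tau_0/\dot\gamma + k\,(\dot\gamma/\dot\gamma_c)^{n-1}$ with
  $\tau_0 = 0.01$ Pa, $k = 0.04$, $n = 0.7$, $\dot\gamma_c = 0.001$
  s$^{-1}$.
* Casson: only hematocrit ($H = 0.40$) and plasma viscosity (1.4 mPa s)
  are standard inputs, so the Merrill closure is adopted:
  $\tau_{0} = 0.1\,(0.625H)^3$ Pa,
  $\eta_c = \eta_{plasma}(1-H)^{-5/2}$, and
  $\eta(\dot\gamma) = (\sqrt{\tau_0/\dot\gamma}+\sqrt{\eta_c})^2$. This is
  an assumption: commercial solvers do not document their exact Casson
  parameterisation, and any hematocrit-consistent closure produces the same
  qualitative shear-thinning.

The Casson and Herschel-Bulkley laws diverge as $\dot\gamma \to 0$;
evaluations clamp the shear rate from below at `gammaFloor` ($10^{-6}$
s$^{-1}$ by default), mirroring the internal clipping finite-volume solvers
apply. `strainRateMagnitude()` computes $\dot\gamma = \sqrt{2\,S:S}$ from
central differences (one-sided at faces), and `reynoldsNumber()` implements
$Re = 4\rho Q/(\pi\mu D)$.

`wallShearFromFlow()` is the package's mechanistic link between rheology
and wall shear: at each wall node the tangential velocity is interpolated
one voxel inside the wall, the near-wall shear rate is
$\dot\gamma = |v_t|/h$, and $\tau = \eta(\dot\gamma)\,\dot\gamma\,\hat t$.
This first-order wall model is deliberately simple — it is not a resolved
boundary layer — but it responds to the viscosity law exactly where
shear-thinning matters, so paired Newtonian/non-Newtonian comparisons have
a genuine mechanistic difference rather than an injected one.

# Wall-shear-stress metrics

All time integrals are cyclic trapezoids: the segment from the last frame
back to the first (closing the cardiac cycle) is included. Spatial
aggregates are area-weighted (mesh-independence); a count-weighted OSI is
available via `osiWeighting = "count"`.

* TAWSS per node: $\frac{1}{T}\int |\tau|\,dt$; STA-WSS is its
  area-weighted mean.
* WSS-max: maximum $|\tau|$ over nodes and frames.
* WSS-min: "spatiotemporally averaged minimum" is ambiguous in common
  usage; the default reading is the time average of the per-frame spatial
  minimum, with `minMode = "global_min"` as the alternative.
* LSA: percent of wall area with TAWSS strictly below 2 Pa.
* OSI $= \tfrac12\big(1-|\int\tau\,dt| / \int|\tau|\,dt\big)$ (He-Ku
  form), defined as 0 for a node whose shear vanishes at every frame.
* RRT $= 1/((1-2\,\mathrm{OSI})\cdot\mathrm{TAWSS})$ (Himburg form), with
  the denominator clamped at $10^{-6}$ so fully oscillatory nodes stay
  finite (clamps are reported via a message).

# Vortex analysis

`lambda2Field()` forms the velocity-gradient tensor by central differences,
splits it into symmetric ($S$) and antisymmetric ($\Omega$) parts, and
returns the middle eigenvalue of $S^2+\Omega^2$ via the closed-form
trigonometric symmetric eigensolve (vectorized over the volume; accuracy
about $10^{-8}$ relative near repeated eigenvalues, which only matters at
the $\lambda_2 \approx 0$ boundary). Swirling regions are
$\lambda_2 < 0$; a Q-criterion alternative is available for sensitivity
checks. Components smaller than 8 voxels are discarded (26-connectivity).

The degree of vortex overlap (DVO) is defined here as the cyclic
consecutive-pair Dice coefficient of the vortex masks, averaged over the
cycle: 1 for a temporally stable vortex, decreasing with vortex movement.
A frame pair with two empty masks contributes 1 (no vortex, no movement);
exactly one empty mask contributes 0. An alternative `mode = "reference"`
compares each frame against the union of all masks; consecutive-pair is
the default because it directly expresses temporal stability. Vt/V is the
time-averaged fraction of sac voxels inside the vortex masks.

# Directional velocity informatics

The encoding maps each voxel's angle $\theta \in [0,\pi]$ between its
velocity and the inflow-jet direction linearly to gray
$\mathrm{round}(255\,\theta/\pi)$ (half-up rounding, fixed across
platforms): flow aligned with the jet is dark, opposed flow is bright.
The linear-in-angle map is the simplest monotone choice consistent with
that semantics. Voxels slower than `vFloor` ($10^{-6}$ mm/s) are excluded.
The jet direction is estimated as the mean velocity in the one-voxel
neighbourhood of the ostium plane at the peak-speed frame, falling back to
the sac-mean direction when the ostium flux is near zero.

Features (74 total: 18 first-order, 24 GLCM, 16 GLRLM, 16 GLSZM) follow
the IBSI reference definitions. First-order features always use the raw
0-255 gray; matrix features use an equal-width quantization, default 16
levels (configurable). GLCM and GLRLM matrices are built at distance 1
for the 13 unique 3-D directions and the per-direction features averaged;
GLCM matrices are symmetric and normalized per direction. GLSZM zones are
26-connected equal-level components. Degenerate conventions (constant
volume): skewness/kurtosis 0, GLCM correlation and MCC 1, IMC1 0 — each
matching the brute-force oracles in the test suite entry for entry.

By default features are extracted from the peak-systole frame
(`frameMode = "peak"`); per-frame extraction with feature averaging is
available, since temporal handling is a genuinely open choice for this
method family.

# Agreement statistics

`rpd()` is the symmetric relative percent difference
$100\,|a-b|/\big((|a|+|b|)/2\big)$ (0 when both magnitudes vanish);
`blandAltman()` returns bias and bias $\pm 1.96\,\mathrm{sd}$ limits;
`slopeAndPcc()` fits ordinary least squares with a free intercept (a
through-origin option exists). `wilcoxonRankSum()` enumerates all group
assignments exactly (mid-rank ties) when $n_1+n_2 \le 12$ and otherwise
uses the normal approximation with continuity correction. `pairedT()`
defines $p = 1$ for identically zero differences and rejects the
zero-variance nonzero case.

`artAnova()` implements the aligned rank transform for the location
(3-level, between-case) by rheology-model (2-level, within-case) factorial:
for each effect the responses are aligned by removing the cell-mean
estimates of all other effects, ranked with mid-rank ties, and tested in a
fixed-effects two-factor ANOVA on ranks (sequential sums of squares; only
the aligned effect's row is read from each fit). Two design notes:

* An earlier variant additionally removed each case's deviation from its
  location-cell mean as a blocking term; a null simulation showed that
  inflates the type-I error to 0.12-0.26, so the standard fixed-effects
  alignment is used and `caseId` only validates the paired structure.
* With the 112-case 39/52/21 design, a 3000-replicate null simulation gave
  per-effect type-I rates 0.046/0.056/0.055 at $\alpha = 0.05$; type-III
  tests were conservative for the 2-level model effect (0.031-0.033),
  which is why sequential SS is used.

No multiple-testing correction is applied to per-feature p-values by
default (raw p-values are reported, as is conventional for descriptive
feature screens); Benjamini-Hochberg is available via `p.adjust` on the
returned values.

# Rupture-status modeling

The protocol: Wilcoxon pre-filter dropping features with $p > 0.8$
(constant columns are retained but flagged); a morphological baseline
(aneurysm location one-hot, parent vessel diameter, ostium minimum, NRV2);
greedy forward augmentation by pooled 10-fold cross-validated AUC with a
stopping tolerance of 0.002 and at most 3 added features (three is what a
well-tuned augmentation of this kind typically admits before gains vanish);
then 100 stratified 9:1 train/test repeats, standardizing on the training
data only (leakage prevention), tuning the linear-SVM cost over
$2^{-5..5}$ by 10-fold CV AUC within each training set, and averaging
held-out AUC and per-class accuracy. The SVM is unweighted despite the
44/68 class imbalance — matching the characteristically low ruptured-class
accuracy such models report. AUC uses the exact rank (Mann-Whitney)
formula on decision values. SHAP attributions use the exact linear form
$\phi_j(x) = w_j(x_j-\bar x_j)$ with base value $f(\bar x)$, valid because
the kernel is linear; positive attributions push toward the ruptured class.

One subtlety worth recording: the sign of `e1071` decision values follows
the order in which classes first appear in the training data, not the
factor level order; scores are re-oriented from the model's internal label
order so "larger = more ruptured" holds in every fold.

A second subtlety concerns null-model checks. Even with all effect sizes
zero, the mean held-out AUC over repeated splits of one finite cohort is
biased away from 0.5 by up to about 0.1: the training and test portions of
a fixed cohort have anti-correlated spurious feature-label associations.
Sanity checks therefore average over several independent null cohorts
(5 cohorts x 20 repeats), which restores means of 0.48-0.51.

# Synthetic data: what it emulates and what it does not

`makeDomain()` builds a spherical sac truncated by the ostium plane
(neck radius sets the truncation); the default cohort geometry spans
2.5-4 mm radii. `makeFlowSeries()` sums Lamb-Oseen swirling cores
($v_\theta(r) = \frac{\Gamma}{2\pi r}(1-e^{-r^2/r_c^2})$, chosen for
smoothness and a known $\lambda_2$ sign structure), a uniform inflow jet,
and seeded Gaussian noise, all scaled by a positive waveform — by default a
raised-cosine pulse peaking at 30% of the cycle, since published inlet
waveforms are described rather than tabulated; any positive samples are
accepted. Core paths are explicit inputs, so DVO ground truth is
controllable. The composite field is not divergence-free (cores are
individually solenoidal, the jet is, the noise is not); no downstream
operation assumes incompressibility. Known limitation, accepted.

`makeWallShear()` constructs per-node series
$\tau(t) = m\,(\cos\theta\,\hat d + \sin\theta\,s(t)\,\hat e)$ with $s(t)$
a balanced square wave, which makes per-node OSI exactly
$(1-\cos\theta)/2$ under the cyclic trapezoid, and draws node magnitudes
as a low block (spread below 2 Pa, mean 1 Pa) plus a high block placed so
the area-weighted mean hits the TAWSS target — hence requested TAWSS, OSI
and LSA are recovered closed-loop to 5%, 0.02 and 0.05 respectively.
Infeasible combinations (for example LSA = 1 with TAWSS at or above 2 Pa)
are rejected rather than approximated.

`makeCohort()` emits the study-shaped cohort: 112 cases, 44 ruptured,
locations ICA/MCA/ACA at 39/52/21, morphology plus the 74 named features
as standardized Gaussians with configurable ruptured-group mean shifts.
Default velocity-feature shifts (about 0.4-0.5 on `GLCM.JointAverage`,
`GLCM.SumAverage`, `FirstOrder.Mean`, `FirstOrder.Range`) and morphology
shifts (0.6/0.2/0.8 on vessel diameter, ostium minimum, NRV2) reproduce
the magnitude of group separation such cohorts show; they were chosen once
from those reported group statistics and are not tuned. What the generator
does not emulate: inter-feature correlation structure, non-Gaussian feature
distributions, and any coupling between a case's flow field and its
feature vector — so passing tests demonstrate the correctness of the
pipeline's statistics and mechanics, not clinical performance on real
cohorts.

# Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale by design:
sac radii about 3 mm at 0.3-0.4 mm spacing (roughly $20^3$-$30^3$ grids),
8-20 frames, 20-seed closed-loop checks, 500-replicate ART null
simulations, and 100 total split repeats for the ML checks. Oracle
equivalence for the texture features is property-tested on 50 seeded
volumes of at most $5^3$ voxels against independent loop-based
implementations. Tie-breaks and tolerances: half-up rounding in the gray
encoding; strict inequality at the 2 Pa LSA threshold; RRT denominator
floor $10^{-6}$; vortex components under 8 voxels discarded; cost grid
ties resolved toward the smaller cost.

# Limitations

The wall model is first-order (no boundary-layer resolution), the
synthetic flow is kinematic rather than dynamic, vortex DVO semantics
follow this package's Dice definition (original formulations of the
overlap notion vary), and the cohort generator's independence assumptions
are stated above. VTK support covers legacy structured-points ASCII only;
the native container is the primary interchange format.
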