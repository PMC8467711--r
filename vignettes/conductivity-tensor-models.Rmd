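---
title: "Conductivity tensor reconstruction from multi-b diffusion MRI: models, simulator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conductivity tensor reconstruction from multi-b diffusion MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condtensor)
```

## The problem

Low-frequency electrical conductivity of tissue is anisotropic wherever
elongated cells align: extracellular ions are forced to drift along fibers,
so in white matter conductivity is a symmetric positive-definite 3×3
tensor $C$ (S/m). The same geometric restriction shapes water diffusion, so
$C$ and the water diffusion tensor $D$ (mm²/s) share eigenvectors, and a
family of *cross-property* models maps measured diffusion to conductivity.
This package implements five such reconstructions as one tested pipeline,
together with a forward simulator that produces every measurement they
consume, so the comparison between them can be reproduced without scanner
data.

The five models:

* **LEM** (linear eigenvalue model): $C = \eta D$ with one global
  $\eta$ — either the empirical constant $0.844\ \mathrm{S \cdot s/mm^3}$,
  or matched per subject by least squares from two reference regions,
  $\eta = (d_{WM}\sigma_{WM} + d_{GM}\sigma_{GM}) / (d_{WM}^2 + d_{GM}^2)$.
* **FEM** (force equilibrium model): $C = \eta D_f$ with the microscopic
  constant $\eta = 0.76\, q^2 N / k_B T$ (Stokes–Einstein drag balanced
  against the electric force), applied to the *fast* diffusion tensor of a
  bi-exponential fit.
* **VCM** (volume constraint model): per-voxel
  $\eta = 3\sigma_{iso}/\mathrm{trace}(D)$, so the mean conductivity is
  pinned exactly to an assigned isotropic literature (or measured) value.
* **VFM** (volume fraction model): diffusion eigenvalues are decomposed
  into fractions of three orthogonal fiber groups plus isotropic tissue;
  conductivity eigenvalues are the matching weighted sums of literature
  compartment conductivities. The only model that is not a scalar scaling
  of a diffusion tensor.
* **CTI** (conductivity tensor imaging): per voxel
  $\eta = \alpha \sigma_H / (\alpha d_e^w + (1-\alpha) d_i^w \beta)$,
  combining a high-frequency conductivity map $\sigma_H$ with the
  bi-exponential water-compartment estimates ($\alpha$ fast fraction,
  $d_e^w$, $d_i^w$ fast/slow diffusivities); $C = \eta D_e$. The only
  model sensitive to ion concentration differences.

## The stated world of the simulator

The generator defines per voxel: an extracellular diffusion tensor $D_e$,
an intracellular diffusivity $d_i^w$, an extracellular volume fraction
$\alpha$, and an apparent extracellular ion concentration $\bar c_e$. From
these it derives, in forward form,

$$C_{true} = \alpha \bar c_e D_e, \qquad
\sigma_H = \bar c_e\left(\alpha d_e^w + (1-\alpha) d_i^w \beta\right),$$

with $d_e^w = \mathrm{trace}(D_e)/3$ and $\beta = 0.41$ the assumed
intracellular-to-extracellular concentration ratio. Diffusion-weighted
signals follow the two-compartment decay
$S_i(b)/S_i(0) = \alpha e^{-b\, u_i^T D_e u_i} + (1-\alpha) e^{-b d_i^w}$
over fifteen shells from 50 to 5000 s/mm² (the published multi-b
protocol) and, by default, fifteen deterministic Fibonacci-hemisphere
directions (the in vivo protocol size; direction count is configurable).

**Phantom presets.** Two three-compartment phantoms reproduce the published
compositions: four electrolytes (EL1–EL4; $\alpha = 1$) and two
giant-vesicle suspensions (GVS1 $\alpha = 0.10$, GVS2 $\alpha = 0.50$) with
reference 10 Hz conductivities 1.56, 0.83, 0.29, 0.55, 0.70, 0.45 S/m.
Compartments are parallel cylinders in a masked-out background.

Choices the sources leave open, fixed once here:

* The compositions state mobility *classes*, not diffusivities. Defaults:
  high-mobility $d_e^w = 2.0\times10^{-3}$, low-mobility
  $1.1\times10^{-3}$, vesicle interior $d_i^w = 0.4\times10^{-3}$ mm²/s —
  ordinary magnitudes for saline and restricted compartments;
  configurable per compartment.
* $\bar c_e$ is in arbitrary units anchored by back-solving
  $\mathrm{mean}(C_{true}) = \sigma_{ref}$ per compartment, which makes
  every reconstruction error interpretable against the impedance-analyzer
  reference scale.
* Noise is off by default so the analytic acceptance checks are exact;
  Rician magnitude noise (`add_rician_noise()`) is seeded and applied to
  the weighted and unweighted images alike.

**Brain preset.** Nested ellipsoids: a CSF rim plus central ventricle
($\alpha = 1$, $D_e = 3.0\times10^{-3}$ mm²/s isotropic), a GM shell
($\alpha = 0.45$, $0.8\times10^{-3}$), and a WM core whose fibers circle
the ventricle in-plane with eigenvalues
$(1.7, 0.4, 0.3)\times10^{-3}$ mm²/s ($\alpha = 0.30$). Tissue
concentrations are anchored to the literature conductivities 0.14 / 0.27 /
1.79 S/m (WM/GM/CSF); an optional ±10 % linear in-plane concentration
gradient inside WM and GM (off in CSF, so its 1.79 S/m anchor is exact)
makes the true conductivity depart from any global rescaling of
diffusion — this is what drives the CTI-vs-diffusion decorrelation that a
global-scale model cannot show.

What the simulator does **not** emulate: partial-volume mixing at
boundaries, coil/EPI artifacts, spatially correlated noise, realistic
anatomy, or the MREPT reconstruction of $\sigma_H$ (the map is produced
directly). A green test therefore establishes correctness of the models
and estimators under their own assumptions, not robustness to real
acquisition physics.

## Numerical choices

**Units.** Diffusivities are always mm²/s, b-values s/mm², conductivities
S/m. Scale factors $\eta$ therefore carry S·s/(m·mm²); published
"S·s/mm³" constants are converted on ingestion by the documented factor
1000 (1/mm → 1000/m), so the empirical LEM constant is 844 internally and
the FEM constant $9.49\times10^{7}$ S·s/m³ becomes 94.9.

**Tensors.** Stored as six components in the fixed order xx, xy, xz, yy,
yz, zz. Eigenvalues are sorted descending per voxel (the sources never
state a sorting convention; no attempt is made to align eigenvectors
across voxels by fiber continuity). Fitted tensors with eigenvalues in
$[-10^{-12}\lambda_{max}, 0)$ are clamped to zero; stronger violations
raise an error.

**Bi-exponential fitting.** The model
$vf\, e^{-b d_f} + (1-vf) e^{-b d_s}$ under $vf + vs = 1$,
$d_f \ge d_s \ge 0$ is non-convex. The fitter is a damped (Levenberg–
Marquardt) least-squares iteration, vectorised across voxel/direction
rows, started from a fixed 27-point grid
($vf \in \{0.3, 0.5, 0.8\}$, $d_f \in \{1,2,3\}\times10^{-3}$,
$d_s \in \{0.1,0.3,0.5\}\times10^{-3}$). All 27 starts are *evaluated*
per row and the iteration runs from the best three; ties at the optimum
break toward larger $vf$. (A variable-projection variant that eliminated
$vf$ analytically was tried first and converged poorly on vesicle-like
decays; the full three-parameter iteration reaches machine-precision
residuals from any of the grid starts.) Identical decay rows are
deduplicated before fitting — an exact optimisation that makes
piecewise-constant synthetic volumes cheap while changing nothing for
real data. Rows whose rates merge within $10^{-5}$ mm²/s, or that a plain
log-linear mono-exponential fits at least as well, are reported as
mono-exponential with $vf = 1$ (the labels fast/slow are meaningless for
merged components). All of this is deterministic: no randomness anywhere
in the fits.

**Scalar summaries of the fit.** In `tensor6plus` mode the package uses
$d_e^w = \mathrm{trace}(D_f)/3$ (and likewise $d_i^w$ from $D_s$) rather
than the plain mean of directional rates: for anisotropic voxels the
directional mean depends on the direction set, while the trace form makes
the CTI inverse algebraically exact against the forward model above. In
`orthogonal3` mode (three orthogonal directions, the historical FEM
acquisition) the two coincide and plain means are used.

**DTI.** Log-linear least squares restricted to the b = 0 and
b = 700 s/mm² shell, per the published processing choice, even when other
shells exist.

**VFM.** With the literature diffusivities fixed, the mixture equations
are linear in the three fiber fractions; the 3×3 system is solved in
closed form, solutions are clipped to the simplex, and voxels needing
clipping beyond $10^{-6}$ are flagged ill-posed (the fit is known to fail
in noisy voxels). The transversal conductivity constraint
$\sigma_{t1} = \sigma_{t2}$ is enforced by averaging the two weighted
sums. The compartment conductivities are *not* printed in the comparison
source (cited to earlier work); they ship as documented stand-ins
$\sigma_{lW} = 0.65$, $\sigma_{tW} = 0.13$, $\sigma_{iso} = 0.27$ S/m,
$d_{lW} = 1.7$, $d_{tW} = 0.3$, $d_{iso} = 0.8 \times 10^{-3}$ mm²/s,
evaluated at b = 700 s/mm². A larger $\sigma_{lW}$ of 1.1 S/m was
considered and rejected: the implied conductivity anisotropy
($\sigma_{lW}/\sigma_{tW} = 8.5$) exceeds the diffusion anisotropy of a
typical bundle, which would *raise* the anisotropy ratio on near-pure WM
voxels — the opposite of the reduction (2.52 → 1.73) the comparison
reports for this model class.

**Erosion.** ROI masks are eroded in-plane (per slice) with a 3×3 cross,
twice by default, matching the stated two-pixel peel; SD is the sample
($n-1$) convention; relative errors are absolute percentages while
relative-difference maps keep their sign
($rd = (\sigma_{ref} - \sigma_{mth})/\sigma_{ref} \times 100\%$).

## What the tests establish

* Exact algebra: calibrated VCM errors are zero on electrolytes; LEM and
  FEM are bitwise identical across compartments differing only in ion
  concentration; $R^2 = 1$ for regressions of LEM/FEM output against
  their own input tensors; anisotropy ratios are preserved by all
  scalar-scaling models and reduced by VFM.
* Inverse consistency: the noiseless CTI chain recovers the true
  conductivities to well below 0.1 % on the phantom presets (errors come
  only from the bi-exponential fit), far inside the 1.10–5.26 % envelope
  reported for the physical phantoms.
* Oracle equivalence: eigendecompositions agree with a characteristic-
  polynomial root solver; the VFM fraction solver inverts its forward
  mixture to $10^{-8}$.
* Stochastic recovery: at SNR 50 the pooled bi-exponential estimates over
  200 voxels recover ($\alpha$, $d_f$, $d_s$) within 10 %. Single-voxel
  estimates scatter several times more — a conditioning property of
  bi-exponential fitting, which is why the package reports ROI summaries.

## Known limitations

* The general finite-$d_i$ eigenvalue relation behind LEM is not
  implemented; only its $d_i \to 0$ limit is used (as in the comparison
  itself).
* $\sigma_H$ is consumed or simulated, never reconstructed from B1 phase;
  MREIT, scanner preprocessing and segmentation are out of scope.
* Identifiability: along gradient directions where $u^T D_e u$ approaches
  $d_i^w$ the two decay components merge and the directional fraction is
  poorly determined; anisotropic-voxel tests therefore assert the fast
  tensor (well conditioned) tightly and the fractions coarsely.
* The brain object is a geometric cartoon; its purpose is controlled
  ground truth, not anatomical realism.
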