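---
title: "Quantifying the mechanics of trophoblast fusion: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the mechanics of trophoblast fusion: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusemech)
```

## Scientific background

Cytotrophoblasts fuse into the multinucleated syncytiotrophoblast that
sheathes the placental villus; in vitro, BeWo cell monolayers induced with
forskolin form scattered syncytial patches amid mononucleated regions.
`fusemech` implements the computational side of asking whether fusion sites
carry a distinctive mechanical signature and whether externally applied
compression promotes fusion:

1. **Traction force microscopy (TFM).** Cells adhere to a soft
   polyacrylamide substrate with embedded fluorescent beads. Bead
   displacements between a stressed state and the reference state at
   induction time report the substrate deformation; inverting the elastic
   problem yields the traction stresses the cells exert.
2. **Stress decomposition at fusion sites.** Around each syncytial (or
   comparison mononucleated) region, traction vectors are decomposed into
   radial and tangential components about the region's areal centroid,
   yielding a signature of inward (compressive) versus circumferential
   loading.
3. **Fusion-efficiency statistics.** Nuclear and syncytium counts give the
   fraction of nuclei in fused structures; in spheroids, a volume-normalized
   marker intensity substitutes where nuclei cannot be resolved.
4. **Osmotic compression mechanics.** Dextran added to the medium compresses
   spheroids isotropically; a linear-elastic model converts measured
   shrinkage into the applied pressure.

Every stage can be exercised on synthetic data with known ground truth, so
the pipeline is testable end to end without microscopy data.

## Displacement recovery: alignment and iterative PIV

A time-lapse stack is first rigidly aligned to the reference frame
(whole-frame normalized cross-correlation with three-point Gaussian subpixel
refinement) to remove stage drift. Displacement fields are then recovered by
windowed normalized cross-correlation in three passes with progressively
smaller interrogation windows, 128, 64 and 48 px. Each pass median-smooths
(3 x 3) and bilinearly interpolates the previous pass's field and uses it to
offset the interrogation window in the current image, so the correlation
only has to resolve the residual; the search radius per pass is a quarter
window. The reference is always the frame at t = 0 (induction time), never
frame-to-frame chaining, so recovered displacements and stresses are
relative to the induction-time configuration.

Two numerical choices matter for accuracy:

* **Subpixel peak fit.** The correlation peak is located to subpixel
  precision with a three-point Gaussian fit (parabolic fallback when a log
  fit is not admissible). Because the broad correlation peak of
  diffraction-limited beads is not exactly Gaussian, this fit alone carries
  a peak-locking bias that grows with the fractional part of the shift (we
  measured up to ~0.15 px). The final pass therefore polishes each vector by
  iterative fractional window shifting: the current window is re-sampled
  (bilinear) at the running estimate and re-correlated, which drives the
  residual - and with it the bias - to second order. Uniform shifts are then
  recovered to ~0.02-0.08 px.
* **Output lattice.** The final lattice spacing equals the final window (48
  px, non-overlapping windows), i.e. 48 x 0.3086 um ~ 14.8 um. A half-window
  overlap rule is available in the configuration.

Vectors whose correlation coefficient falls below 0.6 are invalidated and
replaced by the median of their valid 8-neighbors, iterated until nothing
more can be filled; fields with more than half their vectors rejected are
flagged as quality failures rather than silently repaired. Degenerate
(flat-intensity) windows are flagged invalid with correlation 0.

## Traction reconstruction (FTTC)

The substrate is modeled as a linear-elastic half-space (Young's modulus
3900 Pa, Poisson ratio 0.457, pixel 0.3086 um for the monolayer
experiments). In Fourier space the surface displacement responds to surface
traction through the Boussinesq tensor

$$\tilde G(\mathbf k) = \frac{2(1+\nu)}{E k^3}
\begin{pmatrix}(1-\nu)k^2+\nu k_y^2 & -\nu k_x k_y\\
-\nu k_x k_y & (1-\nu)k^2+\nu k_x^2\end{pmatrix},$$

and tractions are recovered per wavevector by 0th-order Tikhonov
regularization, $\tilde T = (\tilde G^\top \tilde G + \lambda I)^{-1}
\tilde G^\top \tilde u$. Numerical choices:

* **Regularization scale.** `lambda` is expressed relative to the squared
  kernel gain at the lattice Nyquist wavevector; the default 99 damps the
  highest-wavevector response ~100-fold while leaving long-wavelength modes
  (whose gain is orders of magnitude larger) essentially untouched. It is
  exposed in the configuration because absolute traction magnitudes depend
  on it; comparisons between regions at a fixed `lambda` do not.
* **Padding.** Fields are zero-padded 2x before the FFT to suppress
  periodic wrap-around. The forward/inverse pair is exact on a periodic
  domain; with padding and a finite field of view the roundtrip error is
  dominated by the cropped displacement tails and falls below 5% (relative
  L2) for a compact traction pattern on a 128 x 128 lattice.
* **DC and Nyquist modes.** The net-force (DC) mode is zeroed, consistent
  with force balance over the field of view, so recovered tractions sum to
  zero exactly. The off-diagonal kernel term, odd in $k_x$ and $k_y$, is
  zeroed at the Nyquist bins of even lattices, where the wavevector sign is
  ambiguous; without this the operator loses its exact rotation covariance.

## Stress decomposition about fusion sites

A region of interest is a pixel mask labeled `syncytial` or
`mononucleated`, annotated (not computed) with its fused fraction: the
reference selection takes 75-80% fused syncytial patches and 25-30% fused
mononucleated comparison patches of matched area. The ROI is dilated by a
Euclidean disk of 80 px to include one to two cell widths outside the fused
patch, but the areal centroid is always computed from the *original* region
- the centroid defines the fusion site, the dilation only widens stress
sampling. The spatial mean runs over the full dilated ROI (an annulus
excluding the core would be an alternative; the dilated-ROI mean is used
here).

At every traction lattice point inside the dilated mask the stress vector
is projected on the unit ray from the centroid ($S_R$, positive pointing
away - compressive stresses directed into the region appear as negative
means) and its perpendicular ($S_T$, absolute value taken *before* spatial
averaging, while the radial component is averaged signed). Per-vector
$S_R^2 + S_T^2 = |S|^2$ holds to machine precision, and both means are
invariant under 90-degree rotation of field plus ROI. Time courses are
aggregated by an unweighted mean over 12-48 h, skipping the onset transient
so regions are compared on their sustained stress state; syncytial and
mononucleated groups are compared with a two-sided equal-variance
two-sample t-test (with fixed conventions for degenerate inputs: two
constant equal groups give p = 1, two constant different groups give
complete separation).

## Fusion-efficiency statistics

With T total nuclei, F nuclei inside syncytia, S syncytia, and FS nuclei in
Syndecan-1-positive regions:

* E-cadherin efficiency: $100\,(F - S + 1)/T$ when at least one syncytium
  exists. The `+1` makes a single fully fused sheet (F = T, S = 1) score
  exactly 100%. At S = 0 the printed formula would yield a spurious
  $100/T$ for a fully unfused field, so the package defines the S = 0 case
  as 0; this is the only departure from the literal formula and only where
  the formula's premise (at least one syncytium) fails.
* Syndecan-1 efficiency: $100\,\mathrm{FS}/T$.
* Nuclear density: T over a fixed 0.34 mm^2 viewfield.
* Spheroid fusion level: total integrated marker intensity across optical
  sections divided by spheroid volume (per-slice areas x 10 um slice
  spacing by default).
* Fold normalization: values divided by their batch's control mean, because
  passage number shifts baseline fusion efficiency and absolute values are
  not comparable across batches.

Counts are derived from masks by connected-component labeling; a nucleus
belongs to a syncytium (or Syndecan-1-positive region) if its centroid
falls inside the component, which is robust to partial boundary overlap.

## Osmotic compression of spheroids

The calibration gel's Young's modulus comes from shear rheometry through
$E = 2G(1+\nu)$ (G = 5150 Pa, nu = 0.457 by default, E ~ 15 kPa). For a
homogeneous isotropic linear-elastic disc under pressure on its free
surfaces with a frictionless (roller) support, the uniform hydrostatic
state $\sigma = -p\,I$ satisfies equilibrium and every boundary condition
exactly, so the finite-element solve that this boundary-value problem is
usually given reduces to the closed form

$$\varepsilon = \frac{p\,(1 - 2\nu)}{E},$$

with $\varepsilon$ the engineering strain of any linear dimension. The
package therefore inverts pressure from strain directly; a numerical solver
could only add discretization error. Strain is diameter-based (volumetric
strain would be ~3x for small strains), reported positive in compression,
relative to the t = 0 measurement; spheroid diameters come from projected
areas assuming a spherical shape, $d = 2\sqrt{A/\pi}$. Pressure recovery
from a track averages the strain over all post-reference timepoints. With
25 and 50 mg/mL dextran the reference experiments report ~2 and ~3 kPa;
those magnitudes anchor the synthetic scenarios (the measured disc
diameters behind them are not available to recompute).

## What the synthetic data emulates - and what it does not

* **Bead images**: isotropic Gaussian spots (sigma 1.5 px) at 0.08
  beads/um^2 (10-20 beads per final window) with additive Gaussian read
  noise - the simplest model that exercises cross-correlation PIV. Deformed
  frames are rendered by *moving bead centers* (forward warping), so ground
  truth carries no interpolation bias. No photon (Poisson) noise,
  photobleaching, out-of-focus light or bead aggregation.
* **Contraction movies**: one or more circular patches whose rim pulls
  inward with a Gaussian-profiled annulus of traction, zero before an onset
  time, ramping linearly over 2 h, then constant - matching the observed
  transition-then-plateau time course without inventing dynamics. Peak
  tractions default to 40 Pa (order 10-100 Pa, typical of soft-gel TFM;
  the reference figures do not print absolute magnitudes). Displacements
  come from the forward Boussinesq solver, so PIV + FTTC are tested against
  self-consistent elastic fields.
* **Fusion masks**: nuclei as disks on a jittered grid, syncytia as labeled
  rectangles containing exactly their member nuclei - counts are exact by
  construction, which is the point; no nuclear texture or realistic
  morphology.
* **Spheroid tracks**: immediate elastic equilibrium plus Gaussian
  measurement noise on the diameter (the t = 0 reference is noise-free). No
  poroelastic transient or active compaction, so recovery statistics test
  the inversion, not time-dependent rheology.

Passing tests on these generators therefore demonstrates the correctness of
the *analysis* under its stated model, not robustness to every property of
real microscopy data.

## Study sizes and defaults

The bundled synthetic contraction study (`run_pipeline()`) uses a
1440 x 1440 px field (~444 x 444 um) holding 7 contractile patches (radius
25 um, peak tractions drawn from N(40, 6) Pa) and 7 traction-free neutral
positions on a shuffled slot grid, imaged at 13 frames over 0-48 h (every
4 h; the 30-min cadence of the reference acquisition is available through
`study$times_h` but adds nothing to a synthetic plateau). Stresses are
aggregated over 12-48 h and patch vs. neutral mean radial stresses are
compared with the two-sample t-test; under these defaults the contrast is
separated at p < 1e-8.

```{r, eval = FALSE}
res <- run_pipeline(pipeline_config(seed = 7))
res$comparison$p
```

Other defaults worth knowing: PIV threshold 0.6; ROI dilation 80 px;
FTTC lambda 99 (relative, see above) with 2x padding; spheroid scenarios
450 um diameter, 2 kPa, 1 um diameter noise, measured at t = 0, 3, 6, 24,
30, 48 h; stimulation regimen 5% compression per daily cycle, two cycles,
10% total (strains add across cycles - the engineering-strain convention
the reference arithmetic uses).

## Known limitations

* Absolute traction magnitudes depend on the regularization level; only
  contrasts between regions analyzed at the same settings are meaningful.
* The half-space model ignores finite gel thickness; tractions near the
  field border are affected by windowing despite padding.
* The linear-elastic spheroid model has no time dependence; it infers the
  equilibrium pressure, not the compaction dynamics.
* ROI fused fractions are annotations supplied by the user, not measured by
  the package.
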