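---
title: "Reconstructing Bragg intensities from sparse rotation frames: models and methods"
author: "SparseEMC authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing Bragg intensities from sparse rotation frames}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Serial microcrystallography at storage-ring sources pushes crystal sizes and
exposure times down to the point where a single detector frame contains only
a few hundred photons — far too few to see, let alone index, Bragg peaks.
`SparseEMC` reconstructs the full three-dimensional Bragg intensity of a
crystal rotating about one known axis from millions of such *sparse,
non-oriented* frames, treating the rotation angle of every frame as a latent
variable.

The package covers the complete chain: Ewald-sphere detector geometry, a
synthetic-frame simulator with recorded ground truth, the
expand-maximize-compress (EMC) reconstruction, z-score peak segmentation
with lattice refinement and ellipsoid integration, and validation metrics
(reference assembly, amplitude R factor, orientation-error histograms,
reflection-condition checks, background-photon fraction).

## The statistical model

A frame `k` records photon counts $K_{ik}$ at pixels $i$.  Given the 3D
intensity $W(\mathbf q)$ (expected photons per frame per pixel) and the
crystal rotation $\Omega_j$, the counts are independent Poisson variables
with means $W_{ij}$, the intensity sampled on the Ewald sphere rotated to
$\Omega_j$.  With a uniform prior over the sampled rotations, the posterior
that frame $k$ was taken at rotation $j$ is

$$P_{jk} \;\propto\; \prod_i W_{ij}^{K_{ik}}\, e^{-W_{ij}},$$

computed in the log domain (only the sparse nonzero $K_{ik}$ contribute to
the product; the exponential term uses the slice total $\sum_i W_{ij}$),
normalized per frame by log-sum-exp.  The M step replaces each slice by the
posterior-weighted mean photon count,

$$W'_{ij} \;=\; \frac{\sum_k P_{jk} K_{ik}}{\sum_k P_{jk}},$$

and compression maps the updated slices back onto the voxel grid (trilinear
adjoint weighting, per-voxel weighted average).  Iterating
expand → E step → M step → compress is an expectation-maximization scheme
for the most probable intensity consistent with all frames.  Because frames
carry no absolute angle information, the solution is determined only up to
a global rotation about the axis (the *gauge*); all comparisons first fit
that offset.

### Orientation space

Only one-dimensional rotations about the goniometer axis are sampled
(`rotationSet`), uniformly on $[0^\circ, 360^\circ)$.  In the sparse regime
the per-frame constraint is too weak to search all of SO(3); restricting to
the known axis is what makes the problem tractable.  Full rotation-group
sampling is out of scope.

### Coordinate conventions

Right-handed lab frame, beam along $+z$, rotation axis along $+y$, flat
detector normal to the beam at `distance` mm.  Pixel centers sit at integer
(fast, slow) indices; the beam center may be fractional and may lie outside
the active area (the experimental layout puts it in a corner to reach
$\approx 1.3$ Å at the far corner).  A pixel maps to
$\mathbf q = (\hat s - \hat z)/\lambda$, so $|\mathbf q| = 2\sin\theta/\lambda$.
The reciprocal grid is cubic with an odd extent, so the central voxel is
exactly $\mathbf q = 0$; the conventional voxel size is a stated fraction of
$a^*$ (the full-scale experiment used $a^*/7$, then $a^*/9$ for the
resolution-extension stage).

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `meanPhotons` | 200 | photons/frame | the sparse regime of the experiment |
| `backgroundFraction` | 0.8 | — | share of photons from diffuse scatter |
| `peakSigma` | 0.8 | voxels | "small" Gaussian reflections on an $a^*/7$ grid |
| rotation count | 360 (toy) / 1080 (full) | — | slice spacing at the grid edge stays below the trilinear support (≈1.6 voxels at full scale) |
| `nIter` | 30 | — | the full-scale run used 30; toy runs converge in 15–30 |
| `peakWidth` (seed) | 1.2 | voxels | slightly wider than the truth width; EM sharpens |
| `floorValue` | 1e-10 | photons | a photon where $W=0$ must not give $-\infty$ |
| segmentation `n` | 15 | voxels | the experiment's window size |
| `gammaSchedule` | 1.0 → 3.0, 4 passes | — | stated endpoints; linear spacing is our choice |
| `windowFractions` | 10/25/50 % | of reciprocal cell | stated integration range |
| `betaStart`, `betaDouble` | 0.1, 3 | — | annealing schedule (below) |

## Seeding

The initial estimate places small 3D Gaussians of random height at every
predicted Bragg position of the rough cell (plus a small uniform floor).
No symmetry is imposed — Friedel mates are independent and systematically
absent reflections are seeded too — so symmetry in the converged model is
evidence, not input.  Two numerical choices:

* **Radial envelope.**  Seed heights are exponential draws multiplied by a
  Wilson-type envelope $\exp(-2(q/q_{max})^2)$ (`radialDecay = 2`).  A rough
  radial falloff is exactly what a powder pattern of the sample — the
  stated source of the rough cell — would provide.  With envelope-free
  heights the toy-scale EM tends to lock into orientation-smeared local
  optima; `radialDecay = 0` restores plain random heights.
* **Deterministic annealing.**  The E step exponentiates the per-frame
  log-likelihood by $\beta$, starting at `betaStart = 0.1` and doubling
  every `betaDouble = 3` iterations until $\beta = 1$ (plain EM from then
  on).  Early flat posteriors prevent the iteration from confidently
  mis-assigning frames while the random seed heights are still being
  corrected; this is standard practice in EMC implementations.  The
  convergence trace always reports the *unannealed* log-likelihood, which
  is non-decreasing (up to compress/expand interpolation error, < 0.1 %)
  once $\beta$ reaches 1.

## Resolution extension and rescaling

Orientation posteriors converge on a coarse grid; a single M-step plus
compression on a finer grid (`extendResolution`) then incorporates all
photons to the full resolution without further probability updates.  The
final model is rescaled so its voxel sum equals the total recorded photon
count (`rescaleToPhotonCount`); the background-fraction estimate requires
this normalization.

## Peak analysis

**Segmentation** classifies voxels by local standard score
$z = (W - \mu)/\sigma$ over an $n^3$ window, four passes with
$\gamma = 1.0 \to 3.0$, passes 2–4 recomputing $\mu, \sigma$ from
previously-background voxels only.  Degenerate windows ($\sigma = 0$) label
on-level voxels background and strictly-above-level voxels signal, keeping
the classification invariant under affine rescaling.  Unobserved voxels
(never crossed by the rotating Ewald sphere) are excluded from the window
statistics.

**Lattice refinement** scans candidate $(a, c)$ cells and keeps the one
whose predicted ellipsoids (axes $\propto (a^*, a^*, c^*)$, a small
fraction of the reciprocal cell) capture the greatest segmented intensity.
Two toy-scale caveats we measured and document rather than hide: the radial
diffuse background biases any intensity-sum score toward smaller cells
(predicted positions move inward, onto higher background), and the $c$ axis
has little leverage when only $|l| \le 3$ fits inside the resolution
sphere.  At toy scale the attainable precision is roughly 0.5–1 %, which is
why the refinement tests use a 2 % search step.

**Integration** centers an ellipsoid window on every predicted peak; voxels
inside belong to the peak (shared voxels to the nearer center, via
nearest-lattice-point assignment), the local background mean — over
same-cell voxels outside the window that are not segmentation-labeled
signal — is subtracted per voxel, and the result is summed.  Each peak uses
the smallest window fraction containing its segmented voxels.  Peaks whose
window leaves the observed region (map edge, unvisited voxels, exclusion
zones such as a beamstop sphere) are flagged partial and carry no
intensity; negative intensities are retained and flagged.  The $\sigma(I)$
column is a package convention (background-spread propagation,
$\sigma = \sqrt{n_{sig}\,\mathrm{var}(bg)\,(1 + n_{sig}/n_{bg})}$); the
procedure itself does not prescribe uncertainties.

For reference-versus-reconstruction comparisons, `integrateConsistently`
re-integrates both maps with identical per-reflection windows (the union of
the two adaptive choices, one schedule step larger).  Letting each map pick
its own windows turns window-truncation differences into apparent intensity
differences and roughly doubles the measured R factor.

## Validation metrics

* `assembleReference` deposits photons at their *true* angles (one
  maximize-plus-compress with one-hot probabilities) — possible only for
  simulated data, used only for validation.
* `rFactor` is the crystallographic amplitude R factor
  $R = \sum\big||F_{ref}| - s|F_{rec}|\big| / \sum |F_{ref}|$ over common
  fully-recorded reflections, with the global scale $s$ fitted by least
  absolute residuals (flag to fix $s = 1$).  The denominator uses the
  reference; the metric is deliberately asymmetric.
* `orientationErrors` takes per-frame argmax rotations, fits the single
  gauge offset (and optionally a sense flip) maximizing the within-tolerance
  fraction, and reports wrapped errors.  "Within 1°" means
  $\le \max(1°, \Delta/2)$ so the metric stays meaningful on grids coarser
  than 1°.
* `checkReflectionConditions` compares mean intensities of allowed versus
  forbidden axis classes (default rules of the tetragonal space group
  P4~3~2~1~2: 00l with l = 4n, h00/0k0 even); recovery of absences that were
  never seeded is direct evidence of orientation recovery.
* `backgroundFraction` is the share of the (photon-rescaled) map total in
  background-labeled voxels.

## What the simulator emulates — and what it does not

The generator reproduces the experiment's *statistics*: a tetragonal cell
near $a = b = 77$, $c = 36$ Å, Cu Kα (1.54 Å) at 33 mm, ≈200 photons per
frame of which ≈80 % come from a smooth isotropic background, Gaussian
reflections of width 0.8 voxels with Wilson-like exponential intensities
(radial decay $e^{-2(q/q_{max})^2}$, so bright low-resolution and dim
high-resolution peaks both occur), Friedel symmetry and the space-group
absences imposed on the truth, a random recorded crystal orientation (so
lattice axes are not grid-aligned), and a beamstop mask.  The background's
radial profile is not documented for the experiment; we give it the same
decay as the Wilson envelope (diffuse solvent/air scatter tracks the
overall scattering power), and only its integral is constrained by
`backgroundFraction`.

It does **not** model: structure factors from atomic coordinates (true
intensities are random draws), detector point-spread/charge sharing,
absorption or polarization corrections, per-frame beam fluctuations, or
radiation damage.  Passing tests therefore demonstrate correct *orientation
recovery and integration under sparse Poisson statistics*, not end-to-end
fidelity to any particular protein's diffraction.

## Problem sizes used by the tests and the acceptance script

The full-scale experiment (8.8 million frames, $543^3$ and $939^3$ grids,
1080 rotations, 30 × 1.3 h iterations) is far beyond a desk run.  The
package's own study conditions, fixed once:

* **Orientation recovery**: 5000 frames, 360 rotations at 1°, grid to 7 Å
  ($a^*/7$ voxels, $157^3$), 128×128 pixel detector.  The resolution is
  chosen so a photon at the sphere's edge moves ≈1 voxel per degree —
  matching the experiment's regime, where the 2 Å working resolution gave
  individual photons strong angular leverage.  Fractions across seeds:
  99.7–100 %.
* **End-to-end reconstruction**: 20 000 frames, 360 rotations, grid to 13 Å
  ($87^3$), 30 annealed EMC iterations, then segmentation, refinement and
  consistent integration of reconstruction and reference.  The coarser
  limit keeps ≈2000 signal photons per reflection, so the two-map Poisson
  noise floor stays below the orientation-assignment error the R factor is
  meant to expose.  Across seeds this yields R ≈ 1–2 % (the full-scale
  experiment reported 4.73 %) and background-fraction estimates of 79–82 %
  against a simulated 80 %.

Module tests run the same machinery at still smaller sizes (≈60³ grids,
≤120 rotations, thousands of frames) chosen to finish in seconds.

## Known limitations

* Single-axis rotations only; no SO(3) sampling, no per-frame scale or
  partiality refinement.
* Trilinear interpolation in expand/compress smooths ~1-voxel peaks
  slightly each iteration; at very low redundancy this can stall EM below
  perfect assignment (the annealing schedule mitigates, but does not
  eliminate, this).
* The refinement's hard-ellipsoid score has limited $c$-axis leverage at
  low resolution (see above).
* MRC export stores float32; exact voxel values round-trip only to single
  precision.
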