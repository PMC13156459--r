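---
title: "Joint image and coil-map estimation with phase-pole correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint image and coil-map estimation with phase-pole correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The estimation problem

In parallel MRI the signal received by coil $i$ is the Fourier transform of
the product of one complex image $\rho(r)$ with that coil's complex
sensitivity profile $c_i(r)$, observed on a sampling pattern
$\mathcal{P}$:

$$ y_i = \mathcal{P}\,\mathcal{F}(c_i \odot \rho) + n_i. $$

Only the products $c_i \odot \rho$ are observable: if $(\rho, c)$ explains
the data, so does $(\vartheta^{-1}\rho,\ \vartheta c)$ for any nowhere-zero
complex field $\vartheta(r)$. Joint estimation therefore needs a
normalization, and NLINV supplies it through regularization: the coils are
penalized in a Sobolev norm (they are physically smooth), the image in a
plain $\ell_2$ norm,

$$ \min_{\rho,\tilde c}\ \|y - \tilde F(\rho, \tilde c)\|_2^2
   + \alpha\|\rho\|_2^2 + \alpha\|\tilde c\|_2^2,
   \qquad c = W\tilde c, $$

where $W$ is the k-space low-pass weighting
$w(k) = (1 + a\|\hat k\|^2)^{-b}$ with $\hat k \in [-0.5, 0.5]^2$ the
frequency per sample, $a = 220$, $b = 16$ (`sobolev_weights()`). Working in
the preconditioned variables $\tilde c$ makes the coil penalty a plain
$\ell_2$ norm and the inner problems well scaled.

The non-convex problem is solved by an iteratively regularized Gauss-Newton
method (`nlinv()`): at each outer step the forward model is linearized and
the ridge problem

$$ (DF^H DF + \alpha_k I)\,\delta x = DF^H (y - F(x_k)) - \alpha_k (x_k - x_0) $$

is solved by conjugate gradients. The regularization anchor $x_0$ is the
standard initialization — image constant one, coils zero — which favors
real-valued, pole-free images early on; $\alpha_k = \max(\alpha_{\min},
q^k)$ decays from 1 with $q = 1/2$ to $\alpha_{\min} = 10^{-3}$ over the
default 12 steps. The data is first normalized to $\|y\|_2 = 100$, the
scaling the schedule is calibrated for in 2D; the output is un-scaled and
rescaled so the coils have unit root-sum-of-squares (RSS) and the image
magnitude matches the conventional RSS combination.

A warm start (`init=`) changes only where the iteration begins, never the
anchor $x_0$. Anchoring at a warm start would freeze its gauge — including
any phase pole it carries — into the penalty, which defeats the correction
step below; this was confirmed empirically before fixing the design.

## Phase poles

A phase pole is a point where the phase of a complex field is undefined
and a closed loop around it accumulates $\pm 2\pi$ of phase: the field's
values along the loop wind around the complex origin a nonzero integer
number of times. For a smooth field, a pole forces the amplitude to zero
at its center. True images have single-valued phase (a time-integrated
Larmor frequency) and should be pole-free, but coil sensitivities can
carry genuine poles — the transverse field $B_x - iB_y$ of a magnetic
dipole perpendicular to the imaging plane has exactly one, and the
`coil_layout(style = "dipole")` simulator realizes that analytic field.

Because of the $\vartheta$-ambiguity, the solver can converge to a local
minimum in which the image carries a spurious pole compensated by
conjugate poles in *every* coil map. The smoothness penalty then drives
the coil amplitude to zero near the pole, leaving a signal void — a
"black hole" — in the RSS-scaled reconstruction.

## Detection: winding numbers and weighted consensus

Detection runs on the coil maps, not the image, for robustness: a spurious
pole is mirrored in all coils, while image-based detection is easily fooled
by noise in low-signal regions. The steps (`coil_winding_maps()`,
`detect_poles()`):

1. For every pixel of every coil, the winding number $S_i(r)$ is computed
   on a discretized circle of diameter $d = 0.05$ FoV
   (`circle_curve()`, `winding_number()`): principal-value phase
   differences in $(-\pi, \pi]$ are summed around the loop, divided by
   $2\pi$, and rounded to the nearest integer. If the field is exactly
   zero at a curve point the winding is set to 0, as the phase is
   undefined there. The diameter trades off overlap of slightly misaligned
   per-coil detections (too small: no consensus) against merging of
   independent poles (too large: lost resolution); 0.05 FoV works across
   resolutions.
2. The per-coil maps are averaged with weights $w_i = |c_i|^2$. Genuine
   coil poles sit at amplitude zeros, so they are weighted out of the
   consensus $\bar S(r)$; a pole shared by all coils keeps
   $|\bar S| \approx 1$. With $n_c$ comparable-magnitude coils, a pole in
   a single coil is bounded by $1/n_c$.
3. The consensus is thresholded at $|\bar S| > t$ with $t = 1/2$ (strict
   inequality; the choice matters only exactly at $t$).
4. The binary mask is closed morphologically with a disk of diameter
   $d_{\mathrm{closing}} = d$, merging a pole fragmented into nearby
   components so it is corrected once, not twice.
5. Components are labeled (8-connectivity by default; 4 available) and
   each unweighted component centroid becomes a pole location; the sign is
   taken from the component mean of $\bar S$ and reported in the
   image-pole convention (the coils carry the conjugate winding).

Poles closer than $d/2$ to the FoV edge are undetectable by construction:
their circles are clipped at the boundary and report winding 0. This blind
zone is logged, not hidden.

## Correction

For each detected pole the elementary unit-magnitude phase vortex

$$ \vartheta^{\pm}_{r_0}(r)
   = \frac{(r - r_0)_x \pm i (r - r_0)_y}{\|r - r_0\|} $$

is built (`phase_vortex()`); the product over poles, with windings chosen
to cancel the image-domain poles, forms the correction field
(`build_correction()`). Its global phase is then fixed so that
$\langle \rho, \vartheta \odot \rho \rangle$ is real and positive
(`global_phase()`): the correction changes the image phase as little as
possible where signal power is high. Inside the solver
(`apply_correction()`), the image is multiplied by $\vartheta$ and the
coils by $\bar\vartheta$ in the natural domain, pushed back to the
preconditioned variables through a regularized pseudoinverse
$W^+ = w/(w^2 + \varepsilon)$ with $\varepsilon = 10^{-6}$, which caps the
worst-case high-frequency amplification at
$1/(2\sqrt{\varepsilon}) = 500$. By default detection runs once, after
step 8 of 12 — late enough that the estimate has stabilized, early enough
that four steps remain to refine the corrected maps; `detect_every`
enables repeated detection for multi-pole cases.

The vortex multiplication leaves the data residual invariant only up to
the $W^+$ band truncation of the corrected coils. On coarse grids this
transient is clearly visible in the residual log (tens of percent right
after the correction on a $64\times 64$ grid) and decays over the
remaining steps; the final pole count and the recovered RSS are the
meaningful outcomes.

Externally estimated coil stacks (ESPIRiT-style), whose reference-phase
construction puts the identical pole at exactly the same pixel in every
map, use `correct_external_coils()`: winding numbers from the four
neighboring pixels (a 1-pixel circle), no closing, and a plain vortex
multiplication that preserves the coil-image products exactly since no
weighting pseudoinverse is involved.

## The simulator and what passing tests mean

`make_phantom()` builds piecewise-constant ellipse phantoms with a smooth
quadratic background phase — pole-free by construction, as a true image
should be. `make_coils()` provides two layouts: `gaussian_ring` (eight
Gaussian lobes of width $\sigma = 0.35$ FoV centered on a ring of radius
0.55 FoV, smooth low-order polynomial phase of roughly 2.5 rad across the
FoV — strictly positive, singularity-free) and `dipole` (one genuine
singularity per coil). `plant_artificial_pole()` realizes the ambiguity
exactly: image times vortex, coils times conjugate vortex, products
unchanged to machine precision. `sample_kspace()` applies the centered
unitary FFT, adds iid complex Gaussian noise (pre-whitened coils are
assumed), and masks with `make_pattern()` — a regular acceleration lattice
through the k-space center plus a fully sampled central auto-calibration
block.

The simulator does *not* emulate coil compression (which can create
genuine poles in virtual coils — the dipole layout stands in for those),
non-Cartesian trajectories, off-resonance, motion, or 3D vortex lines.
Passing tests therefore demonstrate the estimator's and detector's
contracts on smooth, Cartesian, pre-whitened 2D data; they do not certify
behavior under those unmodeled effects.

## Numerical choices

* FFTs are unitary and centered (shift-FFT-shift), so Parseval holds
  exactly, the adjoint equals the inverse, and Sobolev weights and AC
  blocks are symmetric about the array center. Pixel $(i_x, i_y)$
  (0-based) sits at FoV position $((i_x{+}0.5)/n_x - 0.5,\,
  (i_y{+}0.5)/n_y - 0.5)$.
* Winding sums are rounded to the nearest integer; for clean fields the
  discretized sum is within $1/2$ of an integer, and the consensus
  averaging assumes integer per-coil maps. Circles use
  $N = \max(8, \lceil \pi d_{px} \rceil)$ points before deduplication,
  which keeps per-segment phase steps below $\pi$ for unit vortices at
  diameters of 2 pixels and up.
* The inner CG starts from zero each step and stops at relative residual
  $10^{-6}$ or 50 iterations. The Gauss-Newton step was verified against a
  dense-matrix solve of the same ridge problem on a small instance (the
  trajectory agrees to solver precision).
* At the $\alpha$ floor the regularized solution retains a bias whose
  size depends on the grid: with the per-sample frequency normalization of
  $w$, a $64\times 64$ grid resolves coil structure only up to roughly
  2–3 cycles per FoV, and the noiseless product error settles around
  1.5% (computed by the acceptance script's `recon_product_rel_error`);
  the same protocol on finer grids, or a smaller $\alpha_{\min}$, lowers
  this floor. This is a property of the protocol, not of the solver's
  convergence — inner and outer iterations drive the gradient to zero.
* Degenerate inputs: all-zero k-space is rejected at normalization;
  all-zero coil pixels make the consensus and the projection operator
  zero rather than raising; a correction with zero image-power overlap
  leaves the global phase unchanged with a warning.

## Problem sizes

The test-suite and acceptance experiments use $64\times 64$ grids with 8
coils (detection statistics over 50 planted-pole and 50 pole-free coil
sets, and single reconstructions per arm of the black-hole experiment),
and $32\times 32$ or smaller instances for solver unit tests and the
dense-matrix oracle. Detection statistics are measured on the generator's
coil maps directly — the detector is the object under test there — while
in-solver behavior is covered by the end-to-end correction experiments.

## Limitations

* Strictly 2D: in 3D, poles form vortex lines and a per-slice application
  only works where those lines cross slices near-perpendicularly.
* Poles within $d/2$ of the FoV boundary are invisible to the detector.
* Two close poles of equal sign merge into one detection (by design, to
  avoid double correction); repeated detection rounds handle them.
  Close opposite-sign pairs cancel in the winding sum and are not
  detected — in practice they annihilate during the iteration.
* The $\ell_2$-regularized inner problem only; no sparsity-promoting
  variants, no non-Cartesian sampling, no GPU path.
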