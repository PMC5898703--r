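---
title: "Wave-optical simulation of light-sheet image formation: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wave-optical simulation of light-sheet image formation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(LightSheetSim)
```

# The problem

A light-sheet microscope illuminates a fluorescent sample with a thin sheet of
coherent light and images the excited plane with an orthogonal detection lens.
In optically heterogeneous tissue both paths are degraded: the sheet refracts,
scatters and develops speckle; the detection point-spread function (PSF)
acquires aberrations that differ for virtually every point in the sample.
`LightSheetSim` simulates this process with scalar wave optics, producing
camera images whose blur, contrast loss, speckle and geometric distortions
arise from the sample itself rather than from a phenomenological model.

# The propagation model

## Split-step scheme

The scalar field $u(x,y)$ is advanced slice by slice through the complex
refractive-index volume $n(x,y,z)$ by a symmetric split-step scheme. Each
slice of thickness $\Delta z$ applies

1. a half diffraction step through a homogeneous reference index $n_0$, using
   the exact (non-paraxial) angular-spectrum propagator
   $\hat H(k_x,k_y) = \exp\!\big(i\,\tfrac{\Delta z}{2}
   \sqrt{(n_0 k_0)^2 - k_x^2 - k_y^2}\big)$, $k_0 = 2\pi/\lambda$;
2. the thin phase screen
   $u \leftarrow u \exp\!\big(i k_0 (n(x,y,z) - n_0)\,\Delta z\big)$, whose
   imaginary index part yields Beer–Lambert absorption;
3. a second half diffraction step.

The symmetric ordering is second-order accurate in $\Delta z$; the naive
(diffract-then-refract) ordering is only first-order. With
`nRefMode = "per_slice_mean"` (the default, the *locally adapted expansion*)
the reference index of each slice is its mean real index, which minimizes the
phase-screen residual and preserves accuracy beyond the strictly paraxial
regime; `"global"` uses the ambient (immersion) index throughout.

All lengths are micrometers and `wavelength` is the *vacuum* wavelength.
Modes beyond the propagating band, $k_x^2 + k_y^2 > (n_0 k_0)^2$, are either
zeroed (default, keeps the power bookkeeping simple) or damped with their
physical evanescent rate. FFTs imply periodic transverse boundaries; an
optional super-Gaussian absorbing frame (16 px, applied per step) suppresses
wrap-around, and every conservation test disables it.

## Validity guards

The propagator warns (it does not fail) when `dx > lambda / (2 max(n))` —
the transverse grid then cannot carry the full propagating circle and
high-angle content aliases — and when `dz > dx`, outside the regime where
the split-step factorization is accurate. Published grids for this kind of
simulation use $\Delta z = \Delta x = 100\,$nm; the desk-scale test grids
here use 100–400 nm and respect both guards wherever a test asserts tight
tolerances.

## What validates it

* **Plane waves** are exact eigenmodes (machine precision).
* **Gaussian beams** reproduce $w(z) = w_0\sqrt{1 + (z/z_R)^2}$ to better
  than 2% over two Rayleigh ranges.
* **Direct Rayleigh–Sommerfeld summation** (an $O(N^4)$ brute-force oracle,
  `directDiffraction`) agrees with the angular-spectrum step to relative
  $L_2 \le 10^{-3}$ on $64^2$ grids, once the periodic replicas are pushed
  out of frame by zero-padding — the summation assumes an isolated aperture,
  the FFT a periodic one, so the padded comparison is the physically
  meaningful one.
* **Scalar Mie series** (`mieNearField`): a plane wave scattered by a
  sphere of radius 2.5 µm and contrast $\Delta n = 0.05$ at
  $\lambda = 0.5\,$µm matches the partial-wave solution of the scalar
  Helmholtz equation to a few percent in near-field intensity, with the
  error growing monotonically in $\Delta n$. The scalar series is the
  like-for-like reference: the propagator solves the scalar equation, so a
  vector (electromagnetic) near field would conflate polarization effects
  with split-step error. Far-field quantities (`miePhaseFunction`,
  $Q_{sca}$), which are standard observables, use the full vector
  (Bohren–Huffman) coefficients for both solid and coated spheres; the
  coefficients are obtained by solving the per-order boundary-condition
  system directly, with column equilibration because the irregular radial
  functions explode for orders above the size parameter.
* **Fresnel knife edge**: the diffraction profile behind a half-plane
  matches the closed-form Fresnel-integral solution to ~0.2% at 100 µm
  depth. At 30 µm the *closed form itself* is off by ~3% in a ±12 µm
  window — its paraxial phase error $k x^4 / 8z^3$ reaches 0.6 rad — so the
  tight comparison is made where the approximation is valid, and the 30 µm
  case is asserted at a 5% derived tolerance.
* **Reciprocity**: forward propagation, conjugation and backward
  propagation through the reversed volume reproduces the source field
  ($10^{-6}$ relative for moderate media) — the numerical foundation of the
  adaptive-optics module. Residual irreversibility comes from content
  scattered beyond the propagating band; it grows with medium strength.

# Input fields

Every source is synthesized in the pupil plane: fill the support
($|k_\perp| \le k_0\,\mathrm{NA}$), apply the defocus kernel
$e^{-i k_z z_f}$ and a linear phase for the lateral focus, inverse
transform, normalize to unit power. The catalogue covers plane waves,
Gaussian beams, cylindrical-lens light sheets (a one-dimensional slit
pupil, uniformly filled — pupil apodization for sheets is not specified
anywhere authoritative, so uniform is the default), Bessel beams (annulus),
Bessel lattices (annulus times a finite comb; default period
$2\lambda/\mathrm{NA}$ following the lattice light-sheet literature), and
diffraction-limited point sources. Scanned-sheet (DSLM) illumination is the
incoherent mean of member intensities, as is the random-tilt plane-wave set
used to emulate an incoherent low-NA source.

# Multiplexed PSFs

Because the wave equation is linear, a whole lattice of point sources can be
propagated in a single run and the per-source PSFs recovered by cropping
tiles around each refocused spot (`computePSFSet`): one propagation instead
of hundreds. The detection path is modeled as the tissue between the focal
plane and the detection-side boundary ("half-volume"), followed by an ideal
telecentric 4f system: a hard NA crop of the exit spectrum and free-space
refocusing through the immersion medium (no lens aberrations; the immersion
index, not a tissue average, is used for the refocus — the conventional
idealization of a corrected objective).

Two design choices deserve emphasis:

* **Source apodization.** A hard-aperture point source has Airy side lobes
  whose amplitude at one-tile separation is $10^{-3}$–$10^{-2}$; the
  interference cross-term between neighboring spots then floors the
  multiplexed-vs-sequential agreement at that level *regardless of
  tiling*. The engine therefore defaults to Gaussian-apodized source
  pupils ($\sigma = \mathrm{NA}/4$, hard crop at $4\sigma$), whose spot
  tails decay like $e^{-r^2/w_0^2}$: the vacuum equivalence between one
  multiplexed run and 64 sequential runs then measures $\sim 3\times
  10^{-5}$ relative $L_2$ per tile (8×8 tiles of 16 px on a $128^3$ grid).
  Tests that check the diffraction-limited (Airy) width use
  `sourceFill = "uniform"`.
* **Cross-talk is physical in tissue.** In a scattering medium each
  source grows a halo; a neighbor's halo inside my tile interferes with my
  field at amplitude level ($2\varepsilon$, not $\varepsilon^2$). The
  sequential reference has no neighbors, so the equivalence degrades
  proportionally to the medium contrast (measured: index std
  0.002/0.005/0.01 gives $8\times10^{-3}/1.8\times10^{-2}/5.5\times
  10^{-2}$). This is the operational content of the "non-overlapping PSFs"
  assumption: the engine measures a per-tile border-ring energy fraction
  and flags tiles above a 1% tolerance (configurable), defining
  "non-overlapping" operationally.

Per-tile aberrations are summarized as Zernike maps (`zernikeMap`): the
in-focus tile field is transformed to the pupil plane (the tile center is
placed at the FFT origin so no carrier ramp or sign alternation corrupts
the phase), the phase is unwrapped inside the disk (a sequential
center-column-then-rows unwrap — adequate for smooth, residue-free pupil
phases; pathological tiles surface through the reported residual RMS), and
fit by least squares against the RMS-normalized Noll basis on
$0.95\,\mathrm{NA}$, weighted by pupil intensity so the rim of an apodized
pupil (pure noise phase) cannot pollute the fit. The synthesize→decompose
round trip is exact to $10^{-8}$.

# Image formation

The emitted density is excitation × fluorophore (fluorescence is fully
incoherent: coherent propagation per point source, intensity summation
across sources). The camera image is the spatially varying convolution of
the emitted density with the tiled PSF set — each emitter contributes
through its nearest tile's volumetric PSF or through the bilinear blend of
the four surrounding tiles (default; outside the outermost tile centers the
blend clamps to nearest). Tile PSFs enter scaled by their raw in-focus
integrals, so detection-path attenuation needs no separate bookkeeping; an
emitter outside the PSFs' axial support is truncated with a warning and an
energy estimate. On $32^3$ instances the FFT-based implementation matches a
direct triple-loop superposition to $10^{-10}$, which is the key
correctness surface of this module.

The nearest and bilinear blends converge onto each other as the tiling
refines *provided the aberrations vary smoothly on the tile scale*; for
media whose index structure is comparable to the tile size the PSF is
genuinely discontinuous between tiles and neither blend is privileged — the
convergence test therefore uses a long-correlation phantom (12 µm structure
against 3–13 µm tiles).

Energy accounting: total image energy is bounded by emitted energy times
the largest raw PSF integral; equality would require every PSF to be fully
contained in its crop window, so the bound is asserted with $10^{-6}$
slack. How illumination attenuation composes with detection attenuation in
an absolute-radiometry sense is not specified by any reference we follow;
the package's convention — excitation in source-power units times raw
detection transmission — is stated here instead.

# Phantoms

All inputs are generated in code with ground truth retained and are
bit-reproducible under `(spec, seed)`; module substreams are derived from
one root seed so each stage is independently reproducible.

* **Spheres / coated spheres** are voxelized with $3^3$ supersampled
  (anti-aliased) boundaries by default: the ~100 nm grids of full-scale
  simulations avoid staircase scattering artifacts by resolution, and
  desk-scale grids need the sub-voxel averaging instead.
* **Embryo**: an ellipsoidal eggshell, Poisson-disk (dart-throwing) nuclei
  with a guaranteed minimum gap, and band-limited cytoplasmic granularity,
  clamped to the biologically plausible aqueous range
  $n \in [n_{ambient}, 1.43]$ (defaults: cytoplasm 1.36, nuclei 1.39,
  shell 1.41). It is parametric — sized to scale down to $64^3$ with tens
  of nuclei — not a replica of any particular specimen.
* **Perlin tissue**: single-octave 3D gradient noise. The sample mean and
  standard deviation equal the requested values by construction; the
  autocorrelation FWHM is calibrated (0.83 of the lattice cell, ±5%
  measured over cells of 8–24 voxels) to land within 15% of the requested
  correlation length. Gradient noise is only $C^2$; its $k^{-4}$ spectral
  tails would otherwise bleed past the propagating band, where the one-way
  propagator must discard them — a *lossless* $\sigma_n = 0.03$ medium then
  appears to lose $\sim 5\times10^{-6}$ of its power per step, a property
  of the medium's spectrum rather than of the scheme. The generator
  therefore band-limits the noise by default (Gaussian spectral filter,
  $\sigma = 1$ voxel, correlation length deconvolved); the strict unitarity
  check uses $\sigma = 2$ voxels, after which the drift is
  $5\times10^{-11}$ per step.
* **Test chart**: USAF-style three-bar groups at configurable periods in a
  one-voxel plane, with exact bar geometry in the truth record.

# Adaptive optics

A guide star (ideal point emitter, no saturation or noise) at depth $d$
radiates to the entry surface through the reversed volume; conjugating the
recorded wavefront (fully, or phase-only at equal power) and propagating it
forward refocuses the light onto the star. The Strehl denominator is the
peak of the identical experiment through a homogeneous volume at the same
NA, depth and power. Numerical reciprocity makes full conjugation in the
$n = 1.36 \pm 0.03$ tissue at two scattering mean free paths essentially
perfect (Strehl ≈ 1), while an uncorrected ideal wavefront reaches a few
percent of the corrected peak.

The **shift–shift memory effect** is probed by translating the conjugated
wavefront laterally (sub-voxel shifts via the Fourier shift theorem) and
recording the refocused *peak intensity* near the shifted target:
$C(\Delta x) = I(\Delta x)/I(0)$. (Whether the headline correlation is a
peak-intensity ratio or a full-field correlation is not settled by the
available material; the peak ratio is implemented, and the full-field
variant is a one-line change on the recorded focal fields.) The reference
curve is the normalized intensity autocorrelation of the speckle a plane
wave produces at the same depth. For the comparison to be meaningful the
speckle must be reasonably developed: a fine-grained medium (correlation
length 0.7 µm at $\sigma_n = 0.03$, scattering mean free path ≈ 19 µm)
scatters into a cone comparable to the NA-0.8 guide-star cone by four mean
free paths. Seed-averaged over 20 realizations, $C(\Delta x)$ then tracks
the speckle autocorrelation to within 0.1 everywhere, with matching
correlation lengths; at one mean free path the focus *outlives* the speckle
prediction — the same depth ordering reported experimentally. The original
study's 22500-PSF sweep is scaled here to seed-averaged shift grids at
$128^2$ transverse resolution.

The **scattering mean free path** $\ell_s$ — the depth unit of all the
above — is estimated from first principles: plane waves through independent
medium realizations, ensemble average of the complex field per depth, and
an exponential fit of the ballistic power
$|\langle u(z)\rangle|^2 \propto e^{-z/\ell_s}$. The ballistic definition
(rather than Mie cross-section bookkeeping) applies to continuous media,
which is what the memory-effect experiments use. Homogeneous media report
`noDecay = TRUE` with $\ell_s = \infty$.

# What the synthetic world does and does not establish

The phantoms emulate low-contrast, forward-scattering aqueous tissue — the
regime where a one-way scalar beam propagation is the right physics. They do
not contain back-reflecting interfaces, polarization effects, high-contrast
organelles ($|m - 1| > 0.2$ triggers a warning in the Mie oracle for the
same reason), fluorophore saturation, photobleaching or camera electronics
beyond optional Poisson/Gaussian noise. A green test establishes the
numerics (propagator, multiplexing, convolution, conjugation) against
analytic and brute-force references inside this regime; it does not certify
the model outside it.

# Numerical choices worth knowing

* Tolerances asserted in tests were derived from oracle runs, not tuned:
  Mie near-field 8% (measured ~2–3% at $\Delta n = 0.05$), knife edge 2% at
  100 µm (measured 0.2%), multiplexing 1e-4 in vacuum (measured 3e-5).
* Ties in nearest-tile blending split evenly; bilinear weights are
  normalized to sum to one everywhere.
* The memory-effect curve truncates shifts beyond a quarter of the field
  with a warning (periodic wrap would otherwise fold the shifted beam).
* Degenerate inputs: zero-power sources, foci outside the volume,
  undersampled NAs, mismatched pitches and non-finite fields all fail fast
  with named errors.

# Known limitations

* One-way propagation: no back-reflections or standing waves; iterative
  two-way schemes are out of scope by design.
* Scalar fields: vectorial high-NA corrections (beyond NA ≈ 0.9) are not
  modeled.
* The multiplexed-vs-sequential equivalence is limited by physical
  scattered-light cross-talk between tiles (see the PSF section); in
  visibly heterogeneous media the per-tile agreement is $10^{-3}$–$10^{-2}$,
  not the vacuum-level $10^{-5}$ — the acceptance suite documents this
  honestly rather than hiding it.
* GPU acceleration and runtime benchmarks are out of scope; the R
  implementation favors clarity and testability at desk scale
  ($\le 256^2 \times 256$ grids).
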