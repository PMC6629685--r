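---
title: "FRC-based resolution estimation and blind restoration: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FRC-based resolution estimation and blind restoration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
set.seed(1)
```

```{r setup}
library(frcrestore)
```

## The measurement model

A fluorescence microscope records

$$ i(\mathbf{x}) \;=\; (h \otimes o)(\mathbf{x}) + b, $$

the object $o$ blurred by the point-spread function (PSF) $h$ plus a
background level $b$, with photon-counting (Poisson) noise on top.  Fourier
ring correlation (FRC) estimates the *effective* resolution of such an image
— the spatial frequency beyond which no detail rises above the noise — from
two images of the same field with independent noise:

$$ \mathrm{FRC}(r_i) \;=\;
   \frac{\sum_{r \in r_i} \mathrm{Re}\, F_1(r)\,F_2(r)^*}
        {\sqrt{\sum_{r \in r_i} |F_1(r)|^2 \; \sum_{r \in r_i} |F_2(r)|^2}}, $$

where the sums run over concentric rings (2D) or shells (3D) of the centred
spectra.  Shared structure keeps the correlation near 1 at low frequency;
independent noise drives it to 0 at high frequency.  The resolution
$d_\mathrm{min}$ is the inverse of the frequency at which the curve first
drops below a threshold — the fixed $1/7$ criterion by default, or the
SNR-based family

$$ T(r_i) = \frac{\mathrm{SNR}_e + (2\sqrt{\mathrm{SNR}_e}+1)/\sqrt{N(r_i)}}
  {\mathrm{SNR}_e + 1 + 2\sqrt{\mathrm{SNR}_e}/\sqrt{N(r_i)}} $$

with $N(r_i)$ Fourier samples per ring; $\mathrm{SNR}_e = 0.5$ is the
"one-bit" curve used for the sectioned 3D measurement.  The crossing is
located by linear interpolation between the two bracketing rings (the
choice of interpolation is ours; ring-resolution quantization would
otherwise dominate small images).  The DC ring is never eligible as a
crossing, and a curve that never crosses is flagged and reported at the
sampling bound $2\,d_\mathrm{pixel}$ rather than silently extrapolated.

Everything downstream follows from one identification: the measured
$d_\mathrm{min}$ is used as the full width at half maximum of an effective
Gaussian PSF, $\sigma = d_\mathrm{min} / (2\sqrt{2\ln 2})$.  That PSF feeds
an ideal/Butterworth/Gaussian low-pass denoiser (cutoff at
$1/d_\mathrm{min}$), a Wiener inverse filter, and Richardson–Lucy (RL)
iteration, making all three *blind*: no instrument calibration data is
needed.

## Single-image FRC and its calibration

When only one image exists, it is split by pixel parity into four
sub-images: the (even, even)/(odd, odd) classes form one pair, the
(even, odd)/(odd, even) classes the other.  Sub-images of a pair share
structure but have independent noise, so FRC applies; the two pair curves
are averaged bin-wise, which cancels the strong asymmetry that appears when
image detail runs predominantly in one direction.  Two conventions matter:

* the raw curve's frequency axis is expressed against the **original**
  pixel pitch even though the sub-images are sampled at twice the pitch, and
* the diagonal offset between the sub-images of a pair modulates the
  spectrum, compressing the apparent curve.

Both displacements are monotone in resolution at a fixed threshold, so the
raw single-image value is mapped onto the two-image ("gold standard") scale
by a monotone correction fitted once against paired measurements:
`fit_calibration()` fits a least-squares quadratic (falling back to linear
if the quadratic is non-monotone over the data range), and
`default_calibration()` reproduces the whole procedure on synthetic data —
a filament phantom imaged at pixel sizes 29–113 nm with the optical
resolution held at 250 nm, two scene replicates per pixel size.  The model
is tagged with the threshold it is valid for (1/7 only) and warns when
extrapolating.  We do not attempt to correct the entire curve, only the
threshold crossing.

```{r calibration, eval = FALSE}
cal <- default_calibration(seed = 123)
one_image_frc(img, calibration = cal)
```

## Sectioned FSC in 3D

Fluorescence stacks resolve several-fold worse axially than laterally, so a
single spherical-shell FSC number is of little use.  The sectioned FSC
splits every shell into angular sections indexed by the inclination
$\theta$ from the lateral plane (multiples of $\alpha$, default 15°), and
computes a separate correlation curve and resolution per section, using the
one-bit threshold with the *section's* per-shell sample counts.

**Section geometry (a deliberate design choice).**  A natural reading of
"rotating a dual wedge about the y axis" assigns a voxel by the angle of
its direction *projected* onto the xz plane.  We implemented and rejected
that convention: voxels lying close to the rotation axis (large $f_y$,
small $f_z, f_x$) are then assigned an essentially arbitrary section, and
because they carry sharp *lateral* signal, the axial sections inherit
high-frequency correlation that is not axial at all.  On synthetic volumes
with a threefold axial blur, the axial/lateral resolution ratio collapsed
to ≈1.1.  The shipped convention assigns each voxel its **true inclination**
$\arctan\!\big(|f_z| \,/\, \sqrt{f_x^2+f_y^2}\big)$, with the sign of
$f_\perp f_z$ ($f_\perp$ = the lateral axis perpendicular to the rotation
axis) separating the two mirror wedge families.  Inside the perpendicular
plane this is identical to the dihedral wedge; off-plane voxels are binned
by the angle that actually determines their transfer by an axially
symmetric OTF.  Sections remain a point-symmetric partition of the sphere,
per-shell section counts still sum to the plain-FSC counts, and at
$\alpha = 2\pi$ the measurement reduces to plain FSC exactly.  With this
geometry the synthetic threefold anisotropy is recovered with a ratio of
≈2.5 (the residual shortfall is the finite 15° section width mixing
inclinations, plus the leakage floor discussed next).

**Windowing (a second deliberate choice).**  2D FRC uses the customary
Hamming window.  For the sectioned 3D measurement Hamming is not good
enough: its side lobes decay slowly, and the in-plane spectral ridge of a
typical specimen is many orders of magnitude stronger than the noise floor
in the sparsely populated axial sections.  The leaked (deterministic,
therefore *correlated*) signal held the axial correlation near 0.9 far
beyond the axial band limit in our simulations.  `sfsc()` therefore windows
with Hann by default, whose faster side-lobe decay suppresses the artefact;
`apply_window()` exposes both windows, and `sfsc(..., window = "hamming")`
restores the classical behaviour.

Anisotropic sampling is corrected by multiplying the voxel size for the
section at $\theta$ by $k(\theta) = 1 + (z-1)\,|\sin\theta|$, $z$ the
axial/lateral sampling ratio: no correction laterally, full correction
axially.  (A form of this factor sometimes quoted,
$(1+(z-1))\cdot|\sin\theta|$, vanishes at $\theta = 0$ and would make
lateral resolutions infinite; we implement the evidently intended form
above.)
Volumes are linearly resampled to isotropic spacing
(`resample_isotropic()`) before any shell measurement; a single volume is
split with `volume_split()` — one checkerboard diagonal per xy plane,
consecutive z layers summed pairwise so proportions are kept and no axial
offset is introduced.

## Restoration

**Low-pass denoising.**  The FRC cutoff $1/d_\mathrm{min}$ parameterizes an
ideal, Butterworth ($H = 1/(1+(r/r_{th})^{2n})$, $H(r_{th}) = 1/2$ for
every order) or Gaussian ($H = e^{-r^2/2r_{th}^2}$, $H(r_{th}) = 0.607$)
transfer function.  The ideal filter is the default: beyond the FRC cutoff
there is, by construction, no signal to ring against.  All filters have
$H(0)=1$ (mean preserved exactly) and $H \le 1$ (energy never increases).
With an SFSC result the cutoff surface becomes elliptical (per-axis
cutoffs), an extension the 2D theory leaves open.

**Wiener inverse filtering.**  $O = H^*/(|H|^2 + w)\, I$ with $w$ the
noise-to-signal power ratio.  Note the parameter convention: `snr_reg` *is*
the additive constant $w$ (0.1 for 2D, 0.005 for 3D are the customary
choices), so smaller values regularize less.  Quoting these values as an
"SNR" to be inverted would flip their meaning and turn the inverse filter
into a matched-filter blur — with $|H| \le 1$, adding $1/0.1 = 10$ to
$|H|^2$ leaves essentially $O \propto H^* I$.  We verified both readings on
synthetic data and implemented the one under which the published parameter
values actually sharpen.

**Richardson–Lucy.**  The multiplicative update
$o_{k+1} = \{ i/(h \otimes o_k + b) \otimes h^* \}\, o_k$, optionally
divided by the total-variation factor
$1 - \lambda_{TV}\,\mathrm{div}(\nabla o_k/|\nabla o_k|)$
($\lambda_{TV} = 5\times10^{-4}$ is the customary weight).  Convolutions
are evaluated in the frequency domain after mirror-padding by one PSF half
support, so periodic wrap never crosses real structure; a `"circular"`
boundary is available and conserves flux exactly at $b = 0$.  The
background $b$ defaults to 0 and can be estimated blindly as the mean of
the below-threshold segment of an Otsu split (`estimate_background()`).
$o_0$ is the observed image (common convention).  Denominators are floored
at machine epsilon; estimates are clipped at 0 after every step.

**FRC-driven stopping.**  After every iteration the single-image FRC
resolution of the estimate is recorded (for 3D estimates, on the central z
plane — a cheap per-iteration proxy for the full SFSC).  Its first
difference ∇Resolution (nm/iteration) drives the stopping rule: stop when
∇Resolution rises to or above a threshold, with −1 nm it⁻¹ ("most of the
gain made"), −0.2 nm it⁻¹ ("near convergence") and 0 ("maximal
resolution") the recommended settings — these are physical-unit thresholds
and assume nanometre spacing.  When a calibration model is supplied in
`rl_options()`, the per-iteration resolution is calibrated so the
thresholds act on the two-image-equivalent scale; this is the recommended
configuration.  A failsafe watches the second difference: once the
resolution has been improving, a sign flip of ∇Resolution (equivalently a
∇² zero crossing against the convergence trend) aborts the run — the
signature of background over-fitting.  Because per-iteration FRC values
are noisy, `rl_options(grad_smooth = 3)` offers a 3-point moving average
of the gradient; the default is the raw difference.  Two classical
convergence metrics, $\tau_1$ (relative change of successive estimates)
and $\eta_k$ (fraction of non-converging ratio-image pixels,
$\varepsilon = 0.05$ by default), are recorded alongside for comparison;
they track convergence but carry no resolution information.

In *adjustive* mode the Gaussian PSF is re-rendered from the latest
resolution estimate after every iteration — useful when the initial
estimate is poor (very noisy data), at the cost of a possible PSF
overestimate, which the TV term is there to restrain.

## The synthetic-acquisition module

`acquisition_spec()` + `make_phantom()` + `simulate_acquisition()` generate
the test conditions every claim above is validated against: filament
phantoms (smoothed random walks deposited with sub-pixel linear splatting,
emulating cytoskeletal fibres), point phantoms (Poisson-count sub-pixel
emitters), or a mixture; Gaussian blur with per-axis FWHM; scaling so the
blurred peak equals `peak_photons`; optional uniform background; pure
Poisson counting noise in `n_realizations` independent streams derived
from one seed.  Everything is deterministic given the spec.

Default study conditions (chosen once, stated here so the tests are
interpretable): 2D — 256² pixels at 50 nm, FWHM 250 nm, peak 200 photons,
no background; 3D — 96³ voxels at 40 nm, lateral FWHM 200 nm, axial
600 nm (the threefold anisotropy typical of a single-objective system),
peak 500 photons; calibration series — pixel sizes 29, 46, 63, 80, 97,
113 nm.  Test suites use smaller crops (64²–128², 64³) of the same
conditions to stay fast.

What the generator does *not* emulate: read noise and detector offset,
optical aberrations and vectorial PSF structure, scanning artefacts,
sample drift between the two realizations (the registration path is
exercised with synthetic shifts instead), and spatially varying PSFs.
Passing tests therefore demonstrate correctness of the estimators and
restoration machinery under photon-limited Gaussian-blur imaging — not
robustness to every instrument artefact found in real data.

## Numerical conventions and degenerate inputs

* Spacing is stored in nm throughout; µm inputs are converted on entry.
  Axis order is (z, y, x), z the optical axis; indices in the parity
  splits are 0-based.
* Rings/shells have unit width in frequency pixels of the longest axis;
  DC is its own bin.  The real part of the cross-spectrum is used; rings
  with vanishing normalization are dropped (a constant image keeps only
  DC and is flagged "no crossing").
* Odd dimensions are truncated by one trailing sample before parity
  splitting, preserving the parity classes.
* PSF kernels are rendered on odd-sized grids (centre on a voxel) with
  ±4σ support and unit sum.
* Isotropic resampling targets the *smallest* spacing (upsampling), and
  keeps the physical origin of the first sample.
* Registration guarantees integer-pixel accuracy by phase correlation;
  the sub-pixel refinement is a quadratic fit of the correlation peak and
  is reported alongside the integer shift actually applied.
* Images at least 16×16 are required for single-image FRC; smaller inputs
  error out rather than returning meaningless numbers.

## Known limitations

* The axial SFSC resolution is biased optimistic by ≈25 % at the default
  15° section width (inclination mixing within a section); the
  lateral/axial *ratio* — the quantity of practical interest — is
  recovered well.  Narrower sections trade this bias for noisier curves.
* The single-image calibration is threshold-specific; applying it to any
  criterion other than 1/7 is refused with a warning.
* Per-iteration FRC inside RL is an estimate with its own noise; on very
  small images the stopping rules should be used with `grad_smooth = 3`.
* The Wiener and RL paths assume a spatially invariant Gaussian PSF; block-wise
  locally adaptive deconvolution is out of scope.
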