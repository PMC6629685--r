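# frcrestore

Blind image restoration for fluorescence microscopy driven by Fourier ring
correlation (FRC) resolution measurements.

## The problem

Deconvolution and frequency-domain denoising need to know how blurred an
image actually is — classically supplied as a calibrated point-spread
function (PSF) or a hand-measured resolution.  FRC provides that number
automatically: given two images of the same field with independent noise,

```
FRC(r_i) = Σ_{r∈r_i} Re F₁(r)·F₂(r)*  /  sqrt( Σ|F₁|² · Σ|F₂|² )
```

computed over concentric frequency rings, drops from ~1 (shared structure)
to ~0 (independent noise); the frequency where it falls below the 1/7
threshold is the effective resolution `d_min`.  This package implements
that measurement and everything it unlocks:

* **two-image FRC** with phase-correlation registration and Hamming
  windowing, and **single-image FRC** via checkerboard splitting with a
  calibration against the two-image reference;
* **sectioned Fourier shell correlation (SFSC)** for direction-dependent
  resolution of 3D stacks with strong axial anisotropy, with the one-bit
  SNR threshold and anisotropic-sampling correction;
* an **effective Gaussian PSF** from the resolution
  (`FWHM = d_min`, `σ = d_min / 2√(2 ln 2)`);
* **restoration**: low-pass denoising at the FRC cutoff (ideal /
  Butterworth / Gaussian), blind **Wiener** inverse filtering
  (`O = H*/(|H|²+w)·I`), and blind **Richardson–Lucy** deconvolution with
  total-variation regularization, blind background estimation, adjustive
  per-iteration PSF updates, and FRC-driven stopping rules
  (∇Resolution thresholds −1 / −0.2 / 0 nm it⁻¹ plus a ∇² failsafe);
* a **synthetic-acquisition module** (filament/point phantoms, Gaussian
  blur, Poisson noise) providing ground truth for every test.

Audience: microscopists and image-analysis developers who want
resolution-aware, parameter-light restoration of confocal / STED style
data without instrument calibration.

## Worked example

```r
library(frcrestore)

# a synthetic confocal acquisition: filaments, 50 nm pixels,
# 250 nm PSF FWHM, peak 200 photons, two noise realizations
spec    <- acquisition_spec(kind = "filaments", shape = c(256, 256),
                            pixel_size_nm = 50, fwhm_nm = 250,
                            peak_photons = 200, seed = 7)
phantom <- make_phantom(spec)
imgs    <- simulate_acquisition(phantom, spec)

# reference two-image measurement
two_image_frc(imgs[[1]], imgs[[2]])
#> <frc_resolution> d_min = 252.6 nm (1/7 threshold)

# single-image measurement, calibrated to the two-image scale
cal <- default_calibration(seed = 123)
one_image_frc(imgs[[1]], calibration = cal)
#> <frc_resolution> d_min = 241.7 nm (1/7 threshold, calibrated)

# blind Richardson-Lucy restoration with FRC-driven stopping
res <- restore(imgs[[1]], "blind_rl", calibration = cal)
res
#> <restore_result> blind_rl: d_min 241.7 -> 227.8 nm (one_image_calibrated FRC)
head(res$report$trace, 4)
#>   k d_min_nm      grad      grad2       tau1       eta
#> 1 0 241.7385        NA         NA         NA        NA
#> 2 1 236.6826 -5.055917         NA 0.09439218 0.6548309
#> 3 2 232.6772 -4.005469  1.0504474 0.06292369 0.6122284
#> 4 3 228.4616 -4.215602 -0.2101321 0.04722601 0.5785675
```

The two-image FRC recovers the simulated 250 nm PSF width within ~1 %;
the calibrated single-image value agrees with it to a few per cent.  The
RL trace records, per iteration, the estimate's resolution, its first and
second differences (the stopping signals), and the classical convergence
metrics τ₁ and η_k; the run stopped when ∇Resolution rose above the
default −1 nm it⁻¹ threshold.

For 3D stacks, `resample_isotropic()` + `volume_split()` + `sfsc()` give
per-angle resolutions (and a polar plot via `plot()`); `restore()` uses
the lateral/axial values for an anisotropic PSF automatically.

A thin command-line wrapper over these functions ships in
`inst/cli/frcrestore.R` (`frc`, `denoise`, `wiener`, `rl`, `simulate`
subcommands, TIFF in/out with pixel-size metadata).

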