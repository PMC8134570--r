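# fanxrd

A digital twin of a fan-beam coded-aperture X-ray imaging system that
acquires co-registered **transmission** and **diffraction (XRD)** images of
thin objects. X-ray transmission resolves shape and density but often
cannot tell materials apart; coherent-scatter (XRD) spectra are
molecular-structure fingerprints but are classically slow to image. The
fan-beam coded-aperture architecture measures multiplexed scatter from an
entire 150 mm fan slice in one exposure — a patterned absorbing plate
imposes a position-dependent modulation on the scatter, so computation can
recover where along the fan each spectral contribution originated.

`fanxrd` implements the whole computational chain for this architecture in
simulation, for people studying or designing such systems: synthetic
phantoms and reference spectra, the physical forward model, the
statistical reconstruction, and the derived image products and
characterization metrics.

## The model in brief

* **Conversion**: momentum transfer `q = sin(θ/2)/λ(E)` (Å⁻¹), with
  `λ = hc/E` and `hc = 12.39842 keV·Å`.
* **Source**: Kramers-law Bremsstrahlung filtered by Be/Al/Hf slabs
  (`exp(−μ(E) t)`, log-log interpolated attenuation tables); the hafnium
  K-edge at 65.35 keV shapes a quasi-monochromatic band summarized by an
  effective energy `E0 = 60 keV`.
* **Coded aperture**: random 40%-open pattern of 0.75 mm square features
  in 3 mm copper with an 8 mm central slit, 100:1 modulation contrast, and
  `atan(0.75/3) ≈ 14°` thickness collimation.
* **Forward model**: sparse system matrix `H` mapping (fan voxel, q bin)
  coefficients to expected detector counts via per-pixel scattering
  angles, solid angle, mask transmission of each voxel→pixel ray, and the
  Thomson polarization factor; scatter frames are
  `Poisson(φ·H f + b)`.
* **Reconstruction**: Poisson maximum-likelihood (MLEM / Richardson–Lucy)
  multiplicative updates `f ← (f / Hᵀ1) ⊙ Hᵀ(m/(Hf+b))`, per slice,
  stitched into a hyperspectral datacube.
* **Products**: mean-q maps over 0.1–0.3 Å⁻¹, viridis colorization, TQC
  (transmission × q-color) images, hyperspectral q windows, zero-lag
  normalized spectrum cross-correlation, and FWHM-based q/spatial
  resolution reports.

## Worked example

Simulate the aluminum well calibration phantom — twelve paired 1 × 4 × 3 mm³
wells spanning the fan, signal wells filled with aluminum powder, paired
background wells empty — then reconstruct and characterize it:

```r
library(fanxrd)

geometry <- system_geometry(pixel_pitch = 0.5)
mask     <- generate_mask(seed = 7)
qgrid    <- q_grid(0.04, 0.33, 0.002)
sm       <- build_system_matrix(geometry, mask, qgrid)

wells <- make_well_phantom()          # 12 aluminum-filled wells over 150 mm
scan  <- assemble_scan(wells, sm, seed = 1)
cube  <- reconstruct_scan(scan, sm)
characterize(cube, wells)
```

```
<characterization_report> 12 wells (12 detected)
  centroid error: 0.0332 +/- 0.0276 mm (max 0.0758)
  line position error: 0.00011 +/- 0.00008 1/A
  line FWHM: 0.00958 +/- 0.00006 1/A
  spectrum cross-correlation: 0.9725 +/- 0.0012
```

Reading the report: every 1 mm aluminum feature is detected and localized
to well under 0.2 mm across the 150 mm field of view; the reconstructed
aluminum (111) line at q = 0.2139 Å⁻¹ comes back within ~1e−4 Å⁻¹ of the
Bragg position with a full width at half maximum of ≈ 0.0095 Å⁻¹; and each
well's background-subtracted spectrum cross-correlates at ≈ 97% with the
ground-truth aluminum reference.

From a reconstruction you can then render the combined
transmission + q-colorized view or pull region spectra:

```r
mq  <- mean_q_map(cube)                       # mean q per XRD voxel
img <- tqc_image(cube$transmission, mq)       # RGB array
spec <- region_mean_spectrum(cube, 5:7, 70:72)
cross_correlation(spec, reference_spectrum("aluminum", qgrid)$intensity)
```

The end-to-end chain (phantom → scan → reconstruction → products →
manifest) is one call: `run_pipeline(default_config(), seed = 1,
out_dir = "runs/demo")`, with presets `calibration_wells`, `letter_d`, `two_pill`
and `tissue_slab`.

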