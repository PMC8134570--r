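---
title: "Methods: the fanxrd digital twin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the fanxrd digital twin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fanxrd)
```

## The system being modeled

`fanxrd` is a digital twin of a fan-beam coded-aperture X-ray imaging
system that acquires co-registered transmission and diffraction (XRD) data
from thin objects (up to 10 mm). A filtered Bremsstrahlung source
illuminates a 150 × 1 mm² slice of the object; the transmitted beam passes
through a slit in a patterned copper plate (the coded aperture) and forms a
transmission profile, while coherent scatter from every position along the
fan passes through the random open/closed pattern of the plate. Because
scatter originating at different fan positions projects the mask pattern
differently onto the detector, a single multiplexed frame encodes *where*
each contribution came from, and per-voxel momentum-transfer spectra can be
recovered computationally. Scanning the object through the fan in 1 mm
steps (step-and-shoot) and stitching the per-slice estimates yields a
planar hyperspectral datacube with a co-registered transmission image.

The momentum-transfer convention throughout is

$$q = \frac{\sin(\theta/2)}{\lambda(E)}, \qquad
\lambda(E) = \frac{hc}{E} = \frac{12.39842\ \mathrm{keV\,\text{Å}}}{E},$$

with $\theta$ the full scattering angle, so the water coherent-scatter peak
falls near 0.16 Å⁻¹ and the design range is 0.05–0.3 Å⁻¹.

## Forward model

**Source.** The tube output follows Kramers' law,
$\Phi(E) \propto (E_\mathrm{kVp}-E)/E$ on 1 keV bins from 10 keV, without
tungsten characteristic lines. Beam filtration (0.75 mm Be, 1 mm Al, and a
50 µm hafnium foil) is applied per-bin as
$\exp(-\mu(E)\,t)$; the hafnium K-edge at 65.35 keV truncates the hardened
spectrum from above, producing the quasi-monochromatic XRD band that the
scatter model summarizes by a single effective energy $E_0 = 60$ keV.
Mass attenuation coefficients are compact representative tabulations
(about a dozen energies per material, log-log interpolated, K-edges
represented by closely spaced duplicate points); tissue-like materials
reuse the water table with their own density, which is accurate at these
energies where their attenuation is water-like.

**Coded aperture.** A 2D random pattern of 0.75 mm square features in 3 mm
copper, 40% open among the non-slit cells (exactly
$\mathrm{round}(0.4N)$ open cells placed by a seeded shuffle), with a fully
open 8 mm central slit for the primary fan. The plate's modulation
contrast is taken as the operative 100:1 figure rather than recomputed
from the copper table (which gives ≈ 70–80:1 at 60 keV): a fully closed
chord transmits the contrast floor 0.01, and partial chords transmit
$\exp(-\mu_\mathrm{eff} L_\mathrm{closed})$ with
$\mu_\mathrm{eff} = -\ln(0.01)/3\,\mathrm{mm}$, where the closed path
length is found by sampling the chord at 11 depths through the plate.
This reproduces the gradual angular rolloff implied by the
$\arctan(0.75/3) \approx 14°$ collimation cutoff of the feature geometry.

**System matrix.** For each fan voxel $v$ and q bin $j$, the scatter cone
is traced by a dense per-pixel angle computation: every pixel $p$ of the
scatter readout band is assigned the q bin of its exact scattering angle
from $v$, with weight

$$H_{p,(v,j)} = \underbrace{\frac{A\,\Delta z}{\|d\|^3}}_{\text{solid angle}}
\cdot\; T_\mathrm{mask}(v \to p) \;\cdot\;
\underbrace{\tfrac{1}{2}(1+\cos^2\theta)}_{\text{polarization}},$$

where $d$ is the voxel-to-pixel vector and $T_\mathrm{mask}$ the
coded-aperture transmission of that ray at its aperture-plane crossing.
Scatter is monoenergetic at $E_0$; incident-beam attenuation upstream of
the voxel and self-attenuation are ignored (thin-sample regime), while
transmission imaging uses the full polychromatic Beer–Lambert model.
Every column with $q_j$ in the design range is checked to have positive
sensitivity at matrix build time.

**Polychromatic blur.** The finite spectral width of the XRD band is
emulated by a Gaussian q-smearing kernel applied to the true spectra
before projection, with $\sigma_q(q) = q\,\sigma_E/E_0$. The
reconstruction deliberately uses the *unsmeared* monoenergetic operator,
so the recovered spectra carry the blur — mirroring the real system, where
the estimator's monoenergetic approximation leaves the spectral width in
the result. The default $\sigma_E = 0.75$ keV is a calibration: together
with the default crystalline reference line width (below) it gives
$\mathrm{FWHM} = 2.355\sqrt{(q\,\sigma_E/E_0)^2 + w_c^2} \approx
0.0095\ \text{Å}^{-1}$ at the aluminum (111) line at $q = 0.214$ Å⁻¹,
the resolution regime this class of system operates in. The hardware
literature quotes a much narrower "effective width" for the filtered band
than standard attenuation physics can produce from a 50 µm foil, so the
width is exposed as a parameter rather than asserted.

**Noise.** Scatter frames are Poisson draws around the linear model mean,
$m \sim \mathrm{Poisson}(\phi\,Hf + b)$, with the flux scale $\phi$
calibrated so the brightest expected pixel reaches ≈ 2500 counts (the
detector operating point), and a small uniform air-scatter/detector
background $b$ (default 2 counts/pixel) that is also what the bracketing
air scans measure. Transmission acquisitions are modeled noise-free: they
are short, high-flux, energy-integrating slit readouts whose photon noise
is negligible relative to the scatter channel.

## Geometry defaults

Component distances are not published for the hardware, so the defaults
are chosen to make the optical layout self-consistent: source–object
450 mm, source–aperture 600 mm, source–detector 800 mm, with the
detector's long axis (292 mm) along the fan. The resulting magnification
(800/450 ≈ 1.78) keeps the whole 150 mm fan *and* the q = 0.3 ring
(θ ≈ 7.1°, ring radius ≈ 44 mm at the 350 mm object–detector lever) on the
active area, and the q = 0.05 ring (radius ≈ 7.2 mm) outside the 10 mm
beam-block band. A shorter lever would degrade the q per-pixel sampling;
a larger magnification would push the fan ends off the detector. The
scatter readout band is one side of the fan projection (5–65 mm); the
half-ring carries the same positional information as the full ring at half
the compute. All distances and windows are config-overridable.

## Synthetic data

The phantom factory generates the study objects programmatically at a
0.25 mm grid (4× finer than the 1 mm fan voxels, so partial-volume mixing
at boundaries emerges naturally):

* **Well phantom** — a PLA slab spanning the fan with 12 paired
  1 × 4 × 3 mm³ wells at 12.5 mm spacing: signal wells hold aluminum
  powder, background wells are empty, enabling paired background
  subtraction of the body's own scatter.
* **Two-material phantom** — a 30 × 30 × 6.5 mm³ plastic body with a 5 mm
  deep letter-shaped well filled with water.
* **Pills and tissue slab** — gel-shelled liquid capsules in air, and an
  adipose/fibroglandular slab with an embedded cancer blob.

Reference spectra are parameterized forms: crystalline aluminum as a Bragg
comb from the fcc lattice ($q_{hkl} = \sqrt{h^2+k^2+l^2}/2a$,
$a = 4.0495$ Å, relative powder intensities), convolved with a Gaussian
line width $w_c = 0.003$ Å⁻¹ approximating the instrumental width of a
commercial powder diffractometer (the role the reference measurement plays
when real data are scored); PLA as a semicrystalline line at 0.094 Å⁻¹
(the 16.7° Cu-Kα reflection converted by Bragg's law) over an amorphous
hump; water, gel and tissues as 1–3 Gaussian humps at the canonical
positions (adipose 0.111, water/fibroglandular/cancer near 0.16 Å⁻¹ with
differing widths and shoulder ratios). Each material carries a relative
per-mm scatter strength. These shapes reproduce the *positions, widths
and contrasts* that drive the imaging products; they are not digitized
literature curves, so fidelity claims are about parameter recovery, not
tissue-curve realism.

## Reconstruction

Per slice, the classic MLEM / Richardson–Lucy multiplicative update

$$f \leftarrow \frac{f}{H^\top 1} \odot H^\top\!\frac{m}{Hf + b}$$

maximizes the Poisson likelihood, preserving nonnegativity exactly and
increasing the log-likelihood at every iteration. Defaults: uniform
positive initialization, 150 iterations, stop at relative log-likelihood
change below 1e−6. No regularization is applied. Coefficients whose
sensitivity $H^\top 1$ is below 1e−12 of the maximum are frozen at zero;
an all-zero measurement returns a zero estimate with a warning. The
background rate $b$ is the per-pixel mean of the bracketing air scatter
frames. The estimator is deterministic: identical inputs give
bit-identical estimates.

## Image products

* **Mean q** — intensity-weighted mean over 0.1–0.3 Å⁻¹ per voxel; voxels
  with in-range integral below 2% of the image maximum are invalid
  (masked, not NaN-propagated).
* **Colorization** — linear map of mean q onto a perceptually uniform
  palette (viridis by default) over a *fixed* 0.1–0.3 Å⁻¹ range so colors
  are comparable across scans; invalid voxels render neutral grey.
* **TQC** — per-pixel multiplication of the transmission intensity with
  the mean-q color, after nearest-neighbor upsampling of the 1 mm XRD
  voxels onto the finer transmission grid (nearest preserves voxel
  boundaries). The default intensity convention is attenuation-bright
  ($1-T$): dense material bright, air black; a flag flips it.
* **Cross-correlation** — zero-lag normalized inner product
  $\sum a_i b_i / \sqrt{\sum a_i^2 \sum b_i^2}$ on raw nonnegative
  spectra, without mean subtraction (a Pearson variant would change the
  values; the raw form is the one whose axioms — symmetry, scale
  invariance, 1 iff proportional — the tests assert).
* **FWHM** — half-maximum crossings by linear interpolation on each side
  of the peak, apex by a parabolic fit through the three bins around the
  maximum; edge peaks are flagged and reported one-sided.

## Problem sizes and numerical choices

The shipped configurations are desk-scale: 0.5 mm detector binning for
scans (0.2 mm for the resolution studies), a 0.04–0.33 Å⁻¹ q grid at
0.002–0.0025 Å⁻¹ bins, 150 fan voxels at 1 mm. At these sizes a full-fan
system matrix has 2–12 million nonzeros, builds in seconds to tens of
seconds, and a slice reconstructs in about a second — the well-phantom and
two-material studies in the acceptance script complete in a couple of
minutes on one CPU. The q grid extends slightly past the 0.05–0.3 Å⁻¹
design range so peaks at the range ends are not truncated; each pixel is
assigned its nearest q bin (sub-bin spreading is unnecessary at these bin
widths); chord sampling through the mask plate uses 11 depths.

## What passing tests do and do not show

The twin commits the "inverse crime" deliberately for everything except
the spectral blur: the reconstruction uses the same geometry and mask
model that generated the data. Passing the characterization suite
therefore shows that the *pipeline* — encoding, system matrix, Poisson
estimator, products — is internally correct and achieves the design
resolution and fidelity under the stated noise and flux, not that the
model matches any physical scanner. Effects absent from the twin and
therefore untested: tungsten characteristic lines, Compton scatter,
detector energy response and lag, focal-spot blur, textured
(non-isotropic) crystalline scatter, self-attenuation and multiple
scatter beyond the thin-sample regime, and depth-resolved (volumetric)
reconstruction.
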