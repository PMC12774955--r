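---
title: "Coded-surface lensless ptychography: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coded-surface lensless ptychography: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`codedpty` simulates and inverts a lensless microscope in which the only
"optic" is a known random complex modulator (the *coded surface*) resting a
fixed distance `d2` above the pixel array, with the sample a millimeter-scale
distance `d1` above the surface. The sensor is shifted laterally between
exposures; each exposure records the intensity of the sample's diffracted
field after modulation by the coded surface. This vignette explains the
forward model, the reconstruction, and every numerically meaningful choice
the package makes, so results can be interpreted and the defaults challenged.

## Forward model

A scan position $i$ shifts the sample field laterally by $(x_i, y_i)$
relative to the sensor assembly. Writing $E_s$ for the field of source state
$s$ at the coded-surface plane, the recorded intensity is an incoherent sum
over mutually incoherent contributions,

$$I_i(x,y) \;=\; \sum_s |OS_s(x,y)|^2 \;+\; \sum_s |VS_s(x,y)|^2,$$

with the object path

$$OS_s = \{E_s(x - x_i,\, y - y_i)\cdot CS(x,y)\} * \mathrm{PSF}_{\mathrm{free}}(d_2)$$

and, during reconstruction only, a *virtual error-bin* path $VS_s$ built the
same way from an auxiliary field $E_{\mathrm{virtual}}$ and a deliberately
perturbed propagation distance $d_2 \cdot a$ (default $a = 1.1$). The
simulator (`simulate_dataset()`) implements the true physics — object path
only — plus controllable artifacts; the reconstruction
(`reconstruct()`) fits both paths. Because the virtual path's forward model
is wrong by construction, signal consistent with the accurate object model
has no incentive to enter it, while artifact energy — finite source
bandwidth, sensor-stack double reflections, other model mismatch — drains
into $E_{\mathrm{virtual}}$ instead of corrupting the object estimate. With
$a = 1$ and a shared coded surface the two paths are degenerate duplicates
and the mechanism collapses, which is why `recon_options()` refuses that
combination.

Free-space propagation uses the band-limited angular-spectrum method: the
exact scalar transfer function
$H(u,v) = \exp\!\big(i 2\pi d \sqrt{1/\lambda^2 - u^2 - v^2}\big)$ with
evanescent components zeroed and the local-frequency band limit applied so
that long-distance propagation does not alias across the periodic grid.
FFTs are unitary throughout, so $\sum |E|^2$ is conserved exactly on the
band-limited support and energy checks are direct. A paraxial Fresnel
transfer function is available (`method = "fresnel"`) as a cross-check; at
the package's 0.2–2 mm working distances the two agree to a global phase.
The field of view is treated as periodic (circular shifts); the simulator
and the reconstruction share this convention exactly, and phantoms keep a
margin so content never straddles the wrap.

## Partial coherence

An LED emitter is modeled geometrically: each spatially incoherent point
state at emitter offset $\delta$ shifts the detector-plane pattern by
$\delta\,(d_1 + d_2)/D_{\mathrm{source}}$ (shadow magnification through the
$\approx$ 3 mm lever arm of a $\approx$ 200 mm folded path), and intensities
add. Finite temporal bandwidth is simulated by re-evaluating the propagation
phases at each sampled wavelength of a Gaussian spectrum — the physically
correct mismatch a coherent reconstruction cannot explain — rather than by
blurring intensities. In the reconstruction, source states are shifted
replicas of a single master field with fixed offsets and weights, keeping
one unknown field; fully independent mode fields are out of scope. The
emitter size and state count are free parameters (the hardware papers do not
publish them); the examples use a 300 µm-scale disc with five states, a
typical LED die size.

## Reconstruction engine

Each epoch visits the frames in a seeded random order. Per frame: evaluate
the forward model; replace the modeled magnitudes by the measured ones with
a *shared-magnitude projection* — every state is scaled by
$\sqrt{I_{\mathrm{meas}}/I_{\mathrm{model}}}$ pixel-wise, so the updated
mixture reproduces the measurement exactly while preserving per-state
ratios (pixels whose model intensity is below $10^{-12}\times$ the frame
mean take the measured magnitude with their current phase); back-propagate
the *residual* spectrum with the conjugate transfer function; update the
object field with a regularized inverse modulation (rPIE-style denominator
$(1-\gamma)|CS|^2 + \gamma\,\max|CS|^2$, $\gamma = 1 -$ `update_step`,
default 0.1). Two details matter numerically:

* The residual is formed **in-band**: the update uses
  $\mathcal{F}^{-1}\{(\hat\psi' - \hat\psi)\,H^*\}$, never a difference
  against the raw exit field. Out-of-band exit content is invisible to a
  band-limited measurement, and subtracting it would erode the object
  estimate even at the exact solution; with the in-band residual the truth
  is an exact fixed point (verified in the tests to data error $< 10^{-20}$).
* The coded surface is known and held fixed, as is the virtual path's copy
  of it; only the two fields are updated. With a known, strongly modulating
  surface the inverse problem has no global-shift or scale gauge freedom
  (only a global phase), which is why noiseless benchmarks recover the
  phantom to machine precision.

The multi-resolution schedule (default 2 levels) spends 30% of iterations
at half resolution — frames $2\times2$-binned, coded surface Fourier-cropped
— then upsamples the fields and refines at full resolution. The binned
problem is only approximately consistent, so this stage is a warm start, not
an oracle; its usefulness depends on the coded surface being representable
at half-band, which is one reason the default coded-surface correlation
length is 4 pixels (also the scale of fabricated disorder-engineered
diffusers). A surface with pixel-scale features would alias badly under
Fourier cropping and make the warm start counterproductive.

Scan positions are refined post-measurement (`refine_positions()`,
every `refine_positions_every` iterations): the measured frame is projected
and back-propagated to an implied object patch, demodulated by the coded
surface, and cross-correlated against the current model patch; the sub-pixel
peak (quadratic fit, lowest-index tie-break) corrects the stored position,
clamped to 1 px per update. A single-frame dataset is left pinned — with one
frame the positions are defined only up to a global offset.

## Deep-UV mass recovery

Absorption obeys the decadic Beer–Lambert law on intensity,
$I = I_{\mathrm{bg}}\,10^{-\varepsilon c l}$, so the simulator's exit
*amplitude* carries half the optical density. Only the product $c\,l$ is
identifiable, so phantoms and results store *areal molar densities*
(mol/µm²); extinction coefficients are correspondingly per mol·µm⁻²
(a conventional $\varepsilon$ in M⁻¹cm⁻¹ times $10^{11}$). The two-wavelength
system

$$OD_\lambda = \varepsilon_\lambda^{pro}\, n^{pro} +
             \varepsilon_\lambda^{nuc}\, n^{nuc}, \qquad
  \lambda \in \{266, 280\}\ \mathrm{nm}$$

is inverted per pixel by the closed-form 2×2 determinant expressions;
negative amounts (noise) are reported, then clipped. Masses follow as
$m = n \cdot (\mathrm{pixel\ size})^2 \cdot M$ in femtograms per pixel. The
shipped `default_extinction_table()` is **synthetic**: a BSA-like protein
(66.5 kDa, $\varepsilon_{280} \approx 4.4\times10^4$ M⁻¹cm⁻¹, lower at
266 nm) and an average nucleotide (330 g/mol, $\varepsilon$ peaking near
260 nm, roughly halved at 280 nm). These reproduce the *shape* of real DUV
contrast; quantitative work on real data must supply measured constants.
The full path (`duv_mass_pipeline()`) squares the reconstructed amplitudes,
takes the background as the median over a stated empty region of interest,
registers the 280 nm image onto the 266 nm image by upsampled phase
cross-correlation, unmixes, and converts to mass.

## Autofocus and height mapping

Focus is scored with the Brenner gradient (squared finite differences at
offset 2, normalized by pixel count) over a back-propagation sweep, with
parabolic sub-step refinement. The score is computed on the **amplitude**
by default: for specimens with phase structure the defocused *intensity*
develops caustic texture whose gradient energy grows past the true focal
plane and pulls an intensity-based metric toward millimeter-scale errors,
while the amplitude metric stays sharply peaked at focus (intensity scoring
remains available via `on = "intensity"`). Even so, a strong phase
component displaces the amplitude-sharpness plane by a constant offset
(~0.1 mm at the defaults) — constant because the score depends only on
$d_1 - z$ — so focus-recovery accuracy is specified for
absorption-dominated samples, the regime of stained-free smears the method
targets. `height_map()` refocuses the *full* field at each candidate $z$
and scores overlapping tiles on the refocused amplitude; cropping tiles
before propagating would sever their diffraction context. Tiles are marked
invalid — and filled from the nearest valid tile, with the validity mask
returned — unless their best-focus amplitude shows real dynamic range,
their score curve is peaked rather than flat, and their peak score clears a
field-relative floor (near-empty tiles score an order of magnitude below
tiles with structure, and fringe leakage from neighbours must not
masquerade as content); $z$ is reported relative to the coded surface, and
converting it to a display height is a presentation choice.

## Virtual staining and cytometry

Rendering is a pure deterministic function of the mass maps. Fluorescence
mode maps each species through a saturating linear response
$\min(m/\mathrm{scale}, 1)$ (scale defaulting to the species' 95th positive
mass percentile) along fixed color vectors — nucleic acid in blue, protein
in purple — on a dark background; the saturating *linear* map was chosen
over an exponential soft-knee so that doubling a mass doubles the rendered
excess below saturation. H&E mode mixes optical densities,
$RGB = 10^{-(m'_{nuc} v_{nuc} + m'_{pro} v_{pro})}$, using the classic
hematoxylin and eosin stain-separation directions, then adds a constant
green term so empty background renders white; every channel is
non-increasing in every mass before that term. The palette is numeric and
user-replaceable — the underlying works describe the colors only
qualitatively. The contrast metric used for method comparisons is declared,
not inherited: Michelson contrast on a 1st–99th percentile-clipped region
of interest, which is gain-invariant and robust to isolated pixels.

Segmentation is deliberately standard, with one considered substitution:
the cell mask uses a triangle (Zack) threshold — estimated on the smoothed
image for stability, applied to the raw image so boundaries stay faithful,
followed by a small morphological opening — because the histogram is
background-dominated with a two-tier foreground (faint cytoplasm, dense
nuclei) and Otsu then cuts *inside* the foreground, halving cells at the
nuclear boundary. Hole filling and watershed on the distance map split
touching cells; nucleus masks use Otsu restricted to cell interiors on the
nucleic-acid channel, where the two-class assumption does hold.
Features are the usual morphometrics; nuclear roundness is the
isoperimetric quotient $4\pi A/P^2$ with the perimeter measured as traced
contour length summed over nucleus components (and clamped at 1, where
rasterization can slightly overshoot). The phantom generator's
mononuclear-like kind (one round nucleus, high nuclear-to-cell area ratio)
and polymorphonuclear-like kind (three lobes, low roundness) separate with
zero overlap along the roundness axis at the generator defaults — a
property of the generator's morphology, not a claim about real leukocytes.

## What the simulations do and do not show

The phantom generator emulates: smooth elliptical cells with
nucleic-acid-rich nuclei, Beer–Lambert DUV absorption at realistic optical
densities (nuclear nucleic acid ~0.3–0.7 at 266 nm, matching ~6 pg per
diploid-scale nucleus; protein ~0.1–0.2 at 280 nm), micron-scale topography
with an index contrast of 0.1, partially coherent illumination, shot/read
noise, ghost reflections and scan-position jitter. One bookkeeping caveat:
because the default table represents "total protein" by a BSA-like *molar*
coefficient, per-cell protein masses implied by these optical densities
land a few times above textbook per-cell protein content — the unmixing is
exactly self-consistent either way, but absolute protein femtograms from
the default table should be read as order-of-magnitude. It does not emulate: out-of-band scattering,
refractive-index dispersion, coded-surface calibration error, sensor PRNU,
thick (multi-slice) samples, or the morphological diversity of real
cytology. Passing the simulation benchmarks therefore demonstrates the
*inverse machinery* — propagation, projection, unmixing, refinement — is
correct and self-consistent, not that real-data image quality is attained.
Problem sizes in the tests (256×256 detector with an 8×8 scan for the main
benchmark; 128×128 with 6×6 for the ablations) were chosen as the smallest
grids on which the benchmarks are well-conditioned, with every quantity
recomputed from scratch at run time.

## Defaults worth knowing

| Parameter | Default | Meaning |
|---|---|---|
| `d2` | 840 µm | coded surface to pixels, fixed by the sensor assembly |
| `d1` | 200–2000 µm | sample to coded surface; 800 µm in examples |
| `a` | 1.1 | virtual-path distance perturbation factor |
| `pitch` | 1.85 µm | assumed back-illuminated CMOS pitch (not a published value) |
| scan steps | 1–3 µm (hardware-scale) / 4–7 µm in tests | uniform per-move step range |
| `update_step` | 0.9 | rPIE relaxation; denominator mixes 10% of max |CS|² |
| `feature_size` | 4 × pitch | coded-surface correlation length |
| photon budget | 10⁴ counts/px | shot-noise scale at background |
| ghost | r = 0.1, δ = 2·d2 | sensor-stack double-bounce artifact |
| LED bandwidth | 10 nm FWHM, 5 samples | finite temporal coherence artifact |

Open choices resolved here, for the record: the propagation operator is the
transfer-function (angular-spectrum) form, not an impulse-response
convolution; the virtual path shares the object path's coded surface and
only the virtual *field* is refined; registration uses upsampled phase
cross-correlation; the background for optical density is an ROI median.
Each is exposed as a parameter where a practitioner might reasonably
disagree.
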