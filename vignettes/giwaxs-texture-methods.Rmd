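---
title: "Methods: grazing-incidence texture analysis of cell-wall cellulose"
author: "gixtex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: grazing-incidence texture analysis of cell-wall cellulose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gixtex)
```

This vignette is the package's account of the science it implements: the
optical and crystallographic model, the reduction and stitching procedure,
the tunable parameters and the numerical choices behind them, what the
synthetic-data generator does and does not emulate, and the known
limitations.

## 1. The measurement model

A plant primary cell wall mounted flat on a substrate is probed by an
X-ray beam at a grazing incidence angle $\alpha_i$ close to the critical
angle for total external reflection. Three closed-form quantities anchor
the geometry:

* wavelength $\lambda = hc/E$ with $hc = 12.3984$ keV·Å;
* electron density $\rho_e = \rho N_A \sum_i w_i Z_i / A_i$ of the wall,
  modelled as anhydroglucose (C$_6$H$_{10}$O$_5$) at $\rho = 1.5$ g/cm³ —
  cellulose, pectin and hemicellulose are all hexose/pentose polymers with
  nearly this composition and density, so one carbohydrate formula
  represents the dried wall;
* critical angle $\theta_c = \sqrt{2\delta}$,
  $\delta = r_e \lambda^2 \rho_e / 2\pi$. At 10 keV this gives 0.147°, at
  12.7 keV 0.116°, which is why incidence angles of 0.12–0.15° are used.

The 1/e penetration depth is
$\Lambda = \lambda / (c \,\mathrm{Im}\sqrt{\alpha_i^2 - \theta_c^2 + 2i\beta})$
with $\beta = \mu\lambda/4\pi$ and $c = 4\pi$ (intensity-1/e, the package
default) or $2\pi$ (amplitude-1/e, exactly twice as deep). Published
grazing-incidence depths rarely state which convention or which
attenuation data they used, so the package implements both behind a flag
and treats literature depths as order-of-magnitude anchors only. Mass
attenuation coefficients for H, C, N, O are embedded as anchors at 8, 10,
15 and 20 keV with log–log interpolation; no network access is needed or
attempted.

### Detector to reciprocal space

Every pixel of a flat detector at distance $D$ is mapped exactly: the
pixel direction in the beam frame, $(D, h, v)/L$, is rotated by
$-\alpha_i$ about the horizontal axis into the laboratory frame, the
scattered wavevector $\mathbf{k}_f$ lies on the Ewald sphere, and
$\mathbf{q} = \mathbf{k}_f - \mathbf{k}_i$ is decomposed into $q_{xy}$ and
$q_z$. The polar angle is $\chi = \mathrm{sign}(h)\,
\mathrm{atan2}(|q_{xy}|, q_z)$, with $\chi = 0$ along the substrate
normal and $\pm 90^\circ$ in plane. No small-angle approximation is made
anywhere in the mapping.

On the detector meridian the identity
$\chi = (\alpha_f - \alpha_i)/2$ holds exactly, which makes the
missing-wedge rule
$\chi_\mathrm{min}(q) = \arcsin(q/2k) - \alpha_i$ exact there: no
accessible exit direction reaches a smaller $|\chi|$ at that $q$.
Refraction shifts near $\theta_c$ are ignored; at the working band
$q \ge 0.99$ Å⁻¹ they are far below the bin width. The per-pixel
solid-angle weight is $(D/L)^3$, normalised to 1 at the beam centre.

## 2. Cellulose Iβ crystallography

d-spacings come from the general triclinic reciprocal metric tensor, so
the monoclinic Iβ cell (a = 7.784, b = 8.201, c = 10.38 Å, γ = 96.5°) is
just a special case, and the orthorhombic closed form is recovered when
all angles are 90° (a property test). The principal equatorial
reflections come out at q = 1.055 and 1.182 Å⁻¹ — the (110)/(1̄10) pair —
and 1.625 Å⁻¹ for (200). Which member of the pair carries which label
varies across the literature with the sign convention of the monoclinic
angle, so the package reports the pair with low-q/high-q roles and never
asserts the assignment.

Size broadening follows the q-space Scherrer form
$\Delta q_\mathrm{FWHM} = 2\pi K / L$ with $K = 0.9$ by default. At the
$L \approx 30$ Å coherent size of primary-wall microfibrils,
$\Delta q \approx 0.19$ Å⁻¹ exceeds the 0.13 Å⁻¹ splitting of the pair,
so the simulated 1D pattern shows a single merged maximum near
1.12 Å⁻¹ — the package's explanation of the broad experimental feature
near 1.15 Å⁻¹ — while $L = 300$ Å resolves both members. Peak profiles
are area-normalised Gaussians by default (pseudo-Voigt via `eta`);
no profile function is asserted beyond that, and no structure factors are
computed: relative reflection weights are user inputs, with equal weights
as the neutral default.

The epicuticular wax phase is a two-reflection lamellar stack with
d = 4.13 and 3.73 Å (q = 1.521, 1.684 Å⁻¹) and a 300 Å default size —
much sharper than the cellulose reflections, as observed.

## 3. The synthetic-data generator

A `Scene` is a sum of phases (reflection list × texture × scale), an
amorphous Gaussian halo, and a flat background, all multiplied by an
exposure scale and the solid-angle weight. Orientation densities
$g(\chi)$ are normalised over the hemisphere with the $\sin\chi$ measure,
$\int_0^{90^\circ} g(\chi)\sin\chi\, d\chi = 1$, so "fraction within
$\pm\chi_0$" has an unambiguous analytic value for any texture — the
ground truth the pole-figure estimator is tested against. Kinds:
isotropic ($g \equiv 1$), Gaussian about the normal, and a 4°-wide
Gaussian at $\chi = 90°$ standing in for a true in-plane delta (a delta
cannot be rendered on a pixel grid).

Expected counts are Poisson means; noisy frames draw independent Poisson
counts per pixel from one integer seed. Rendering conventions worth
stating:

* **GIWAXS**: intensity at a pixel is the radial profile at $q$ times
  $g(\chi)$ at the Ewald-corrected $\chi$; the missing wedge is zeroed.
* **Transmission WAXS**: the beam is normal to the wall, so out-of-plane
  texture is invisible; each phase contributes its radial profile
  isotropically (in-plane isotropy of the polylamellate wall).
* **Rocking series**: the sample rocks through $\theta_s$; the package
  uses the small-tilt mapping in which a pixel with apparent polar offset
  $\chi_\mathrm{det}$ probes crystallite tilt
  $\chi = \chi_\mathrm{det} + (\theta_s - \theta_B(q))$,
  $\theta_B = \arcsin(q/2k)$. The specular $q = 2k\sin\theta_s$ sweeps
  the 110 band as $\theta_s$ goes 4.4°→5.9° at 12.7 keV (0.99→1.31 Å⁻¹).
  The mapping is quoted as valid for $|\chi| \lesssim 30°$, which is
  exactly the sector the rocking branch uses. Summing the series smears
  tilts by about ±1.5°, less than the default 2.5° χ bin. An exact
  Ewald-wedge treatment of each rocking frame was considered and
  rejected: it introduces a partial-coverage dip for $|\chi| \lesssim
  1.5°$ that the stitched-pole-figure method does not model.

Scene presets mirror specimen preparations: `unextracted` (textured
cellulose + in-plane wax + halo), `driselase` (wax + halo only — the
polysaccharides digested), `chloroform` (cellulose + halo — wax
extracted), `ground` (isotropic cellulose + halo), `stem_segment`
(tighter texture). The cellulose texture width defaults to σ = 35°, a
moderate out-of-plane preference of the kind epidermal walls show. The
halo (centre 1.4 Å⁻¹, FWHM 0.7 Å⁻¹, amplitude 20 × the cellulose scale)
is a synthetic stand-in chosen so that amorphous scattering is comparable
to the Bragg peaks, as in real walls; it is not a fitted literature
parameterisation. With these presets the unextracted-style scene yields a
Segal CI near 30%.

What the generator does **not** emulate: detector point-spread and
flat-field structure, polarization, air scatter, refraction distortion,
paracrystalline disorder, and any Iα/Iβ mixture. Passing tests therefore
demonstrate the correctness of the reduction and estimators on data obeying
the stated forward model, not robustness to every instrumental artefact of
real beamline frames.

## 4. Reduction

Profiles are means per bin (not sums), so sectors of different area are
comparable. Pixels are assigned to the nearest bin centre; pyFAI-style
pixel splitting is deliberately not used, which matters only for
low-count bins. Bins no valid pixel reaches are flagged (`nPixels = 0`,
NA), never zero-filled. Poisson uncertainties propagate per pixel
($\hat\sigma^2 = \mathrm{counts}$), and cake integration with the
solid-angle correction off conserves the masked counts exactly — a test
to 1e-6 relative.

One refinement beyond plain histogramming: the azimuthal profile first
regroups the annulus into `qCells` radial sub-cells per χ bin (default 8)
and then averages cells with equal weight. On coarse detectors the pixel
grid samples the ring tangentially near the vertical axis, so plain
per-pixel means weight the q positions unevenly in exactly the bins the
rocking branch owns — up to several percent of deterministic shape
distortion. Equalising the q weighting removes it while leaving flat
frames and uniform scenes bit-exact.

Sector defaults are the out-of-plane −17°…+17° and in-plane 78°…88°
conventions; whether the two signed in-plane lobes are combined is
exposed as `bothLobes` since the convention in use at beamlines varies.
Local background subtraction is pointwise in χ with uncertainties in
quadrature; negative differences are kept (clipping would bias the
estimator) and counted in the profile metadata. The registry of
background bands holds the onion GIWAXS [0.5, 0.6] Å⁻¹ choice plus the
Arabidopsis/moss GIWAXS and per-specimen rocking bands.

GISAXS line cuts default to the vertical cut at $q_y = 0.012$ Å⁻¹ and
horizontal cut at $q_z = 0.03$ Å⁻¹, both 0.005 Å⁻¹ wide, and record
their parameters in the profile metadata.

## 5. Pole figures and metrics

The χ-pole figure of the 110 band ($1.15 \pm 0.16$ Å⁻¹) combines:

* the **GIWAXS branch**, background-corrected azimuthal profile for
  $|\chi| \ge 7.5°$ (smaller $|\chi|$ is wedge territory);
* the **rocking branch**, the summed series reduced within
  $|\chi| < 30°$ and background-corrected with the rocking band.

The GIWAXS branch is multiplied by
$s = \overline{I_\mathrm{rock}(\pm 7.5°)} / \overline{I_\mathrm{GIWAXS}(\pm 7.5°)}$
— the two match bins averaged, deliberately not a fit. In the 7.5°–30°
overlap the GIWAXS branch wins: it has far better statistics
off-specular, and the small-tilt mapping of the rocking data is least
accurate toward its 30° edge. The scale factor's relative variance is
carried in the pole-figure metadata so that downstream integrals can
count the shared-scale noise of the whole GIWAXS branch, which per-bin
uncertainties alone miss.

**Oriented fraction.** $F(\chi_0) = \int_0^{\chi_0} I w\, d\chi \big/
\int_0^{90} I w\, d\chi$ on the folded $|\chi|$ trace, with
$w = \sin\chi$ (hemisphere measure, default) or $w = 1$; both are always
computed because the convention behind literature "fraction within ±34°"
figures is often unstated, and the choice is recorded in the result.
Numerically, each bin value is treated as the *average* of $I$ over the
bin's support — that is what the histogram reduction delivers — and the
weight is integrated in closed form per bin. Treating bin values as point
samples at centres instead leaves a deterministic quadrature bias of a
few parts in $10^3$, larger than the counting error at $10^6$ counts. A
uniform pole figure reproduces $1 - \cos\chi_0$ and $\chi_0/90$ to
machine precision. Because $\chi = 90°$ itself is unreachable in grazing
incidence, the sub-bin sliver between the last bin edge and 90° is
filled by extrapolating the last two bins. Folding averages the two
signed lobes and warns if their integrals differ by more than 20%.

**Texture width** is the FWHM of the folded trace about its maximum with
linear interpolation, relative to the trace floor; isotropic or monotone
traces return a flagged NA rather than an error.

**Segal crystallinity** uses fixed q windows — maximum in
[1.40, 1.70] Å⁻¹ for $I_{200}$, minimum in [1.10, 1.40] Å⁻¹ for
$I_{am}$ — a wavelength-independent transcription of the classic
Cu-Kα 2θ points. CI is a height-based proxy: it is monotone in the
crystalline fraction only when the amorphous background decays smoothly
across both windows. The test suite therefore exercises it with a broad
decaying background (centre 0.8, FWHM 2.0 Å⁻¹); with the preset halo
centred at 1.4 Å⁻¹ the amorphous window contains the 110 peak and the
index loses that geometry — a known limitation of the Segal method
itself, not of the implementation.

### Interaction of the halo with the fixed background bands

The onion background band [0.5, 0.6] Å⁻¹ removes flat backgrounds
exactly but captures almost none of a halo centred at 1.4 Å⁻¹, so a halo
pedestal survives under the 110 band and inflates the pole-figure tails;
for the `unextracted` preset this depresses the sin-weighted ±34°
fraction from ~0.42 (injected) to ~0.24. This is a faithful rendering of
what the fixed-band method does on halo-dominated data. The
texture-recovery tests consequently use halo-free scenes (cellulose +
flat background), where the estimator is unbiased; recovery there is
verified within 3 Monte-Carlo standard errors for σ = 10°, 20°, 35°,
with the MC error taken from replicate spread (floored by the propagated
counting error).

## 6. Orchestration and reproducibility

`runPipeline()` drives simulate → map → reduce → pole figure → metrics
from one validated YAML config (unknown keys rejected by name before any
computation). Every run writes TIFF frames (32-bit integer counts,
lossless), CSV profiles with '#'-prefixed parameter headers, the
pole-figure CSV with its scale factor, a YAML run record (package
version, config hash, stage seeds, metrics, per-file checksums) and a
plain-text log. Defaults follow the rocking-scan beamline setting
(12.7 keV, 0.12°); the default sample–detector distance is 125 mm, which
puts the wax ring and the 2.0–2.2 Å⁻¹ rocking background band on a
512 × 512 × 0.172 mm detector (at 250 mm that detector would stop near
q ≈ 1.1 Å⁻¹ and the analysis bands would fall off the frame).

Angles are degrees and q is Å⁻¹ at every interface; radians exist only
inside functions. Determinism is by explicit integer seeds: one master
seed per run, per-stage seeds derived from it and logged.

### Problem sizes used by the test suite

Tests run on rebinned versions of the default geometry — 64², 128² and
256² pixels with correspondingly larger pixels — chosen so the full
suite completes in well under a minute while leaving every q band used
by the analysis on the detector. The texture-recovery checks use 256²
frames at ≥ 10⁶ counts each, five (acceptance: three) replicates per
texture width. The map-versus-oracle comparison runs per-pixel scalar
trigonometry on a 32² detector.

## 7. Known limitations

* The mapping ignores refraction (no GTSAXS-style correction) and
  polarization; both are stated assumptions, defensible at
  $q \ge 0.9$ Å⁻¹ and synchrotron polarization geometries for χ-profiles
  near the band used here.
* No intensity model: reflection weights are inputs, so simulated
  patterns index positions and widths, not absolute or relative
  intensities; Rietveld-style refinement is out of scope.
* The Iβ peak-position shifts seen in some tissues (unit-cell angle
  perturbations, Iα/Iβ mixtures) are not modelled.
* The rocking small-tilt mapping degrades beyond $|\chi| \approx 30°$;
  the branch never uses data outside that sector.
* The Segal CI inherits all the known biases of height-based
  crystallinity indices; it is reported for comparability, not as a
  quantitative crystallinity.
* Published penetration depths are convention-sensitive; the package's
  intensity-1/e values at the two beamline settings (0.83 and 1.70 µm)
  agree with literature figures only to within the factor-of-2 band that
  the unstated conventions allow.
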