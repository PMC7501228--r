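# gixtex

Grazing-incidence X-ray texture analysis of cellulose in plant primary
cell walls.

## The problem

Primary plant cell walls are thin (a few µm), weakly scattering composites
of crystalline cellulose microfibrils embedded in amorphous pectin and
hemicellulose. Grazing-incidence wide-angle X-ray scattering (GIWAXS) —
striking the wall near the critical angle for total external reflection —
boosts the signal enough to see how cellulose crystal planes are oriented
with respect to the wall plane. But a flat detector in grazing incidence
cannot intercept the whole Ewald sphere: crystallites lying almost parallel
to the substrate fall in a *missing wedge* around the surface normal, so a
complete orientation distribution needs specular rocking scans stitched
onto the GIWAXS data.

`gixtex` implements that analysis chain end to end, for people who reduce
grazing-incidence data from fibrous or lamellar biological films:

* **X-ray optics** — wavelength λ = hc/E; electron density
  ρₑ = ρ·N_A·Σ wᵢZᵢ/Aᵢ; critical angle θ_c = √(2δ) with
  δ = rₑλ²ρₑ/2π; 1/e penetration depth
  Λ = λ / (4π·Im√(αᵢ² − θ_c² + 2iβ)).
* **Reciprocal-space mapping** — exact per-pixel (q, χ) with
  Ewald-curvature correction, the lab frame rotated by the incidence
  angle αᵢ; χ = 0 along the substrate normal, ±90° in plane; the
  missing-wedge half-angle is χ_min(q) = asin(q/2k) − αᵢ.
* **Cellulose Iβ crystallography** — triclinic d_hkl via the reciprocal
  metric tensor (monoclinic cell a = 7.784, b = 8.201, c = 10.38 Å,
  γ = 96.5°), Scherrer broadening Δq = 2πK/L, simulated 1D powder
  patterns, and the two-ring lamellar wax phase (d = 4.13, 3.73 Å).
* **A forward renderer** — synthetic GIWAXS frames, rocking series and
  transmission frames from generative scenes (textured cellulose,
  in-plane wax, amorphous halo, Poisson noise), so the whole pipeline is
  testable without beamline data.
* **Reduction** — sector profiles (out-of-plane −17°…+17°, in-plane
  78°…88°), azimuthal profiles over q = 1.15 ± 0.16 Å⁻¹, cake
  integration, GISAXS line cuts, local background subtraction.
* **χ-pole figures and metrics** — GIWAXS branch (|χ| ≥ 7.5°) scaled to
  the rocking branch at χ = ±7.5°, oriented fraction
  ∫₀^χ0 I(χ)·sin χ dχ / ∫₀^90 I(χ)·sin χ dχ, distribution FWHM, and the
  Segal crystallinity index CI = 100·(I₂₀₀ − I_am)/I₂₀₀.

## Worked example

Optics of the model cell wall (anhydroglucose at 1.5 g/cm³, 10 keV):

```r
library(gixtex)
wall <- cellWallMaterial()
electronDensity(wall)            # 0.4791 e/A^3
criticalAngle(wall, 10)          # 0.147 deg
criticalAngle(wall, 12.7)        # 0.116 deg
penetrationDepth(wall, 10, 0.15) # 0.83 um (intensity-1/e convention)
```

The critical angles say a 0.12–0.15° incidence sits right at the
enhancement condition for carbohydrate films; the depth says the beam
probes a micron-scale portion of the wall. Indexing the cellulose Iβ
cell:

```r
pl <- peakList(celluloseIbeta(), qMax = 1.7)
pl[pl$family_label %in% c("(1-10)", "(110)", "(200)"), c("family_label", "q_invA")]
#    family_label   q_invA
#  6        (1-10) 1.054887
#  7         (110) 1.181717
#  15        (200) 1.624829
```

These are the q ≈ 1.05, 1.18 and 1.62 Å⁻¹ equatorial reflections; at the
~3 nm crystal size of primary-wall microfibrils the first two merge into
one broad feature near 1.15 Å⁻¹ (`powderPattern(celluloseIbetaPhase(30), ...)`).

A full synthetic run — render, reduce, stitch, measure:

```r
rec <- runPipeline(list(scene = list(preset = "unextracted")),
                   outdir = "demo_run", seed = 1)
rec
# gixtex run record ...
#   config hash: 10d2bf890200dde8  seed: 1
#   oriented fraction (sin): 0.243; FWHM 78.5 deg; Segal CI 32.8%
```

The record means: after local-background correction and stitching, 24% of
the (110)/(1̄10) plane normals sit within ±34° of the wall normal under
the sin χ hemisphere measure (the residual amorphous pedestal under the
reflection depresses this figure for halo-dominated scenes — see the
methods vignette), the orientation distribution is ~79° wide at half
maximum, and the height-based crystallinity of the out-of-plane profile
is ~33%. `demo_run/` holds the frames (TIFF), profiles and pole figure
(CSV), a YAML run record with per-file checksums, and a log.

A thin command-line wrapper lives at `inst/cli/gixtex.R`
(`Rscript gixtex.R optics|simulate|reduce|polefigure|metrics ...`).

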