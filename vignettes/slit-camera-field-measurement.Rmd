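---
title: "Measuring X-ray fields beyond the detector with a fluorescent-foil slit camera"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring X-ray fields beyond the detector with a fluorescent-foil slit camera}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slitfov)
```

## The measurement problem

Every clinical radiography system collimates its beam to a rectangular
field on the detector, and regulations bound how far that field may extend
beyond the image receptor: in mammography, no edge may overshoot by more
than 2% of the source-to-image distance (SID) under the US CFR/MQSA rules,
and no more than 5 mm under the European guidelines. The awkward part of
verifying this is that the interesting part of the field is, by
definition, *off* the detector — conventional tests need external films,
CR plates or electronic rulers, and none of those work per-projection in
digital breast tomosynthesis (DBT), where the field can swing well beyond
the detector at large tube angles.

The method implemented here avoids external sensors entirely. A thin metal
foil is placed in the beam at a known height above the detector, parallel
to it. Primary photons absorbed photoelectrically in the foil re-emit
characteristic (fluorescence) K X-rays isotropically; a slit camera — two
heavy brass plates with a 1 mm gap, the linear analogue of a pinhole —
projects this emission plane onto the detector. The foil keeps fluorescing
wherever the beam hits it, including the part that overhangs the detector,
and the slit maps that overhang back *into* the image. Locating where the
projected fluorescence band vanishes therefore measures the field boundary
that lies outside the detector, using only the system's own detector.

## Projection geometry

All positions are 1D coordinates in mm with the origin at the detector
edge nearest the camera, positive toward the detector centre; heights are
measured above the detector plane. With the foil at height $y_{foil}$, the
slit at $(x_{slit}, y_{slit})$ and the source at $(x_{source}, y_{source}
= SID)$, similar triangles give the field boundary $X_{FOV}$ from the
measured edge position $x_{edge}$:

$$
X_{FOV} \;=\; \frac{x_{edge} + \dfrac{y_{foil}}{y_{slit}}\,(x_{slit} -
x_{edge}) - \dfrac{y_{foil}}{y_{source}}\, x_{source}}{1 -
y_{foil}/y_{source}}
$$

Negative $X_{FOV}$ means the field extends beyond the detector.
`fov_boundary()` implements this relation, `invert_fov_boundary()` its
algebraic inverse (used to place ground truth in synthetic scenes), and
`project_to_plane()` the magnification $SID/(SID - h)$ that scales
distances read on an elevated plane (for instance a ruler on the breast
support, $h$ = 25 mm) down to the detector plane.

```{r}
geom <- slit_geometry(y_foil = 63.5, y_slit = 31.35, x_slit = 33.0,
                      y_source = 661.2, x_source = 23.6, side = "chest_wall")
fov_boundary(geom, x_edge = 69.74)
```

The derivative $dX_{FOV}/dx_{edge} = (1 - y_{foil}/y_{slit})/(1 -
y_{foil}/y_{source})$ is about $-1.13$ for this geometry: edge-localization
errors propagate to the boundary essentially one-to-one, which is why the
edge fit below is the accuracy-critical step.

## Edge localization

The projected edge is not sharp: the focal spot (~0.35 mm) and the 1 mm
slit aperture blur it over a few millimetres, and the fluorescence signal
itself is faint — on a 14-bit detector with a ~50 ADU offset, the band
runs at roughly 150 ADU over a ~100 ADU scattered background under the
camera. The pipeline in `measure_field()` therefore:

1. integrates a 500-pixel-wide region of interest along the slit
   (`extract_profile()`), turning a fraction-of-a-percent pixel-level
   signal into a clean line profile;
2. smooths with a 5-pixel mean filter (`smooth_profile()`); end windows
   are truncated rather than reflected, so no signal is invented beyond
   the detector edge;
3. normalizes the profile to its minimum inside the camera
   (`normalize_profile()`), pinning the background baseline at exactly 1
   and cancelling exposure and incidence-angle differences between views;
4. fits an ordinary least-squares line to the steep intensity fall and
   extrapolates it to the baseline value of 1 (`fit_edge()`); the
   intersection defines $x_{edge}$.

The fit window is the part of the falling flank between 15% and 85% of the
plateau-to-baseline drop (configurable via `profile_config()`). The
plateau level is the median of the longest contiguous run above half the
maximum contrast *inside the camera window* — restricting to the camera
window matters, because the open-field region beyond the camera shadow is
brighter than the fluorescence band and would otherwise hijack the plateau
search at low contrast. The flank walk stops early if the signal rises
again after entering the fit band, which keeps the transmission step at
the end of the foil (visible in hard-spectrum DBT acquisitions) out of the
fitted window. A profile whose contrast never exceeds `min_contrast`
(default 0.05) raises a no-edge error rather than returning a meaningless
fit.

`fit_edge()` returns a small model object with `print`, `summary`, `coef`,
`predict`, `residuals` and `plot` methods; the reported $R^2$ is a useful
health indicator — at realistic noise levels a sound fit sits above 0.9,
and a value far below that usually means slit misalignment (a blurred
flank) or a mis-specified camera window.

## Foil physics and thickness optimization

The foil material must absorb strongly (photoelectric), fluoresce
efficiently, and emit K X-rays energetic enough to cross the breast
support yet soft enough for the detector. The bundled constants (Table of
`element_constants()`) cover Cu, Zr, Mo, Ag and Sn; for a 39 kVp
mammography beam Mo and Zr are the natural candidates, for ~100 kVp
general radiography Sn.

Thickness is a trade-off — a thick foil absorbs more primaries, a thin
foil lets more fluorescence escape. For a foil of thickness $t$ at normal
incidence, integrating K-shell absorption at depth $z$ times downward
escape over the remaining $t - z$ gives a closed form per primary photon
of energy $E$:

$$
D(t, E) = \mu_K(E)\,
\frac{e^{-\mu_f t} - e^{-\mu_p(E)\, t}}{\mu_p(E) - \mu_f},
$$

with $\mu_p$ the foil's total attenuation at $E$, $\mu_f$ at its own
K$\alpha$ energy, and the $\mu_p = \mu_f$ limit handled as
$t\,e^{-\mu t}$. `fluorescence_signal()` weights this by the spectrum, the
K$\alpha$ radiative yield and energy, and the transmission of the escape
path (2.5 mm polycarbonate support plus the air gap, by default — the slit
itself is open, so no brass is crossed). For a monoenergetic beam the
optimum is analytic, $t^* = \ln(\mu_p/\mu_f)/(\mu_p - \mu_f)$, which the
test suite uses as an oracle; for a full spectrum `optimize_thickness()`
evaluates a thickness grid and reports the argmax (ties toward the thinner
foil, which is also the practical choice).

```{r}
s39 <- xray_spectrum(39, target = "W", filters = list(filter_layer("Ag", 60)))
optimize_thickness("Mo", s39, c(5, 10, 25, 50, 100, 250))
```

This is an analytic surrogate for a full Monte Carlo transport
calculation, and it is worth being explicit about what it keeps and drops.
It keeps the terms that decide the argmax: spectrum-weighted K-shell
photoelectric absorption, fluorescence yield, and exponential
self-attenuation of the K$\alpha$ escaping toward the detector. It drops
scatter generated in the support, L-shell fluorescence, oblique incidence
(available as the geometry is normal-incidence by assumption), angular
integration of the escape, and the detector energy response. Those omitted
terms rescale the curve but move its maximum very little, so relative
curves and optimal thicknesses are trustworthy while absolute signal
values are not, and no absolute value is ever asserted.

Numerical choices in the physics layer:

- **Attenuation tables.** Bundled as plain CSV (1–150 keV), derived from
  Cromer–Liberman photoabsorption with Klein–Nishina incoherent and a
  screened-form-factor coherent term (the generation script ships in
  `scripts/`). Interpolation is log-log; every absorption edge is stored
  as a duplicated grid-point pair (±0.1%) and queries falling inside a
  pair resolve to the above-edge branch, so interpolation never bridges a
  discontinuity. Photoelectric mean free paths in brass at the Mo/Zr/Ag
  K$\alpha$ energies agree with reference values within ~3%; the scattering
  channels are a few-percent-level approximation that never dominates any
  quantity the package reports.
- **K-shell partition.** $\mu_K = \mu_{PE}(1 - 1/J_K)$ with the jump
  ratio $J_K$ read off the table's own edge pair; accurate to a few
  percent above the edge, which is ample for an argmax.
- **Spectrum model.** A Kramers-type bremsstrahlung shape
  $\propto (E_{max} - E)/E$ on a 0.5 keV grid (bin centres offset from
  edge energies), filtered by $e^{-\sum \mu_i t_i}$ and renormalized.
  Characteristic anode lines and anode self-filtration are not modelled;
  the filtered mean energy of the 39 kVp W + 60 µm Ag beam comes out
  ~21.2 keV, at the soft end of the expected 22.5 ± 1.5 keV band. Users
  who need spectral fidelity can load a measured spectrum with
  `read_spectrum()` — every downstream function only consumes the
  (energy, weight) grid.

## The synthetic scene generator

`render_scene()` exists so that the whole measurement pipeline can be
exercised with known ground truth and no hardware. It emulates exactly the
features the edge fit has to cope with: the 50 ADU offset, a ~150 ADU open
background halved under the brass shadow, the fluorescence band at its
configured plateau, Poisson noise on everything above the offset, 14-bit
clipping, the 2×2-binned DBT variant (`bin_2x2()`), and optional artifact
toggles for the foil-end transmission step and direct slit transmission
seen at large DBT angles.

Two modelling decisions deserve justification:

- **Flank shape and placement.** The falling flank is a single linear ramp
  of width penumbra + slit blur whose *foot* — the point where the linear
  extrapolation meets the baseline — sits exactly at
  `invert_fov_boundary(geom, x_fov_true)`. Since $x_{edge}$ is defined
  operationally as that extrapolation point, this placement makes the
  ground truth self-consistent: a noiseless render is recovered to
  numerical precision, and any error measured on noisy renders is
  attributable to noise and the fitting procedure rather than to an
  arbitrary convention about where "the edge" of a blurred ramp lies. A
  centred two-box trapezoid was considered and rejected because it builds
  a fixed half-kernel offset into every recovery comparison.
- **Penumbra model.** The focal-spot blur needs a beam-defining aperture
  to exist at some height; the prototype description does not state one,
  so the renderer assumes a collimator edge 100 mm below the source
  (configurable). The resulting width — focal spot × collimator-to-foil
  lever arm × slit demagnification — is linear in the spot size and is
  cross-checked in the tests against a 10⁴-ray sampling oracle.

What the generator does *not* emulate, and what passing tests therefore do
not demonstrate about real acquisitions: heel effect, anti-scatter grid
residues, off-focal radiation, detector MTF beyond the two geometric
blurs, gain non-uniformity, and slit-to-detector misalignment (the slit is
assumed parallel to the pixel grid; on real data misalignment shows up as
a blurred flank and a depressed $R^2$). Recovery statistics quoted by the
tests are statements about this noise model at the stated contrast, not
about clinical images.

## Compliance checking

`check_compliance()` applies the CFR any-side rule ($|X_{FOV}| \le$ 2% of
SID), the MQSA chest-wall addition (the beam must actually reach past the
chest wall edge, $X_{FOV} < 0$), and the EU overhang limit (≤ 5 mm beyond
the detector). `light_xray_misalignment()` and `congruence_verdict()`
cover the light/X-ray congruence sum (≤ 2% of SID over opposing sides).
`qc_report()` assembles per-view measurements into a table with
differences against a reference view (by default the full-field
mammogram), attaches the verdicts, and serializes to JSON with 17
significant digits so a re-loaded report reproduces every numeric field
exactly. Reports always state the sign convention in their header.

## Default parameters at a glance

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `roi_width` | 500 | px | integration band along the slit; SNR grows as √n |
| `smooth_width` | 5 | px | mean filter; wide enough to help, narrow vs the flank |
| `camera_window` | (5, 95) | mm | inside the 100 mm camera shadow, clear of both ends |
| `fit_fraction_low/high` | 0.15 / 0.85 | — | mid-flank band, avoids both toes |
| `min_contrast` | 0.05 | — | below this, declare "no edge" instead of fitting noise |
| plateau / background / offset | 150 / 100 / 50 | ADU | signal levels of the prototype acquisitions |
| `focal_spot` | 0.35 | mm | clinical mammography tube |
| `aperture_mm` | 1 | mm | prototype slit gap |
| escape path | 2.5 mm polycarbonate + air | — | breast support; slit is open |

## Problem sizes and determinism

The test suite and the acceptance script run at desk scale by design:
rendered scenes are 520 × 1500 px (a ~105 mm span at mammography pitch,
amply covering the camera), recovery statistics use 20 seeds, spectra use
0.5 keV bins, and the depth-quadrature oracle uses 2000 steps. All
randomness flows through explicit seeds; `render_scene()` restores the
caller's RNG state, so identical configurations give bit-identical images
without perturbing the session.

## Known limitations

- Image input is TIFF/PNG/CSV (plus in-memory matrices); DICOM metadata
  must be supplied via the YAML sidecar or function arguments.
- One detector side per measurement; assembling a four-side congruence
  assessment from separate acquisitions is the operator's composition,
  mirrored by `congruence_verdict()`.
- No deskew: a slit not parallel to the pixel grid blurs the flank and is
  only detectable through the fit diagnostics.
- The fluorescence model is relative; absolute ADU predictions are out of
  scope.
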