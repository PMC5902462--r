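---
title: "Methods: tube morphometry, biomechanics and motility of the embryonic gut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tube morphometry, biomechanics and motility of the embryonic gut}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutmorph)
```

## Scope and model

The embryonic chick midgut (around E8) herniates out of the body cavity and
hangs under sustained longitudinal tension transmitted by the vitelline duct
and omphalomesenteric artery. `gutmorph` implements the quantitative machinery
needed to study how that tension drives organ growth in culture:

1. **Morphometry** of a 2D silhouette of the demesenterized midgut, treated as
   a locally axisymmetric tube: midline length $l$, arclength-weighted mean
   diameter $d$, and the solid-of-revolution volume
   $V = \int \pi\, r(s)^2\, ds$ along the arclength-parameterized midline.
   The lumen (< 5% of volume at these stages) is neglected.
2. **Biomechanics**: the hanging mass $m$ exerts a buoyancy-corrected force
   $F = m g (1 - \rho_\mathrm{medium}/\rho_\mathrm{object})$; the applied
   stress is $\sigma = F/S$ with $S = \pi d^2/4$ the initial cross-section;
   the instantaneous elastic strain is $\varepsilon = \sigma/E$; the
   irreversible elongation over culture time $\Delta T$ defines an effective
   tissue viscosity $\eta = \sigma\,\Delta T/(\Delta l/l)$. Dry-mass and
   cell-number budgets are computed against reference densities of native
   tissue: $(m_f - \rho\,V_i)/(\rho\,V_i)$ and $(N_f - n\,V_i)/(n\,V_i)$.
3. **Motility**: kymographs along the tube axis; propagating constrictions
   appear as sloped stripes whose temporal frequency and slope are extracted
   spectrally.
4. **Cohort statistics**: box-plot summaries (median, quartiles, mean),
   two-tailed Mann-Whitney tests, and linear stress-response trend fits.
5. **Synthetic data**: generators for every input above, with analytic ground
   truth, so the whole pipeline is validated end to end.

## Voronoi medial-axis morphometry

The measurement pipeline mirrors the classic silhouette workflow:

* **Segmentation** — Otsu threshold (overridable by a fixed value), largest
  connected component, interior holes filled.
* **Contour** — the binary mask is Gaussian-blurred (default sigma 1 px) and
  the 0.5 iso-level is traced by marching squares. The blur acts as
  anti-aliasing: it converts the staircase pixel boundary into a subpixel
  contour (a 100 px-radius disk's perimeter is recovered to ~0.3%). The
  polygon is resampled to uniform spacing (<= 2 px) and oriented consistently.
* **Medial axis** — the Voronoi diagram of densely resampled contour points
  (at least 400, or 1 point per pixel of perimeter) is computed via a
  Bowyer-Watson Delaunay triangulation written for this package (the
  deployment environment offers no R triangulation library, and the medial
  axis is the heart of the method). Circumcenters of triangles interior to
  the contour approximate the medial axis; the midline is the longest
  geodesic path through the interior Voronoi vertex graph. Input points are
  jittered by ~1e-9 of the object diameter to break the cocircular
  degeneracies a pixel grid creates; this is far below all physical
  tolerances.
* **Smoothing** — x(s) and y(s) are fitted with smoothing splines whose
  penalty is chosen by generalized cross-validation, then reduced if the
  smoothed path deviates from the raw path by more than a tolerance
  (default 1 px). GCV is the primary criterion because the raw interior
  Voronoi path is already extremely clean (deviations ~0.01 px on phantoms);
  an aggressive "smooth as much as the tolerance allows" rule was tried and
  rejected: it shaves the inside of bends and biases the radius low.
* **End handling** — tubes in silhouettes end in rounded tips. Interior
  Voronoi vertices generated by near-collinear point triples on a rounded tip
  have unstable circumcenters that scatter along the axis, so the raw path is
  first trimmed of its cap regions, smoothed, extended along its end tangents
  to the contour tips, and finally cut at the *cap centers*: from each tip,
  the midline is trimmed at the first arclength $u$ where $u \ge w(u)$, with
  $w$ the perpendicular half-width of the silhouette. Inside a hemispherical
  cap $w(u) = \sqrt{2 r u - u^2}$, so the crossing sits exactly at the cap
  center. Reported length is therefore cap-center to cap-center, and volume
  integrates $\pi r^2$ over that span. The nearest-boundary distance cannot
  be used for this trim: inside a spherical cap it equals $u$ everywhere,
  which makes the crossing degenerate.
* **Radius** — at each resampled midline point, the distance to the nearest
  contour point (for Voronoi vertices this is the circumradius, by the empty
  circumcircle property).
* A silhouette whose midline length is less than 3 mean diameters (e.g. a
  disk) is rejected as non-tubular.

### Why cap-center, not tip-to-tip

The synthetic phantoms sweep a disk along a midline of arclength $L$, which
produces hemispherical caps protruding $r$ beyond each midline endpoint.
Ground truth is defined **on the midline**: length $L$, volume
$\int_0^L \pi r^2 ds$ (so a straight phantom with $L = 10$ mm, $d = 0.4$ mm
has truth volume $\pi\,0.2^2\,10 = 1.2566$ mm^3 — exactly the cylinder
formula). Reading length tip-to-tip would systematically add one diameter
(+4% at aspect ratio 25) and make the pipeline disagree with its own ground
truth; reading it cap-center to cap-center makes both measurement routes and
the generator agree to well under 1% on clean phantoms. An `end_rule = "tips"`
option preserves the tip-to-tip convention for users who want the
photographic full extent.

## The independent Bezier reconstruction

As a cross-check (mirroring the original validation of the silhouette
software against a manual Bezier-fitting 3D reconstruction plugin),
`bezier_profile_volume()` reconstructs the tube without any medial-axis
computation: the two contour banks between the tube tips (farthest hull
vertex pair) are paired by normalized arclength; their midcurve is fitted
with a least-squares Bezier curve (default 8 control points); the pairing is
refined twice by reprojecting the banks onto the fitted axis; the end caps
are trimmed with the same perpendicular-half-width convention; and a Bezier
radius profile is fitted to the projected contour-point distances over the
trimmed span and revolved into a volume. A radius-fit residual above 5% of
the mean radius flags the result `"high_residual"`.

On suites of curved phantoms (bend amplitude up to 2 diameters, taper up to
30%, boundary jitter up to 0.5 px) the two routes agree to within ~4% in
length, diameter and volume — `scripts/acceptance.R` recomputes this
agreement from scratch.

## Biomechanical constants

* Stainless steel 7.8 g/cm^3, aqueous medium 1.0 g/cm^3, g = 9.81 m/s^2.
  These standard values reproduce the reported 9-17 uN force range for 1-2 mg
  weights after integer rounding; the original buoyancy note is not
  available, so they are the package's own choices.
* Effective modulus default 1 kPa — the unique value consistent with both
  reported stress-strain pairs (70-100 Pa at 7-10% strain and 100-140 Pa at
  10-14%).
* Mesentery + OMA absorb 25% of the transmitted force; the remainder splits
  over 2 midgut branches.
* Reference densities: dry mass 0.100 (native E8), 0.104 (cultured control),
  0.081 (cultured under tension) mg/mm^3; cells 4.15e5 (native) and 6.60e5
  (cultured) per mm^3.
* With $\sigma = 100$ Pa, $\Delta T = 48$ h and $\Delta l/l = 1$ the
  viscosity formula gives $1.7\times 10^7$ Pa s. The formula is implemented
  exactly as stated; no attempt is made to reconcile it with larger
  order-of-magnitude quotes for gut tissue.

## The synthetic world

The generators are a *stated world*, not tuning knobs; their defaults encode
the experimental conditions and are not adjusted to make tests pass.

* **Tube phantoms**: swept-disk capsules, straight/sinusoidal/seeded-smooth
  midlines, linear taper, smooth radius jitter (Gaussian-correlated, SD in
  px), sub-pixel dither of the grid origin (a photograph never aligns an
  organ to the pixel lattice; perfect alignment creates a degenerate
  half-pixel bias in the raster). Truth is computed by quadrature of the
  generator's own continuous profile at 10x finer than a pixel.
* **Growth cohorts**: percent changes are piecewise linear in stress,
  anchored at the reported control values (-18% length, +2% volume at 0 Pa)
  and the reported +200% length / +180% volume at 150 Pa; the diameter change
  follows the axisymmetric identity
  $(1 + \Delta V/V) = (1 + \Delta l/l)(1 + \Delta d/d)^2$ before independent
  Gaussian noise (6/7/7% SD — the reported control spreads) is added per
  channel. Initial diameters are N(0.35, 0.05) mm — chosen so a 1 mg weight
  produces ~70-100 Pa, since the source reports only that initial diameters
  varied — and initial lengths N(11, 1.5) mm, a realistic E8 midgut scale.
  Final dry mass is rho_group x V_final and final cell count
  n_cultured x V_final.
* **Peristalsis movies**: a straight tube with Gaussian constrictions
  (default depth 0.5, sigma 0.5 mm) nucleating at one end at the stated
  frequency and translating at the stated speed; frames are rendered with a
  1 px anti-aliased edge. Two numerical artifacts motivated these defaults:
  hard binary edges quantize the apparent width to whole pixels and imprint
  strong subharmonics of the nucleation frequency onto the kymograph, and a
  constriction narrower than ~0.5 mm passes a fixed point in under one frame
  interval at the upper physiological speed (0.2 mm/s at 0.5 Hz imaging),
  aliasing the temporal signal. Real optics blur edges and real constrictions
  are broad, so the defaults model the physical situation, not the test.
* **Calibration tables**: deflection = sensitivity x force, Gaussian reading
  noise, four increasing masses as in the weighing protocol.

What a green test does **not** establish: phantoms are noise-free in texture
(no mesentery remnants, no uneven illumination), constrictions are perfectly
Gaussian and periodic, and cohort noise is Gaussian and independent across
channels. Real-image robustness (stains, shadows, touching tissue) is outside
what this synthetic world can certify.

## Motility estimation choices

Frequency is the dominant peak of the Hann-windowed temporal power spectrum
averaged over positions, refined by parabolic interpolation of log-power.
Because a train of localized constrictions is a frequency comb whose dominant
tooth may be a harmonic, the estimator folds the dominant peak onto an
integer submultiple when that submultiple carries a local peak (>= 25% of the
dominant) and the full comb up to the dominant tooth is present. A
consequence worth stating: superimposed waves at exactly f and 2f are
indistinguishable from a single non-sinusoidal wave train and fold onto f;
the `"mixed"` flag therefore considers only non-harmonic secondary peaks
(>= 80% of the primary). Frequencies below the detection floor of two periods
per recording report as 0.

Speed is estimated by a shear search: each kymograph row is advanced in time
by $x/v$ and the variance of the row-averaged profile is maximized over a
log-spaced grid of candidate speeds (both signs), then a fine local grid.
At the true speed the stripes align and their contrast survives averaging.
A spatially mirrored movie flips the reported direction, not the magnitude.

## Numerical conventions

* Units: mm, mm^3, mg, uN, Pa, Pa s, mHz, mm/s; densities mg/mm^3 for tissue
  and g/cm^3 for weights/medium. Conversions are centralized in the
  biomechanics functions.
* Image coordinates: x = column x scale, y = row x scale, origin at the
  top-left pixel center, 0-based.
* Quantiles: linear interpolation (R type 7), matching box-plot convention.
* Mann-Whitney: exact enumeration for pooled n <= 14 without ties; otherwise
  normal approximation with tie and continuity corrections. U counts pairs
  with a > b.
* Trend fits are ordinary least squares of percent change vs stress, controls
  included at 0 Pa; the model is linear because the claimed response is
  proportional to stress (the generator's piecewise law is a property of the
  synthetic world, not of the fit).
* File formats: the deployment environment has no R TIFF/PNG codec, so
  images are written as NetPBM PGM (P5; P2 on request) and movies as
  concatenated P5 frames; tables are CSV and nested results JSON.

## Known limitations

* The Bezier route identifies tips as the farthest hull vertex pair, which
  assumes the tube is globally elongated; a U-bent organ (bend amplitude
  comparable to length) would need manual tip seeding.
* The medial-axis graph is assumed tree-like; silhouettes with holes
  (overlapping loops) are outside scope.
* Kymograph speed estimation assumes a single dominant propagation speed per
  recording.
* The cap-trim convention presumes rounded tube ends; a square-cut tube end
  is trimmed at most half a diameter short.
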