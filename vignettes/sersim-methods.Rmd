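---
title: "Models and methods behind sersim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sersim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sersim)
```

# Scope

`sersim` addresses one question from two sides: *why* do silver
nanostructured surfaces enhance the Raman scattering of cytochrome *c*
sitting 7–17 nm away inside intact mitochondria, and *how* should the
resulting SERS spectra be processed to read out the redox state of the
cytochrome pool? The first half is an electromagnetic scattering model
(coupled dipoles over a metal substrate); the second half is a spectral
pipeline (baseline subtraction, band ratios, redox classification) plus a
synthetic-spectrum generator used to validate the pipeline end to end.

# The coupled-dipole model

## Equations and conventions

Each silver nanosphere, small compared with the wavelength, is replaced by a
point electric dipole at its center. The moments solve the self-consistent
system

$$
\mathbf p_i \;=\; \alpha_i\Big[\mathbf E_{\rm in}(\mathbf r_i)
 + \frac{k_0^2}{\varepsilon_0}\sum_{j\ne i}\hat G(\mathbf r_i,\mathbf r_j)\,\mathbf p_j
 + \frac{k_0^2}{\varepsilon_0}\hat G_s(\mathbf r_i,\mathbf r_i)\,\mathbf p_i\Big],
$$

and the field anywhere outside the spheres is

$$
\mathbf E(\mathbf r) = \mathbf E_{\rm in}(\mathbf r)
 + \frac{k_0^2}{\varepsilon_0}\sum_i \hat G(\mathbf r,\mathbf r_i)\,\mathbf p_i .
$$

Here $\hat G = \hat G_0 + \hat G_s$ combines the free-space dyadic Green
tensor with the substrate-reflected part, $\mathbf E_{\rm in}$ is the
incident plane wave plus its Fresnel reflection from the bare substrate, and
$\alpha_i$ is the Mie dipole polarizability of sphere $i$. Conventions, fixed
once and used everywhere:

* time dependence $e^{-i\omega t}$, so passive media have
  $\mathrm{Im}\,\varepsilon \ge 0$ and outgoing waves carry $e^{+ikR}$;
* SI units with lengths in nanometres;
* the substrate occupies $z \le 0$; a particle resting on it has center
  $z =$ radius (contact, no gap);
* the incident amplitude is 1, so intensities are relative to the incident
  intensity (the experiments report only relative intensities).

The system is solved by a dense direct solve of the $3N\times3N$ matrix
(`solve_dipoles()`), which reports the relative residual and a
reciprocal-condition estimate. At the scales the package targets
($N \lesssim$ a few hundred) this is faster and more transparent than
iterative solvers.

## Materials

The silver permittivity is an analytic Drude–Lorentz fit evaluated by
`silver_drude_lorentz()`; the fit was made against the embedded
Johnson–Christy tabulation (`johnson_christy_silver()`), which doubles as an
independent interpolation oracle in the tests. At 532 nm the fit and the
table agree to about 1% on both the real and imaginary part. One of the
three Lorentz correction terms carries a negative strength; this is a fit
artifact that improves the mid-visible imaginary part, and the total model
remains passive ($\mathrm{Im}\,\varepsilon \ge 0$) over its declared
300–1100 nm validity window, which the test suite sweeps.

The ambient medium defaults to vacuum. The experiments take place in
buffer ($\varepsilon \approx 1.77$), and `optical_constants()` accepts any
lossless ambient; the vacuum default was chosen because the reference
near-field maps were computed for particles in vacuum-like surroundings and
because the qualitative conclusions (oblique TM beats normal incidence) do
not depend on this choice. This divergence is deliberate and documented.

## Polarizability

`mie_dipole_polarizability()` converts the Mie coefficient $a_1$ into
$\alpha = 6\pi i\,\varepsilon_0\varepsilon_{\rm amb}\,a_1/k^3$, which keeps
retardation and radiative damping. The free-space self-term
$\hat G_0(\mathbf r_i,\mathbf r_i)$ is *excluded* from the linear system
because its radiative part is already inside the Mie polarizability;
including both would double-count radiation reaction. The quasi-static
Clausius–Mossotti form (`quasistatic_polarizability()`) is kept as the
small-radius limit check: the relative difference falls monotonically with
radius and is below 1% at 1 nm for silver at 532 nm. A warning is issued
when the size parameter $ka$ exceeds 1.5, where the dipole term alone stops
being a good description; the 40–50 nm particles used here sit near
$ka \approx 0.3$.

## Substrate coupling: the image approximation

The exact reflected Green tensor of a metal half-space requires Sommerfeld
integrals. `sersim` instead uses the image approximation: the source dipole
is mirrored through the interface, its in-plane components flipped and the
moment scaled by the quasi-static reflection factor
$\beta = (\varepsilon_s-\varepsilon_a)/(\varepsilon_s+\varepsilon_a)$, and
the image radiates with the free-space tensor. This is accurate at
sub-wavelength heights — which dominate here, since particle centers sit
20–25 nm above the surface — and the function boundary (`reflected_green()`,
`surface_self_term()`) is drawn so an exact Sommerfeld backend could be
swapped in without touching the solver. The self-term is finite (the image
sits at distance $2z_i$), diagonal in the surface frame, scales as
$1/z_i^3$ in the quasi-static regime, and its normal element is twice the
in-plane one in the perfect-conductor limit.

The mechanism behind the oblique-illumination advantage is the sign pattern
of the image: an in-plane dipole and its image are antiparallel (their far
fields cancel above the surface), while a normal dipole and its image are
parallel (they reinforce). One subtlety worth recording: the textbook
statement "the in-plane dipole *moment* is suppressed near the surface"
holds cleanly in the perfect-conductor limit, where the tangential driving
field vanishes at the surface. Over *real* silver at 532 nm the Fresnel
coefficient carries a phase that moves the tangential-field null away from
the particle height, so the solved in-plane moment of a 22.5 nm sphere is
actually slightly larger than in free space; what remains robust — and what
the tests assert — is the PEC-limit statement and, independently of it, the
field-level observation that oblique TM illumination produces much stronger
near fields above the layer than normal incidence (mean enhancement
ratio ≈ 1.8 for the default ensembles).

## Geometry, illumination and evaluation planes

`generate_ensemble()` places spheres by seeded rejection sampling: radii
uniform in 20–25 nm (diameters 40–50 nm), centers uniform in a 600 × 600 nm
region, a 2 nm minimum surface gap, all spheres resting on the substrate. A
conservative area check (45% coverage) rejects infeasible requests before
sampling; the sampler itself gives up after a bounded number of attempts
(default $10^5$) so failures are deterministic. Illumination defaults are
532 nm, TM polarization and 65° incidence for the oblique case — the
configuration under which the reference near-field maps show strong
enhancement, with the angle itself described there as merely an example.
The default evaluation plane is 60 nm above the substrate, i.e. just above
a 50 nm particle, and `field_vs_height()` probes the 7–17 nm band above the
particle tops where mitochondrial cytochrome *c* resides. Evaluation points
inside particles are masked, not extrapolated — the point-dipole field is
not valid there. Note that the *total* intensity above the layer contains
the incident/reflected standing wave, which oscillates with height; the
monotonically decaying quantity is the scattered part, which
`field_vs_height()` reports separately.

# The spectral pipeline

## Band library

`band_library()` encodes the marker bands of mitochondrial and purified
cytochrome *c* spectra in both redox states. The *positions* follow the
published assignments (ν4 at 1371 oxidized → 1356 cm⁻¹ reduced; ν10 at
1638 → 1605 cm⁻¹; a 690 cm⁻¹ band appearing only on reduction; the
748 cm⁻¹ heme-breathing band growing on reduction). The *widths and
relative amplitudes* are not published; the package uses Lorentzian FWHM
12 cm⁻¹ for every band and amplitudes ordered to resemble measured
mitochondrial traces (strong 748/1371/1585/1638 in the oxidized state, a
dominant 748 in the reduced state). These are fixture constants — editable,
serializable via `write_band_library()`, and chosen once; they are not
measurements.

## Synthetic spectra

`synthesize_spectrum()` builds a trace as (sum of Lorentzians) + (cubic
spline through stated baseline knot values) + (i.i.d. Gaussian noise), on a
default axis of 600–1800 cm⁻¹ with a 1 cm⁻¹ step. `mixture_spectrum()`
forms $f_{\rm red}\,S_{\rm red} + (1-f_{\rm red})\,S_{\rm ox}$ *before*
baseline and noise, emulating the partially reduced cytochrome pool of
respiring mitochondria. What the generator does **not** emulate: shot
(Poisson) noise, cosmic-ray spikes, instrument response, wavenumber
calibration error, the *b*-type cytochrome contribution (absent from the
SERS signal), or protein/lipid background bands. Pipeline results on these
synthetic traces therefore validate the *algorithms*, not instrument
behavior on real data.

## Baseline subtraction

`subtract_baseline()` models the background as a cubic spline through knots
whose x-positions are fixed across a study and placed in band-free windows;
each knot's y-value is the average of the 5 nearest points (half-width 2) so
single-pixel noise does not steer the spline. The default 12 positions sit
in the gaps between the heme bands (below 640, 800–1100, 1200–1290,
1420–1520, above 1660 cm⁻¹). The spline uses Forsythe–Malcolm–Moler end
conditions, which reproduce any cubic polynomial exactly. Two numerical
facts shape the tests: (i) a constant offset is absorbed exactly regardless
of the neighborhood width, because averaging and the spline are both linear
and reproduce constants; (ii) the *exactness* statements (self-subtraction,
cubic polynomials to 10⁻⁸) hold for point-anchored knots
(`half_width = 0`) — the 5-point average introduces an
$O(h^2 f'')$ bias that is negligible for real baselines but visible at
10⁻⁸ tolerances, so the exactness tests anchor the knots on the curve.

## Ratios and classification

`peak_ratios()` reports I748/I1638, I1170/I1638 and I1371/I1638 as maxima in
±15 cm⁻¹ windows, computed after baseline subtraction and normalized to the
1638 cm⁻¹ maximum. The half-window keeps the largest redox shift
(1638 → 1605 cm⁻¹, 33 cm⁻¹ apart) out of the oxidized windows; for
spectra of the reduced state the windows re-center on the shifted marker
positions (1356, 1605 cm⁻¹), and the report records which centers were
used. Ties inside a window break toward the lower wavenumber. Ratios are
scale invariant by construction.

`classify_redox()` estimates the reduced fraction by non-negative least
squares against the two noiseless library end members and reads the marker
evidence (ν4 window 1341–1386 cm⁻¹; high-frequency marker window
1590–1653 cm⁻¹; the r748 level). Thresholds 0.3/0.7 separate
oxidized/mixed/reduced; they are deliberately wide because intermediate
fractions are genuinely mixed states, not classification failures. When the
strongest marker peak is below 5 times the scatter in the 820–1090 cm⁻¹
quiet window the call degrades to "mixed" with a low-confidence flag rather
than guessing.

## Treatment emulation

`treatment_series()` emulates the pharmacological experiments: a control
arm at reduced fraction 0.6 — respiring mitochondria hold their cytochrome
pool partially reduced, and 0.6 puts the control on the reduced side
without saturating either marker — and a treated arm shifted by
$\Delta f_{\rm red}$ (−0.3 for FCCP-like uncoupling, which oxidizes the
pool; +0.3 for oligomycin-like ATP-synthase inhibition, which reduces it).
Ten replicates per arm at 3% Gaussian noise, ratios computed with the fixed
oxidized-state windows for comparability across arms (matching how the
measured ratios were formed), percent-of-control against the mean control
ratios. Only the *direction* of these percentages is meaningful — the
magnitudes depend on the fixture amplitudes, and the corresponding
experimental values exist only graphically — so the tests and the
acceptance report assert directions, never magnitudes.

# Reproducibility and problem sizes

Every stochastic step takes an explicit integer seed and is bit-reproducible
from it; workflow runs write their resolved configuration and an MD5
manifest beside the outputs. The default problem sizes — ensembles of 30
particles, 41 × 41 evaluation grids, ~100 synthetic mixtures, 10 replicates
per treatment arm — were chosen as the smallest sizes at which the
qualitative claims are stable across seeds; all of them solve in seconds on
a laptop and scale up by changing one config value.

# Known limitations

* The image approximation omits surface-plasmon-polariton poles and lateral
  waves; absolute enhancement values carry model error even though the
  normal-vs-oblique comparison is robust. No quantitative near-field
  reference values exist to calibrate against.
* Dipole order only: no multipoles, no T-matrix, so touching particles
  (gap → 0 "hot spots") are underestimated.
* The ensemble model is a flat layer; the real surfaces are hierarchical
  (rings, cavities, multi-scale particle stacking). Oblique illumination of
  the flat layer is the stand-in for normally illuminated cavity walls.
* Band widths/amplitudes of the library, and hence all ratio magnitudes on
  synthetic data, are fixture choices.
* Gaussian i.i.d. noise; no shot noise or spikes. No peak fitting — maxima
  in windows only, as in the original processing.
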