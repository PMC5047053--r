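---
title: "Methods: layered-tissue ultrasound over a fractured cortical plate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: layered-tissue ultrasound over a fractured cortical plate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteowave)
```

## The physical model

The package simulates a 1-MHz therapeutic ultrasound beam entering the
soft tissue over a fractured long bone. The cross-section is idealized
as a horizontally layered 2D plane-strain solid: skin (0.55 mm), fat
(0.58), muscle (1.73), a thin cortical plate (0.04), bone marrow
(0.10), a second cortical plate (0.04), then muscle, fat and skin again
(5.90 mm total). The fracture is an interruption of both cortical
plates over a centered 4-mm lateral span. Because nothing in the model
specifies what occupies a fresh fracture gap, the interrupted cortical
cells default to bone marrow — the medullary channel the gap exposes —
and the fill is configurable (`gap_fill`, `plate_tissue` in
`rasterize_model()`).

Each tissue is an isotropic elastic solid described by Young's modulus
E, Poisson's ratio σ and density ρ, converted to plane-strain
stiffnesses c11 = λ + 2µ, c12 = λ, c33 = µ. Soft tissues are nearly
incompressible (σ within 1e−5 of 0.5), so their shear moduli are tiny
but deliberately kept non-zero: zeroing them would change the character
of the equations, and the staggered scheme handles the stiff contrast
as long as the time step respects the fastest P velocity (cortical
bone, 3669.7 m/s). Intrinsic absorption is not modeled; all amplitude
structure comes from impedance contrasts, geometry and the absorbing
boundaries.

### The inconsistent fat row

The built-in five-tissue table reproduces its published longitudinal
velocities and impedances from (E, σ, ρ) for four of five rows. The fat
row does not: ρ = 1940 kg/m³ with the published E and σ gives
c_l ≈ 1001 m/s, while the published velocity (1462.84) and impedance
(13.75 × 10⁵) are mutually consistent only with ρ ≈ 940. We read the
leading "1" as a typographic slip. `tissue_table("verbatim")` keeps
every printed value and flags the row; `tissue_table("reconciled")`
(the simulation default) substitutes ρ = 940 so that the impedance
contrast at the fat interfaces — which governs reflection amplitudes —
is within 2 % of the published Z column. Even reconciled, the row stays
flagged: c_l from the printed E and σ at ρ = 940 is 1438 m/s, still
1.7 % short of the printed 1462.84, so the original E for fat was
probably also slightly different. Neither variant silently edits the
printed numbers.

## The solver

`fdtd_run()` implements the classic velocity–stress staggered grid
(Virieux-type, 2nd order in time and space) for 2D plane strain,
written in C++. Material parameters are averaged onto staggered
positions the standard way: arithmetic density at velocity points,
harmonic shear modulus at the shear-stress points. The source injects
an isotropic normal-stress (pressure) increment across the aperture
cells — a 10-mm line on the top surface, uniformly apodized — using a
Hann-windowed 1-MHz toneburst of 3 µs, unit peak, identically zero
outside its support. Receivers record pressure as the negative mean
in-plane normal stress −(σxx+σzz)/2.

Numerical choices:

- **Time step.** dt = cfl·dx/(c_max·√2) with cfl = 0.95 by default;
  c_max is the fastest material present on the grid.
- **Absorbing boundaries.** Split-field PML on all four sides, 40 cells
  by default, quadratic damping ramp with
  d₀ = 3 c_max ln(1e6)/(2L). "Absorbing" here refers to the domain
  edges only; internal interfaces are welded (continuous traction and
  velocity) and lossless.
- **Plane-wave runs.** A laterally uniform source (`aperture_mm =
  "full"`) makes the field x-invariant, and the lateral PML is then
  disabled: rigid sidewalls are exact for an x-invariant field, whereas
  damping the injected stress inside the side layers would erode the
  plane wave edge-inward. This configuration is what the reflection and
  convergence checks use.
- **Rasterization.** A cell covers the half-open square
  [i·dx,(i+1)·dx); a cell is inside the gap iff its center satisfies
  |x − width/2| < gap_width/2. Layer boundaries that miss a grid line
  snap to the nearest row with a warning, using round-half-up so that a
  one-cell cortical plate can never round away.
- **Instability guard.** The kernel aborts if the recorded field
  exceeds 10³ × the source peak, the signature of a violated CFL
  condition.

The solver's validation suite checks first arrivals against the
analytic d/c travel time (and its improvement under 2× refinement, with
the source-envelope onset bias removed by subtracting the detected
onset of the source waveform itself), plane-wave reflection at a
two-half-space interface against (Z₂−Z₁)/(Z₂+Z₁), discrete energy
conservation in a closed lossless run (the leapfrog-consistent energy
uses ρ·v(t−dt/2)·v(t+dt/2) for the kinetic part), and source–receiver
reciprocity of the pressure Green's function between points in like
material.

## Receiver metrics

- **Onset (TOF_FAS).** First sample of |A| above a threshold fraction
  of the record's own peak (default 0.05; no canonical value exists for
  this kind of onset picking, so the choice is explicit, configurable
  and recorded in the manifest), then a least-squares parabola through the
  five |A| points centered on the crossing refines the onset to the
  parabola's threshold crossing, clamped to ±1 sample. R1's onset is
  reported but flagged non-comparable: the reference receiver sits
  inside the source aperture, so the TOF series is meaningful from R2
  onward.
- **SPL.** 20·log10 of the peak ratio to R1; R1 is 0 dB by
  construction.
- **RMS.** Root mean square over the half-open window
  [FAS, FAS + 10.9 µs); N is the number of samples in the window (an
  alternative reading of the defining formula would divide by the
  number of receivers, which would make one receiver's energy depend on
  unrelated records and is rejected). A window overrunning the record
  truncates with a warning.

### Receiver layout

Fifteen receivers sit on the vertical axis through the gap center:
R1 on the surface, even receivers at the mid-depth of the seven layers
the axis crosses (skin, fat, muscle, gap, muscle, fat, skin), odd
receivers from R3 one cell on the shallow side of each internal
interface, and R15 one cell above the bottom surface. The odd
interface receivers are therefore R3 (skin–fat), R5 (fat–muscle), R7
(muscle–gap), R9 (gap–muscle), R11 (muscle–fat), R13 (fat–skin); R11
at the lower muscle–fat interface is the only assignment that keeps
fifteen receivers in strict depth order.

### What the model reproduces, and what it cannot

Reproducible properties are qualitative: TOF_FAS increases strictly
with receiver depth; the smallest consecutive TOF increments occur
across the fracture interior (R7→R8→R9 — these receivers are the most
closely spaced, 0.13 and 0.05 mm apart); and the SPL/RMS maxima sit at
receivers flanking the high-contrast soft-tissue interfaces rather than
in mid-muscle or at the absorbing bottom. Absolute SPL/RMS magnitudes
depend on unstated details of the original processing (threshold,
envelope, windowing) and are not targets. One stronger reading — that
the TOF increment across the gap is the smallest *per unit depth* — is
not physically attainable in this model and is deliberately not
asserted: the marrow-filled gap (1476 m/s) is slower than muscle
(1657 m/s), there is no fast lateral path through the interrupted
plates at the gap center, and the analytic ray oracle already refutes
it (0.66 µs/mm across the gap band vs 0.60 in muscle). The
"fastest-inside-the-fracture" observation is about absolute increments,
and that is what the test suite asserts.

### Resolution profiles

The default profile is reduced: dx = 0.04 mm, width 12 mm, full 20-µs
recording (≈150 × 300 cells plus PML, a few seconds per run). The
published profile (dx = 0.01 mm, width 16 mm) is available via
`fracture_model_config(full_resolution = TRUE)`. The reduced width is
12 mm rather than anything narrower because the 10-mm source aperture
needs lateral margin before the PML, and the recording keeps the full
20 µs so the 10.9-µs RMS window fits after a ~1.8–3.9 µs FAS. At
dx = 0.04 mm the 0.04-mm cortical plates are one cell thick and the
1-MHz wavelengths stay ≥ 36 cells, comfortable for the 2nd-order
scheme.

## The experimental-arm statistics

- **Pooled t from summaries.** The worked comparison (alkaline
  phosphatase 86.38 ± 18.94 vs 82.86 ± 10.03) reproduces t(13) = 0.439,
  CI (−13.79, 20.83), p = 0.668 only under an 8/7 split of the fifteen
  usable sera; that split is adopted for the worked example and
  documented as inferred, since only the total (22 animals minus 7
  discarded samples) and the df were published. The serum-calcium
  t = −0.842 is not exactly recoverable from the published summaries
  under either split (reconstruction gives −0.87 to −0.89), consistent
  with rounding of the printed means/SDs; it is recorded, not tuned
  around.
- **Mann–Whitney U.** Mid-rank ties; the reported statistic is
  min(U_x, U_y), stated in the output method string. p is by exact
  enumeration of all group assignments when min(n) ≤ 8, otherwise a
  tie-corrected normal approximation. The published U = 118 is not
  reproducible under this (or any standard) convention with the stated
  group sizes and is not a target.
- **Kappa.** Marginal-product chance agreement; undefined (error) when
  both raters are constant and identical.
- **KS normality.** Plug-in mean/SD (Lilliefors-type) statistic; p by
  Monte-Carlo under the same plug-in procedure, because the classical
  KS null distribution is invalid with estimated parameters.
- **Sample sizing.** Smallest integer n per group whose two-sample
  two-sided t power reaches the target; the power function is the
  standard noncentral-t computation. At d = 1.2, α = 0.05, power 0.8
  this yields 12 per group (the companion study housed 11).
- No multiple-testing correction is applied anywhere, matching the
  analysis being reproduced.

## Synthetic data

`make_toneburst()` produces delayed Hann-windowed bursts with optional
white noise and returns the ground-truth onset, for validating the
onset detector independently of the solver. `make_study()` draws
per-animal biochemistry (Gaussian per group — matching the use of t
tests after a normality screen) and paired ordinal scores from
per-category distributions; rater 2 repeats rater 1 with probability
`agreement` (default 0.85, in the range of the published per-category
agreements) and otherwise resamples. All generators are pure functions
of (spec, seed) and restore the global RNG state. The default score
distributions describe a mid-healing callus (mode at mild-to-moderate
periosteal reaction and bridging, little remodeling); they are a
plausible stand-in, not published data. What the synthetic tables do
not emulate: correlated categories within an animal, rater bias (the
agreement model is symmetric), non-Gaussian biochemistry tails, and
any treatment effect on scores unless the per-group distributions are
set to differ — so passing calibration tests shows the toolkit's
arithmetic and calibration are right, not that the biological data
behaved this way.

## Known limitations

2D plane strain (no out-of-plane spreading), no intrinsic absorption or
dispersion, welded flat interfaces, uniform apodization, and a
receiver "pressure" defined as mean in-plane normal stress — all
adequate for the qualitative interface physics studied here, none
sufficient for absolute dosimetry in tissue. The 0.04-mm cortical
thickness is thin for a rat tibia; it is taken as given and is
configurable through the layer stack.
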