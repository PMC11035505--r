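---
title: "Modelling external dose rates from nuclear-medicine patients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling external dose rates from nuclear-medicine patients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

A patient who has received a radiopharmaceutical is an extended,
inhomogeneous, time-varying photon source. Risk assessments for people
near the patient (staff, caregivers, the public) traditionally reduce
this source to a dose-rate reading at one point and a whole-body
retention curve. `nmdoserate` implements the more complete computational
chain: reference biokinetics resolved into anatomical source regions,
photon transport from each region through a body model, and superposition
over time with a defensible uncertainty statement.

## The model

**Biokinetics.** Activity moves between named compartments by first-order
transfer, $\dot A = M A$, with the administered activity placed in the
injection compartment at $t = 0$ and physical decay applied as a common
factor $e^{-\lambda_p t}$. The solver propagates the state with matrix
exponentials (`Matrix::expm`, scaling and squaring), which is exact to
machine precision for any rate matrix — including degenerate eigen-rates,
which therefore need no special-case handling. Urinary excretion follows
an accumulate-and-void bladder: transfers into the reserved `bladder`
target accumulate without outflow, and at each time of a voiding schedule
the content is set to zero, instantaneously and completely. Complete
emptying is a deliberate convention: no voided fraction is part of the
model vocabulary, and the characteristic sharp drop of the dose-rate
curve at the first void reflects it. Between voids everything is closed
form; time-integrated activities use the block-matrix exponential
integral, so there is no quadrature error anywhere in the biokinetic
layer. Activity is conserved to better than $10^{-9}$: compartments +
bladder + voided + decayed = administered, which the test suite asserts.

The three bundled models (a ⁹⁹ᵐTc diphosphonate bone agent, ¹⁸F-FDG, and
Na¹³¹I iodide) carry *illustrative* transfer coefficients chosen once on
physiological grounds: the bone agent retains about half of the activity
on bone mineral and excretes the rest renally with a plasma clearance
half-time of ~15 min; FDG is trapped in glucose-avid organs with renal
spill; iodide splits between thyroid uptake (~23%) and urine. They are
configuration, not code — the JSON model files are meant to be replaced
with the compilation values of whichever reference model a study
requires, and `read_model_json()` accepts any file with the same schema.

**Four voiding regimes** mirror clinical practice for bone scans:
first void at 30 min then hourly (a), 45 min then hourly (b), 120-min
intervals (c), and 210-min intervals (d, the reference biokinetic
assumption). `categorize_voiding()` assigns a patient's observed first
void to the nearest regime with midpoint boundaries (37.5, 82.5,
165 min); a time exactly on a boundary goes to the lower category. The
boundaries are this package's choice — regime assignment by first void
time is standard, but no published boundary values exist.

**Phantoms.** `generate_phantom()` builds a stylized adult voxel body:
elliptical-cylinder trunk (half-width : half-depth = 1.8), spherical-cap
head, neck, and two legs, with ellipsoidal organs at fixed fractional
anatomical positions and a homogenized skeleton (spine, pelvis, skull
shell, leg bones) at 1.40 g/cm³. The trunk cross-section is calibrated so
the voxelized mass matches the requested body mass within 1%; heavier
bodies at fixed height are thicker, so deep organs (bladder, kidneys) see
more overlying tissue and their dose-rate factors at 1 m fall
monotonically with mass. This is a synthetic stand-in for segmented
reference anatomies, which cannot be redistributed: absolute organ doses
from these phantoms should not be quoted, but ratios, trends and bounds
across morphologies — the quantities the validation study uses — are
meaningful and are what the tests assert. A seeded jitter of up to 1.5%
individualizes organ positions without affecting those conclusions.

**Transport.** The Monte Carlo engine (C++ core) samples emission
positions uniformly over the source-region voxels, isotropic directions,
and line energies from the bundled spectra; it transports photons by
Woodcock (delta) tracking with photoelectric absorption and free-electron
Klein–Nishina Compton scattering, and absorbs photons below 15 keV
locally. Coherent scattering and electron binding are omitted — a known
bias of a few percent at these energies, acceptable against the ~10%
validation tolerances. Point tallies use a forced-detection (next-event)
estimator at every emission and scattering vertex, which makes a 1 mm³
air tally at 1 m tractable: the tally converges to sub-percent
statistical error within seconds. Fluence is converted to ambient dose
equivalent with the bundled monoenergetic coefficients (log-log
interpolated, exact at nodes, no extrapolation). Organ doses in an
exposed phantom are scored as analog energy deposition divided by organ
mass (collision-kerma approximation, no electron transport), and
`effective_dose()` applies the tissue weighting factors to the
sex-averaged organ doses, with unlisted tissues backed by the remainder
dose.

**The point kernel.** A deterministic backend sums, over source voxels,
the line-of-sight attenuated primary fluence to the tally point times a
water buildup factor. Classical infinite-medium buildup tables are wrong
for this framework's geometry — the detector sits in air a metre from
the body, so scatter generated near a detector embedded in the medium
never exists. The bundled table was therefore computed with the
package's own Monte Carlo engine in two reference geometries: a point
source at the centre of a water sphere of optical radius $\tau$ tallied
in air at 1 m (forward Berger term $1 + a\tau e^{b\tau}$), and a source
at depth in a thick backed slab (an excess-backing multiplier
$1 + \beta e^{-\gamma \tau_f}(1 - e^{-1.5\,\Delta})$, with $\Delta$ the
optical depth behind the source in excess of the forward depth). The
kernel evaluates both arguments per source voxel by ray tracing. With
this table the two backends agree to within about 5–11% on the additive
region-summed ambient dose rate for the benchmark scenes at 50 and
100 cm and on the reference vial; individual regions are typically
within 10%, with the skeleton the worst case (up to ~25% — thin limbs
violate the slab/sphere assumptions). The Monte Carlo backend is always
the reference; the kernel exists for fast sensitivity sweeps, where only
across-phantom contrasts matter.

**Superposition and uncertainty.** The cumulated quantity is the
pointwise region sum $\dot H^*(10)(t) = \sum_r a_r(t)\,C_r$ (`cumulate()`;
a region lacking a factor is an error, never a silent drop). The
combined uncertainty follows the GUM quadrature over regions,
$U(t) = \big(\sum_r [a_r u(C_r)]^2 + \sum_r [C_r u(a_r)]^2\big)^{1/2}$,
where the activity-fraction uncertainty comes from a log-normal
variability transform: a multiplicative factor $f$ (default 2 — kinetics
of a given radiopharmaceutical are commonly credited with a factor-2
population variability) becomes
$u(a) = a[\exp((\ln f / k)^2) - 1]^{1/2}$ at coverage $k = 2$. Because
$k$ is already embedded there, the 95% band is reported as
value $\pm\, U(t)$; this single interpretation is applied consistently.
Measurement-side budgets combine in quadrature and are reported as
integer percentages; the positioning component follows the inverse-square
rule, symmetrized over $\pm\delta$: ±10 cm at 1 m gives ±20%, and device
10% + positioning 20.4% + activity 7.5% combine to 24%. (Published
accounts of this budget sometimes quote the positioning term as 10%
while deriving 20% from the inverse-square rule; only the 20% figure
reproduces the 24% combination, so the package implements the derivation
and flags the discrepancy here rather than reconciling it silently.)

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| voxel edge | 5 (phantoms), 1 (vial) | mm | desk-scale speed/accuracy compromise |
| energy cutoff | 15 | keV | below it photons cannot escape the body |
| chest height | 0.75 × height | – | fixed tally-height convention |
| distance convention | skin-to-skin on the tally line | cm | one documented choice; inter-user spread here is a known error source |
| trunk aspect ratio | 1.8 | – | adult width : depth |
| log-normal factor | 2 | – | population biokinetic variability |
| coverage factor | 2 | – | ~95% confidence |
| spectrum threshold | 0.01 | photons/decay | "lines above 1% of decays" simplification |

## What the synthetic generators emulate — and what they do not

The phantom generator spans the morphology range of the published
sensitivity study (162.7–165.5 cm, 50.8–85.3 kg) with anatomically
plausible organ placement, but real bodies have arms, postures,
heterogeneous soft tissue and individual organ shapes; passing tests on
these phantoms demonstrates the *pipeline* (per-region factors, their
mass trends, RSD bounds), not patient-specific accuracy. The measurement
generator draws times uniformly, applies a fixed device bias,
inverse-square positioning jitter and multiplicative Gaussian noise —
it emulates the error structure of a hospital campaign, not its
time-sampling habits or detector energy response. Coverage tests against
the 95% band therefore validate the statistics, not any specific
instrument.

## Numerical choices

Log-log interpolation is used for all photon data (attenuation,
conversion coefficients), exact at nodes and refusing extrapolation.
The Woodcock majorant is re-evaluated per flight over the materials
actually present. Ray tracing uses exact voxel-boundary traversal.
Degenerate inputs fail loudly: empty source regions, gaps ≤ 0,
overlapping phantoms, non-increasing grids, negative rates, deviations
≤ −100%, unknown region labels. The acceptance computations use
5 mm phantoms, 5-min biokinetic grids, 5 × 10⁵ vial histories and the
point-kernel backend for the four-phantom sweep; the whole set completes
in well under a minute on one core, and the quantities are stable to
three figures across seeds.

## Known limitations

No electron/beta transport (the ¹³¹I spectrum is photon-only); no
coherent scattering; single-region uniform activity within each source
region; "Blood" is treated as a whole-body uniform source; the point
kernel underperforms for thin, laterally extended source regions; the
bundled biokinetic coefficients are illustrative defaults, not a
reference compilation; and scatter from outside the scene bounding box
(walls, floor) is not modelled.
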