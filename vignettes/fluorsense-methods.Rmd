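---
title: "Models and methods behind fluorsense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fluorsense}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorsense)
```

`fluorsense` packages the quantitative half of a turn-off fluorescence
sensing study: the reaction-greenness bookkeeping, the photophysical tables,
and the sensing fits. This vignette explains the models behind each module,
the tunable parameters and their defaults, the numerical choices, and what
the synthetic-data module does and does not emulate.

## The chemistry being modeled

A push–pull fluorophore (here, an amino-substituted tetrahydroacridine built
by Friedländer condensation of a 2-aminoaryl ketone with a diketone) emits
strongly because its amino group feeds electron density into the conjugated
ring system. An electron-poor nitroaromatic guest such as picric acid
hydrogen-bonds to the amino group and accepts excited-state electron density
(photoinduced electron transfer), switching the emission off. Everything the
package computes serves the characterization of that switch: how green the
synthesis is, where the probe absorbs and emits, how strongly and selectively
the guest quenches it, how little guest can be detected, and whether the
quench can be reversed.

## Molecular formulas and masses

Formulas are parsed with a deliberately small grammar — an element token is
`[A-Z][a-z]?`, optionally followed by an integer count, with parenthesized
groups and integer multipliers — after stripping whitespace, underscores and
Unicode subscript digits, so formulas copied from typeset text
(`"C_25_ H_25_ NO"`) parse unchanged. Canonical output is Hill order
(C, H, then alphabetical). Unknown element symbols and zero counts are hard
parse errors: silently guessing at a formula would poison every metric
downstream.

Molecular weights use average (conventional) atomic masses to 3–4 decimals,
compiled into `atomic_masses()`. Average rather than monoisotopic masses are
the right basis for stoichiometric metrics (you weigh bulk material, not a
single isotopologue); isotopic fine structure and adduct calculus are out of
scope.

## Green metrics

The five metrics follow their standard definitions on a reaction
specification whose product coefficient is fixed at 1:

- **Atom economy**: `100 · MW(product) / Σ νᵢ MW(reactantᵢ)`. A property of
  the balanced equation only — masses and yield never enter.
- **PMI** and **E-factor**: input mass over product mass, and its excess
  over 1. The default input basis counts reactants and catalyst but
  *excludes solvent*: the package targets syntheses in recyclable media
  (deep eutectic solvents), where the recovered solvent is conventionally
  left out of the intensity. `include_roles` widens the basis when a process
  view is wanted. E-factor is computed as `PMI − 1` on the same basis, so
  the identity holds to machine precision by construction.
- **RME**: product mass over summed reactant masses. On a reactant-only
  basis RME and PMI are exact reciprocals (`RME = 100/PMI`), which the test
  suite asserts.
- **Carbon efficiency**: mole-weighted product carbon over reactant carbon
  using the masses actually charged, so CE scales linearly with yield. The
  report also carries a stoichiometric-basis CE (the balanced equation at
  full conversion) because tabulated CE values in the synthesis literature
  are often quoted on that basis.
- **Percent yield**: obtained moles over theoretical moles from the limiting
  reactant, identified as the smallest moles/equivalents ratio — the
  standard stoichiometric convention.

Uncomputable metrics are *flagged*, never defaulted to zero. The
element-balance audit compares summed reactant elements against product plus
byproducts; when byproducts are omitted and the imbalance is exactly
`k · H₂O`, the audit infers `k` condensation waters — the implicit byproduct
of the Friedländer reactions this package was built around (2 per monomer,
4 per dimer condensation).

## Spectra and photophysics

Spectra are wavelength-gridded traces (nm, ascending, linear interpolation,
no default smoothing). Peak picking takes local maxima — plateau ties
resolved toward longer wavelength — filters them by topographic prominence
(default threshold 5% of the global maximum, enough to reject grid-level
noise while keeping genuine shoulders), and refines each surviving maximum
by fitting a parabola through the three surrounding points. For a symmetric
band whose center sits on the grid the refinement is exact; off-grid centers
are recovered to a small fraction of the grid step.

The Stokes shift is `Δν = 10⁷(1/λ_abs − 1/λ_em)` cm⁻¹ for λ in nm, positive
when emission lies red of absorption and antisymmetric under swapping its
arguments. Aromatic push–pull chromophores typically show two absorption
bands — a short-wavelength π–π* band and a longer n–π* band. The
photophysics table pairs the **shortest-wavelength** absorption maximum with
the emission maximum by default: the large (>10⁴ cm⁻¹) solvatochromic Stokes
shifts characteristic of intramolecular charge transfer are tabulated
against that band; `band = "longest"` selects the other convention. A
negative shift (emission blue of absorption) is reported but flagged — it
usually means band misassignment.

Molar absorptivity is plain Beer–Lambert arithmetic `ε = A/(c·l)`, and the
bathochromic range is the max-minus-min of the chosen wavelength across a
solvent series — the single-number summary of positive solvatochromism.

## Sensing analytics

**Stern–Volmer.** `I₀/I = 1 + K_SV[Q]` is fitted by ordinary least squares.
The default keeps the intercept free and flags it when it strays more than
0.05 from the theoretical 1 — upward curvature at high quencher
concentration (mixed static/dynamic quenching, inner-filter effects) shows
up first in the intercept, and the flag plus `range_mask` let the user
restrict the fit to the linear low-concentration regime rather than trusting
a silently biased slope. `fix_intercept = TRUE` imposes the theoretical
model, which on exactly Stern–Volmer data recovers the constant to linear
algebra precision.

**Detection limit.** `LOD = 3σ_blank/|slope|` with σ the *sample* (n−1)
standard deviation of the blank replicates and the slope from a least-squares
fit of the response over the low-concentration linear regime. The default
response variable is the raw intensity; `delta_intensity` (I₀ − I) is
available since both conventions appear in the sensing literature and they
give identical LODs up to sign. The identity `LOD·|slope| = 3σ` holds exactly
per fit because the LOD is stored in that form.

**Job's method.** At fixed total concentration the complex concentration is
maximal at the host mole fraction m/(m+n) for an HₘGₙ complex. The analysis
locates the discrete maximum, refines it with the same 3-point parabola used
for spectra, and converts to a small-integer ratio via
`round((1−x)/x)` (or its reciprocal). Ratios beyond 4 are declared
inconclusive — continuous variation genuinely cannot resolve higher
stoichiometries — as is a maximum at the edge of the sampled range. The
symmetry score `1 − mean|s(x) − s(1−x)|/max(s)` quantifies the hallmark of
1:1 binding (a curve symmetric about x = ½).

**Selectivity and reversibility.** The panel reports the relative turn-off
response `1 − I/I₀` per analyte and flags the strongest positive responder;
interference mode compares probe + competitor against probe + competitor +
target. The reversibility index `(I_rec − I_q)/(I₀ − I_q)` is clipped to
[0, 1] for reporting (slight over-recovery from dilution or drift is common)
with the raw value retained. Both are invariant to rescaling all intensities,
as any ratio of intensities must be.

## The synthetic-data module

The simulators generate every input the analyses consume, with known ground
truth:

- **Spectra** are sums of Gaussian bands plus i.i.d. additive Gaussian noise —
  an instrument-like noise floor. Real band shapes are asymmetric
  (vibronic structure, log-normal-ish tails); passing peak-recovery tests on
  Gaussians therefore validates the peak-picking numerics, not robustness to
  vibronic shoulders.
- **Host–guest equilibria**: the 1:1 complex concentration has a closed form
  (the smaller root of the mass-balance quadratic), evaluated in the
  cancellation-free form `2H₀G₀/(s + √(s² − 4H₀G₀))`, `s = H₀+G₀+1/Ka`,
  which stays accurate in both the saturation and mass-action limits. The
  general HₘGₙ balance is solved by bisection (the residual is strictly
  decreasing in the complex concentration, so the bracket is certain) to
  1×10⁻¹² relative width; the two routes agree to 1×10⁻¹⁰ against each other
  and against an independent bisection oracle in the tests.
- **Quenching titrations**: `dynamic_SV` applies the Stern–Volmer law
  directly; `static_complex` maps the bound probe fraction to fully dark
  complexes, `I = I₀(1 − [HG]/H₀)` — the pure static limit appropriate for a
  ground-state hydrogen-bonded complex with photoinduced electron transfer.
  In the weak-binding regime the static model reduces to a Stern–Volmer line
  with apparent K_SV ≈ Ka, which the tests exploit as a cross-check.
- **Job series** sweep the host mole fraction over `(1:n)/(n+1)` — exact 0
  and 1 are excluded because the equilibrium is degenerate there.
- **LOD calibrations** draw calibration points and blanks from the same
  Gaussian noise model, so the planted detection limit `3σ/slope` is
  recoverable by construction. Defaults (12 calibration points over
  0–5×10⁻⁸ M, 20 blanks, baseline 100 a.u.) describe a realistic nanomolar
  working regime; 20 blanks keep the small-sample bias of the sample SD
  below 2%.

Seeds are mandatory arguments everywhere; simulators save and restore the
global RNG state so library code never perturbs a user's random stream.
Noise is additive Gaussian only — no shot noise, drift, or inner-filter
effects — which is the simplest model consistent with the least-squares
analyses performed on it.

## Parameter magnitudes used in examples and tests

Simulated studies use the magnitudes typical of nitroaromatic turn-off
sensing: quenching constants near 10⁶ M⁻¹, probe concentrations near
10⁻⁵ M, titrations over sub-micromolar quencher ranges, detection limits of
a few nanomolar, and six-solvent solvatochromic series whose emission maxima
span ~30 nm. Monte-Carlo recovery tests run 100 seeded replicates; oracle
comparisons for the equilibrium solver run 1,000 random cases. All of it
executes in seconds on one CPU.

## Known limitations

- Quantum yields, lifetimes, Lippert–Mataga regressions and inner-filter
  corrections are out of scope; the package characterizes steady-state
  intensities only.
- Job's method itself (not the implementation) is unreliable for
  stoichiometries beyond small integers and for very strong binding, where
  the curve degenerates to a tent whose discrete sampling limits the
  attainable x_max precision.
- Tabulated literature metrics are sometimes computed on undisclosed mass
  bases; the package implements the standard definitions and surfaces
  internal identities (E = PMI − 1, RME = 100/PMI on a reactant basis)
  rather than attempting to reverse-engineer a particular table.
- Titration concentrations are taken as given; when a series was recorded
  as incremental µL additions of a stock, `dilution_concentrations()`
  converts it to `[Q] = V_added·C_stock/V_total` as an explicit
  pre-processing step, but no hidden correction is ever applied inside the
  fitting functions.
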