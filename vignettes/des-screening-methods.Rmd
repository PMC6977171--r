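---
title: "Methods: segment thermodynamics for DES solubility screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segment thermodynamics for DES solubility screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model and its assumptions

`descreen` predicts relative solubilities of drug-like solutes in
multicomponent solvents from σ-profiles — histograms of molecular
surface area over the screening charge density σ (e/Å²) that a perfect
conductor induces on the molecular cavity.  The model rests on the
usual assumptions of segment thermodynamics:

* the liquid is an ensemble of independently pairing surface segments;
  the three-dimensional arrangement of segments on a molecule is
  ignored;
* the conductor state is the energy reference, so dispersion
  contributions (assumed equal in reference and liquid) drop out;
* every species is unionised and represented by a single profile (one
  conformation); salts such as choline chloride enter as one neutral
  species;
* each component of a multicomponent solvent is an independent
  mole-bearing particle: a 1:0.9:0.6 DES recipe contributes 2.5 mol of
  particles per formula set.  This convention fixes both the mixture
  profile weights and the mean molar mass used in mg/g ↔ mole-fraction
  conversions.  (The alternative "DES as one pseudo-molecule" view is
  a rescaling of ratios and can be expressed through
  `composition_spec()` directly.)

Two contacting segments interact through a misfit penalty
`a_eff·c_mf·(σ+σ′)²` and a hydrogen-bond term that is non-zero only
when the donor side lies below `−σ_hb` and the acceptor side above
`+σ_hb`.  The printed formulations of the bond term in the literature
are not always unambiguous; the package's default (`donor_acceptor`)
is `a_eff·c_hb·min(0, σ_d+σ_hb)·max(0, σ_a−σ_hb)` with
`σ_d = min(σ,σ′)`, `σ_a = max(σ,σ′)`, which realises the threshold
behaviour exactly; the literal product form
`a_eff·c_hb·min(0, σσ′+σ_hb²)` is selectable
(`hb_form = "product_threshold"`) for sensitivity analysis.  The
contact area and the effective segment area are identified as a single
constant `a_eff`.

## Parameters

| parameter | default | unit | role |
|---|---|---|---|
| `temperature` | 298.15 | K | room-temperature experiments |
| `a_eff` | 7.5 | Å² | effective segment contact area |
| `c_misfit` | 4593.117... | kJ mol⁻¹ Å⁻² (e/Å²)⁻² | electrostatic mismatch penalty |
| `c_hb` | 47742.229... | kJ mol⁻¹ Å⁻² (e/Å²)⁻² | hydrogen-bond strength |
| `sigma_hb` | 0.0082 | e/Å² | donor/acceptor polarity threshold |

The energetic coefficients derive from the published original open
parameterisation of the segment model (α′/2 = 8233.36 and
c_hb = 85580 kcal Å⁴ mol⁻¹ e⁻² at a 7.5 Å² segment), converted to kJ
and expressed per unit contact area; commercial parameterisations are
proprietary and are not reproduced.  All constants ship versioned in
`inst/extdata/interaction_params.txt`, and `read_interaction_params()`
/ `write_interaction_params()` round-trip them bit-exactly.  Every
model computation is parameter-agnostic: only the acceptance-level
defaults pin these numbers.

## Numerics

**Grid.** σ ∈ [−0.030, 0.030] e/Å² in 61 bins of 0.001 — the
conventional axis; the grid must contain σ = 0 exactly because several
closed-form limits are anchored there.  File input is apportioned
linearly onto bracketing bins (conserves area); σ-averaging of raw
quantum-chemistry segments is out of scope (inputs are already-binned
profiles).

**σ-potential solver.** The fixed-point equation is iterated from
μ ≡ 0 with log-sum-exp stabilisation; convergence is declared when the
max-norm update falls below `tol` (default 1e-8 kJ mol⁻¹ Å⁻²,
`max_iter = 500`).  A practical observation drives the damping design:
at hydrogen-bond strengths of the order of the published constants the
*undamped* substitution map is not a contraction — for
donor/acceptor-active profiles it settles into a genuine 2-cycle with
amplitude far above any useful tolerance.  The default therefore
watches for sign-alternating updates and engages damping at 0.5,
escalating in steps of 0.2 (cap 0.9) if the oscillation persists; a
fixed damping fraction can be forced.  Because damping moves the
iterate and not the fixed point, the solution is independent of the
damping value wherever the damped map converges, and the test suite
asserts this across 0.3–0.7 and the adaptive default.  Non-convergence
is always reported (`converged = FALSE` with residual and iteration
count), never silent.

**Conventions.** μ is stored per unit area, so the solute chemical
potential is the plain area-weighted sum over the solute profile (the
grid is the quadrature rule; no sub-bin interpolation) and `a_eff`
enters the solubility chain exactly once.  Predicted `ln x` is capped
at 0 with a `miscible` flag.  Degenerate inputs (zero-area profiles,
grid mismatches, solids without fusion energy in absolute mode) raise
typed errors.  Solvent rankings break exact ties lexicographically by
label.

**Self-consistent ("iterative") solubility.** The finite-concentration
mode starts from the infinite-dilution estimate and repeatedly
rebuilds the liquid as solvent + solute at the current mole fraction,
re-solving the potential until `ln x` is stable (`tol = 1e-6`).  We
interpret the iteration as being over the dissolved solute
concentration; whether reference implementations instead iterate an
internal solid-activity loop is not documented, and in the dilute
regime (x below ~1e-4) the two agree with the dilute formula to
better than 1e-6 in `ln x` anyway.

**Combinatorial term.** Default `combinatorial_form = "none"`: the
size/shape correction largely cancels in relative solubilities between
chemically similar media, and no published formula accompanies the
model description this package follows.  A Staverman–Guggenheim-style
`"area_volume"` form (z = 10, r/q normalisers 66.69 Å³ / 79.53 Å²)
is provided for sensitivity checks; it requires cavity volumes and
vanishes for a solute identical in size and shape to the solvent.

## The packaged study fixtures

The measured table of 11 APIs × 10 solvents (plus three
lactic-acid-alone records) and the six DES molar compositions ship as
plain-text CSVs with the APIs' molar masses.  Choices and known
internal inconsistencies, kept as documented rather than "fixed":

* compositions are nominal (as weighed in); glucose enters anhydrous
  with recipe water explicit; a titration-corrected water content can
  be expressed by building a custom `composition_spec()`;
* fold ratios are quoted with the convention that reproduces the
  published wording (one decimal below 10, nearest integer above);
* one published fold list transposes two of its four values relative
  to the table it cites; only the two internally consistent entries
  (1.3-fold vs ethanol, 2.1-fold vs lactic acid for paracetamol) are
  used as checks;
* the celecoxib DES-vs-water gain computed from the table and nominal
  compositions is 4.81 log units, whereas 4.91 is quoted in prose
  (which also prints 18.3 mg/g against the table's 18.6); the package
  reports what it computes;
* the viscous-dissolution footnote is attached to the lidocaine cell
  it follows in the table (LGW, value retained); prose elsewhere
  quotes 469.4 mg/g against the table's 459 ± 15 — the fixture follows
  the table.

Below-LOQ cells carry a flag and no value and are excluded from every
fit, never imputed.  For the two drugs unquantifiable in water the
relative-solubility reference is ethanol.

## The synthetic generator

`synthetic_study()` emulates the *statistical shape* of a screening
campaign: solutes and multicomponent solvents assembled from Gaussian
σ-profile peaks (apolar backbone, polar shoulders, donor/acceptor
peaks beyond ±0.0082 e/Å²), true solubilities computed by the model,
and "experimental" tables obtained by multiplicative lognormal noise —
additive on the log10 scale, matching how screening data are compared.
One seed drives everything; the noise substream is derived
deterministically from it, so studies with the same seed share species
and standardised noise draws across noise levels (noise enters scaled
by `noise_sd`), which makes the fit-quality decline in noise a clean
within-seed comparison.

Two generator defaults encode the study conditions deliberately.
First, the peak library is sized so solute transfer free energies span
roughly −1 to +17 kJ/mol, i.e. relative solubilities of a few log
units — the range of the packaged experimental table.  Second, fusion
energies are drawn from U(18, 40) kJ/mol, *above* that envelope, so
every synthetic solid stays strictly solubility-limited: no prediction
hits the miscibility cap, and rank statistics at zero noise are free
of artificial ties.  (These values are at the high end for real drugs;
they are chosen for the regime, not as a fusion-energy model.)  A
related guard: generated species always carry at least two peaks,
because a single-peak species' normalised profile — and hence its
σ-potential — is independent of its surface area, making all such
species thermodynamically identical.

What the generator does *not* emulate: quantum-chemical realism of
σ-profiles, conformational ensembles, element-specific hydrogen-bond
strengths, ionic speciation, or the chemical diversity between (say)
water and PEG — synthetic solvents drawn from one library are more
alike than real solvent panels, so between-solvent signal is smaller
than in real data.  Passing the closure tests therefore shows the
pipeline's internal consistency (generate → predict → compare recovers
the identity fit exactly at zero noise, degrades monotonically with
noise), not predictive accuracy against laboratory measurements.

## Comparison analytics

Experimental values are regressed on predicted ones (the identity line
is the reference in predicted-vs-experimental plots; the regression
direction is stated because conventions differ), with R² of that fit,
RMSE of its residuals, and Spearman's ρ (ties mid-ranked).  Headline
regression statistics published for the original study depend on
proprietary parameterisations and DFT-derived profiles for all
species and are deliberately **not** reproduction targets; the
package's acceptance surface is the in-table arithmetic plus the
synthetic closure properties.

## Problem sizes

The test suite and acceptance script use 61-bin grids throughout;
closure runs use 8 solutes × 6 solvents, and noise-response medians
use 20 replicate studies per noise level in {0.1, 0.5, 1.0} — sizes at
which every quantity stabilises while the full suite runs in well
under a minute on one CPU.

## Known limitations

* Absolute solubilities require a user-supplied fusion energy and an
  open parameterisation: no parity with proprietary reference
  implementations is claimed.  Relative solubilities are the intended
  prediction surface.
* No temperature-dependent hydrogen-bond scaling, dispersion terms, or
  electrostatic corrections beyond the misfit/bond pair model.
* A single hydrogen-bond coefficient for all elements.
* Vapour pressures, partition coefficients and other fluid-phase
  properties the framework could express are not implemented.
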