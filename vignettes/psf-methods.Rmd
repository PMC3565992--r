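---
title: "Protein signaling functions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protein signaling functions: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

psfkit turns a mass-action kinetic model of signal transduction into a set of
*protein signaling functions* (psfs): steady-state transfer functions from the
total concentration of a designated input species to the settled concentration
of every other species, together with the delay needed to complete each
transition. This vignette records the model assumptions, the numerical
choices, and the places where the design was genuinely open.

## The reaction-system model

A system is a list of species with initial total concentrations (nM) and a
list of reaction schemes of five kinds, each expanding into elementary
mass-action steps:

* **binding** `A + B <-> AB` — two steps (association `kon`, dissociation
  `koff`);
* **irreversible_binding** — the forward step only;
* **enzymatic** `S + E <-> SE -> P + E` — three steps (`kon`, `koff`,
  `kcat`), the enzyme is recycled by the catalytic step;
* **conversion** `A -> B` and **decomposition** `AB -> products` — one step.

Units are nM and s throughout: `kon` in nM⁻¹s⁻¹ (nM⁻³s⁻¹ for the one
fourth-order calcium association in the bundled model), `koff`/`kcat` in s⁻¹.
Each step's rate is `k · Π conc(reactant)^stoich`; the per-species derivative
is the stoichiometry-weighted sum over steps. Stoichiometry is taken literally
from the model tables: coefficient 1 everywhere except the `1 PP2A + 4 Ca`
association. Composite names such as `Ca2CaM` or `PKAcAMP2` are opaque
identifiers — no hidden multi-ion stoichiometry is inferred from a name. We
verified the alternative reading (2 ions per calcium-binding event) and it
moves free calcium far below the published window rather than into it, so the
literal reading stands.

Finite steady states require *weak reversibility*: every species must be both
produced and consumed by at least one step. `check_weak_reversibility()`
reports per-species flags; the bundled model passes only because an
`AMP -> ATP` recycling step closes the nucleotide loop.

**Moieties.** Conserved groups (all D1R-containing forms, the DARPP-32 forms,
the PKA regulatory and catalytic cores, the G-protein alpha and beta-gamma
pools, ...) are declared with multiplicities and checked numerically: along
any integrated trajectory their weighted totals drift by less than 1e-6
relative. The adenine pool is declared `conserved = FALSE`: the holoenzyme
re-association scheme `PKAr + PKAc <-> PKAcAMP4` regenerates a cAMP-carrying
complex without consuming free cAMP, so no multiplicity assignment makes that
pool exact — this is a bookkeeping property inherited from the source model,
not a solver artifact. Calcium and cAMP totals are likewise not declared
conserved because composite-species names leave their ion counts ambiguous.

## The bundled striatal model

`builtin_striatal_model()` ships the 40-scheme dopamine/DARPP-32 network
(D1 receptor and Golf cycle, AC5 with Da- and Ca-bound forms, cAMP
production and PDE1/PDE4 degradation, PKA, calmodulin/calcineurin buffering,
CaMKII, and the DARPP-32 phosphorylation hub) with its published rate
constants and initial totals; the PP1 subsystem of the original model is not
part of it. Inputs are total dopamine (`Da`) and total calcium (`Ca`). The
same model is shipped as a plain-text file in `inst/extdata/` in the
package's TSV dialect (one row per scheme: `id kind lhs mid rhs kon koff
kcat`, with `#% species` directive lines for initial totals), and
`parse_model()`/`write_model()` roundtrip it losslessly.

## Steady state, pragmatically

Rate constants span ~1e-12 to 1e3, so integration uses a stiff solver
(`deSolve::lsoda`) with an analytic Jacobian; negative solver excursions are
clipped to zero before rate evaluation. Steady state is declared by a
deliberately pragmatic criterion: *every species above a floor of 1e-6 nM
must change by less than 2% over a trailing 100 s window*, checked jointly on
a 10 s cadence. The criterion names no per-species scope, so the joint
reading (strictest) is used. This criterion is part of the method's
definition, not a solver tolerance: slowly creeping species can satisfy it
well before true equilibrium. Where a test needs true equilibrium (the
closed-form and flux-balance oracle comparisons), the suite tightens the
criterion to 1e-7 over 500 s instead of loosening the assertion.

Solver tolerances are `rtol = atol = 1e-8` by default; with concentrations
spanning 1e-3 to 2e6 nM this keeps the smallest reported species comfortably
above the integration error.

## Sweeps, fits and transmission strength

A systemic psf sweep sets the input's free pool to each grid value with every
other species at its declared initial total — no pre-equilibrated basal state
— and settles each grid point independently. The default grid is 20 points,
logarithmic (hyperbolae are resolved at the low end); linear spacing is a
flag. Each curve is fitted with the saturating hyperbola

y(x) = y0 + Y·xⁿ/(Cⁿ + xⁿ)

by Nelder–Mead over (Y, log C, log n, y0) — log-space enforces positivity of
C and n — initialized at y0 = min, Y = signed range, C = the grid point
nearest half-range, n = 1. A linear fit is preferred when its squared error
is no larger, or when the fitted C exceeds 10× the grid maximum: such a curve
is only a short section of its full mapping and a two-parameter line is the
honest description. Degenerate (flat) curves get a constant fit with slope 0.

Transmission strength is reported two ways: the local slope of the fit (or a
central difference on the raw curve), and the *relative gain* — the
fractional output change for a factor-2 input change. For the unit hyperbola
these have closed forms (gain 1/3 at x = C, 1/39 at x = 19C) which the test
suite pins down. Published percentages attached to one illustration of this
quantity do not follow from the analytic definition and are not targeted.

Two-input sweeps settle the full grid product and report per-input
*dependence shares*: the variance of the response along one axis (averaged
over the other), normalized. This deliberately replaces a full principal
component analysis — the decomposition answers the only question the analysis
asks (which input does a target listen to?) with two numbers.

`adjust_elementary_to_match()` inverts the map locally: derivative-free
search over a scheme's chosen rate constants minimizing the squared distance
between the recomputed systemic psf and a target fit. One caveat found while
testing: at steady state a reversible binding step carries zero net flux, so
only `koff/kon` is identifiable from steady-state data and scaling both
constants together leaves every psf unchanged; the self-recovery test
therefore perturbs a single constant.

## Delays

The transition delay is measured by equilibrating at the pre-step input
total, raising (or lowering) the free input pool instantaneously at t = 0,
integrating until the steady-state criterion holds, and reporting the *last*
time the trajectory is outside the band covering 95% of its total change —
last band exit rather than first crossing, so transient overshoots do not
shorten the reported delay. Crossing times are interpolated linearly between
samples (0.02 s resolution early, coarser later). Species whose total change
is below the criterion floor report an undefined delay.

Decreases remove free input first; any remainder is removed proportionally
from complexes that a single binding scheme forms from the input, returning
the binding partner so every other moiety stays conserved. Complexes further
from the input (e.g. ternary calcium complexes) are left untouched because
the species that should receive their non-input content is not identifiable
in general.

Two conditions of the published delay table are not recoverable from its
caption: the calcium total (the initial-concentration table says 1 uM, the
range figures use 8 uM) and the decrease bookkeeping. The package computes
either; the bundled analysis and the reproduction script use 8 uM, under
which the slow species (PKAc, pThr34, PP2A forms, pThr75) and the
AC5/cAMP tier agree with the published values within ±30%. The published
receptor-proximal entries do not emerge from the printed constants in our
integration: Da–D1R unbinding at `koff = 10 s⁻¹` completes 95% of a decrease
in ~0.3 s against a printed 10.1 s, and the increase delays are about half
the printed ones. The printed decrease values are consistent with a
G-protein re-equilibration time scale (`kon·[Gabc] ≈ 0.2 s⁻¹`), suggesting a
larger slow-tail amplitude in the original implementation than in ours; we
report what the stated constants produce.

## Modularity

For each target the EC90 (rising) or EC10 (falling) cutoff is the smallest
grid input at which the species has covered 90% of — or fallen to within 10%
of — *its own* observed range, held to the end of the grid so a transient
spike does not count as saturation. Measuring against each species' own
min/max is the only reading that applies uniformly to rising and falling
targets. Exactly linear responders (relative residual < 1e-9 against a line)
have no cutoff: they transmit uniformly over the whole window. A species is
*nonresponsive* when its relative span (range/maximum) is below 10% — the
one numeric threshold of this analysis whose published value is typeset
unrecoverably; 10% matches the stated "no response (less than 10%)" and is
configurable. *Inactive* means the queried input level is at or beyond the
cutoff. Modules are connected components of the species–reaction graph
restricted to active species, reaction nodes acting as conduits.

On the bundled model this reproduces the published structure: under calcium
input at saturating dopamine the receptor/G-protein tier is entirely
nonresponsive and the active graph splits into ≥ 2 modules; under dopamine
input the number of inactive links grows with the input level
(high connectivity at low input, modularization at high input). The raw
counts of nonresponsive species under the two inputs are nearly tied in our
integration, so the regression test asserts the robust per-pathway form
rather than a count inequality.

## Discrete state-change simulation

`assign_timescales()` bins each species' maximal observed delay into update
intervals (default 10/300/600 s, matching the three time scales the delay
table separates into; ties at a bin edge take that bin, overflows take the
largest bin with a warning). `simulate_discrete()` then advances a state by
setting each species, at multiples of its interval, to the psf lookup for
the current input (linear interpolation in log-input for log grids, bilinear
for two-input matrices), with linear interpolation in time between slow
updates. All species update at t = 0; staggering is not modeled. By
construction the simulator cannot produce values outside the psf range and
misses ODE transients — `compare_with_ode()` quantifies this against the
continuous model, and the suite includes a deliberately transient-rich toy
(fast complex formation followed by slow sequestration) whose overshoot the
discrete model provably misses. Inputs changing faster than the fastest
update interval are outside the method's domain.

## What the toy generators do and do not show

The test oracles are closed-form or root-finding solutions of small systems:
the quadratic steady state of isolated binding, a flux-balance bisection for
the covalent modification cycle, single-exponential relaxation for the
two-state converter, and seeded random weakly-reversible systems for
structural invariants. They validate the integrator, the settle criterion,
the delay measurement and the fitting machinery to 1e-6; they do not probe
stiffness of the magnitude the full model exercises, parameter uncertainty,
or spatial/stochastic effects, all of which are outside the model class.
Problem sizes in the suite (20-point sweeps, 5×5 input matrices, 12-point
calcium sweeps) are the analysis' own defaults.

## Known limitations

* The steady-state criterion is pragmatic; reported "settled" values for the
  slowest calcium-buffer redistribution are criterion-settled, not
  equilibrium values.
* Free calcium under the high-calcium condition settles near 103 nM in this
  implementation against a published 64–69 nM; neither the literal nor the
  multi-ion stoichiometry reading reproduces the published window (see the
  moiety discussion above).
* Receptor-proximal delays disagree with the published table as discussed;
  all downstream tiers agree.
* Fitting is local (Nelder–Mead from a data-driven start, one restart); no
  global optimality is claimed, and `adjust_elementary_to_match()` inherits
  this.
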