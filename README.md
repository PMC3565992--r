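# psfkit

Signal transduction models are usually written as stiff mass-action ODE
systems — dozens of species, rate constants spanning fifteen orders of
magnitude, and very little insight per simulation. psfkit implements an
alternative formulation: it transforms such a kinetic model into **protein
signaling functions** (psfs) — steady-state transfer functions from the total
concentration of an input species to the settled concentration of every other
species — plus the **delay** each species needs to complete a transition.
Concentration (magnitude) and time are analyzed separately, which makes the
complex system dissectable: each reaction gets a fitted dose–response curve,
each species a concentration range and a time scale, and the network a
well-defined input-dependent modular structure.

It is aimed at systems biologists who have (or build) mass-action models of
signaling pathways and want dose–response surfaces, EC-style saturation
analysis, and reduced discrete-time simulations out of them.

## The method in brief

For a reaction system with elementary mass-action steps (binding
`A + B <-> AB`, enzymatic `S + E <-> SE -> P + E`, conversions,
decompositions), choose an input species, fix its total at a grid value, and
integrate the stiff ODE system until every species changes by less than 2%
over 100 s. Repeating over a (log-spaced) grid of n = 20 input totals gives
per-species curves

y(x) = y0 + Y·xⁿ/(Cⁿ + xⁿ)

fitted by derivative-free least squares (a linear fit is used where the curve
is only a short section of its full mapping). `C` is the half-maximal input,
the slope at `C` the transmission strength; EC90/EC10 cutoffs on each curve
mark where a species saturates or depletes and stops transmitting signal —
links become *inactive*, and the active subgraph decomposes into modules that
depend on the input level. Delays (time to complete 95% of a transition after
an input step) assign each species a time scale; a discrete state-change
simulator then advances the system using psf lookups alone, at 10/300/600 s
resolution per species.

The flagship instance is the published 40-reaction striatal
dopamine/DARPP-32 model (D1 receptor, Golf cycle, AC5, cAMP/PKA,
calmodulin/calcineurin, CaMKII, DARPP-32 phosphorylation hub), bundled both
in code (`builtin_striatal_model()`) and as a plain-text model file in the
package's TSV dialect (`inst/extdata/striatal_model.tsv`).

## Worked example

```r
library(psfkit)
library(dplyr)

sys <- builtin_striatal_model()
sys
#> <reaction_system> 55 species, 40 schemes (85 elementary steps)
#>   inputs: Da, Ca
#>   weakly reversible: yes

# dose-response sweep: total dopamine 100 nM .. 5 uM at high calcium
sw <- systemic_psf(sys, "Da", c(100, 5000), n = 20, fixed = c(Ca = 8000))

fit_psf(psf_curve(sw, "DaD1R"))
#> <psf_fit> hyperbolic (target DaD1R)
#>         Y         C         n        y0
#> 5.169e+02 1.080e+04 9.664e-01 1.489e+00
#> sse: 0.1355

transmission_strength(fit_psf(psf_curve(sw, "DaD1R")), 1000)
#> # A tibble: 1 × 3
#>       x  slope relative_gain
#>   <dbl>  <dbl>         <dbl>
#> 1  1000 0.0414         0.773

delay_table(sys, "Da", list(c(60, 500)),
            species = c("DaD1R", "cAMP", "PKAc"), fixed = c(Ca = 8000))
#> # A tibble: 3 × 2
#>   species `60->500`
#>   <chr>       <dbl>
#> 1 DaD1R        1.88
#> 2 cAMP         6.30
#> 3 PKAc       309.

# input-dependent modularity at saturating dopamine
act <- classify_activity(sw, input_level = 5000)
count(act, status)
#> # A tibble: 3 × 2
#>   status            n
#>   <chr>         <int>
#> 1 active            9
#> 2 inactive         28
#> 3 nonresponsive    18
modules_at(sys, act)
#> <modularity_report> 2 modules among 9 active species; 46 inactive/nonresponsive
```

Reading the numbers: the active receptor pool `DaD1R` follows a nearly pure
hyperbola whose half-maximal input (~10.8 uM total dopamine) lies above the
physiological range, so the receptor itself never saturates here — while a
doubling of dopamine at 1 uM still yields a 77% increase in occupancy.
Receptor-proximal species settle in seconds; free catalytic PKA needs ~5
minutes. At saturating dopamine most of the network has stopped transmitting
(28 species sit beyond their EC90/EC10 cutoffs) and the remaining active
species fall into two disconnected modules — the dopamine/cAMP pathway and
the calcium pathway decouple at high input.

`autoplot()` methods exist for sweeps, fits and discrete trajectories;
`tidy()`/`glance()` for fits and steady states. A thin command-line wrapper
(`inst/cli/psfkit`) exposes the same pipeline as subcommands
(`validate`, `psf`, `fit`, `delays`, `graph`, `modularity`, `statesim`)
writing CSV/JSON/GraphML.

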