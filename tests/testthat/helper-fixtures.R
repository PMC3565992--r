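# Shared lazily-computed objects. Expensive sweeps of the built-in model are
# computed once per test run and reused across files.
.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.cache[[name]])) .cache[[name]] <- force(expr)
  .cache[[name]]
}

builtin_sys <- function() cached("builtin", builtin_striatal_model())

# Da sweep under the high-Ca condition (the figure condition): 20 log points
# over 100 nM .. 5 uM, total Ca 8 uM.
builtin_da_sweep <- function() cached("da_sweep", {
  systemic_psf(builtin_sys(), "Da", c(100, 5000), n = 20, fixed = c(Ca = 8000))
})

# Ca sweep at saturating Da (Fig-8A-style condition), coarser grid.
builtin_ca_sweep <- function() cached("ca_sweep", {
  systemic_psf(builtin_sys(), "Ca", c(100, 10000), n = 12, fixed = c(Da = 5000))
})

table5_species <- c("DaD1R", "AC5GoaGTP", "AC5CaGoaGTP", "cAMP", "PKAc",
                    "pThr34", "PP2Ap", "PP2Ac", "pThr75")

# published delay table (s) for the four Da transitions
table5_printed <- tibble::tribble(
  ~species,       ~up_small, ~up_large, ~down_small, ~down_large,
  "DaD1R",         3.6,       0.8,       10.1,        10,
  "AC5GoaGTP",     7.8,       2.4,       19,          20,
  "AC5CaGoaGTP",   8.1,       2.4,       19.5,        26,
  "cAMP",          7.8,       3.1,       18.1,        18,
  "PKAc",          251,       164,       347,         300,
  "pThr34",        288,       200,       369,         307,
  "PP2Ap",         511,       387,       706,         683,
  "PP2Ac",         600,       483,       756,         717,
  "pThr75",        493,       359,       756,         755)

# delay table for the built-in model under the high-Ca configuration
builtin_delays <- function() cached("delays", {
  delay_table(builtin_sys(), "Da",
              list(c(60, 500), c(60, 4500), c(500, 60), c(4500, 60)),
              species = table5_species, fixed = c(Ca = 8000))
})

toy_binding_sys <- function(Atot = 100, Btot = 100, kon = 0.01, koff = 1) {
  make_fixture("toy_binding", list(Atot = Atot, Btot = Btot, kon = kon, koff = koff))
}

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_true(all(abs(actual - expected) <= rel_tol * abs(expected)),
              label = paste0("relative agreement within ", rel_tol, " (got ",
                             paste(signif(actual, 5), collapse = ", "),
                             " vs ", paste(signif(expected, 5), collapse = ", "), ")"))
}

# true-equilibrium criterion for oracle-equivalence checks (the pragmatic
# 2%/100s default stops far from 1e-6 agreement on slow toy cycles)
oracle_criterion <- function() {
  steady_state_criterion(rel_change = 1e-7, window = 500, max_time = 1e7)
}
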