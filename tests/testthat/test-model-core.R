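test_that("scheme construction matches the printed kinetic table rows", {
  s1 <- build_scheme("binding", "Da + D1R", "DaD1R", kon = 0.00111, koff = 10)
  steps1 <- expand_system(s1)
  expect_equal(nrow(steps1), 2)
  expect_equal(steps1$rate, c(0.00111, 10))
  expect_equal(steps1$reactants[[1]]$species, c("Da", "D1R"))
  expect_equal(steps1$products[[1]]$species, "DaD1R")

  s6 <- build_scheme("conversion", "GoaGTP", "GoaGDP", kcat = 10)
  expect_equal(nrow(expand_system(s6)), 1)

  s9 <- build_scheme("enzymatic", "ATP + AC5GoaGTP", "cAMP + AC5GoaGTP",
                     mid = "AC5GoaGTP_ATP", kon = 0.000128, koff = 0.261,
                     kcat = 28.46)
  steps9 <- expand_system(s9)
  expect_equal(nrow(steps9), 3)
  expect_equal(steps9$role, c("forward", "reverse", "catalytic"))
  expect_equal(steps9$rate, c(0.000128, 0.261, 28.46))
})

test_that("expansion sizes per kind are fixed and expansion conserves appearances", {
  expect_equal(nrow(expand_system(NULL)), 0)
  kinds <- list(
    binding = build_scheme("binding", "A + B", "AB", kon = 1, koff = 1),
    irreversible = build_scheme("irreversible_binding", "A + B", "AB", kon = 1),
    enzymatic = build_scheme("enzymatic", "A + E", "P + E", mid = "AE",
                             kon = 1, koff = 1, kcat = 1),
    conversion = build_scheme("conversion", "A", "B", kcat = 1),
    decomposition = build_scheme("decomposition", "AB", "A + B + C", kcat = 1))
  sizes <- vapply(kinds, function(s) nrow(expand_system(s)), numeric(1))
  expect_equal(unname(sizes), c(2, 1, 3, 1, 1))
  # decomposition row of the receptor/G-protein cycle: 1 step, 3 products
  d <- expand_system(build_scheme("decomposition", "DaD1RGabc",
                                  "DaD1R + GoaGTP + Gbc", kcat = 20))
  expect_equal(nrow(d), 1)
  expect_equal(nrow(d$products[[1]]), 3)
})

test_that("scheme validation rejects malformed input", {
  expect_error(build_scheme("binding", "A + B", "AB", kon = 1), "koff")
  expect_error(build_scheme("binding", "A + B", "AB", kon = -1, koff = 1), ">= 0")
  expect_error(build_scheme("made_up", "A", "B", kcat = 1), "unknown scheme kind")
  expect_error(build_scheme("conversion", "A + B", "C", kcat = 1), "inconsistent")
})

test_that("the built-in model reproduces the printed tables", {
  sys <- builtin_sys()
  expect_equal(nrow(sys$schemes), 40)
  # step count = sum of per-kind expansion sizes over the printed rows:
  # 21 bindings (x2) + 12 enzymatic (x3) + 5 conversions + 1 decomposition +
  # 1 irreversible binding
  counts <- table(sys$schemes$kind)
  expect_equal(unname(counts[c("binding", "enzymatic", "conversion",
                               "decomposition", "irreversible_binding")]),
               c(21, 12, 5, 1, 1), ignore_attr = TRUE)
  expect_equal(nrow(sys$steps), 21 * 2 + 12 * 3 + 5 + 1 + 1)
  init <- stats::setNames(sys$species$initial_total, sys$species$name)
  expect_equal(init[["D1R"]], 500)
  expect_equal(init[["DARPP32"]], 50000)
  expect_equal(init[["ATP"]], 2e6)
  expect_setequal(sys$inputs, c("Da", "Ca"))
  # spot-check rates across the three tables
  sch <- sys$schemes
  expect_equal(sch$kon[sch$id == 1], 0.00111)
  expect_equal(sch$koff[sch$id == 1], 10)
  expect_equal(sch$kcat[sch$id == 6], 10)
  expect_equal(sch$kon[sch$id == 38], 7.72e-12)
  expect_equal(sch$kcat[sch$id == 31], 0.004)
  # the order-4 calcium binding uses stoichiometry 4
  r38 <- sys$steps$reactants[[which(sys$steps$scheme_id == 38 &
                                    sys$steps$role == "forward")]]
  expect_equal(r38$stoich[r38$species == "Ca"], 4)
})

test_that("mass-action rates follow k * prod(conc^stoich)", {
  sys <- builtin_sys()
  x <- initial_state(sys)
  x[] <- 0
  x[c("Da", "D1R")] <- c(5000, 500)
  rates <- mass_action_rates(sys, x)
  # only scheme 1 forward fires: 0.00111 * 5000 * 500 = 2775 nM/s
  expect_equal(rates[["DaD1R"]], 2775)
  expect_equal(rates[["Da"]], -2775)
  # zero-concentration reactant gives a zero step rate
  x2 <- x; x2["Da"] <- 0
  expect_equal(mass_action_rates(sys, x2)[["DaD1R"]], 0)
  # order-4 step: rate = k * [PP2A] * [Ca]^4
  x3 <- initial_state(sys); x3[] <- 0
  x3[c("PP2A", "Ca")] <- c(2000, 100)
  expect_equal(mass_action_rates(sys, x3)[["PP2Ac"]], 7.72e-12 * 2000 * 100^4)
  expect_error(mass_action_rates(sys, c(Da = 1)), "missing concentration")
})

test_that("weak reversibility passes on the built-in model and fails without recycling", {
  sys <- builtin_sys()
  expect_true(attr(sys$weak_reversibility, "pass"))
  # reversible binding alone passes; forward-only fails for every species
  rev <- reaction_system(c("A", "B", "AB"),
                         build_scheme("binding", "A + B", "AB", kon = 1, koff = 1))
  expect_true(attr(check_weak_reversibility(rev), "pass"))
  irr <- reaction_system(c("A", "B", "AB"),
                         build_scheme("irreversible_binding", "A + B", "AB", kon = 1))
  wr <- check_weak_reversibility(irr)
  expect_false(attr(wr, "pass"))
  expect_false(wr$ok[wr$species == "AB"])
  # dropping the AMP -> ATP recycling step breaks the nucleotide loop
  no40 <- reaction_system(builtin_sys()$species,
                          dplyr::filter(builtin_sys()$schemes, id != 40),
                          inputs = c("Da", "Ca"))
  wr40 <- check_weak_reversibility(no40)
  expect_false(attr(wr40, "pass"))
  expect_false(wr40$ok[wr40$species == "AMP"])
})

test_that("declared conserved moieties stay constant along trajectories", {
  sys <- builtin_sys()
  tr <- integrate_system(sys, initial_state(sys, c(Da = 500)), times = seq(0, 500, 25))
  mt <- moiety_totals(sys, traj_wide(tr))
  strict <- dplyr::filter(mt, conserved)
  drift <- strict |>
    dplyr::group_by(moiety) |>
    dplyr::summarise(rel = (max(total) - min(total)) / max(total))
  expect_true(all(drift$rel < 1e-6))
  # the D1R receptor pool is the printed total at every sample time
  d1r <- dplyr::filter(mt, moiety == "D1R")
  expect_equal(d1r$total, rep(500, nrow(d1r)), tolerance = 1e-9)
})
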