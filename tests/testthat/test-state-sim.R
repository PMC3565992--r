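test_that("time-scale bins absorb the published delay structure", {
  d <- tibble::tibble(species = c("DaD1R", "PKAc", "PP2Ap"),
                      t1 = c(3.6, 251, 511), t2 = c(0.8, 164, 387))
  asg <- assign_timescales(d, bins = c(10, 300, 600))
  expect_equal(asg$interval[asg$species == "DaD1R"], 10)
  expect_equal(asg$interval[asg$species == "PKAc"], 300)
  expect_equal(asg$interval[asg$species == "PP2Ap"], 600)
  # all fast
  fast <- assign_timescales(tibble::tibble(species = c("a", "b"),
                                           d = c(2, 9.9)), c(10, 300, 600))
  expect_equal(fast$interval, c(10, 10))
  # tie at a bin edge goes to that bin
  tie <- assign_timescales(tibble::tibble(species = "x", d = 300), c(10, 300, 600))
  expect_equal(tie$interval, 300)
  # exceeding the largest bin warns and assigns the largest
  expect_warning(
    over <- assign_timescales(tibble::tibble(species = "x", d = 1000),
                              c(10, 300, 600)), "exceed")
  expect_equal(over$interval, 600)
  expect_error(assign_timescales(tibble::tibble(species = "x", d = 1),
                                 bins = numeric(0)), "non-empty")
})

toy_sim_setup <- function() {
  sys <- toy_binding_sys(Atot = 100, Btot = 200, kon = 0.01, koff = 1)
  sw <- cached("toy_sim_sweep", systemic_psf(sys, "A", c(10, 1000), n = 10))
  asg <- assign_timescales(
    tibble::tibble(species = unique(sw$target), d = c(3, 3, 120)[
      match(unique(sw$target), c("A", "AB", "B"))]),
    bins = c(10, 300))
  list(sys = sys, sw = sw, asg = asg)
}

test_that("fast species sit on their psf value at every update step", {
  s <- toy_sim_setup()
  sched <- tibble::tibble(input_total = c(50, 500), duration = c(100, 100))
  disc <- simulate_discrete(sched, s$asg, s$sw)
  ab <- dplyr::filter(disc, species == "AB", updated)
  for (i in seq_len(nrow(ab))) {
    lvl <- if (ab$time[i] < 100) 50 else 500
    cv <- psf_curve(s$sw, "AB")
    expected <- stats::approx(log(cv$input_total), cv$value, xout = log(lvl))$y
    expect_equal(ab$value[i], expected, tolerance = 1e-9)
  }
  # slow species (B, 300 s interval) is piecewise linear between updates
  b <- dplyr::filter(disc, species == "B")
  expect_true(all(abs(diff(diff(b$value[b$time <= 200]))) < 1e-9))
})

test_that("a held constant input converges to the ODE steady state", {
  s <- toy_sim_setup()
  sched <- tibble::tibble(input_total = 500, duration = 400)
  disc <- simulate_discrete(sched, s$asg, s$sw)
  final <- dplyr::filter(disc, time == 400)
  ode <- settle(s$sys, initial_state(s$sys, c(A = 500)))
  for (i in seq_len(nrow(final))) {
    expect_equal(final$value[i], ode$concentrations[[final$species[i]]],
                 tolerance = 0.05)
  }
  # and matches the systemic psf lookup exactly (fixed-point consistency)
  cmp <- compare_with_ode(s$sys, "A", sched, s$asg, s$sw)
  last <- dplyr::filter(cmp$discrete, time == 400)
  for (i in seq_len(nrow(last))) {
    cv <- psf_curve(s$sw, last$species[i])
    expect_equal(last$value[i],
                 stats::approx(log(cv$input_total), cv$value, xout = log(500))$y,
                 tolerance = 1e-9)
  }
})

test_that("discrete values stay inside the psf range", {
  s <- toy_sim_setup()
  sched <- tibble::tibble(input_total = c(20, 900, 50), duration = c(50, 50, 50))
  disc <- simulate_discrete(sched, s$asg, s$sw)
  rng <- s$sw |>
    dplyr::group_by(target) |>
    dplyr::summarise(lo = min(value), hi = max(value))
  j <- dplyr::left_join(disc, rng, by = c(species = "target"))
  expect_true(all(j$value >= j$lo - 1e-9 & j$value <= j$hi + 1e-9))
})

test_that("schedule levels outside the lookup grid are rejected by name", {
  s <- toy_sim_setup()
  sched <- tibble::tibble(input_total = 5000, duration = 50)
  expect_error(simulate_discrete(sched, s$asg, s$sw), "5000")
  expect_error(simulate_discrete(tibble::tibble(input_total = 50, duration = 0),
                                 s$asg, s$sw), "> 0")
})

test_that("the discrete simulator misses ODE transients by construction", {
  # incoherent cascade: input A binds B quickly, the complex is then slowly
  # sequestered by C, so the ODE AB trajectory overshoots its steady state
  schemes <- dplyr::bind_rows(
    build_scheme("binding", "A + B", "AB", kon = 0.1, koff = 1, id = 1L),
    build_scheme("binding", "AB + C", "ABC", kon = 0.002, koff = 1e-4, id = 2L))
  sys <- reaction_system(
    tibble::tibble(name = c("A", "B", "C", "AB", "ABC"),
                   initial_total = c(0, 100, 150, 0, 0)),
    schemes, inputs = "A")
  sw <- systemic_psf(sys, "A", c(10, 2000), n = 8)
  asg <- assign_timescales(tibble::tibble(species = unique(sw$target), d = 500),
                           bins = c(600))
  sched <- tibble::tibble(input_total = 1000, duration = 1200)
  disc <- simulate_discrete(sched, asg, sw, dt = 10)
  base <- settle(sys, initial_state(sys, c(A = 1e-3)))
  st <- apply_input_step(sys, base$concentrations, "A", 1e-3, 1000)
  tr <- integrate_system(sys, st, times = seq(0, 1200, 5))
  ode_ab <- traj_wide(tr)[, "AB"]
  disc_ab <- dplyr::filter(disc, species == "AB")$value
  expect_gt(max(ode_ab), 1.2 * max(disc_ab))  # the overshoot is invisible discretely
})

test_that("fast species track the ODE better than slow species at 10 s sampling", {
  s <- toy_sim_setup()
  sched <- tibble::tibble(input_total = c(50, 500, 50, 500),
                          duration = c(50, 50, 50, 50))
  cmp <- compare_with_ode(s$sys, "A", sched, s$asg, s$sw)
  sm <- cmp$summary
  expect_lt(sm$mean_rel_dev[sm$species == "AB"],
            sm$mean_rel_dev[sm$species == "B"] + 0.5)
})
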