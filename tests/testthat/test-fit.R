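make_hyp_curve <- function(Y = 100, C = 500, n = 1, y0 = 0,
                           grid = psf_grid(c(10, 1e4), 15)) {
  tibble::tibble(input_total = grid, value = y0 + Y * grid^n / (C^n + grid^n))
}

test_that("noiseless hyperbolic data are recovered to 0.1%", {
  for (p in list(c(100, 500, 1, 0), c(2500, 80, 1.7, 30), c(12, 4000, 0.8, 2))) {
    f <- fit_psf(make_hyp_curve(p[1], p[2], p[3], p[4]))
    expect_equal(f$model, "hyperbolic")
    expect_rel_equal(unname(f$params[c("Y", "C", "n")]), p[1:3], 1e-3)
    expect_lt(abs(f$params[["y0"]] - p[4]), 1e-3 * p[1])
  }
})

test_that("parameters survive 1% multiplicative noise within estimator error", {
  set.seed(11)
  ok <- replicate(5, {
    d <- make_hyp_curve(100, 500, 1, 0)
    d$value <- d$value * (1 + rnorm(nrow(d), 0, 0.01))
    f <- fit_psf(d)
    f$model == "hyperbolic" &&
      abs(f$params[["Y"]] - 100) / 100 < 0.1 &&
      abs(f$params[["C"]] - 500) / 500 < 0.2
  })
  expect_true(all(ok))
})

test_that("model selection prefers the smaller residual and flags short sections", {
  grid <- psf_grid(c(10, 1e4), 12)
  lin <- tibble::tibble(input_total = grid, value = 2 * grid + 5)
  f <- fit_psf(lin)
  expect_equal(f$model, "linear")
  expect_equal(unname(f$params[["slope"]]), 2, tolerance = 1e-8)
  # degenerate flat curve: constant fit with zero slope
  flat <- tibble::tibble(input_total = grid, value = rep(7, 12))
  expect_equal(fit_psf(flat)$model, "constant")
  expect_equal(fit_psf(flat)$params[["slope"]], 0)
  # decreasing (depletion) curves fit with negative amplitude
  dec <- make_hyp_curve(-80, 300, 1, 90)
  fd <- fit_psf(dec)
  expect_equal(fd$model, "hyperbolic")
  expect_lt(fd$params[["Y"]], 0)
  # selection consistency: the returned residual never exceeds the linear one
  set.seed(3)
  for (i in 1:6) {
    d <- make_hyp_curve(runif(1, 10, 200), runif(1, 50, 5000), 1, runif(1, 0, 20))
    d$value <- d$value * (1 + rnorm(nrow(d), 0, 0.02))
    f <- fit_psf(d)
    lf <- stats::lm.fit(cbind(1, d$input_total), d$value)
    expect_lte(f$sse, sum(lf$residuals^2) + 1e-9)
  }
})

test_that("transmission strength matches the analytic hyperbola properties", {
  f <- fit_psf(make_hyp_curve(100, 500, 1, 0))
  # relative gain 1/3 at x = C and 1/39 at x = 19C (EC95) for a 2x input step
  ts <- transmission_strength(f, c(500, 19 * 500))
  expect_equal(ts$relative_gain, c(1 / 3, 1 / 39), tolerance = 1e-6)
  # slope at x -> 0 tends to Y/C for n = 1
  expect_equal(transmission_strength(f, 1e-4)$slope, 100 / 500, tolerance = 1e-4)
  # gain is monotone decreasing in x for a rising n = 1 hyperbola
  gains <- transmission_strength(f, psf_grid(c(10, 1e4), 12))$relative_gain
  expect_true(all(diff(gains) < 0))
  # undefined gain where the output is zero (raw curve starting at 0)
  raw <- tibble::tibble(input_total = c(0, 10, 100, 1000),
                        value = c(0, 5, 30, 80))
  expect_warning(tz <- transmission_strength(raw, 0), "undefined")
  expect_true(is.na(tz$relative_gain))
})

test_that("raw curves give finite-difference slopes close to the analytic ones", {
  d <- make_hyp_curve(100, 500, 1, 0, grid = psf_grid(c(10, 1e4), 40))
  ts <- transmission_strength(d, 500)
  expect_equal(ts$slope, 100 * 500 / (500 + 500)^2, tolerance = 0.05)
})

test_that("rate adjustment is a fixed point at the current psf and recovers a perturbation", {
  sys <- toy_binding_sys(Atot = 0, Btot = 200, kon = 0.01, koff = 1)
  grid <- psf_grid(c(10, 2000), 6)
  sw <- systemic_psf(sys, "A", grid = grid, targets = "AB")
  target_fit <- fit_psf(psf_curve(sw, "AB"))
  # the residual floor is the fit's own sse (the fit is not a perfect
  # interpolant of the curve), so "matched" means: no worse than that
  tol <- target_fit$sse * 1.01 + 1e-8
  # adjusting toward the system's own psf changes nothing
  adj <- adjust_elementary_to_match(sys, 1, target_fit, c("kon", "koff"),
                                    input = "A", grid = grid, target = "AB",
                                    tolerance = tol)
  expect_true(adj$converged)
  expect_equal(unname(adj$rates[c("kon", "koff")]), c(0.01, 1))
  # doubling koff shifts the psf; the search recovers the original curve
  pert <- sys
  pert$schemes$koff[1] <- 2
  pert <- reaction_system(pert$species, pert$schemes, inputs = pert$inputs,
                          moieties = pert$moieties)
  adj2 <- adjust_elementary_to_match(pert, 1, target_fit, "koff",
                                     input = "A", grid = grid, target = "AB",
                                     tolerance = tol, maxit = 80)
  expect_true(adj2$converged)
  expect_equal(unname(adj2$rates[["koff"]]), 1, tolerance = 0.05)
})
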