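ideal_sweep <- function(curves, grid = psf_grid(c(1, 1e4), 25)) {
  # build a psf_sweep-shaped tibble from closed-form curves
  rows <- purrr::map_dfr(names(curves), function(tg) {
    tibble::tibble(input_species = "x", input_total = grid, target = tg,
                   value = curves[[tg]](grid), settle_time = 100,
                   converged = TRUE)
  })
  structure(rows, input = "x", grid = grid,
            class = c("psf_sweep", class(rows)))
}

test_that("cutoffs land at 9C for an ideal hyperbola and nowhere for a linear ramp", {
  grid <- psf_grid(c(1, 1e4), 400)
  sw <- ideal_sweep(list(
    hyp = function(x) 100 * x / (100 + x),
    lin = function(x) x / 20,
    flat = function(x) rep(5, length(x))), grid)
  cuts <- input_target_cutoffs(sw)
  # for y = Y x / (C + x) the 90%-of-observed-range point solves
  # y(x) = y_min + 0.9 (y_max - y_min); with this grid that is x ~ 9C
  # corrected for the finite observed range
  C <- 100
  y <- function(x) 100 * x / (C + x)
  thr <- y(min(grid)) + 0.9 * (y(max(grid)) - y(min(grid)))
  x_star <- C * thr / (100 - thr)
  hyp_cut <- cuts$cutoff_input[cuts$target == "hyp"]
  expect_gte(hyp_cut, x_star * 0.999)
  expect_lte(hyp_cut, x_star * (max(grid) / min(grid))^(1 / (length(grid) - 1)))
  expect_true(is.na(cuts$cutoff_input[cuts$target == "lin"]))
  expect_equal(cuts$direction[cuts$target == "flat"], "flat")
  expect_equal(cuts$relative_span[cuts$target == "flat"], 0)
})

test_that("cutoffs are invariant under output rescaling", {
  grid <- psf_grid(c(1, 1e4), 50)
  sw1 <- ideal_sweep(list(a = function(x) 80 * x / (500 + x)), grid)
  sw2 <- ideal_sweep(list(a = function(x) 8000 * x / (500 + x)), grid)
  expect_equal(input_target_cutoffs(sw1)$cutoff_input,
               input_target_cutoffs(sw2)$cutoff_input)
})

test_that("activity classification follows the span and cutoff rules", {
  grid <- psf_grid(c(1, 1e4), 50)
  sw <- ideal_sweep(list(
    responsive = function(x) 100 * x / (50 + x),
    weak = function(x) 95 + 5 * x / (50 + x),       # 5% relative span
    falling = function(x) 100 - 90 * x / (50 + x)), grid)
  low <- classify_activity(sw, input_level = 10)
  high <- classify_activity(sw, input_level = 9000)
  expect_equal(low$status[low$species == "weak"], "nonresponsive")
  expect_equal(low$status[low$species == "responsive"], "active")
  expect_equal(high$status[high$species == "responsive"], "inactive")
  # depletion works symmetrically through EC10
  expect_equal(low$status[low$species == "falling"], "active")
  expect_equal(high$status[high$species == "falling"], "inactive")
  # monotone curves switch active -> inactive at most once along the grid
  for (lvl in grid) {
    st <- classify_activity(sw, lvl)$status[1]
    expect_true(st %in% c("active", "inactive"))
  }
  statuses <- vapply(grid, function(lvl) {
    classify_activity(sw, lvl)$status[1] == "inactive"
  }, logical(1))
  expect_true(all(diff(statuses) >= 0))  # never flips back to active
})

test_that("a fully active system forms a single module", {
  sys <- toy_binding_sys()
  act <- tibble::tibble(species = c("A", "B", "AB"),
                        relative_span = 1, direction = "rising",
                        cutoff_input = NA_real_, status = "active")
  rep <- modules_at(sys, act)
  expect_equal(rep$n_modules, 1)
  expect_equal(nrow(rep$inactive_links), 0)
})

test_that("receptor-proximal species saturate later than downstream targets", {
  cuts <- input_target_cutoffs(builtin_da_sweep())
  c_dad1r <- cuts$cutoff_input[cuts$target == "DaD1R"]
  c_pthr34 <- cuts$cutoff_input[cuts$target == "pThr34"]
  # early steps in the cascade saturate at a higher input level
  expect_true(is.na(c_dad1r) || c_dad1r > c_pthr34)
  expect_false(is.na(c_pthr34))
})

test_that("the built-in model modularizes under saturating inputs", {
  sys <- builtin_sys()
  swCa <- builtin_ca_sweep()
  actCa <- classify_activity(swCa, input_level = max(swCa$input_total))
  repCa <- modules_at(sys, actCa)
  # calcium input at saturating dopamine splits the active graph
  expect_gte(repCa$n_modules, 2)
  # receptor/G-protein species are unresponsive to calcium, responsive to Da
  gpcr <- c("D1R", "DaD1R", "GabcD1R", "DaD1RGabc", "Gabc", "Gbc",
            "GoaGTP", "GoaGDP")
  expect_true(all(actCa$status[actCa$species %in% gpcr] == "nonresponsive"))
  swDa <- builtin_da_sweep()
  actDa_low <- classify_activity(swDa, input_level = 150)
  # the large Gabc reservoir itself moves < 10% under Da; the signal-carrying
  # receptor/G-protein species all respond
  carriers <- setdiff(gpcr, "Gabc")
  expect_true(all(actDa_low$status[actDa_low$species %in% carriers] != "nonresponsive"))
  # interconnectedness shrinks with input level: more inactive links at high
  actDa_high <- classify_activity(swDa, input_level = 5000)
  expect_gt(sum(actDa_high$status == "inactive"),
            sum(actDa_low$status == "inactive"))
})
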