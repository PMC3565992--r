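# Protein signaling functions: steady-state input -> output mappings.
# Sweeps integrate the full system from its declared initial totals with the
# input's free pool set to each grid value (no pre-equilibrated basal state),
# and settle each grid point independently under the 2%-over-100-s criterion.

#' Input grid for a psf sweep
#'
#' Logarithmic by default (hyperbolae are resolved at the low end).
#'
#' @param range length-2 numeric, nM.
#' @param n number of grid points (default 20).
#' @param log logical, log-spaced (default) or linear.
#' @return strictly increasing numeric vector.
#' @export
psf_grid <- function(range, n = 20, log = TRUE) {
  stopifnot(length(range) == 2, all(range > 0) || !log, range[2] > range[1])
  if (log) exp(seq(base::log(range[1]), base::log(range[2]), length.out = n))
  else seq(range[1], range[2], length.out = n)
}

#' Systemic protein signaling functions for one input
#'
#' For each grid value of the input's total concentration, the system is
#' integrated to steady state and every species' settled concentration is
#' recorded; the column for one target species over the grid is its
#' systemic psf.
#'
#' @param system a `reaction_system`.
#' @param input declared input species name.
#' @param range length-2 input-total range, nM.
#' @param n grid size (default 20).
#' @param targets species to keep (default: all).
#' @param criterion a [steady_state_criterion()].
#' @param fixed named totals for other species held at a non-default value,
#'   e.g. `c(Ca = 8000)`.
#' @param grid explicit grid overriding `range`/`n`.
#' @param log log-spaced grid (default TRUE).
#' @return tibble of class `psf_sweep`, long format: `input_species`,
#'   `input_total`, `target`, `value` (nM), `settle_time` (s), `converged`.
#' @export
systemic_psf <- function(system, input, range, n = 20, targets = NULL,
                         criterion = steady_state_criterion(), fixed = NULL,
                         grid = NULL, log = TRUE) {
  if (!input %in% system$inputs) {
    abort(paste0("'", input, "' is not a declared input of the system"))
  }
  if (is.null(grid)) grid <- psf_grid(range, n, log = log)
  rows <- purrr::map_dfr(grid, function(g) {
    st <- initial_state(system, c(stats::setNames(g, input), fixed))
    res <- settle(system, st, criterion)
    if (!res$converged) {
      warn(paste0("no convergence at ", input, " = ", format(g), " nM"))
    }
    tibble(input_species = input, input_total = g,
           target = names(res$concentrations),
           value = unname(res$concentrations),
           settle_time = res$settle_time, converged = res$converged)
  })
  if (!is.null(targets)) rows <- filter(rows, .data$target %in% targets)
  structure(rows, input = input, grid = grid, log = log,
            class = c("psf_sweep", class(rows)))
}

#' Extract one psf curve from a sweep
#'
#' @param sweep a `psf_sweep`.
#' @param target species name.
#' @return tibble `input_total`, `value` (plus settle metadata).
#' @export
psf_curve <- function(sweep, target) {
  out <- filter(sweep, .data$target == !!target)
  if (nrow(out) == 0) abort(paste0("no curve for target '", target, "'"))
  arrange(out, .data$input_total)
}

#' Elementary psf of an isolated complex-formation reaction
#'
#' Builds the isolated `A + B <-> AB` system and settles it at each grid
#' value of the total of `A`; the result agrees with the quadratic
#' closed form [binding_closed_form()].
#'
#' @param Atot_grid source totals, nM.
#' @param Btot partner total, nM.
#' @param kon,koff rate constants (`koff > 0`).
#' @param criterion a [steady_state_criterion()].
#' @return `psf_sweep` tibble restricted to target `AB`.
#' @export
elementary_binding_psf <- function(Atot_grid, Btot, kon, koff,
                                   criterion = steady_state_criterion()) {
  stopifnot(all(Atot_grid >= 0), Btot >= 0, kon >= 0, koff > 0)
  sys <- make_fixture("toy_binding", list(Atot = 0, Btot = Btot,
                                          kon = kon, koff = koff))
  rows <- purrr::map_dfr(Atot_grid, function(a) {
    res <- settle(sys, initial_state(sys, c(A = a)), criterion)
    tibble(input_species = "A", input_total = a, target = "AB",
           value = res$concentrations[["AB"]],
           settle_time = res$settle_time, converged = res$converged)
  })
  structure(rows, input = "A", grid = Atot_grid,
            class = c("psf_sweep", class(rows)))
}

#' Elementary psf of a reversible enzymatic reaction
#'
#' The forward enzyme `E1` converts substrate `S` to `Sp`; a reverse
#' enzymatic scheme regenerating `S` is required (without it the modified
#' form simply absorbs all substrate and no transfer function exists).
#' Sweeps the forward enzyme total and reports steady-state `[Sp]`.
#'
#' @param Etot_grid forward-enzyme totals, nM.
#' @param substrate_total total substrate, nM.
#' @param forward_rates named list/vector `kon`, `koff`, `kcat`.
#' @param reverse_scheme named list/vector `kon`, `koff`, `kcat`, plus
#'   `Etot` for the reverse-enzyme total; `NULL` is an error.
#' @param criterion a [steady_state_criterion()].
#' @return `psf_sweep` tibble with input `E1` and target `Sp`.
#' @export
elementary_enzymatic_psf <- function(Etot_grid, substrate_total, forward_rates,
                                     reverse_scheme,
                                     criterion = steady_state_criterion()) {
  if (is.null(reverse_scheme)) {
    abort("a reverse scheme regenerating the substrate is required")
  }
  f <- as.list(forward_rates); r <- as.list(reverse_scheme)
  sys <- make_fixture("toy_covalent_cycle", list(
    Stot = substrate_total, E1tot = 0, E2tot = r$Etot %||% 50,
    kon1 = f$kon, koff1 = f$koff, kcat1 = f$kcat,
    kon2 = r$kon, koff2 = r$koff, kcat2 = r$kcat))
  rows <- purrr::map_dfr(Etot_grid, function(e) {
    res <- settle(sys, initial_state(sys, c(E1 = e)), criterion)
    tibble(input_species = "E1", input_total = e, target = "Sp",
           value = res$concentrations[["Sp"]],
           settle_time = res$settle_time, converged = res$converged)
  })
  structure(rows, input = "E1", grid = Etot_grid,
            class = c("psf_sweep", class(rows)))
}

#' Two-input psf matrix
#'
#' Settles the system on the full grid of two input totals and reports the
#' target's steady-state value per cell, together with per-input dependence
#' shares (variance explained along each axis, averaged over the other).
#'
#' @param system a `reaction_system`.
#' @param inputs character vector of two distinct declared inputs.
#' @param grids list of two numeric grids (nM), same order as `inputs`.
#' @param target target species (single name).
#' @param criterion a [steady_state_criterion()].
#' @param fixed named totals for other species.
#' @return tibble of class `psf_matrix` with columns `input1`, `input2`,
#'   `value`, `converged`; attributes `inputs`, `shares` (named length-2:
#'   fraction of response variance attributable to each input).
#' @export
psf_matrix <- function(system, inputs, grids, target,
                       criterion = steady_state_criterion(), fixed = NULL) {
  stopifnot(length(inputs) == 2, inputs[1] != inputs[2])
  if (!all(inputs %in% system$inputs)) abort("both inputs must be declared inputs")
  cells <- tidyr::expand_grid(input1 = grids[[1]], input2 = grids[[2]])
  vals <- purrr::pmap_dfr(cells, function(input1, input2) {
    st <- initial_state(system, c(stats::setNames(c(input1, input2), inputs), fixed))
    res <- settle(system, st, criterion)
    tibble(input1 = input1, input2 = input2,
           value = res$concentrations[[target]], converged = res$converged)
  })
  V <- matrix(vals$value, nrow = length(grids[[1]]), byrow = TRUE)
  shares <- dependence_shares(V)
  structure(vals, inputs = inputs, target = target, grids = grids,
            shares = stats::setNames(shares, inputs),
            class = c("psf_matrix", class(vals)))
}

# variance decomposition along the two axes of a response matrix:
# share_i = mean variance along axis i (holding the other fixed), normalized.
dependence_shares <- function(V) {
  v1 <- mean(apply(V, 2, stats::var))  # varying input1 within each input2 level
  v2 <- mean(apply(V, 1, stats::var))
  tot <- v1 + v2
  if (tot <= 0) return(c(0, 0))
  c(v1, v2) / tot
}

#' @export
print.psf_matrix <- function(x, ...) {
  sh <- attr(x, "shares")
  cat("<psf_matrix> target:", attr(x, "target"), "\n")
  cat("  dependence shares:", paste(names(sh), "=", signif(sh, 3), collapse = ", "), "\n")
  NextMethod()
}
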