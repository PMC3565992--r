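# Stiff integration and the pragmatic steady-state machinery. Rate constants
# in the striatal model span ~1e-12 to 1e3, so lsoda with an analytic
# Jacobian is used throughout; negative excursions from the solver are
# clipped to zero before rate evaluation.

#' Steady-state convergence criterion
#'
#' Steady state is declared pragmatically: every species above `floor` must
#' change by less than a fraction `rel_change` over a trailing `window`
#' seconds, checked jointly on a fixed `cadence`.
#'
#' @param rel_change maximal relative change over the window (default 0.02).
#' @param window trailing window in s (default 100).
#' @param floor concentration in nM below which a species is exempt from the
#'   relative test (default 1e-6).
#' @param max_time give up after this much model time, s.
#' @param cadence sampling interval for the check, s.
#' @return list of class `ss_criterion`.
#' @export
steady_state_criterion <- function(rel_change = 0.02, window = 100,
                                   floor = 1e-6, max_time = 1e5, cadence = 10) {
  stopifnot(rel_change > 0, rel_change < 1, window > 0, cadence > 0)
  structure(list(rel_change = rel_change, window = window, floor = floor,
                 max_time = max_time, cadence = cadence), class = "ss_criterion")
}

ode_fn <- function(t, y, parms) {
  x <- pmax(y, 0)
  list(drop(parms$S %*% step_rates(parms, x)))
}

ode_jac <- function(t, y, parms) {
  mass_action_jacobian(parms, y)
}

#' Integrate a reaction system
#'
#' Thin wrapper over [deSolve::lsoda()] with the system's compiled
#' mass-action right-hand side and analytic Jacobian.
#'
#' @param system a `reaction_system`.
#' @param state named initial concentration vector (defaults to the system's
#'   initial totals; see [initial_state()]).
#' @param times numeric vector of output times (s), or a scalar duration
#'   which is expanded to 201 samples.
#' @param rtol,atol solver tolerances.
#' @return tibble of class `psf_trajectory` in long format (`time`,
#'   `species`, `conc`); the wide matrix is kept in attribute `"wide"`.
#' @export
integrate_system <- function(system, state = NULL, times = 100,
                             rtol = 1e-8, atol = 1e-8) {
  cc <- system$compiled
  if (is.null(state)) state <- initial_state(system)
  if (any(state < 0)) abort("initial concentrations must be >= 0")
  if (length(times) == 1) times <- seq(0, times, length.out = 201)
  y0 <- stats::setNames(as.numeric(state[cc$species]), cc$species)
  out <- deSolve::lsoda(y0, times, ode_fn, parms = cc, jacfunc = ode_jac,
                        jactype = "fullusr", rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0) {
    abort(paste0("solver failure at t = ", max(out[, 1]), " s"))
  }
  wide <- out[, -1, drop = FALSE]
  rownames(wide) <- NULL
  tidy <- tidyr::pivot_longer(as_tibble(cbind(time = out[, 1], as_tibble(wide))),
                              -"time", names_to = "species", values_to = "conc")
  structure(tidy, wide = wide, times = out[, 1], class = c("psf_trajectory", class(tidy)))
}

#' Wide matrix view of a trajectory
#'
#' @param traj a `psf_trajectory` from [integrate_system()].
#' @return numeric matrix, one row per time, one column per species.
#' @export
traj_wide <- function(traj) attr(traj, "wide")

traj_times <- function(traj) attr(traj, "times")

#' Integrate to steady state under a pragmatic criterion
#'
#' Integrates in chunks, sampling every `criterion$cadence` seconds, and
#' stops at the first sample time at which every species above the floor has
#' changed by less than `rel_change` relative over the trailing window.
#'
#' @param system a `reaction_system`.
#' @param state named initial concentrations (defaults to initial totals).
#' @param criterion a [steady_state_criterion()].
#' @param keep_trajectory return the full sampled trajectory as attribute
#'   `"trajectory"` (wide matrix) for delay measurement.
#' @param dense_times optional extra output times prepended to the cadence
#'   grid (used for delay measurement of fast species).
#' @return list of class `ss_result`: `concentrations` (named vector, nM),
#'   `settle_time` (s), `converged` (flag); optionally the trajectory.
#' @export
settle <- function(system, state = NULL, criterion = steady_state_criterion(),
                   keep_trajectory = FALSE, dense_times = NULL,
                   rtol = 1e-8, atol = 1e-8) {
  cc <- system$compiled
  if (is.null(state)) state <- initial_state(system)
  y <- stats::setNames(as.numeric(state[cc$species]), cc$species)
  cad <- criterion$cadence
  win_n <- max(1L, round(criterion$window / cad))
  chunk <- max(criterion$window * 4, 400)
  t0 <- 0
  hist_t <- 0
  hist_x <- matrix(y, nrow = 1, dimnames = list(NULL, cc$species))
  settled_at <- NA_real_
  while (t0 < criterion$max_time && is.na(settled_at)) {
    t_end <- min(t0 + chunk, criterion$max_time)
    times <- seq(t0, t_end, by = cad)
    if (!is.null(dense_times)) {
      extra <- dense_times[dense_times > t0 & dense_times < t_end]
      times <- sort(unique(c(times, extra)))
    }
    out <- deSolve::lsoda(y, times, ode_fn, parms = cc, jacfunc = ode_jac,
                          jactype = "fullusr", rtol = rtol, atol = atol)
    if (attr(out, "istate")[1] < 0) {
      abort(paste0("solver failure at t = ", max(out[, 1]), " s"))
    }
    hist_t <- c(hist_t, out[-1, 1])
    hist_x <- rbind(hist_x, out[-1, -1, drop = FALSE])
    y <- stats::setNames(out[nrow(out), -1], cc$species)
    t0 <- t_end
    # check on the cadence grid only
    on_grid <- which(abs(hist_t %% cad) < 1e-9 | abs(hist_t %% cad - cad) < 1e-9)
    gt <- hist_t[on_grid]
    first_check <- which(gt >= criterion$window)
    for (ii in first_check[gt[first_check] > (gt[length(gt)] - chunk)]) {
      jj <- on_grid[ii]
      prev_t <- gt[ii] - criterion$window
      kk <- on_grid[which.min(abs(gt - prev_t))]
      cur <- pmax(hist_x[jj, ], 0); old <- pmax(hist_x[kk, ], 0)
      active <- cur > criterion$floor
      if (!any(active) || all(abs(cur[active] - old[active]) / cur[active] < criterion$rel_change)) {
        settled_at <- hist_t[jj]
        hist_t <- hist_t[seq_len(jj)]
        hist_x <- hist_x[seq_len(jj), , drop = FALSE]
        break
      }
    }
  }
  converged <- !is.na(settled_at)
  res <- structure(list(
    concentrations = stats::setNames(pmax(hist_x[nrow(hist_x), ], 0), cc$species),
    settle_time = if (converged) settled_at else criterion$max_time,
    converged = converged), class = "ss_result")
  if (keep_trajectory) {
    attr(res, "trajectory") <- list(time = hist_t, conc = hist_x)
  }
  res
}

#' @export
print.ss_result <- function(x, ...) {
  cat("<steady state> converged:", x$converged, " settle_time:", x$settle_time, "s\n")
  invisible(x)
}

#' Apply an instantaneous input step to a state
#'
#' Increases add the difference to the free input pool. Decreases remove
#' from the free pool first; any remainder is removed proportionally from
#' complexes that a single binding scheme forms from the input, returning
#' the binding partner so that all other moieties are conserved.
#'
#' @param system a `reaction_system`.
#' @param state named concentration vector.
#' @param input input species name.
#' @param total_before,total_after input totals in nM (>= 0).
#' @return updated named concentration vector.
#' @export
apply_input_step <- function(system, state, input, total_before, total_after) {
  if (total_before < 0 || total_after < 0) abort("totals must be >= 0")
  delta <- total_after - total_before
  if (delta >= 0) {
    state[input] <- state[input] + delta
    return(state)
  }
  need <- -delta
  take_free <- min(state[[input]], need)
  state[input] <- state[input] - take_free
  need <- need - take_free
  if (need > 1e-12) {
    # complexes directly formed from the input by one binding scheme
    part <- purrr::map_dfr(seq_len(nrow(system$schemes)), function(i) {
      r <- system$schemes[i, ]
      if (!r$kind %in% c("binding", "irreversible_binding")) return(NULL)
      L <- parse_side(r$lhs)
      if (!input %in% L$species || nrow(L) != 2) return(NULL)
      tibble(complex = r$rhs, partner = setdiff(L$species, input))
    })
    part <- part[!duplicated(part$complex), , drop = FALSE]
    avail <- sum(state[part$complex])
    if (avail + 1e-9 < need) {
      abort(paste0("requested removal of ", input,
                   " exceeds its removable total (free + direct complexes)"))
    }
    frac <- need / avail
    for (i in seq_len(nrow(part))) {
      rem <- state[[part$complex[i]]] * frac
      state[part$complex[i]] <- state[[part$complex[i]]] - rem
      state[part$partner[i]] <- state[[part$partner[i]]] + rem
    }
  }
  state
}

# hybrid output grid for delay measurement: dense early, cadence later
delay_sample_times <- function(upto = 100) {
  unique(c(seq(0, min(10, upto), by = 0.02),
           if (upto > 10) seq(10, min(100, upto), by = 0.2),
           if (upto > 100) seq(100, upto, by = 2)))
}

#' Measure 95%-of-change transition delays after an input step
#'
#' Equilibrates at `total_before` (or uses `baseline`), applies the step at
#' t = 0, integrates until the steady-state criterion holds, and reports for
#' each species the last time its trajectory is outside the band covering
#' `fraction` of its total change (robust to transients: last band exit, not
#' first crossing; crossing times are linearly interpolated between samples).
#'
#' @param system a `reaction_system`.
#' @param input input species name.
#' @param total_before,total_after input totals, nM.
#' @param species species to report (default: all).
#' @param fraction completed fraction defining the band (default 0.95).
#' @param criterion a [steady_state_criterion()].
#' @param baseline optional precomputed baseline `ss_result` at `total_before`.
#' @param fixed named totals for other species (e.g. `c(Ca = 8000)`).
#' @return tibble `species`, `delay` (s, `NA` when the change is below the
#'   criterion floor), `c_old`, `c_new`, `change`.
#' @export
transition_delay <- function(system, input, total_before, total_after,
                             species = NULL, fraction = 0.95,
                             criterion = steady_state_criterion(),
                             baseline = NULL, fixed = NULL) {
  stopifnot(fraction > 0, fraction < 1)
  if (is.null(baseline)) {
    baseline <- settle(system, initial_state(system, c(stats::setNames(total_before, input), fixed)),
                       criterion)
  }
  state0 <- apply_input_step(system, baseline$concentrations, input,
                             total_before, total_after)
  dense <- delay_sample_times(2000)
  post <- settle(system, state0, criterion, keep_trajectory = TRUE,
                 dense_times = dense)
  tr <- attr(post, "trajectory")
  tt <- tr$time; X <- tr$conc
  c_old <- baseline$concentrations
  c_new <- post$concentrations
  if (is.null(species)) species <- system$species$name
  band <- 1 - fraction
  purrr::map_dfr(species, function(sp) {
    ch <- c_new[[sp]] - c_old[[sp]]
    if (abs(ch) < criterion$floor) {
      return(tibble(species = sp, delay = NA_real_,
                    c_old = c_old[[sp]], c_new = c_new[[sp]], change = ch))
    }
    r <- abs(X[, sp] - c_new[[sp]]) / abs(ch)
    outside <- r > band
    if (!any(outside)) {
      delay <- 0
    } else {
      i <- max(which(outside))
      if (i == length(r)) {
        delay <- tt[i]  # never re-entered within the settled window
      } else {
        # linear interpolation of the band crossing between samples i, i+1
        f <- (r[i] - band) / (r[i] - r[i + 1])
        delay <- tt[i] + f * (tt[i + 1] - tt[i])
      }
    }
    tibble(species = sp, delay = delay, c_old = c_old[[sp]],
           c_new = c_new[[sp]], change = ch)
  })
}

#' Delay table for a set of input transitions
#'
#' Computes [transition_delay()] for each transition and lays the result out
#' with one row per species and one column per transition.
#'
#' @param system a `reaction_system`.
#' @param input input species name.
#' @param transitions list of `c(before, after)` pairs in nM.
#' @param species species rows to include.
#' @inheritParams transition_delay
#' @return tibble, first column `species`, then one delay column per
#'   transition labeled `"before->after"`.
#' @export
delay_table <- function(system, input, transitions, species = NULL,
                        fraction = 0.95, criterion = steady_state_criterion(),
                        fixed = NULL) {
  baselines <- new.env()
  get_base <- function(tot) {
    key <- format(tot, digits = 12)
    if (is.null(baselines[[key]])) {
      baselines[[key]] <- settle(system,
        initial_state(system, c(stats::setNames(tot, input), fixed)), criterion)
    }
    baselines[[key]]
  }
  cols <- purrr::map(transitions, function(tr) {
    d <- transition_delay(system, input, tr[1], tr[2], species = species,
                          fraction = fraction, criterion = criterion,
                          baseline = get_base(tr[1]), fixed = fixed)
    stats::setNames(d["delay"], paste0(format(tr[1], trim = TRUE), "->",
                                       format(tr[2], trim = TRUE)))
  })
  sp <- if (is.null(species)) system$species$name else species
  dplyr::bind_cols(c(list(tibble(species = sp)), cols))
}
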