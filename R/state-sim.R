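# Discrete state-change simulation: species jump to precomputed systemic
# psf values on their characteristic time scale (update interval drawn from
# delay-derived bins), with linear interpolation between slow-species
# updates. Transients of the underlying ODE model are deliberately not
# reproduced; for constant inputs held long enough the discrete model's
# limit equals the systemic psf value.

#' Assign update time scales from a delay table
#'
#' Each species receives the smallest bin that is >= its maximal observed
#' delay (ties at a bin edge go to that bin); species exceeding the largest
#' bin get the largest bin with a warning.
#'
#' @param delays tibble with a `species` column and one or more delay
#'   columns in s (e.g. from [delay_table()]); `NA` delays are ignored.
#' @param bins ascending update intervals in s (default `c(10, 300, 600)`).
#' @return tibble `species`, `max_delay`, `interval`.
#' @export
assign_timescales <- function(delays, bins = c(10, 300, 600)) {
  if (length(bins) == 0) abort("bins must be non-empty")
  bins <- sort(bins)
  num_cols <- names(delays)[vapply(delays, is.numeric, logical(1))]
  md <- apply(as.matrix(delays[num_cols]), 1, function(r) {
    r <- r[!is.na(r)]
    if (!length(r)) NA_real_ else max(r)
  })
  interval <- vapply(md, function(d) {
    if (is.na(d)) return(bins[1])
    i <- which(bins >= d)
    if (!length(i)) NA_real_ else bins[i[1]]
  }, numeric(1))
  over <- is.na(interval)
  if (any(over)) {
    warn(paste0("delays exceed the largest bin for: ",
                paste(delays$species[over], collapse = ", ")))
    interval[over] <- bins[length(bins)]
  }
  tibble(species = delays$species, max_delay = md, interval = interval)
}

# interpolate a psf lookup at an input total (linear in log-input when the
# sweep grid is log-spaced)
lookup_value <- function(grid, values, x, log_grid = TRUE) {
  if (x < min(grid) - 1e-9 || x > max(grid) + 1e-9) {
    abort(paste0("input level ", format(x), " nM outside the lookup grid [",
                 format(min(grid)), ", ", format(max(grid)), "]"))
  }
  x <- min(max(x, min(grid)), max(grid))
  if (log_grid) stats::approx(base::log(grid), values, xout = base::log(x))$y
  else stats::approx(grid, values, xout = x)$y
}

#' Discrete state-change simulation from psf lookups
#'
#' At each multiple of its assigned interval, a species is set to the
#' interpolated psf value for the current input total; between updates of
#' slow species, values are linearly interpolated in time. All species are
#' eligible at t = 0.
#'
#' @param schedule tibble `input_total` (nM), `duration` (s, > 0): an
#'   ordered sequence of held input levels.
#' @param assignment result of [assign_timescales()].
#' @param lookup a `psf_sweep` spanning the schedule's totals (its `log`
#'   attribute decides the interpolation scale).
#' @param dt output sampling interval, s (default: smallest interval).
#' @return tibble of class `discrete_trajectory`: `time`, `species`,
#'   `value`; update times carry `updated = TRUE`.
#' @export
simulate_discrete <- function(schedule, assignment, lookup, dt = NULL) {
  if (any(schedule$duration <= 0)) abort("schedule durations must be > 0")
  log_grid <- attr(lookup, "log") %||% TRUE
  grid <- sort(unique(lookup$input_total))
  ends <- cumsum(schedule$duration)
  total_T <- ends[length(ends)]
  # at a boundary the new level applies (the step happens at the boundary)
  input_at <- function(t) {
    i <- which(t < ends - 1e-9)[1]
    schedule$input_total[if (is.na(i)) length(ends) else i]
  }
  if (is.null(dt)) dt <- min(assignment$interval)
  times <- seq(0, total_T, by = dt)
  species <- intersect(assignment$species, unique(lookup$target))
  purrr::map_dfr(species, function(sp) {
    cv <- psf_curve(lookup, sp)
    iv <- assignment$interval[assignment$species == sp][1]
    upd_t <- seq(0, total_T, by = iv)
    upd_v <- vapply(upd_t, function(t) {
      lookup_value(cv$input_total, cv$value, input_at(t), log_grid)
    }, numeric(1))
    vals <- if (length(upd_t) == 1) rep(upd_v, length(times)) else
      stats::approx(upd_t, upd_v, xout = times, rule = 2)$y
    tibble(time = times, species = sp, value = vals,
           updated = times %in% upd_t)
  }) |>
    (\(d) structure(d, class = c("discrete_trajectory", class(d))))()
}

#' Compare a discrete state-change simulation with the continuous model
#'
#' Runs the ODE model over the same input schedule (starting from the
#' settled state at the first level, stepping the input instantaneously at
#' each boundary) and reports per-species maximal and mean relative
#' deviation of the discrete trajectory at its sample times.
#'
#' @param system a `reaction_system`.
#' @param input input species name.
#' @param schedule tibble `input_total`, `duration`.
#' @param assignment result of [assign_timescales()].
#' @param lookup a `psf_sweep` for `input`.
#' @param criterion a [steady_state_criterion()].
#' @param fixed named totals for other species.
#' @param floor concentrations below this are excluded from relative errors.
#' @return list: `summary` (tibble `species`, `max_rel_dev`,
#'   `mean_rel_dev`), `discrete`, `ode` (long tibbles).
#' @export
compare_with_ode <- function(system, input, schedule, assignment, lookup,
                             criterion = steady_state_criterion(),
                             fixed = NULL, floor = 1e-3) {
  disc <- simulate_discrete(schedule, assignment, lookup)
  times <- sort(unique(disc$time))
  # continuous reference
  base <- settle(system, initial_state(
    system, c(stats::setNames(schedule$input_total[1], input), fixed)), criterion)
  state <- base$concentrations
  ends <- cumsum(schedule$duration)
  starts <- c(0, ends[-length(ends)])
  cur_total <- schedule$input_total[1]
  ode_rows <- list()
  for (i in seq_len(nrow(schedule))) {
    if (schedule$input_total[i] != cur_total) {
      state <- apply_input_step(system, state, input, cur_total,
                                schedule$input_total[i])
      cur_total <- schedule$input_total[i]
    }
    seg_t <- unique(c(starts[i], times[times >= starts[i] & times <= ends[i]], ends[i]))
    tr <- integrate_system(system, state, times = seg_t - starts[i])
    W <- traj_wide(tr)
    state <- stats::setNames(pmax(W[nrow(W), ], 0), colnames(W))
    keep <- seg_t %in% times & seg_t < ends[i] | (i == nrow(schedule) & seg_t == ends[i])
    ode_rows[[i]] <- tibble(time = rep(seg_t[keep], ncol(W)),
                            species = rep(colnames(W), each = sum(keep)),
                            value = as.numeric(W[keep, , drop = FALSE]))
  }
  ode <- bind_rows(ode_rows)
  joined <- dplyr::inner_join(disc, ode, by = c("time", "species"),
                              suffix = c("_disc", "_ode"))
  summary <- joined |>
    filter(pmax(abs(.data$value_disc), abs(.data$value_ode)) > floor) |>
    mutate(rel = abs(.data$value_disc - .data$value_ode) /
             pmax(abs(.data$value_ode), floor)) |>
    group_by(.data$species) |>
    summarise(max_rel_dev = max(.data$rel), mean_rel_dev = mean(.data$rel))
  list(summary = summary, discrete = disc, ode = ode)
}
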