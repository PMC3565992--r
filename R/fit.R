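# Hyperbolic / linear parameterization of psf curves.
# The hyperbolic model is y(x) = y0 + Y * x^n / (C^n + x^n): amplitude Y
# (negative for depletion psfs), half-maximal input C > 0, exponent n > 0,
# baseline y0. Fitting is derivative-free (Nelder-Mead) over
# (Y, log C, log n, y0); a linear fit is preferred when it has no larger
# squared error, or when the fitted C lies far beyond the sampled grid
# (the curve is then only a short section of the full mapping).

hyperbolic_predict <- function(x, Y, C, n, y0) {
  y0 + Y * x^n / (C^n + x^n)
}

#' Fit a psf curve with a saturating hyperbolic or linear function
#'
#' @param curve a tibble with columns `input_total` and `value` (e.g. from
#'   [psf_curve()]), with at least 4 points.
#' @param init optional named list of starting values (`Y`, `C`, `n`, `y0`).
#' @param linear_C_factor select the linear model when fitted `C` exceeds
#'   this multiple of the grid maximum (default 10).
#' @return object of class `psf_fit`: list with `model` ("hyperbolic",
#'   "linear" or "constant"), `params` (named vector), `sse`, `data`.
#' @export
#' @examples
#' x <- exp(seq(log(10), log(1e4), length.out = 12))
#' curve <- tibble::tibble(input_total = x, value = 100 * x / (500 + x))
#' fit_psf(curve)
fit_psf <- function(curve, init = NULL, linear_C_factor = 10) {
  x <- curve$input_total; y <- curve$value
  if (length(x) < 4) abort("need at least 4 grid points to fit a psf")
  if (max(y) - min(y) < .Machine$double.eps * max(1, abs(max(y)))) {
    fit <- new_psf_fit("constant", c(slope = 0, intercept = y[1]), 0, curve)
    return(fit)
  }
  # linear candidate
  lf <- stats::lm.fit(cbind(1, x), y)
  lin_par <- c(slope = unname(lf$coefficients[2]), intercept = unname(lf$coefficients[1]))
  lin_sse <- sum(lf$residuals^2)
  # hyperbolic candidate: optimize (Y, logC, logn, y0)
  rising <- y[length(y)] >= y[1]
  if (is.null(init)) {
    y0_0 <- if (rising) min(y) else max(y)
    Y_0 <- if (rising) max(y) - min(y) else min(y) - max(y)
    half <- y0_0 + Y_0 / 2
    C_0 <- x[which.min(abs(y - half))]
    if (C_0 <= 0) C_0 <- stats::median(x)
    init <- list(Y = Y_0, C = C_0, n = 1, y0 = y0_0)
  }
  obj <- function(p) {
    pred <- hyperbolic_predict(x, p[1], exp(p[2]), exp(p[3]), p[4])
    sum((y - pred)^2)
  }
  p0 <- c(init$Y, base::log(init$C), base::log(init$n), init$y0)
  opt <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-12))
  # one restart from the optimum helps Nelder-Mead on narrow valleys
  opt2 <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                       control = list(maxit = 4000, reltol = 1e-12))
  if (opt2$value < opt$value) opt <- opt2
  hyp_par <- c(Y = opt$par[1], C = exp(opt$par[2]), n = exp(opt$par[3]),
               y0 = opt$par[4])
  hyp_sse <- opt$value
  if (lin_sse <= hyp_sse || hyp_par[["C"]] > linear_C_factor * max(x)) {
    new_psf_fit("linear", lin_par, lin_sse, curve)
  } else {
    new_psf_fit("hyperbolic", hyp_par, hyp_sse, curve)
  }
}

new_psf_fit <- function(model, params, sse, data) {
  structure(list(model = model, params = params, sse = sse, data = data,
                 target = if ("target" %in% names(data)) data$target[1] else NA_character_),
            class = "psf_fit")
}

#' Predict from a psf fit
#'
#' @param object a `psf_fit`.
#' @param x input totals, nM.
#' @param ... unused.
#' @return predicted target concentrations, nM.
#' @export
predict.psf_fit <- function(object, x, ...) {
  p <- object$params
  switch(object$model,
    hyperbolic = hyperbolic_predict(x, p[["Y"]], p[["C"]], p[["n"]], p[["y0"]]),
    linear = ,
    constant = p[["intercept"]] + p[["slope"]] * x)
}

#' @export
print.psf_fit <- function(x, ...) {
  cat("<psf_fit> ", x$model,
      if (!is.na(x$target)) paste0(" (target ", x$target, ")"), "\n", sep = "")
  print(signif(x$params, 4))
  cat("sse:", format(x$sse, digits = 4), "\n")
  invisible(x)
}

#' Fit every target of a sweep
#'
#' @param sweep a `psf_sweep`.
#' @param ... passed to [fit_psf()].
#' @return tibble: `target`, `model`, `Y`, `C`, `n`, `y0`, `slope`,
#'   `intercept`, `sse`, and a list-column `fit`.
#' @export
fit_all_psfs <- function(sweep, ...) {
  targets <- unique(sweep$target)
  purrr::map_dfr(targets, function(tg) {
    f <- fit_psf(psf_curve(sweep, tg), ...)
    p <- f$params
    g <- function(nm) if (nm %in% names(p)) unname(p[[nm]]) else NA_real_
    tibble(target = tg, model = f$model, Y = g("Y"), C = g("C"), n = g("n"),
           y0 = g("y0"), slope = g("slope"), intercept = g("intercept"),
           sse = f$sse, fit = list(f))
  })
}

#' Signal transmission strength of a psf
#'
#' Reports the local slope (analytic derivative of a fit, or a central
#' difference on a raw curve) and the relative gain: the fractional output
#' change produced by a `factor`-fold input change.
#'
#' @param fit_or_curve a `psf_fit` or a curve tibble (`input_total`, `value`).
#' @param x input level, nM.
#' @param factor fold input change (default 2).
#' @return tibble `x`, `slope` (nM output per nM input), `relative_gain`
#'   (`NA` with a warning when the output at `x` is zero).
#' @export
transmission_strength <- function(fit_or_curve, x, factor = 2) {
  if (inherits(fit_or_curve, "psf_fit")) {
    f <- fit_or_curve
    p <- f$params
    yx <- predict(f, x); yfx <- predict(f, factor * x)
    slope <- switch(f$model,
      hyperbolic = {
        Y <- p[["Y"]]; C <- p[["C"]]; n <- p[["n"]]
        Y * n * C^n * x^(n - 1) / (C^n + x^n)^2
      },
      linear = ,
      constant = rep(p[["slope"]], length(x)))
  } else {
    cx <- fit_or_curve$input_total; cy <- fit_or_curve$value
    yx <- stats::approx(cx, cy, xout = x, rule = 2)$y
    yfx <- stats::approx(cx, cy, xout = factor * x, rule = 2)$y
    h <- pmax(x * 1e-3, 1e-9)
    slope <- (stats::approx(cx, cy, xout = x + h, rule = 2)$y -
              stats::approx(cx, cy, xout = x - h, rule = 2)$y) / (2 * h)
  }
  gain <- ifelse(yx == 0, NA_real_, (yfx - yx) / yx)
  if (any(is.na(gain))) warn("relative gain undefined where the output is zero")
  tibble(x = x, slope = as.numeric(slope), relative_gain = as.numeric(gain))
}

#' Adjust elementary rate constants to match a target systemic psf
#'
#' Derivative-free (Nelder-Mead, in log space) search over the selected rate
#' constants of one scheme, minimizing the squared distance between the
#' recomputed systemic psf of `target` and the target fit's predictions on
#' the sweep grid.
#'
#' @param system a `reaction_system`.
#' @param scheme_id id of the scheme whose rates may move.
#' @param target_fit a `psf_fit` (or any object with a `predict` method over
#'   input totals) describing the desired systemic psf.
#' @param free_parameters subset of `c("kon", "koff", "kcat")`.
#' @param input,grid sweep input species and grid used for the comparison.
#' @param target target species of the systemic psf.
#' @param tolerance residual (sse) below which the search is declared
#'   converged.
#' @param criterion a [steady_state_criterion()].
#' @param fixed named totals for other species.
#' @param maxit optimizer iteration cap (each iteration re-sweeps the system).
#' @return list: `rates` (named vector of the scheme's new constants),
#'   `residual`, `converged`, `system` (updated copy).
#' @export
adjust_elementary_to_match <- function(system, scheme_id, target_fit,
                                       free_parameters, input, grid, target,
                                       tolerance = 1e-3,
                                       criterion = steady_state_criterion(),
                                       fixed = NULL, maxit = 60) {
  i <- match(scheme_id, system$schemes$id)
  if (is.na(i)) abort(paste0("no scheme with id ", scheme_id))
  free_parameters <- match.arg(free_parameters, c("kon", "koff", "kcat"),
                               several.ok = TRUE)
  cur <- unlist(system$schemes[i, c("kon", "koff", "kcat")])
  if (anyNA(cur[free_parameters])) {
    abort("a free parameter is not defined for this scheme kind")
  }
  want <- predict(target_fit, grid)
  sweep_sse <- function(sys) {
    sw <- systemic_psf(sys, input, n = length(grid), grid = grid,
                       targets = target, criterion = criterion, fixed = fixed)
    sum((psf_curve(sw, target)$value - want)^2)
  }
  obj <- function(logp) {
    p <- exp(logp)
    sys2 <- do.call(update_scheme_rates,
                    c(list(system, scheme_id), as.list(stats::setNames(p, free_parameters))))
    sweep_sse(sys2)
  }
  p0 <- base::log(cur[free_parameters])
  r0 <- obj(p0)
  if (r0 <= tolerance) {
    return(list(rates = cur, residual = r0, converged = TRUE, system = system))
  }
  opt <- suppressWarnings(stats::optim(p0, obj, method = "Nelder-Mead",
                                       control = list(maxit = maxit, reltol = 1e-8)))
  best <- exp(opt$par)
  sys2 <- do.call(update_scheme_rates,
                  c(list(system, scheme_id), as.list(stats::setNames(best, free_parameters))))
  rates <- unlist(sys2$schemes[i, c("kon", "koff", "kcat")])
  conv <- opt$value <= tolerance
  if (!conv) {
    warn(paste0("residual ", format(opt$value, digits = 4),
                " above tolerance; returning best-found parameters"))
  }
  list(rates = rates, residual = opt$value, converged = conv, system = sys2)
}
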