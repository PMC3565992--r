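#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line labs scale_x_log10
#' @export
ggplot2::autoplot

#' Tidy a psf fit
#'
#' @param x a `psf_fit`.
#' @param ... unused.
#' @return tibble with one row per parameter: `term`, `estimate`.
#' @method tidy psf_fit
#' @export
tidy.psf_fit <- function(x, ...) {
  tibble(term = names(x$params), estimate = unname(x$params))
}

#' One-row summary of a psf fit
#'
#' @param x a `psf_fit`.
#' @param ... unused.
#' @return tibble: `model`, `sse`, `n`.
#' @method glance psf_fit
#' @export
glance.psf_fit <- function(x, ...) {
  tibble(model = x$model, sse = x$sse, n = nrow(x$data))
}

#' Plot a psf fit over its data
#'
#' @param object a `psf_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot psf_fit
#' @export
autoplot.psf_fit <- function(object, ...) {
  d <- object$data
  xs <- exp(seq(base::log(min(d$input_total)), base::log(max(d$input_total)),
                length.out = 200))
  pred <- tibble(input_total = xs, value = predict(object, xs))
  ggplot(d, aes(x = .data$input_total, y = .data$value)) +
    geom_point() +
    geom_line(data = pred, colour = "steelblue") +
    scale_x_log10() +
    labs(x = "input total (nM)", y = "steady-state concentration (nM)",
         title = paste0(object$model, " psf fit",
                        if (!is.na(object$target)) paste0(": ", object$target)))
}

#' Plot systemic psf curves from a sweep
#'
#' @param object a `psf_sweep`.
#' @param targets optional subset of target species.
#' @param ... unused.
#' @return a ggplot, one facet-free line per target.
#' @method autoplot psf_sweep
#' @export
autoplot.psf_sweep <- function(object, targets = NULL, ...) {
  d <- if (is.null(targets)) object else filter(object, .data$target %in% targets)
  ggplot(d, aes(x = .data$input_total, y = .data$value, colour = .data$target)) +
    geom_line() + geom_point(size = 0.8) +
    scale_x_log10() +
    labs(x = paste0("total ", attr(object, "input"), " (nM)"),
         y = "steady-state concentration (nM)", colour = "target")
}

#' Plot a discrete state-change trajectory
#'
#' @param object a `discrete_trajectory`.
#' @param species optional subset.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot discrete_trajectory
#' @export
autoplot.discrete_trajectory <- function(object, species = NULL, ...) {
  d <- if (is.null(species)) object else filter(object, .data$species %in% species)
  ggplot(d, aes(x = .data$time, y = .data$value, colour = .data$species)) +
    geom_line() +
    geom_point(data = filter(d, .data$updated), size = 1) +
    labs(x = "time (s)", y = "concentration (nM)", colour = "species")
}

#' Tidy a steady-state result
#'
#' @param x an `ss_result` from [settle()].
#' @param ... unused.
#' @return tibble `species`, `conc`.
#' @method tidy ss_result
#' @export
tidy.ss_result <- function(x, ...) {
  tibble(species = names(x$concentrations), conc = unname(x$concentrations))
}

#' One-row summary of a steady-state result
#'
#' @param x an `ss_result`.
#' @param ... unused.
#' @return tibble `converged`, `settle_time`.
#' @method glance ss_result
#' @export
glance.ss_result <- function(x, ...) {
  tibble(converged = x$converged, settle_time = x$settle_time)
}
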