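# Input-dependent modularity: species saturate (or deplete) along their
# systemic psf; beyond the EC90 (rising) / EC10 (falling) input level they
# transmit no further signal change and become inactive links. EC levels
# are measured relative to each species' own min/max over the sweep, so the
# same rule applies to rising and falling targets.

#' EC90/EC10 cutoff input levels per target
#'
#' For a rising target the cutoff is the smallest grid input at which the
#' species has covered at least 90% of its own range; for a falling target,
#' the smallest input at which it has dropped to within 10% of its minimum.
#' `NA` if the cutoff is never reached within the grid.
#'
#' @param sweep a `psf_sweep`.
#' @param ec fraction of range defining the cutoff (default 0.9).
#' @return tibble `target`, `direction` (`"rising"`/`"falling"`/`"flat"`),
#'   `relative_span` ((max-min)/max over the sweep; 0 for an all-zero
#'   curve), `cutoff_input` (nM or `NA`).
#' @export
input_target_cutoffs <- function(sweep, ec = 0.9) {
  targets <- unique(sweep$target)
  purrr::map_dfr(targets, function(tg) {
    cv <- psf_curve(sweep, tg)
    lo <- min(cv$value); hi <- max(cv$value)
    span <- if (hi > 0) (hi - lo) / hi else 0
    if (hi - lo <= .Machine$double.eps * max(1, hi)) {
      return(tibble(target = tg, direction = "flat", relative_span = 0,
                    cutoff_input = NA_real_))
    }
    rising <- cv$value[nrow(cv)] >= cv$value[1]
    # an exactly linear responder transmits uniformly over the whole grid and
    # has no saturation point; curved responses use the range-based EC rule
    lf <- stats::lm.fit(cbind(1, cv$input_total), cv$value)
    if (sum(lf$residuals^2) < 1e-9 * stats::var(cv$value) * (nrow(cv) - 1)) {
      return(tibble(target = tg, direction = if (rising) "rising" else "falling",
                    relative_span = span, cutoff_input = NA_real_))
    }
    thr <- if (rising) lo + ec * (hi - lo) else lo + (1 - ec) * (hi - lo)
    hit <- if (rising) which(cv$value >= thr) else which(cv$value <= thr)
    # require the level to be held to the end of the grid (monotone tail),
    # so a transiently high point does not count as saturation
    cut <- NA_real_
    for (i in hit) {
      tail_ok <- if (rising) all(cv$value[i:nrow(cv)] >= thr)
                 else all(cv$value[i:nrow(cv)] <= thr)
      if (tail_ok) { cut <- cv$input_total[i]; break }
    }
    tibble(target = tg, direction = if (rising) "rising" else "falling",
           relative_span = span, cutoff_input = cut)
  })
}

#' Classify species activity at an input level
#'
#' A species is `nonresponsive` when its relative span over the sweep is
#' below `span_threshold` (it barely responds to the input at all);
#' `inactive` when the queried level is at or beyond its EC90/EC10 cutoff
#' (saturated or depleted; it transmits no further change); otherwise
#' `active`.
#'
#' @param sweep a `psf_sweep`.
#' @param input_level queried input total, nM (within the sweep range).
#' @param span_threshold minimal relative span counted as a response
#'   (default 0.10).
#' @param ec cutoff fraction passed to [input_target_cutoffs()].
#' @return tibble `species`, `relative_span`, `direction`, `cutoff_input`,
#'   `status` (factor-like character: nonresponsive/active/inactive).
#' @export
classify_activity <- function(sweep, input_level, span_threshold = 0.10, ec = 0.9) {
  cuts <- input_target_cutoffs(sweep, ec = ec)
  mutate(
    tibble(species = cuts$target, relative_span = cuts$relative_span,
           direction = cuts$direction, cutoff_input = cuts$cutoff_input),
    status = dplyr::case_when(
      relative_span < span_threshold ~ "nonresponsive",
      !is.na(cutoff_input) & input_level >= cutoff_input ~ "inactive",
      TRUE ~ "active"))
}

#' Extract input-level-dependent modules
#'
#' Modules are the connected components of the species-reaction graph
#' restricted to active species (reaction nodes act as conduits: two species
#' are connected when they share a scheme and both are active). Inactive
#' and nonresponsive species are listed as inactive links.
#'
#' @param system a `reaction_system`.
#' @param activities result of [classify_activity()].
#' @return list of class `modularity_report`: `modules` (tibble `species`,
#'   `module`), `inactive_links` (tibble `species`, `status`), `n_modules`,
#'   `activities`.
#' @export
modules_at <- function(system, activities) {
  active <- activities$species[activities$status == "active"]
  # species co-membership graph via shared schemes
  pairs <- purrr::map_dfr(seq_len(nrow(system$schemes)), function(i) {
    r <- system$schemes[i, ]
    sp <- unique(c(parse_side(r$lhs)$species, parse_side(r$mid)$species,
                   parse_side(r$rhs)$species))
    sp <- intersect(sp, active)
    if (length(sp) < 2) return(NULL)
    cmb <- utils::combn(sp, 2)
    tibble(from = cmb[1, ], to = cmb[2, ])
  })
  if (nrow(pairs) == 0) pairs <- tibble(from = character(), to = character())
  g <- igraph::graph_from_data_frame(pairs, directed = FALSE,
                                     vertices = tibble(name = active))
  comp <- igraph::components(g)
  modules <- tibble(species = names(comp$membership),
                    module = unname(comp$membership))
  inact <- activities[activities$status != "active", c("species", "status")]
  structure(list(modules = modules, inactive_links = as_tibble(inact),
                 n_modules = comp$no, activities = activities),
            class = "modularity_report")
}

#' @export
print.modularity_report <- function(x, ...) {
  cat("<modularity_report> ", x$n_modules, " modules among ",
      nrow(x$modules), " active species; ", nrow(x$inactive_links),
      " inactive/nonresponsive\n", sep = "")
  invisible(x)
}
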