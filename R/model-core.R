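#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr bind_rows mutate filter select arrange group_by summarise ungroup left_join
NULL

SCHEME_KINDS <- c("binding", "irreversible_binding", "enzymatic", "conversion",
                  "decomposition")

# ---- side parsing ------------------------------------------------------------

#' Parse one side of a reaction into species and stoichiometries
#'
#' Accepts `+`-separated terms; each term is a species name optionally
#' prefixed with an integer stoichiometry as `n*species` (e.g. `"1*PP2A + 4*Ca"`).
#'
#' @param text character scalar, e.g. `"A + 2*B"`; `NA` or `""` gives an empty side.
#' @return tibble with columns `species`, `stoich`.
#' @keywords internal
parse_side <- function(text) {
  if (length(text) != 1 || is.na(text) || !nzchar(trimws(text))) {
    return(tibble(species = character(), stoich = integer()))
  }
  terms <- trimws(strsplit(text, "+", fixed = TRUE)[[1]])
  if (any(!nzchar(terms))) abort(paste0("empty term in side: '", text, "'"))
  m <- regmatches(terms, regexec("^([0-9]+)\\*(.+)$", terms))
  sp <- character(length(terms)); st <- integer(length(terms))
  for (i in seq_along(terms)) {
    if (length(m[[i]]) == 3) {
      st[i] <- as.integer(m[[i]][2]); sp[i] <- trimws(m[[i]][3])
    } else {
      st[i] <- 1L; sp[i] <- terms[i]
    }
  }
  if (any(st < 1)) abort("stoichiometry must be >= 1")
  # merge duplicate species within a side
  agg <- tapply(st, sp, sum)
  tibble(species = names(agg), stoich = as.integer(agg))[order(match(names(agg), sp)), ]
}

format_side <- function(side) {
  if (nrow(side) == 0) return("")
  paste(ifelse(side$stoich == 1L, side$species,
               paste0(side$stoich, "*", side$species)), collapse = " + ")
}

# ---- schemes -----------------------------------------------------------------

#' Build a reaction scheme
#'
#' A scheme is one row of a kinetic model table: a `binding` (reversible
#' complex formation, 2 elementary steps), `irreversible_binding` (forward
#' only, 1 step), `enzymatic` (substrate + enzyme <-> complex -> products,
#' 3 steps), `conversion` (A -> B, 1 step) or `decomposition`
#' (AB -> products, 1 step). Rate constants are `kon` in nM^-(order-1) s^-1,
#' `koff` and `kcat` in s^-1.
#'
#' @param kind one of `r paste0('"', SCHEME_KINDS, '"', collapse = ", ")`.
#' @param lhs left-hand side, `+`-separated species with optional `n*` stoichiometry.
#' @param rhs right-hand side (the complex for bindings, products otherwise).
#' @param mid intermediate complex, enzymatic schemes only.
#' @param kon,koff,kcat rate constants required by `kind` (see details).
#' @param id integer scheme id (defaults to `NA`, filled in by [reaction_system()]).
#' @return one-row tibble with class information used by [expand_system()].
#' @export
#' @examples
#' build_scheme("binding", "Da + D1R", "DaD1R", kon = 0.00111, koff = 10)
build_scheme <- function(kind, lhs, rhs, mid = NULL, kon = NULL, koff = NULL,
                         kcat = NULL, id = NA_integer_) {
  if (!kind %in% SCHEME_KINDS) abort(paste0("unknown scheme kind: '", kind, "'"))
  need <- switch(kind,
    binding              = c("kon", "koff"),
    irreversible_binding = "kon",
    enzymatic            = c("kon", "koff", "kcat"),
    conversion           = "kcat",
    decomposition        = "kcat")
  have <- list(kon = kon, koff = koff, kcat = kcat)
  for (nm in need) {
    if (is.null(have[[nm]]) || is.na(have[[nm]])) {
      abort(paste0("scheme kind '", kind, "' requires rate constant '", nm, "'"))
    }
  }
  for (nm in names(have)) {
    if (!is.null(have[[nm]]) && !is.na(have[[nm]]) && have[[nm]] < 0) {
      abort(paste0("rate constant '", nm, "' must be >= 0"))
    }
  }
  L <- parse_side(lhs); M <- parse_side(mid); R <- parse_side(rhs)
  ok <- switch(kind,
    binding              = nrow(L) >= 1 && nrow(R) == 1 && nrow(M) == 0,
    irreversible_binding = nrow(L) >= 1 && nrow(R) == 1 && nrow(M) == 0,
    enzymatic            = nrow(L) >= 1 && nrow(M) == 1 && nrow(R) >= 1,
    conversion           = nrow(L) == 1 && L$stoich == 1L && nrow(R) == 1 &&
                           R$stoich == 1L && nrow(M) == 0,
    decomposition        = nrow(L) == 1 && nrow(R) >= 2 && nrow(M) == 0)
  if (!ok) abort(paste0("participants inconsistent with kind '", kind, "' in '",
                        lhs, " / ", mid %||% "", " / ", rhs, "'"))
  tibble(id = as.integer(id), kind = kind,
         lhs = format_side(L), mid = if (nrow(M)) format_side(M) else NA_character_,
         rhs = format_side(R),
         kon = kon %||% NA_real_, koff = koff %||% NA_real_, kcat = kcat %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Expand reaction schemes into elementary mass-action steps
#'
#' Bindings expand to forward + reverse steps, enzymatic schemes to
#' forward + reverse + catalytic, the remaining kinds to a single step.
#' Step order is deterministic: schemes in id order, forward / reverse /
#' catalytic within a scheme.
#'
#' @param schemes tibble of schemes as returned by [build_scheme()].
#' @return tibble with columns `scheme_id`, `role`, `rate`, and list-columns
#'   `reactants`, `products` (each a tibble of `species`, `stoich`).
#' @export
expand_system <- function(schemes) {
  if (is.null(schemes) || nrow(schemes) == 0) {
    return(tibble(scheme_id = integer(), role = character(), rate = double(),
                  reactants = list(), products = list()))
  }
  one <- function(row) {
    L <- parse_side(row$lhs); M <- parse_side(row$mid); R <- parse_side(row$rhs)
    switch(row$kind,
      binding = list(
        list(role = "forward", rate = row$kon, reactants = L, products = R),
        list(role = "reverse", rate = row$koff, reactants = R, products = L)),
      irreversible_binding = list(
        list(role = "forward", rate = row$kon, reactants = L, products = R)),
      enzymatic = list(
        list(role = "forward",   rate = row$kon,  reactants = L, products = M),
        list(role = "reverse",   rate = row$koff, reactants = M, products = L),
        list(role = "catalytic", rate = row$kcat, reactants = M, products = R)),
      conversion = list(
        list(role = "catalytic", rate = row$kcat, reactants = L, products = R)),
      decomposition = list(
        list(role = "catalytic", rate = row$kcat, reactants = L, products = R)))
  }
  out <- purrr::map(seq_len(nrow(schemes)), function(i) {
    row <- schemes[i, ]
    steps <- one(as.list(row))
    tibble(scheme_id = row$id, role = purrr::map_chr(steps, "role"),
           rate = purrr::map_dbl(steps, "rate"),
           reactants = purrr::map(steps, "reactants"),
           products = purrr::map(steps, "products"))
  })
  bind_rows(out)
}

# ---- system ------------------------------------------------------------------

#' Construct a reaction system
#'
#' @param species tibble with columns `name`, `initial_total` (nM, >= 0) and
#'   optionally `is_input`; species appearing in schemes but not listed are
#'   added with initial total 0.
#' @param schemes tibble of schemes ([build_scheme()] rows bound together).
#' @param inputs character vector of input species names (overrides `is_input`).
#' @param moieties optional list of moieties, each
#'   `list(name =, members = tibble(species, mult), conserved = TRUE)`.
#' @return object of class `reaction_system`: a list with tibbles `species`,
#'   `schemes`, `steps`, the `moieties` list, `inputs`, and a compiled
#'   stoichiometric form used by the integrator.
#' @export
reaction_system <- function(species, schemes, inputs = NULL, moieties = list()) {
  if (is.character(species)) species <- tibble(name = species, initial_total = 0)
  species <- as_tibble(species)
  if (!"initial_total" %in% names(species)) species$initial_total <- 0
  if (anyDuplicated(species$name)) abort("species names must be unique")
  if (any(species$initial_total < 0)) abort("initial totals must be >= 0")
  if (!is.null(schemes) && nrow(schemes) > 0 && anyNA(schemes$id)) {
    schemes$id[is.na(schemes$id)] <- setdiff(seq_len(nrow(schemes) + sum(!is.na(schemes$id))),
                                             schemes$id)[seq_len(sum(is.na(schemes$id)))]
  }
  schemes <- arrange(as_tibble(schemes), .data$id)
  steps <- expand_system(schemes)
  referenced <- unique(unlist(purrr::map(c(steps$reactants, steps$products), "species")))
  missing <- setdiff(referenced, species$name)
  if (length(missing)) {
    species <- bind_rows(species,
                         tibble(name = missing, initial_total = 0))
  }
  if (is.null(inputs)) {
    inputs <- if ("is_input" %in% names(species)) species$name[isTRUE_vec(species$is_input)] else character()
  }
  bad <- setdiff(inputs, species$name)
  if (length(bad)) abort(paste0("input species not declared: ", paste(bad, collapse = ", ")))
  species$is_input <- species$name %in% inputs
  sys <- structure(list(species = species, schemes = schemes, steps = steps,
                        moieties = moieties, inputs = inputs), class = "reaction_system")
  sys$compiled <- compile_system(sys)
  sys$weak_reversibility <- check_weak_reversibility(sys)
  sys
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' @export
print.reaction_system <- function(x, ...) {
  cat("<reaction_system> ", nrow(x$species), " species, ", nrow(x$schemes),
      " schemes (", nrow(x$steps), " elementary steps)\n", sep = "")
  cat("  inputs: ", paste(x$inputs, collapse = ", "), "\n", sep = "")
  wr <- attr(x$weak_reversibility, "pass")
  cat("  weakly reversible: ", if (isTRUE(wr)) "yes" else "NO", "\n", sep = "")
  invisible(x)
}

# Compile the step list into index vectors for fast mass-action evaluation.
# Each step has at most two distinct reactant species (true for all supported
# scheme kinds); the net stoichiometry matrix S is species x steps.
compile_system <- function(sys) {
  sp <- sys$species$name
  ns <- length(sp); nk <- nrow(sys$steps)
  S <- matrix(0, ns, nk, dimnames = list(sp, NULL))
  i1 <- rep(1L, nk); p1 <- rep(0, nk); i2 <- rep(1L, nk); p2 <- rep(0, nk)
  for (j in seq_len(nk)) {
    r <- sys$steps$reactants[[j]]; p <- sys$steps$products[[j]]
    if (nrow(r) > 2) abort("elementary steps with >2 distinct reactants unsupported")
    if (nrow(r) >= 1) { i1[j] <- match(r$species[1], sp); p1[j] <- r$stoich[1] }
    if (nrow(r) == 2) { i2[j] <- match(r$species[2], sp); p2[j] <- r$stoich[2] }
    for (m in seq_len(nrow(r))) S[r$species[m], j] <- S[r$species[m], j] - r$stoich[m]
    for (m in seq_len(nrow(p))) S[p$species[m], j] <- S[p$species[m], j] + p$stoich[m]
  }
  list(species = sp, S = S, k = sys$steps$rate, i1 = i1, p1 = p1, i2 = i2, p2 = p2)
}

#' Net mass-action rates of change
#'
#' Each elementary step contributes `k * prod(conc^stoich)` over its
#' reactants; the net per-species change is the stoichiometry-weighted sum
#' over all steps.
#'
#' @param system a `reaction_system`.
#' @param concentrations named numeric vector, nM, covering all species
#'   (missing species are an error).
#' @return named numeric vector of d(conc)/dt in nM/s.
#' @export
mass_action_rates <- function(system, concentrations) {
  cc <- system$compiled
  miss <- setdiff(cc$species, names(concentrations))
  if (length(miss)) abort(paste0("unknown species in step evaluation: missing concentration for ",
                                 paste(miss, collapse = ", ")))
  x <- pmax(as.numeric(concentrations[cc$species]), 0)
  v <- step_rates(cc, x)
  drop(cc$S %*% v)
}

step_rates <- function(cc, x) {
  cc$k * x[cc$i1]^cc$p1 * x[cc$i2]^cc$p2
}

# analytic Jacobian of the net rate vector (species x species)
mass_action_jacobian <- function(cc, x) {
  x <- pmax(x, 0)
  nk <- length(cc$k)
  f1 <- x[cc$i1]^cc$p1; f2 <- x[cc$i2]^cc$p2
  d1 <- cc$k * cc$p1 * x[cc$i1]^pmax(cc$p1 - 1, 0) * f2
  d2 <- cc$k * cc$p2 * x[cc$i2]^pmax(cc$p2 - 1, 0) * f1
  ns <- length(cc$species)
  D <- matrix(0, nk, ns)
  D[cbind(seq_len(nk), cc$i1)] <- d1
  idx2 <- which(cc$p2 > 0)
  D[cbind(idx2, cc$i2[idx2])] <- D[cbind(idx2, cc$i2[idx2])] + d2[idx2]
  cc$S %*% D
}

# ---- weak reversibility ------------------------------------------------------

#' Check weak reversibility of a reaction system
#'
#' A system is (weakly) reversible in the sense required for bounded steady
#' states when every species is both produced by at least one elementary step
#' and consumed by at least one step.
#'
#' @param system a `reaction_system`.
#' @return tibble with columns `species`, `produced`, `consumed`, `ok`;
#'   attribute `"pass"` is `TRUE` iff all species pass.
#' @export
check_weak_reversibility <- function(system) {
  sp <- system$species$name
  produced <- consumed <- stats::setNames(rep(FALSE, length(sp)), sp)
  for (j in seq_len(nrow(system$steps))) {
    consumed[system$steps$reactants[[j]]$species] <- TRUE
    produced[system$steps$products[[j]]$species] <- TRUE
  }
  rep_tbl <- tibble(species = sp, produced = unname(produced),
                    consumed = unname(consumed),
                    ok = unname(produced & consumed))
  attr(rep_tbl, "pass") <- all(rep_tbl$ok)
  rep_tbl
}

# ---- moieties ----------------------------------------------------------------

moiety <- function(name, species, mult = NULL, conserved = TRUE) {
  if (is.null(mult)) mult <- rep(1L, length(species))
  list(name = name, members = tibble(species = species, mult = as.integer(mult)),
       conserved = conserved)
}

#' Multiplicity-weighted moiety totals
#'
#' @param system a `reaction_system`.
#' @param concentrations named vector, or a wide trajectory matrix with
#'   species columns.
#' @return tibble `moiety`, `total` (or `moiety` x `time` when given a matrix).
#' @export
moiety_totals <- function(system, concentrations) {
  if (is.matrix(concentrations) || is.data.frame(concentrations)) {
    m <- as.matrix(concentrations)
    purrr::map_dfr(system$moieties, function(mo) {
      w <- stats::setNames(rep(0, ncol(m)), colnames(m))
      w[mo$members$species] <- mo$members$mult
      tibble(moiety = mo$name, row = seq_len(nrow(m)),
             total = as.numeric(m %*% w), conserved = mo$conserved)
    })
  } else {
    purrr::map_dfr(system$moieties, function(mo) {
      tibble(moiety = mo$name,
             total = sum(concentrations[mo$members$species] * mo$members$mult),
             conserved = mo$conserved)
    })
  }
}

#' Initial (free) concentration vector of a system
#'
#' @param system a `reaction_system`.
#' @param totals named numeric vector of overrides for initial totals
#'   (e.g. `c(Da = 60, Ca = 8000)`).
#' @return named numeric vector over all species, nM.
#' @export
initial_state <- function(system, totals = NULL) {
  x <- stats::setNames(system$species$initial_total, system$species$name)
  if (!is.null(totals)) {
    bad <- setdiff(names(totals), names(x))
    if (length(bad)) abort(paste0("unknown species in totals: ", paste(bad, collapse = ", ")))
    x[names(totals)] <- totals
  }
  x
}

# Replace rate constants of one scheme and recompile.
update_scheme_rates <- function(system, scheme_id, kon = NULL, koff = NULL, kcat = NULL) {
  i <- match(scheme_id, system$schemes$id)
  if (is.na(i)) abort(paste0("no scheme with id ", scheme_id))
  if (!is.null(kon))  system$schemes$kon[i] <- kon
  if (!is.null(koff)) system$schemes$koff[i] <- koff
  if (!is.null(kcat)) system$schemes$kcat[i] <- kcat
  reaction_system(system$species, system$schemes, inputs = system$inputs,
                  moieties = system$moieties)
}
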