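#' Construct small test systems with known behaviour
#'
#' * `toy_binding`: a single reversible complex formation `A + B <-> AB`
#'   whose steady state has the quadratic closed form
#'   `AB = ((At+Bt+Kd) - sqrt((At+Bt+Kd)^2 - 4*At*Bt))/2` with `Kd = koff/kon`.
#' * `toy_covalent_cycle`: a substrate shuttled between `S` and `Sp` by a
#'   kinase/phosphatase pair of reversible enzymatic schemes
#'   (Goldbeter-Koshland-type covalent modification cycle).
#' * `toy_relaxation`: a two-state conversion `A <-> B`; after any step in
#'   total, both species relax single-exponentially at rate `r1 + r2`.
#' * `random_weakly_reversible`: a seeded random ring of reversible
#'   conversions with random reversible bindings attached; always passes the
#'   weak-reversibility check and is reproducible per seed.
#'
#' @param kind one of `"toy_binding"`, `"toy_covalent_cycle"`,
#'   `"toy_relaxation"`, `"random_weakly_reversible"`.
#' @param params named list overriding fixture parameters (see source for
#'   defaults; totals nM, rates nM^-1 s^-1 / s^-1).
#' @param seed integer, required for the random fixture.
#' @return a `reaction_system`.
#' @export
#' @examples
#' make_fixture("toy_binding", list(Atot = 100, Btot = 100, kon = 0.01, koff = 1))
make_fixture <- function(kind, params = list(), seed = NULL) {
  p <- function(name, default) {
    v <- params[[name]] %||% default
    if (is.numeric(v) && v < 0) abort(paste0("fixture parameter '", name, "' must be >= 0"))
    v
  }
  switch(kind,
    toy_binding = {
      schemes <- build_scheme("binding", "A + B", "AB",
                              kon = p("kon", 0.01), koff = p("koff", 1), id = 1L)
      reaction_system(
        tibble(name = c("A", "B", "AB"),
               initial_total = c(p("Atot", 100), p("Btot", 100), 0)),
        schemes, inputs = "A",
        moieties = list(moiety("A", c("A", "AB")), moiety("B", c("B", "AB"))))
    },
    toy_covalent_cycle = {
      schemes <- bind_rows(
        build_scheme("enzymatic", "S + E1", "Sp + E1", mid = "SE1",
                     kon = p("kon1", 0.01), koff = p("koff1", 1),
                     kcat = p("kcat1", 0.5), id = 1L),
        build_scheme("enzymatic", "Sp + E2", "S + E2", mid = "SpE2",
                     kon = p("kon2", 0.01), koff = p("koff2", 1),
                     kcat = p("kcat2", 0.5), id = 2L))
      reaction_system(
        tibble(name = c("S", "E1", "E2", "Sp", "SE1", "SpE2"),
               initial_total = c(p("Stot", 1000), p("E1tot", 50), p("E2tot", 50), 0, 0, 0)),
        schemes, inputs = "E1",
        moieties = list(moiety("S", c("S", "Sp", "SE1", "SpE2")),
                        moiety("E1", c("E1", "SE1")),
                        moiety("E2", c("E2", "SpE2"))))
    },
    toy_relaxation = {
      schemes <- bind_rows(
        build_scheme("conversion", "A", "B", kcat = p("r1", 0.1), id = 1L),
        build_scheme("conversion", "B", "A", kcat = p("r2", 0.2), id = 2L))
      reaction_system(
        tibble(name = c("A", "B"), initial_total = c(p("Atot", 100), 0)),
        schemes, inputs = "A",
        moieties = list(moiety("total", c("A", "B"))))
    },
    random_weakly_reversible = {
      if (is.null(seed)) abort("random_weakly_reversible requires a seed")
      n <- as.integer(p("n_species", 6))
      withr_seed(seed, {
        sp <- paste0("X", seq_len(n))
        schemes <- list()
        # reversible conversion ring X1 -> X2 -> ... -> Xn -> X1, each edge
        # present in both directions so every species is produced and consumed
        for (i in seq_len(n)) {
          j <- if (i == n) 1L else i + 1L
          schemes[[length(schemes) + 1]] <-
            build_scheme("conversion", sp[i], sp[j],
                         kcat = stats::runif(1, 0.01, 1), id = length(schemes) + 1L)
          schemes[[length(schemes) + 1]] <-
            build_scheme("conversion", sp[j], sp[i],
                         kcat = stats::runif(1, 0.01, 1), id = length(schemes) + 1L)
        }
        npair <- as.integer(p("n_bindings", 2))
        for (b in seq_len(npair)) {
          ab <- sample(n, 2)
          schemes[[length(schemes) + 1]] <-
            build_scheme("binding", paste(sp[ab[1]], "+", sp[ab[2]]),
                         paste0("C", b),
                         kon = stats::runif(1, 1e-3, 0.1),
                         koff = stats::runif(1, 0.1, 10), id = length(schemes) + 1L)
        }
        totals <- stats::runif(n, 10, 1000)
        reaction_system(tibble(name = sp, initial_total = totals),
                        bind_rows(schemes), inputs = sp[1])
      })
    },
    abort(paste0("unknown fixture kind: '", kind, "'")))
}

# evaluate expr under a local RNG seed without touching the global stream
withr_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Closed-form steady-state complex concentration for isolated binding
#'
#' @param Atot,Btot total concentrations, nM.
#' @param kon,koff rate constants; `Kd = koff/kon`.
#' @return steady-state `[AB]` in nM (vectorized over `Atot`).
#' @export
binding_closed_form <- function(Atot, Btot, kon, koff) {
  Kd <- koff / kon
  s <- Atot + Btot + Kd
  (s - sqrt(s^2 - 4 * Atot * Btot)) / 2
}

#' Flux-balance oracle for the covalent modification cycle
#'
#' Independent root-finding solution of the toy kinase/phosphatase cycle at
#' steady state: for free substrate `u`, complex occupancies follow from
#' enzyme conservation, the forward/reverse fluxes are balanced, and total
#' substrate fixes `u` by bisection.
#'
#' @param Stot,E1tot,E2tot totals, nM.
#' @param kon1,koff1,kcat1,kon2,koff2,kcat2 rate constants.
#' @return named vector with steady-state `S`, `Sp`, `SE1`, `SpE2`.
#' @export
covalent_cycle_oracle <- function(Stot, E1tot, E2tot,
                                  kon1, koff1, kcat1, kon2, koff2, kcat2) {
  KM1 <- (koff1 + kcat1) / kon1
  KM2 <- (koff2 + kcat2) / kon2
  g <- function(u) {
    C1 <- E1tot * u / (u + KM1)
    C2 <- kcat1 * C1 / kcat2
    # phosphatase cannot carry the flux: overshoot (large finite value keeps
    # uniroot's bracketing happy)
    if (C2 >= E2tot) return(Stot * 1e6)
    v <- KM2 * C2 / (E2tot - C2)
    u + v + C1 + C2 - Stot
  }
  if (E1tot == 0 || kcat1 == 0) {
    return(c(S = Stot - 0, Sp = 0, SE1 = 0, SpE2 = 0))
  }
  u <- stats::uniroot(g, c(1e-12, Stot), tol = 1e-12)$root
  C1 <- E1tot * u / (u + KM1)
  C2 <- kcat1 * C1 / kcat2
  v <- KM2 * C2 / (E2tot - C2)
  c(S = u, Sp = v, SE1 = C1, SpE2 = C2)
}
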