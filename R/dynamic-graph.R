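# The weighted dynamic graph: a bipartite species/reaction graph annotated
# with steady-state concentration ranges (species nodes) and psf fit
# parameters (reaction nodes). Attribute schema is stable so that exports
# can be diffed: range_min_nM, range_max_nM, fit_model, Y, C, n, y0,
# slope, intercept (prefix fit2_ for the second label of a binding scheme).

#' Build the weighted dynamic graph
#'
#' Species nodes carry their concentration range over the sweep. Binding
#' reaction nodes carry two fit labels, left to right: complex formation
#' (the complex's systemic psf) and reactant depletion (the second
#' reactant's, typically negative-slope, psf). Enzymatic and conversion
#' nodes carry a single label for the product species.
#'
#' @param system a `reaction_system`.
#' @param sweep a `psf_sweep` covering the species of the system.
#' @param fits optional result of [fit_all_psfs()] on the sweep (computed if
#'   missing).
#' @return igraph object (undirected, bipartite via vertex attribute
#'   `type`: `"species"` / `"reaction"`), class attribute `dynamic_graph`.
#' @export
build_weighted_dynamic_graph <- function(system, sweep, fits = NULL) {
  if (is.null(fits)) fits <- fit_all_psfs(sweep)
  ranges <- sweep |>
    group_by(.data$target) |>
    summarise(range_min_nM = min(.data$value), range_max_nM = max(.data$value))
  sp <- system$species$name
  missing_curve <- setdiff(sp, ranges$target)
  if (length(missing_curve)) {
    warn(paste0("no psf curve for: ", paste(missing_curve, collapse = ", "),
                "; nodes labeled unknown"))
  }
  fit_row <- function(tg) {
    r <- fits[fits$target == tg, ]
    if (nrow(r) == 0) {
      tibble(model = "unknown", Y = NA_real_, C = NA_real_, n = NA_real_,
             y0 = NA_real_, slope = NA_real_, intercept = NA_real_)
    } else r[1, c("model", "Y", "C", "n", "y0", "slope", "intercept")]
  }
  # species vertices
  sv <- tibble(name = sp, type = "species",
               color = NA_character_,
               range_min_nM = ranges$range_min_nM[match(sp, ranges$target)],
               range_max_nM = ranges$range_max_nM[match(sp, ranges$target)])
  # reaction vertices with fit labels
  rv <- purrr::map_dfr(seq_len(nrow(system$schemes)), function(i) {
    r <- system$schemes[i, ]
    L <- parse_side(r$lhs); R <- parse_side(r$rhs)
    is_binding <- r$kind %in% c("binding", "irreversible_binding")
    lab1_target <- if (is_binding) R$species[1] else {
      prods <- setdiff(R$species, L$species)
      if (length(prods)) prods[1] else R$species[1]
    }
    f1 <- fit_row(lab1_target)
    out <- tibble(name = paste0("rxn", r$id), type = "reaction",
                  color = if (is_binding) "red" else "blue",
                  scheme_id = r$id, kind = r$kind,
                  fit_model = f1$model, Y = f1$Y, C = f1$C, n = f1$n,
                  y0 = f1$y0, slope = f1$slope, intercept = f1$intercept)
    if (is_binding && nrow(L) >= 2) {
      f2 <- fit_row(L$species[2])
      out$fit2_model <- f2$model; out$fit2_Y <- f2$Y; out$fit2_C <- f2$C
      out$fit2_n <- f2$n; out$fit2_y0 <- f2$y0; out$fit2_slope <- f2$slope
      out$fit2_intercept <- f2$intercept
    }
    out
  })
  verts <- bind_rows(sv, rv)
  # edges: species <-> reaction, with role
  edges <- purrr::map_dfr(seq_len(nrow(system$schemes)), function(i) {
    r <- system$schemes[i, ]
    rid <- paste0("rxn", r$id)
    L <- parse_side(r$lhs); M <- parse_side(r$mid); R <- parse_side(r$rhs)
    bind_rows(
      tibble(from = L$species, to = rid, role = "source"),
      if (nrow(M)) tibble(from = M$species, to = rid, role = "participant"),
      tibble(from = setdiff(R$species, L$species), to = rid, role = "target"))
  })
  edges <- edges[!duplicated(edges[, c("from", "to")]), ]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
  class(g) <- c("dynamic_graph", class(g))
  g
}

#' Export a dynamic graph
#'
#' @param graph an igraph object (e.g. from
#'   [build_weighted_dynamic_graph()]).
#' @param path output file path.
#' @param format `"graphml"` (canonical; import/export roundtrip preserves
#'   structure and attributes), `"dot"`, or `"json"` (node-link).
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = c("graphml", "dot", "json")) {
  format <- match.arg(format)
  g <- graph
  class(g) <- "igraph"
  if (format %in% c("graphml", "dot")) {
    # igraph's writers reject logical/NA-typed attrs inconsistently; keep it
    # simple by coercing vertex attributes to character for DOT
    if (format == "dot") {
      for (a in igraph::vertex_attr_names(g)) {
        igraph::vertex_attr(g, a) <- as.character(igraph::vertex_attr(g, a))
      }
      for (a in igraph::edge_attr_names(g)) {
        igraph::edge_attr(g, a) <- as.character(igraph::edge_attr(g, a))
      }
    }
    igraph::write_graph(g, path, format = format)
  } else {
    nodes <- as_tibble(igraph::as_data_frame(g, what = "vertices"))
    links <- as_tibble(igraph::as_data_frame(g, what = "edges"))
    jsonlite::write_json(list(nodes = nodes, links = links), path,
                         dataframe = "rows", na = "null", auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a GraphML export back
#'
#' @param path GraphML file.
#' @return igraph object.
#' @export
import_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}
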