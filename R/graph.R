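#' Build the carbon-exchange metabolite graph
#'
#' Nodes are metabolites; a directed arc `i -> j` exists iff at least one
#' reaction exchanges carbon effectively from input `i` to output `j`
#' (i.e. the carbon table holds at least one `(i, j, r)` triple).  Each arc
#' carries its set of supporting reactions, which the path model uses to force
#' at least one supporting reaction active per traversed arc.  Self-pairs are
#' dropped (a simple path never revisits a node).  All network metabolites are
#' kept as nodes even when isolated, so any metabolite can be queried.
#'
#' @param network a `metabolic_network`.
#' @param carbon a `carbon_exchange_table` (validated against `network`).
#' @return an object of class `metabolite_graph`: a tibble with columns
#'   `from`, `to` and list-column `reactions`, plus attribute `nodes`.
#' @examples
#' bundle <- toy_network()
#' g <- build_metabolite_graph(bundle$network, bundle$carbon)
#' g
#' @export
build_metabolite_graph <- function(network, carbon) {
  validate_carbon_table(carbon, network)
  arcs <- carbon |>
    as_tibble() |>
    dplyr::filter(.data$input != .data$output) |>
    dplyr::group_by(from = .data$input, to = .data$output) |>
    dplyr::summarise(reactions = list(sort(unique(.data$reaction))),
                     .groups = "drop") |>
    dplyr::arrange(.data$from, .data$to)
  structure(arcs,
            class = c("metabolite_graph", class(tibble())),
            nodes = network$metabolites$id)
}

#' @export
print.metabolite_graph <- function(x, ...) {
  cat("<metabolite_graph: ", length(graph_nodes(x)), " nodes, ",
      nrow(x), " arcs>\n", sep = "")
  NextMethod()
}

#' Node set of a metabolite graph
#' @param graph a `metabolite_graph`.
#' @export
graph_nodes <- function(graph) {
  attr(graph, "nodes") %||% sort(unique(c(graph$from, graph$to)))
}

#' Convert a metabolite graph to an igraph object
#' @param graph a `metabolite_graph`.
#' @return a directed `igraph` graph with all nodes (including isolated ones).
#' @export
as_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    tibble(from = graph$from, to = graph$to),
    directed = TRUE,
    vertices = tibble(name = graph_nodes(graph))
  )
}

#' Enumerate all simple directed paths between two metabolites
#'
#' Pure graph-level search (no stoichiometry); used by the brute-force oracle
#' and by comparisons between graph-theoretic and flux-level reachability.
#'
#' @param graph a `metabolite_graph`.
#' @param source,target metabolite ids.
#' @param cutoff maximum number of arcs per path (`Inf` for no limit).
#' @return list of character vectors (node sequences), sorted by length.
#' @export
all_simple_paths <- function(graph, source, target, cutoff = Inf) {
  g <- as_igraph(graph)
  if (!source %in% graph_nodes(graph)) abort(paste0("unknown node: ", source))
  if (!target %in% graph_nodes(graph)) abort(paste0("unknown node: ", target))
  ps <- igraph::all_simple_paths(g, from = source, to = target, mode = "out",
                                 cutoff = if (is.finite(cutoff)) cutoff else -1)
  ps <- purrr::map(ps, ~ igraph::as_ids(.x))
  ps[order(lengths(ps))]
}

# arcs of a node sequence as a tibble(from, to)
path_arcs <- function(nodes) {
  if (length(nodes) < 2) return(tibble(from = character(), to = character()))
  tibble(from = nodes[-length(nodes)], to = nodes[-1])
}

# supporting reactions for one arc; character(0) if the arc is absent
arc_support <- function(graph, from, to) {
  hit <- which(graph$from == from & graph$to == to)
  if (length(hit) == 0) return(character())
  graph$reactions[[hit]]
}
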