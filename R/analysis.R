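#' Reference metabolic pathway
#'
#' A canonical route (e.g. a textbook pathway) used to score computed carbon
#' flux paths.
#'
#' @param id pathway identifier.
#' @param arcs ordered arcs: a two-column data frame (`from`, `to`) or a list
#'   of length-2 character vectors.  Must form a simple directed path.
#' @return a `reference_pathway` object.
#' @export
reference_pathway <- function(id, arcs) {
  if (is.list(arcs) && !is.data.frame(arcs)) {
    arcs <- tibble(from = purrr::map_chr(arcs, 1),
                   to = purrr::map_chr(arcs, 2))
  }
  arcs <- as_tibble(arcs)[, c("from", "to")]
  if (nrow(arcs) == 0) abort("reference pathway has no arcs")
  nodes <- c(arcs$from[1], arcs$to)
  if (!identical(arcs$from, nodes[-length(nodes)]) || anyDuplicated(nodes)) {
    abort(paste0("reference pathway ", id,
                 " arcs do not form a simple directed path"))
  }
  structure(list(id = id, arcs = arcs, nodes = nodes),
            class = "reference_pathway")
}

#' @export
print.reference_pathway <- function(x, ...) {
  cat("<reference_pathway ", x$id, ": ",
      paste(x$nodes, collapse = " -> "), ">\n", sep = "")
  invisible(x)
}

arc_key <- function(arcs) paste(arcs$from, arcs$to, sep = "\r")

#' Recovery of a reference pathway among computed paths
#'
#' Recovery is binary: 1 if some computed path's arc list equals the
#' reference's arc list exactly ("fully matches"), 0 otherwise; `rank` is the
#' position of the first match.  The per-pathway accuracy (best fractional
#' arc overlap over the result set) is reported alongside.
#'
#' @param result a `cfp_result_set`.
#' @param reference a `reference_pathway`.
#' @return a one-row tibble: `pathway_id`, `recovered` (0/1), `rank`
#'   (`NA` if unrecovered), `accuracy`.
#' @export
recovery_rate <- function(result, reference) {
  ref_key <- sort(arc_key(reference$arcs))
  hits <- purrr::map_lgl(result$paths, function(p) {
    identical(sort(arc_key(p$arcs)), ref_key)
  })
  acc <- if (length(result$paths)) {
    max(purrr::map_dbl(result$paths, accuracy_rate, reference = reference))
  } else 0
  tibble(
    pathway_id = reference$id,
    recovered = as.integer(any(hits)),
    rank = if (any(hits)) which(hits)[1] else NA_integer_,
    accuracy = acc
  )
}

#' Recovery under stoichiometric feasibility of the reference
#'
#' When a growth medium renders a known pathway unable to operate in steady
#' state, the correct behaviour is to exclude it; recovery is therefore
#' redefined as: 1 if a feasible reference is matched by some computed path,
#' or an infeasible reference is absent from all of them; 0 otherwise.
#'
#' @inheritParams recovery_rate
#' @param feasible is the reference pathway steady-state supportable in the
#'   medium under study?  Decide with [path_supportable()] on the reference
#'   itself.
#' @return 0 or 1.
#' @export
stoichiometric_recovery_rate <- function(result, reference, feasible) {
  matched <- recovery_rate(result, reference)$recovered == 1
  as.integer((feasible && matched) || (!feasible && !matched))
}

#' Fractional arc overlap between a path and a reference pathway
#'
#' @param path a `flux_path` (or anything with an `arcs` tibble).
#' @param reference a `reference_pathway`.
#' @return `|arcs(path) intersect arcs(reference)| / |arcs(reference)|`.
#' @export
accuracy_rate <- function(path, reference) {
  if (nrow(reference$arcs) == 0) abort("reference pathway has no arcs")
  length(intersect(unique(arc_key(path$arcs)),
                   unique(arc_key(reference$arcs)))) / nrow(reference$arcs)
}

#' Is a fixed path steady-state supportable?
#'
#' Decides whether one given simple path (e.g. a reference pathway) can be
#' carried by a steady-state flux distribution under a medium, using the
#' oracle's per-path machinery (support-choice LPs with an exact MILP
#' fallback).
#'
#' @param nodes ordered metabolite ids of the path.
#' @inheritParams build_cfp_program
#' @param use_reversibility keep the reverse-pair exclusion.
#' @return `TRUE`/`FALSE`.
#' @export
path_supportable <- function(nodes, graph, network, med,
                             config = solver_config(),
                             use_reversibility = TRUE) {
  arcs <- path_arcs(nodes)
  missing <- purrr::map2_lgl(arcs$from, arcs$to,
                             ~ length(arc_support(graph, .x, .y)) == 0)
  if (any(missing)) return(FALSE)
  query <- cfp_query(nodes[1], nodes[length(nodes)],
                     use_reversibility = use_reversibility)
  rp <- reverse_pairs(network)
  partner <- setNames(c(rp$rev, rp$fwd), c(rp$fwd, rp$rev))
  supports <- purrr::map2(arcs$from, arcs$to, ~ arc_support(graph, .x, .y))
  combos <- support_choices(supports, partner, use_reversibility, 64)
  if (is.null(combos)) {
    return(oracle_milp_fallback(nodes, arcs, graph, network, med, query,
                                config)$supportable)
  }
  if (length(combos) == 0) return(FALSE)
  models <- purrr::map(combos, oracle_lp, network = network, med = med,
                       query = query, config = config, partner = partner)
  res <- milp_solve_batch(models, time_limit = config$time_limit_seconds)
  any_lp <- FALSE
  for (i in seq_along(res)) {
    if (!identical(res[[i]]$status, "optimal")) next
    any_lp <- TRUE
    cert <- oracle_certificate(res[[i]]$values, combos[[i]], network, query,
                               config, partner)
    if (!is.null(cert)) return(TRUE)
  }
  if (any_lp) {
    return(oracle_milp_fallback(nodes, arcs, graph, network, med, query,
                                config)$supportable)
  }
  FALSE
}

#' Connectivity curve of a source metabolite
#'
#' Solves a shortest-path query from `source` to every other graph node (all
#' queries are independent and solved in one backend batch) and accumulates
#' the shortest lengths: the curve value at `n` steps is the number of
#' metabolites whose shortest carbon flux path from the source has at most
#' `n` arcs.  Metabolites with no path are unreachable and excluded from
#' `total_reachable`; a per-target time-limit hit is warned about and
#' excluded from the curve entirely (it is unknown, not unreachable).
#'
#' Adding the stoichiometric constraints can only remove paths, so the curve
#' with stoichiometry lies pointwise at or below the one without.
#'
#' @param source source metabolite id.
#' @inheritParams build_cfp_program
#' @param use_stoichiometry include steady-state constraints?
#' @return a tibble of class `connectivity_curve` with columns `steps`,
#'   `n_connected`, and attributes `source`, `total_reachable`,
#'   `use_stoichiometry`.
#' @export
connectivity_curve <- function(source, graph, network, med,
                               use_stoichiometry = TRUE,
                               config = solver_config()) {
  targets <- setdiff(graph_nodes(graph), source)
  progs <- purrr::map(targets, function(t) {
    build_cfp_program(graph, network, med,
                      cfp_query(source, t,
                                use_stoichiometry = use_stoichiometry),
                      config)
  })
  res <- milp_solve_batch(purrr::map(progs, ~ .x$model),
                          time_limit = config$time_limit_seconds)
  lens <- purrr::map2_dbl(res, seq_along(targets), function(r, i) {
    if (identical(r$status, "optimal")) {
      q <- cfp_query(source, targets[i], use_stoichiometry = use_stoichiometry)
      extract_flux_path(r$values, graph, q, config)$length
    } else if (identical(r$status, "infeasible")) {
      NA_real_
    } else {
      warn(paste0("target ", targets[i], " not decided (status ", r$status,
                  "); excluded from the curve"))
      -1
    }
  })
  lens <- lens[is.na(lens) | lens > 0]
  reach <- lens[!is.na(lens)]
  max_step <- if (length(reach)) max(reach) else 0
  steps <- seq_len(max_step)
  curve <- tibble(
    steps = as.integer(steps),
    n_connected = purrr::map_int(steps, ~ sum(reach <= .x))
  )
  structure(curve,
            class = c("connectivity_curve", class(tibble())),
            source = source,
            total_reachable = length(reach),
            use_stoichiometry = use_stoichiometry)
}

#' @export
print.connectivity_curve <- function(x, ...) {
  cat("<connectivity_curve from ", attr(x, "source"), ": ",
      attr(x, "total_reachable"), " reachable metabolites, stoichiometry ",
      if (attr(x, "use_stoichiometry")) "on" else "off", ">\n", sep = "")
  NextMethod()
}

#' Arc and metabolite frequencies over a result set
#'
#' Counts how often each arc and each metabolite appears among the returned
#' paths (the quantity usually displayed as arc thickness / node size when K
#' shortest paths are drawn as one graph).
#'
#' @param result a `cfp_result_set`.
#' @return a `cfp_frequency` object: list of tibbles `arcs`
#'   (`from`, `to`, `count`) and `metabolites` (`metabolite`, `count`).
#' @export
frequency_table <- function(result) {
  arcs <- purrr::map(result$paths, ~ .x$arcs) |> dplyr::bind_rows()
  mets <- purrr::map(result$paths, ~ tibble(metabolite = .x$node_sequence)) |>
    dplyr::bind_rows()
  arc_counts <- if (nrow(arcs)) {
    arcs |> dplyr::count(.data$from, .data$to, name = "count") |>
      arrange(dplyr::desc(.data$count))
  } else tibble(from = character(), to = character(), count = integer())
  met_counts <- if (nrow(mets)) {
    mets |> dplyr::count(.data$metabolite, name = "count") |>
      arrange(dplyr::desc(.data$count))
  } else tibble(metabolite = character(), count = integer())
  structure(list(arcs = arc_counts, metabolites = met_counts,
                 n_paths = length(result$paths)),
            class = "cfp_frequency")
}

#' @export
print.cfp_frequency <- function(x, ...) {
  cat("<cfp_frequency over ", x$n_paths, " paths: ", nrow(x$arcs),
      " arcs, ", nrow(x$metabolites), " metabolites>\n", sep = "")
  invisible(x)
}

#' Baseline graph-adjustment strategies
#'
#' Classical path-finding baselines expressed as transformations of the
#' metabolite graph and a node-weight map:
#' * `"topology"` - the unadjusted graph, unit weights (plain shortest
#'   paths);
#' * `"hubs"` - every arc touching a listed highly connected metabolite is
#'   removed, unit weights;
#' * `"connectivity_weighted"` - the graph is unchanged but each metabolite
#'   is weighted by its connectivity (the number of reactions it
#'   participates in), and K-shortest becomes K-lightest: the path objective
#'   sums the weights of entered nodes.
#'
#' @param graph a `metabolite_graph`.
#' @param network the `metabolic_network` (for connectivity counts and hub
#'   validation).
#' @param strategy one of `"topology"`, `"hubs"`, `"connectivity_weighted"`.
#' @param hubs character vector of hub metabolite ids (required for
#'   `"hubs"`); ids absent from the network are skipped with a warning.
#' @return list with the adjusted `graph` and `node_weights` (named numeric
#'   over graph nodes).
#' @export
apply_strategy <- function(graph, network,
                           strategy = c("topology", "hubs",
                                        "connectivity_weighted"),
                           hubs = NULL) {
  strategy <- match.arg(strategy)
  nodes <- graph_nodes(graph)
  unit <- setNames(rep(1, length(nodes)), nodes)
  if (strategy == "topology") {
    return(list(graph = graph, node_weights = unit))
  }
  if (strategy == "hubs") {
    if (is.null(hubs)) abort("hubs strategy requires a hub list")
    unknown <- setdiff(hubs, network$metabolites$id)
    if (length(unknown)) {
      warn(paste0("hub id not in network, skipped: ",
                  paste(unknown, collapse = ", ")))
      hubs <- setdiff(hubs, unknown)
    }
    keep <- !(graph$from %in% hubs | graph$to %in% hubs)
    pruned <- structure(graph[keep, ],
                        class = class(graph), nodes = nodes)
    return(list(graph = pruned, node_weights = unit))
  }
  counts <- network$stoichiometry |>
    distinct(.data$reaction, .data$metabolite) |>
    dplyr::count(.data$metabolite, name = "n_reactions")
  w <- setNames(rep(0, length(nodes)), nodes)
  w[counts$metabolite] <- counts$n_reactions
  list(graph = graph, node_weights = w)
}

#' Find the K shortest carbon flux paths (high-level wrapper)
#'
#' Builds the carbon-exchange metabolite graph, applies an optional baseline
#' strategy and runs the enumeration.
#'
#' @param network a (split) `metabolic_network`.
#' @param carbon a `carbon_exchange_table`.
#' @param med growth medium.
#' @param source,target metabolite ids.
#' @param k number of paths.
#' @param use_stoichiometry,use_reversibility see [cfp_query()].
#' @param strategy,hubs see [apply_strategy()].
#' @param config a [solver_config()].
#' @return a `cfp_result_set`.
#' @examples
#' \donttest{
#' b <- toy_network()
#' find_carbon_flux_paths(b$network, b$carbon, b$medium, "A", "F", k = 5)
#' }
#' @export
find_carbon_flux_paths <- function(network, carbon, med, source, target,
                                   k = 1, use_stoichiometry = TRUE,
                                   use_reversibility = TRUE,
                                   strategy = "topology", hubs = NULL,
                                   config = solver_config()) {
  graph <- build_metabolite_graph(network, carbon)
  adj <- apply_strategy(graph, network, strategy, hubs = hubs)
  objective <- if (strategy == "connectivity_weighted") {
    "connectivity_weighted"
  } else "unit"
  query <- cfp_query(source, target, k = k,
                     use_stoichiometry = use_stoichiometry,
                     use_reversibility = use_reversibility,
                     objective = objective)
  enumerate_k_shortest(adj$graph, network, med, query, config,
                       node_weights = adj$node_weights)
}
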