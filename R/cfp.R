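#' Define a carbon-flux-path query
#'
#' @param source,target metabolite ids (must differ).
#' @param k number of paths requested (enumeration stops earlier when the
#'   solution space is exhausted).
#' @param use_stoichiometry include the steady-state flux constraints
#'   (internal metabolite balancing and medium-restricted external
#'   production)?  When `FALSE` only those two constraint families are
#'   dropped; reaction activity coupling, reverse-pair exclusion and
#'   arc-support linking are always kept.
#' @param use_reversibility keep the constraint forbidding a reaction and its
#'   reverse from being simultaneously active?  Dropping it is only useful to
#'   demonstrate the cycle pathology it prevents.
#' @param objective `"unit"` (path length, i.e. arc count) or
#'   `"connectivity_weighted"` (sum of entered-node weights; see
#'   [apply_strategy()]).
#' @return a `cfp_query` object.
#' @export
cfp_query <- function(source, target, k = 1,
                      use_stoichiometry = TRUE,
                      use_reversibility = TRUE,
                      objective = c("unit", "connectivity_weighted")) {
  objective <- match.arg(objective)
  if (identical(source, target)) {
    abort("source and target metabolites must differ")
  }
  k <- as.integer(k)
  if (is.na(k) || k < 1) abort("k must be a positive integer")
  structure(
    list(source = source, target = target, k = k,
         use_stoichiometry = isTRUE(use_stoichiometry),
         use_reversibility = isTRUE(use_reversibility),
         objective = objective),
    class = "cfp_query"
  )
}

#' Solver configuration
#'
#' @param big_M upper bound on any reaction flux; with the minimum non-zero
#'   flux scaled to 1, any steady-state distribution needing a flux ratio
#'   above `big_M`:1 is infeasible, so raise it for badly scaled networks.
#' @param min_flux minimum non-zero flux (the formulation scales fluxes so
#'   this is 1).
#' @param int_tolerance threshold for reading binary variables from solver
#'   output.
#' @param flux_tolerance numerical tolerance used by the solution verifier;
#'   sits above the backend's feasibility tolerance.
#' @param time_limit_seconds optional per-solve wall-clock limit.  A limit hit
#'   is reported as status `"limit"`, never as "no path".
#' @param solver_name backend label (informational; the bundled backend is
#'   HiGHS).
#' @param random_seed accepted for interface compatibility; the bundled
#'   backend is deterministic and takes no seed.
#' @param z_penalty secondary objective weight on the number of active
#'   reactions, making the supporting flux distribution parsimonious.  The
#'   default `min(1e-4, 0.25/R)` can never trade against one arc of path
#'   length.  Set to 0 to disable.
#' @return a `solver_config` object.
#' @export
solver_config <- function(big_M = 1000, min_flux = 1,
                          int_tolerance = 1e-6, flux_tolerance = 1e-6,
                          time_limit_seconds = NULL, solver_name = "highs",
                          random_seed = NULL, z_penalty = NULL) {
  if (!(big_M > min_flux && min_flux >= flux_tolerance)) {
    abort("need big_M > min_flux >= flux_tolerance")
  }
  structure(
    list(big_M = big_M, min_flux = min_flux,
         int_tolerance = int_tolerance, flux_tolerance = flux_tolerance,
         time_limit_seconds = time_limit_seconds, solver_name = solver_name,
         random_seed = random_seed, z_penalty = z_penalty),
    class = "solver_config"
  )
}

u_var <- function(from, to) paste0("u|", from, "|", to)
z_var <- function(r) paste0("z|", r)
v_var <- function(r) paste0("v|", r)

#' Build the carbon-flux-path mixed-integer linear program
#'
#' Variables: one binary `u_ij` per graph arc (arc used by the path), one
#' binary `z_r` (reaction active) and one continuous `v_r in [0, big_M]`
#' (flux) per reaction.  Constraints:
#' * source/target degree: one arc leaves the source and one enters the
#'   target; no arc enters the source or leaves the target;
#' * flow conservation at every other node, and in-degree at most 1
#'   everywhere (no node revisited);
#' * with stoichiometry: internal metabolites balance exactly; external
#'   metabolites outside the medium may only be net produced (those in the
#'   medium are unconstrained);
#' * activity coupling `z_r <= v_r <= big_M * z_r` (active reactions carry
#'   flux between 1 and big_M, inactive ones none);
#' * reverse-pair exclusion `z_lambda + z_mu <= 1`;
#' * arc support `u_ij <= sum of z_r` over reactions exchanging carbon from
#'   `i` to `j`, linking the path to the flux plane;
#' * one integer cut per previously found path, `sum of its u <= length - 1`,
#'   which also excludes strict supersets.
#'
#' The objective minimises total arc weight (unit weights give path length)
#' plus `z_penalty` times the number of active reactions.
#'
#' @param graph a `metabolite_graph`.
#' @param network the (split) `metabolic_network` behind it.
#' @param med growth medium: character vector of consumable external
#'   metabolites.
#' @param query a `cfp_query`.
#' @param config a `solver_config`.
#' @param node_weights optional named numeric weights per metabolite
#'   (required when `query$objective == "connectivity_weighted"`).
#' @param cuts list of previously found paths, each a character matrix /
#'   tibble of arcs (`from`, `to`) to exclude.
#' @return a list with the `milp_model` and the arc table (`program` class).
#' @export
build_cfp_program <- function(graph, network, med, query,
                              config = solver_config(),
                              node_weights = NULL, cuts = list()) {
  nodes <- graph_nodes(graph)
  if (!query$source %in% nodes) {
    abort(paste0("unreachable endpoint: ", query$source,
                 " is not a node of the metabolite graph"))
  }
  if (!query$target %in% nodes) {
    abort(paste0("unreachable endpoint: ", query$target,
                 " is not a node of the metabolite graph"))
  }
  med <- as.character(med)
  bad <- setdiff(med, external_metabolites(network))
  if (length(bad)) {
    abort(paste0("medium metabolite is not external: ", bad[1]))
  }

  rxns <- network$reactions$id
  eps <- config$z_penalty %||% min(1e-4, 0.25 / max(1L, length(rxns)))

  if (query$objective == "connectivity_weighted") {
    if (is.null(node_weights)) {
      abort("connectivity_weighted objective needs node_weights")
    }
    w <- node_weights[graph$to]
    if (anyNA(w)) abort("node_weights missing for some graph nodes")
  } else {
    w <- rep(1, nrow(graph))
  }

  mp <- milp_new(paste0("cfp:", query$source, "->", query$target))
  u <- u_var(graph$from, graph$to)
  milp_add_variables(mp, u, obj = w, type = "binary")
  milp_add_variables(mp, z_var(rxns), obj = eps, type = "binary")
  milp_add_variables(mp, v_var(rxns), obj = 0, lb = 0, ub = config$big_M)

  arcs_from <- split(seq_len(nrow(graph)), graph$from)
  arcs_to <- split(seq_len(nrow(graph)), graph$to)
  out_arcs <- function(n) u[arcs_from[[n]] %||% integer()]
  in_arcs <- function(n) u[arcs_to[[n]] %||% integer()]

  # source/target degree
  milp_add_constraint(mp, out_arcs(query$source),
                      rep(1, length(out_arcs(query$source))), "==", 1)
  milp_add_constraint(mp, in_arcs(query$target),
                      rep(1, length(in_arcs(query$target))), "==", 1)
  milp_add_constraint(mp, in_arcs(query$source),
                      rep(1, length(in_arcs(query$source))), "==", 0)
  milp_add_constraint(mp, out_arcs(query$target),
                      rep(1, length(out_arcs(query$target))), "==", 0)

  for (n in setdiff(nodes, c(query$source, query$target))) {
    io <- c(in_arcs(n), out_arcs(n))
    if (length(io)) {
      milp_add_constraint(mp, io,
                          c(rep(1, length(in_arcs(n))),
                            rep(-1, length(out_arcs(n)))), "==", 0)
    }
  }
  for (n in nodes) {
    ia <- in_arcs(n)
    if (length(ia) > 1) {
      milp_add_constraint(mp, ia, rep(1, length(ia)), "<=", 1)
    }
  }

  if (query$use_stoichiometry) {
    st <- split(network$stoichiometry, network$stoichiometry$metabolite)
    for (c_int in internal_metabolites(network)) {
      s <- st[[c_int]]
      if (!is.null(s)) {
        milp_add_constraint(mp, v_var(s$reaction), s$coef, "==", 0)
      }
    }
    for (c_ext in setdiff(external_metabolites(network), med)) {
      s <- st[[c_ext]]
      if (!is.null(s)) {
        milp_add_constraint(mp, v_var(s$reaction), s$coef, ">=", 0)
      }
    }
  }

  for (r in rxns) {
    milp_add_constraint(mp, c(z_var(r), v_var(r)),
                        c(config$min_flux, -1), "<=", 0)
    milp_add_constraint(mp, c(v_var(r), z_var(r)),
                        c(1, -config$big_M), "<=", 0)
  }

  if (query$use_reversibility) {
    rp <- reverse_pairs(network)
    for (k in seq_len(nrow(rp))) {
      milp_add_constraint(mp, z_var(c(rp$fwd[k], rp$rev[k])), c(1, 1), "<=", 1)
    }
  }

  for (a in seq_len(nrow(graph))) {
    support <- graph$reactions[[a]]
    milp_add_constraint(mp, c(u[a], z_var(support)),
                        c(1, rep(-1, length(support))), "<=", 0)
  }

  for (cut in cuts) {
    cut <- as_tibble(cut)
    uc <- u_var(cut$from, cut$to)
    milp_add_constraint(mp, uc, rep(1, length(uc)), "<=", length(uc) - 1)
  }

  structure(list(model = mp, graph = graph, query = query, config = config),
            class = "cfp_program")
}

# turn an optimal MILP solution into a flux_path
extract_flux_path <- function(values, graph, query, config) {
  tol <- config$int_tolerance
  u <- u_var(graph$from, graph$to)
  used <- values[u] > 0.5
  arcs <- tibble(from = graph$from[used], to = graph$to[used])
  nodes <- query$source
  while (tail(nodes, 1) != query$target) {
    hit <- match(tail(nodes, 1), arcs$from)
    if (is.na(hit) || arcs$to[hit] %in% nodes) {
      abort("solver returned a malformed path (internal error)")
    }
    nodes <- c(nodes, arcs$to[hit])
  }
  rxns <- sub("^z\\|", "", grep("^z\\|", names(values), value = TRUE))
  zv <- values[z_var(rxns)]
  vv <- values[v_var(rxns)]
  active <- rxns[zv > 0.5]
  fluxes <- setNames(ifelse(abs(vv) < tol, 0, vv), rxns)
  new_flux_path(nodes, arcs = arcs, active_reactions = active,
                fluxes = fluxes)
}

#' Construct a flux path object
#'
#' Usually produced by the solver; exposed so reference paths and synthetic
#' result sets can be built directly.
#'
#' @param node_sequence ordered metabolite ids, source first.
#' @param arcs arc tibble (`from`, `to`); defaults to the consecutive pairs of
#'   `node_sequence`.
#' @param active_reactions character vector of active reaction ids.
#' @param fluxes named numeric vector of reaction fluxes.
#' @return a `flux_path` object.
#' @export
new_flux_path <- function(node_sequence, arcs = NULL,
                          active_reactions = character(),
                          fluxes = numeric()) {
  if (is.null(arcs)) arcs <- path_arcs(node_sequence)
  structure(
    list(node_sequence = node_sequence, arcs = as_tibble(arcs),
         active_reactions = active_reactions, fluxes = fluxes,
         length = length(node_sequence) - 1L),
    class = "flux_path"
  )
}

#' @export
print.flux_path <- function(x, ...) {
  cat("<flux_path: ", paste(x$node_sequence, collapse = " -> "),
      " (", x$length, " arcs, ", length(x$active_reactions),
      " active reactions)>\n", sep = "")
  invisible(x)
}

#' @export
format.flux_path <- function(x, ...) paste(x$node_sequence, collapse = "->")

solver_limit_error <- function(iteration = NULL) {
  msg <- "solver time limit exceeded; the query is unsolved (not infeasible)"
  if (!is.null(msg) && !is.null(iteration)) {
    msg <- paste0(msg, " at enumeration iteration ", iteration)
  }
  abort(msg, class = "cfp_solver_limit")
}

#' Solve for the shortest carbon flux path
#'
#' @inheritParams build_cfp_program
#' @return a `flux_path`, or `NULL` when no carbon flux path exists
#'   (program infeasible).  A backend time-limit hit raises a classed error
#'   (`cfp_solver_limit`) and is never reported as "no path".
#' @examples
#' \donttest{
#' b <- toy_network()
#' g <- build_metabolite_graph(b$network, b$carbon)
#' solve_shortest_cfp(g, b$network, b$medium, cfp_query("A", "F"))
#' }
#' @export
solve_shortest_cfp <- function(graph, network, med, query,
                               config = solver_config(),
                               node_weights = NULL, cuts = list()) {
  prog <- build_cfp_program(graph, network, med, query, config,
                            node_weights = node_weights, cuts = cuts)
  res <- milp_solve(prog$model, time_limit = config$time_limit_seconds)
  switch(res$status,
    optimal = extract_flux_path(res$values, graph, query, config),
    infeasible = NULL,
    limit = solver_limit_error(),
    abort(paste0("solver failed with status: ", res$status))
  )
}

#' Enumerate the K shortest carbon flux paths
#'
#' Solves repeatedly, adding after each solution an integer cut that forbids
#' the found arc set (and any superset), so path lengths are non-decreasing
#' across the enumeration.  Stops after `query$k` paths or at the first
#' infeasible iteration, whichever comes first.
#'
#' @inheritParams build_cfp_program
#' @return a `cfp_result_set`: query, list of `flux_path`s in ascending
#'   length, and `exhausted` (`TRUE` when fewer than `k` paths exist).
#' @examples
#' \donttest{
#' b <- toy_network()
#' g <- build_metabolite_graph(b$network, b$carbon)
#' enumerate_k_shortest(g, b$network, b$medium, cfp_query("A", "F", k = 5))
#' }
#' @export
enumerate_k_shortest <- function(graph, network, med, query,
                                 config = solver_config(),
                                 node_weights = NULL) {
  paths <- list()
  cuts <- list()
  exhausted <- FALSE
  for (k in seq_len(query$k)) {
    p <- withCallingHandlers(
      solve_shortest_cfp(graph, network, med, query, config,
                         node_weights = node_weights, cuts = cuts),
      cfp_solver_limit = function(e) solver_limit_error(iteration = k)
    )
    if (is.null(p)) {
      exhausted <- TRUE
      break
    }
    paths[[k]] <- p
    cuts[[k]] <- p$arcs
  }
  new_cfp_result_set(query = query, paths = paths, exhausted = exhausted,
                     config = config)
}

#' Construct a result set
#'
#' @param query a `cfp_query` (or `NULL` for synthetic sets).
#' @param paths list of `flux_path`s.
#' @param exhausted were fewer paths found than requested?
#' @param config the `solver_config` used.
#' @export
new_cfp_result_set <- function(query = NULL, paths = list(),
                               exhausted = FALSE, config = NULL) {
  structure(list(query = query, paths = paths, exhausted = exhausted,
                 config = config),
            class = "cfp_result_set")
}

#' @export
print.cfp_result_set <- function(x, ...) {
  cat("<cfp_result_set: ", length(x$paths), " path(s)",
      if (x$exhausted) ", exhausted" else "", ">\n", sep = "")
  for (p in x$paths) cat("  ", format(p), "\n", sep = "")
  invisible(x)
}

#' @export
length.cfp_result_set <- function(x) length(x$paths)

#' Independently verify a solved flux path
#'
#' Re-checks, combinatorially and numerically, every constraint family of the
#' formulation on a candidate solution: simple-path structure and degree
#' conditions; exact balancing of internal metabolites within
#' `flux_tolerance`; non-negative net production of external metabolites
#' outside the medium; activity coupling (active reactions carry flux in
#' `[min_flux, big_M]`, inactive ones none); reverse-pair exclusion; and arc
#' support (every path arc covered by at least one active supporting
#' reaction).  Also asserts that the arc set is exactly the path (no disjoint
#' cycle rides along).
#'
#' @param path a `flux_path`.
#' @inheritParams build_cfp_program
#' @param use_stoichiometry,use_reversibility which constraint families to
#'   check (match the query that produced the path).
#' @return a list with `pass` (logical), `first_violation` (constraint label
#'   or `NA`), `checks` (tibble: constraint, ok, detail), and
#'   `off_path_active` (active reactions supporting no path arc).
#' @export
verify_solution <- function(path, graph, network, med,
                            config = solver_config(),
                            use_stoichiometry = TRUE,
                            use_reversibility = TRUE) {
  tol <- config$flux_tolerance
  checks <- list()
  add <- function(label, ok, detail = "") {
    checks[[length(checks) + 1]] <<- tibble(constraint = label, ok = ok,
                                            detail = detail)
  }

  nodes <- path$node_sequence
  arcs <- path$arcs
  add("simple_path", !anyDuplicated(nodes) && length(nodes) >= 2,
      "no metabolite revisited")
  expected <- path_arcs(nodes)
  same_arcs <- nrow(arcs) == nrow(expected) &&
    all(paste(arcs$from, arcs$to) %in% paste(expected$from, expected$to))
  add("path_arcs", same_arcs && path$length == nrow(expected),
      "arc set is exactly the node sequence (no disjoint cycle)")
  in_graph <- purrr::map2_lgl(expected$from, expected$to,
                              ~ length(arc_support(graph, .x, .y)) > 0)
  add("arc_existence", all(in_graph),
      if (all(in_graph)) "" else
        paste0("missing arc ", expected$from[!in_graph][1], "->",
               expected$to[!in_graph][1]))

  fl <- path$fluxes
  if (use_stoichiometry) {
    st <- network$stoichiometry
    resid <- st |>
      mutate(flux = fl[.data$reaction]) |>
      mutate(flux = ifelse(is.na(.data$flux), 0, .data$flux)) |>
      group_by(.data$metabolite) |>
      summarise(net = sum(.data$coef * .data$flux), .groups = "drop")
    net <- setNames(resid$net, resid$metabolite)
    ints <- internal_metabolites(network)
    bal <- abs(net[ints]) <= tol | is.na(net[ints])
    add("internal_balance", all(bal, na.rm = TRUE),
        if (all(bal, na.rm = TRUE)) "" else
          paste0("metabolite ", ints[!bal][1], " unbalanced (",
                 signif(net[ints][!bal][1], 4), ")"))
    exts <- setdiff(external_metabolites(network), as.character(med))
    prod_ok <- net[exts] >= -tol | is.na(net[exts])
    add("external_production", all(prod_ok, na.rm = TRUE),
        if (all(prod_ok, na.rm = TRUE)) "" else
          paste0("non-medium external ", exts[!prod_ok][1], " net consumed"))
  }

  rxns <- network$reactions$id
  v <- setNames(rep(0, length(rxns)), rxns)
  v[names(fl)[names(fl) %in% rxns]] <- fl[names(fl) %in% rxns]
  active <- intersect(path$active_reactions, rxns)
  inactive <- setdiff(rxns, active)
  act_ok <- v[active] >= config$min_flux - tol & v[active] <= config$big_M + tol
  inact_ok <- v[inactive] <= tol
  add("flux_activity",
      all(act_ok) && all(inact_ok),
      if (all(act_ok)) {
        if (all(inact_ok))
          "" else paste0("inactive reaction ", inactive[!inact_ok][1],
                         " carries flux")
      } else paste0("active reaction ", active[!act_ok][1],
                    " outside [min_flux, big_M]"))

  if (use_reversibility) {
    rp <- reverse_pairs(network)
    both <- rp$fwd %in% active & rp$rev %in% active
    add("reverse_exclusion", !any(both),
        if (!any(both)) "" else
          paste0("reverse pair co-active: ", rp$fwd[both][1], " / ",
                 rp$rev[both][1]))
  }

  covered <- purrr::map2_lgl(expected$from, expected$to, function(f, t) {
    length(intersect(arc_support(graph, f, t), active)) > 0
  })
  add("arc_support", all(covered),
      if (all(covered)) "" else
        paste0("arc ", expected$from[!covered][1], "->",
               expected$to[!covered][1], " has no active supporting reaction"))

  checks <- dplyr::bind_rows(checks)
  supports_path <- purrr::map_lgl(active, function(r) {
    any(purrr::map2_lgl(expected$from, expected$to,
                        ~ r %in% arc_support(graph, .x, .y)))
  })
  list(
    pass = all(checks$ok),
    first_violation = if (all(checks$ok)) NA_character_ else
      checks$constraint[!checks$ok][1],
    checks = checks,
    off_path_active = active[!supports_path]
  )
}
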