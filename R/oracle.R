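#' Brute-force enumeration oracle for carbon flux paths
#'
#' Independent ground truth for the MILP enumeration on small instances: all
#' simple directed paths from source to target are enumerated by depth-first
#' search on the metabolite graph, and each is tested for steady-state
#' supportability separately.  The per-path test iterates over the (small)
#' set of choices of one supporting reaction per arc; for each choice a
#' linear feasibility problem is solved (fluxes non-negative, internal
#' metabolites balanced, non-medium externals producible only, chosen
#' reactions forced to carry at least the minimum flux, reverses of chosen
#' reactions shut off).  A feasible LP solution is then lifted to an integral
#' certificate (reverse-pair cancellation followed by scaling so every
#' non-zero flux lies in `[min_flux, big_M]`); in the rare case the lifting
#' fails, the decision falls back to a fixed-path MILP so the verdict is
#' exact.
#'
#' Exponential in the graph size; refuses graphs above `max_nodes`.
#'
#' @inheritParams build_cfp_program
#' @param max_nodes refuse graphs with more nodes than this (the oracle is a
#'   testing device).
#' @param max_choices above this many support-choice combinations per path,
#'   decide directly with the fixed-path MILP.
#' @return a `cfp_result_set` holding every supportable path, sorted by
#'   length (the query's `k` is ignored; `exhausted` is always `TRUE`).
#' @export
brute_force_oracle <- function(graph, network, med, query,
                               config = solver_config(),
                               max_nodes = 15, max_choices = 64) {
  if (length(graph_nodes(graph)) > max_nodes) {
    abort(paste0("oracle refuses graphs with more than ", max_nodes,
                 " nodes (got ", length(graph_nodes(graph)), ")"))
  }
  node_paths <- all_simple_paths(graph, query$source, query$target)
  rp <- reverse_pairs(network)
  partner <- setNames(c(rp$rev, rp$fwd), c(rp$fwd, rp$rev))

  cand <- purrr::map(node_paths, function(nodes) {
    arcs <- path_arcs(nodes)
    supports <- purrr::map2(arcs$from, arcs$to, ~ arc_support(graph, .x, .y))
    list(nodes = nodes, arcs = arcs,
         combos = support_choices(supports, partner,
                                  query$use_reversibility, max_choices))
  })

  if (!query$use_stoichiometry) {
    decide <- purrr::map(cand, function(p) {
      if (is.null(p$combos)) {
        return(oracle_milp_fallback(p$nodes, p$arcs, graph, network, med,
                                    query, config))
      }
      if (length(p$combos) == 0) return(list(supportable = FALSE))
      forced <- p$combos[[1]]
      fluxes <- setNames(rep(0, nrow(network$reactions)),
                         network$reactions$id)
      fluxes[forced] <- config$min_flux
      list(supportable = TRUE,
           path = new_flux_path(p$nodes, arcs = p$arcs,
                                active_reactions = forced, fluxes = fluxes))
    })
  } else {
    # one backend call for every (path, support choice) LP
    jobs <- purrr::imap(cand, function(p, i) {
      purrr::map(p$combos %||% list(), function(forced) {
        list(path = i, forced = forced,
             model = oracle_lp(forced, network, med, query, config, partner))
      })
    })
    jobs <- unlist(jobs, recursive = FALSE) %||% list()
    res <- milp_solve_batch(purrr::map(jobs, "model"),
                            time_limit = config$time_limit_seconds)
    decide <- vector("list", length(cand))
    need_fallback <- logical(length(cand))
    lp_feasible <- logical(length(cand))
    for (i in seq_along(cand)) decide[[i]] <- list(supportable = FALSE)
    for (j in seq_along(jobs)) {
      i <- jobs[[j]]$path
      if (decide[[i]]$supportable || !identical(res[[j]]$status, "optimal")) next
      lp_feasible[i] <- TRUE
      cert <- oracle_certificate(res[[j]]$values, jobs[[j]]$forced, network,
                                 query, config, partner)
      if (!is.null(cert)) {
        decide[[i]] <- list(
          supportable = TRUE,
          path = new_flux_path(cand[[i]]$nodes, arcs = cand[[i]]$arcs,
                               active_reactions = cert$active,
                               fluxes = cert$fluxes))
      }
    }
    for (i in seq_along(cand)) {
      need_fallback[i] <- is.null(cand[[i]]$combos) ||
        (lp_feasible[i] && !decide[[i]]$supportable)
      if (need_fallback[i]) {
        decide[[i]] <- oracle_milp_fallback(cand[[i]]$nodes, cand[[i]]$arcs,
                                            graph, network, med, query, config)
      }
    }
  }

  keep <- purrr::map_lgl(decide, ~ .x$supportable)
  paths <- purrr::map(decide[keep], ~ .x$path)
  paths <- paths[order(purrr::map_int(paths, ~ .x$length))]
  new_cfp_result_set(query = query, paths = paths, exhausted = TRUE,
                     config = config)
}

# all combinations of one supporting reaction per arc, reverse-conflict-free
support_choices <- function(supports, partner, use_reversibility, cap) {
  n_comb <- prod(lengths(supports))
  if (n_comb > cap) return(NULL)
  combos <- expand.grid(supports, stringsAsFactors = FALSE)
  combos <- purrr::map(seq_len(nrow(combos)),
                       ~ unique(as.character(combos[.x, ])))
  if (use_reversibility) {
    combos <- purrr::keep(combos, function(ch) {
      !any(partner[ch] %in% ch, na.rm = TRUE)
    })
  }
  combos
}

# continuous feasibility problem for one support choice
oracle_lp <- function(forced, network, med, query, config, partner) {
  rxns <- network$reactions$id
  mp <- milp_new("oracle-lp")
  milp_add_variables(mp, v_var(rxns), obj = 1, lb = 0, ub = Inf)
  milp_set_bounds(mp, v_var(forced), lb = config$min_flux)
  if (query$use_reversibility) {
    shut <- stats::na.omit(partner[forced])
    if (length(shut)) milp_set_bounds(mp, v_var(shut), ub = 0)
  }
  st <- split(network$stoichiometry, network$stoichiometry$metabolite)
  for (c_int in internal_metabolites(network)) {
    s <- st[[c_int]]
    if (!is.null(s)) milp_add_constraint(mp, v_var(s$reaction), s$coef, "==", 0)
  }
  for (c_ext in setdiff(external_metabolites(network), as.character(med))) {
    s <- st[[c_ext]]
    if (!is.null(s)) milp_add_constraint(mp, v_var(s$reaction), s$coef, ">=", 0)
  }
  mp
}

# lift an LP solution to an integral activity certificate, or NULL
oracle_certificate <- function(values, forced, network, query, config,
                               partner) {
  rxns <- network$reactions$id
  v <- values[v_var(rxns)]
  names(v) <- rxns
  if (query$use_reversibility) {
    rp <- reverse_pairs(network)
    for (k in seq_len(nrow(rp))) {
      a <- rp$fwd[k]; b <- rp$rev[k]
      m <- min(v[a], v[b])
      if (m > 0) {
        v[a] <- v[a] - m
        v[b] <- v[b] - m
      }
    }
  }
  v[v < 1e-9] <- 0
  if (any(v[forced] < config$min_flux - 1e-9)) return(NULL)
  pos <- v > 0
  if (any(pos)) {
    m <- min(v[pos])
    if (m < config$min_flux) v <- v * (config$min_flux / m)
    if (max(v) > config$big_M + config$flux_tolerance) return(NULL)
  }
  list(active = rxns[v > 0], fluxes = v)
}

# exact decision through the full MILP with the path's arcs pinned
oracle_milp_fallback <- function(nodes, arcs, graph, network, med, query,
                                 config) {
  prog <- build_cfp_program(graph, network, med,
                            cfp_query(query$source, query$target, k = 1,
                                      use_stoichiometry = query$use_stoichiometry,
                                      use_reversibility = query$use_reversibility),
                            config)
  on_path <- paste(graph$from, graph$to) %in% paste(arcs$from, arcs$to)
  u <- u_var(graph$from, graph$to)
  milp_set_bounds(prog$model, u[on_path], lb = 1)
  milp_set_bounds(prog$model, u[!on_path], ub = 0)
  res <- milp_solve(prog$model, time_limit = config$time_limit_seconds)
  if (identical(res$status, "limit")) solver_limit_error()
  if (!identical(res$status, "optimal")) return(list(supportable = FALSE))
  p <- extract_flux_path(res$values, graph, query, config)
  list(supportable = TRUE, path = p)
}
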