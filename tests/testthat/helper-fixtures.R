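# Shared fixtures, memoised so expensive solves happen once per test run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

toy_fx <- function() cached("toy", toy_network())
toy_g <- function() {
  cached("toy_g", build_metabolite_graph(toy_fx()$network, toy_fx()$carbon))
}
toy_solution <- function() {
  cached("toy_sol", solve_shortest_cfp(toy_g(), toy_fx()$network,
                                       toy_fx()$medium, cfp_query("A", "F")))
}

glx_fx <- function(shunt = TRUE) {
  cached(paste0("glx_", shunt), glyoxylate_network(shunt))
}
glx_g <- function(shunt = TRUE) {
  cached(paste0("glx_g_", shunt), {
    b <- glx_fx(shunt)
    build_metabolite_graph(b$network, b$carbon)
  })
}

shortcut_fx <- function() cached("shortcut", acetylation_shortcut_network())
shortcut_g <- function() {
  cached("shortcut_g", {
    b <- shortcut_fx()
    build_metabolite_graph(b$network, b$carbon)
  })
}

# two-substrate/two-product phosphotransferase toy (glucose uptake system)
pts_network <- function() {
  metabolic_network(
    tibble::tibble(
      id = c("D-Glc", "PEP", "G6P", "Pyr"),
      is_internal = TRUE,
      formula = c("C6H12O6", "C3H5O6P", "C6H13O9P", "C3H4O3")
    ),
    tibble::tibble(
      id = "PTS",
      stoichiometry = list(c("D-Glc" = -1, PEP = -1, G6P = 1, Pyr = 1))
    )
  )
}

# the family of arc sets of a result set, sorted canonically (order within
# equal-length groups is solver-dependent and must not matter)
arc_family <- function(result) {
  sort(vapply(result$paths, function(p) {
    paste0(p$length, ":",
           paste(sort(paste(p$arcs$from, p$arcs$to, sep = ">")),
                 collapse = "|"))
  }, character(1)))
}
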