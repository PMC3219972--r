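# synthetic result sets are built directly from node sequences (no solver)
synthetic_set <- function(paths, exhausted = TRUE) {
  new_cfp_result_set(
    query = cfp_query(paths[[1]][1], paths[[1]][length(paths[[1]])],
                      k = length(paths)),
    paths = purrr::map(paths, new_flux_path),
    exhausted = exhausted)
}

test_that("recovery is exact arc-list equality, with rank of first match", {
  ref <- reference_pathway("lin", list(c("A", "B"), c("B", "C"),
                                       c("C", "D")))
  hit <- synthetic_set(list(c("A", "B", "C", "D")))
  r <- recovery_rate(hit, ref)
  expect_equal(r$recovered, 1)
  expect_equal(r$rank, 1)
  expect_equal(r$accuracy, 1)

  decoys <- purrr::map(1:100, ~ c("A", paste0("x", .x), "C", "D"))
  miss <- synthetic_set(decoys)
  r0 <- recovery_rate(miss, ref)
  expect_equal(r0$recovered, 0)
  expect_true(is.na(r0$rank))

  planted <- decoys
  planted[[37]] <- c("A", "B", "C", "D")
  r37 <- recovery_rate(synthetic_set(planted), ref)
  expect_equal(r37$recovered, 1)
  expect_equal(r37$rank, 37)
})

test_that("recovery is monotone in the number of enumerated paths", {
  ref <- reference_pathway("lin", list(c("A", "B"), c("B", "C")))
  paths <- c(purrr::map(1:9, ~ c("A", paste0("y", .x), "C")),
             list(c("A", "B", "C")))
  full <- synthetic_set(paths)
  expect_equal(recovery_rate(full, ref)$recovered, 1)
  for (k in c(9, 10)) {
    trimmed <- new_cfp_result_set(paths = full$paths[seq_len(k)])
    rec <- recovery_rate(trimmed, ref)$recovered
    if (k >= 10) expect_equal(rec, 1) else expect_equal(rec, 0)
  }
})

test_that("accuracy counts fractional arc overlap of the reference", {
  ref <- reference_pathway("r", list(c("A", "B"), c("B", "C"), c("C", "D"),
                                     c("D", "E")))
  expect_equal(accuracy_rate(new_flux_path(c("A", "B", "C", "D", "E")), ref), 1)
  expect_equal(accuracy_rate(new_flux_path(c("P", "Q", "R")), ref), 0)
  # shares A->B, B->C, C->D but then diverges: 3 of 4
  expect_equal(accuracy_rate(new_flux_path(c("A", "B", "C", "D", "Z")), ref),
               0.75)
  expect_error(reference_pathway("empty", tibble::tibble(from = character(),
                                                         to = character())),
               "no arcs")
})

test_that("stoichiometric recovery credits correct exclusion", {
  ref <- reference_pathway("tca", list(c("A", "B"), c("B", "C")))
  present <- synthetic_set(list(c("A", "B", "C")))
  absent <- synthetic_set(list(c("A", "Z", "C")))
  # infeasible reference: right answer is to exclude it
  expect_equal(stoichiometric_recovery_rate(absent, ref, feasible = FALSE), 1)
  expect_equal(stoichiometric_recovery_rate(present, ref, feasible = FALSE), 0)
  # feasible reference: right answer is to find it
  expect_equal(stoichiometric_recovery_rate(present, ref, feasible = TRUE), 1)
  expect_equal(stoichiometric_recovery_rate(absent, ref, feasible = TRUE), 0)
})

test_that("path_supportable reproduces the toy medium knock-out", {
  b <- toy_fx()
  nodes <- c("A", "B", "C", "E", "F")
  expect_true(path_supportable(nodes, toy_g(), b$network, b$medium))
  expect_false(path_supportable(nodes, toy_g(), b$network,
                                medium("A_ext", b$network)))
  expect_false(path_supportable(c("A", "Z", "F"), toy_g(), b$network,
                                b$medium))
})

test_that("frequency tables count appearances across paths", {
  paths <- c(purrr::map(1:7, ~ c("S", "H1", "H2", paste0("t", .x), "T")),
             purrr::map(8:10, ~ c("S", paste0("u", .x), "T")))
  ft <- frequency_table(synthetic_set(paths))
  shared <- ft$arcs[ft$arcs$from == "H1" & ft$arcs$to == "H2", ]
  expect_equal(shared$count, 7)
  expect_equal(ft$metabolites$count[ft$metabolites$metabolite == "S"], 10)
  expect_equal(ft$metabolites$count[ft$metabolites$metabolite == "T"], 10)
  expect_true(all(ft$arcs$count <= 10))

  empty <- frequency_table(new_cfp_result_set())
  expect_equal(nrow(empty$arcs), 0)
  expect_equal(nrow(empty$metabolites), 0)
})

test_that("baseline strategies adjust graph and weights as declared", {
  b <- toy_fx()
  g <- toy_g()
  topo <- apply_strategy(g, b$network, "topology")
  expect_equal(nrow(topo$graph), nrow(g))
  expect_true(all(topo$node_weights == 1))

  hub <- apply_strategy(g, b$network, "hubs", hubs = "E")
  expect_equal(nrow(hub$graph), 5)  # C->E, D->E, E->F removed
  expect_false(any(hub$graph$from == "E" | hub$graph$to == "E"))
  expect_warning(apply_strategy(g, b$network, "hubs", hubs = c("E", "zzz")),
                 "skipped: zzz")
  expect_error(apply_strategy(g, b$network, "hubs"), "requires a hub list")

  cw <- apply_strategy(g, b$network, "connectivity_weighted")
  # every internal toy metabolite takes part in exactly two reactions
  expect_equal(unname(cw$node_weights[c("A", "B", "C", "D", "E", "F")]),
               rep(2, 6))
  expect_equal(unname(cw$node_weights[c("A_ext", "D_ext", "F_ext")]),
               rep(1, 3))
})

test_that("hub removal reroutes the weighted search", {
  b <- shortcut_fx()
  # removing the acetyl carrier forces the long unweighted route
  res <- find_carbon_flux_paths(b$network, b$carbon, b$medium, "X", "T",
                                strategy = "hubs", hubs = "Ac")
  expect_equal(res$paths[[1]]$node_sequence, c("X", "Y1", "Y2", "Y3", "T"))
})

test_that("toy connectivity curve accumulates one metabolite per step", {
  b <- toy_fx()
  cv <- cached("toy_curve_on", connectivity_curve("A", toy_g(), b$network,
                                                  b$medium, TRUE))
  expect_equal(cv$steps, 1:5)
  expect_equal(cv$n_connected, 1:5)
  expect_equal(attr(cv, "total_reachable"), 5)  # B, C, E, F, F_ext
  cv0 <- cached("toy_curve_off", connectivity_curve("A", toy_g(), b$network,
                                                    b$medium, FALSE))
  expect_equal(cv0$n_connected, cv$n_connected)  # all toy A-paths supportable
})

test_that("stoichiometry-on curves never exceed stoichiometry-off curves", {
  fixtures <- list(
    list(b = shortcut_fx(), src = "X"),
    list(b = cached("rn5", random_network(5)), src = NULL)
  )
  for (fx in fixtures) {
    b <- fx$b
    src <- fx$src %||% b$source
    g <- build_metabolite_graph(b$network, b$carbon)
    on <- connectivity_curve(src, g, b$network, b$medium, TRUE)
    off <- connectivity_curve(src, g, b$network, b$medium, FALSE)
    expect_lte(attr(on, "total_reachable"), attr(off, "total_reachable"))
    steps <- seq_len(max(nrow(on), nrow(off)))
    at <- function(cv, s) {
      if (nrow(cv) == 0) return(0L)
      c(cv$n_connected, utils::tail(cv$n_connected, 1))[pmin(s, nrow(cv) + 1)]
    }
    expect_true(all(at(on, steps) <= at(off, steps)))
  }
})
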