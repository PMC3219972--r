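test_that("the toy program has the expected variables and constraints", {
  b <- toy_fx()
  prog <- build_cfp_program(toy_g(), b$network, b$medium,
                            cfp_query("A", "F"))
  vars <- prog$model$var_names
  expect_equal(sum(startsWith(vars, "u|")), 8)
  expect_equal(sum(startsWith(vars, "z|")), 7)
  expect_equal(sum(startsWith(vars, "v|")), 7)
  # degree (4) + flow conservation (7 non-endpoint nodes) + one in-degree cap
  # (only E has two incoming arcs) + internal balances (6) + one non-medium
  # external production bound (F_ext) + activity coupling (2 per reaction)
  # + one arc-support link per arc (8)
  expect_equal(prog$model$ncon, 4 + 7 + 1 + 6 + 1 + 14 + 8)

  # dropping stoichiometry removes exactly the balancing constraint families,
  # while activity coupling and arc support (and their z/v variables) remain
  prog0 <- build_cfp_program(toy_g(), b$network, b$medium,
                             cfp_query("A", "F", use_stoichiometry = FALSE))
  expect_equal(prog$model$ncon - prog0$model$ncon, 6 + 1)
  expect_equal(sum(startsWith(prog0$model$var_names, "z|")), 7)
  expect_equal(sum(startsWith(prog0$model$var_names, "v|")), 7)
})

test_that("networks without reverse pairs get no exclusion constraints", {
  b <- toy_fx()
  with_rev <- split_reversible(metabolic_network(
    b$network$metabolites,
    dplyr::bind_rows(
      tibble::tibble(id = "r2", stoichiometry = list(c(A = -1, B = 1)),
                     reversible = TRUE),
      tibble::tibble(id = "r1", stoichiometry = list(c(A_ext = -1, A = 1)),
                     reversible = FALSE)
    )))
  carbon <- align_carbon_table(
    tibble::tibble(input = c("A_ext", "A"), output = c("A", "B"),
                   reaction = c("r1", "r2")), with_rev)
  g <- build_metabolite_graph(with_rev, carbon)
  q <- cfp_query("A_ext", "B")
  n_with <- build_cfp_program(g, with_rev, "A_ext", q)$model$ncon
  n_off <- build_cfp_program(
    g, with_rev, "A_ext",
    cfp_query("A_ext", "B", use_reversibility = FALSE))$model$ncon
  expect_equal(n_with - n_off, 1)  # exactly the one reverse pair
})

test_that("endpoint validation is strict", {
  b <- toy_fx()
  expect_error(cfp_query("A", "A"), "must differ")
  expect_error(
    build_cfp_program(toy_g(), b$network, b$medium, cfp_query("A", "nope")),
    "unreachable endpoint")
  expect_error(solver_config(big_M = 0.5), "big_M > min_flux")
})

test_that("the toy query yields its unique fully active solution", {
  p <- toy_solution()
  expect_equal(p$node_sequence, c("A", "B", "C", "E", "F"))
  expect_equal(p$length, 4)
  expect_setequal(p$active_reactions, paste0("r", 1:7))
  v <- verify_solution(p, toy_g(), toy_fx()$network, toy_fx()$medium)
  expect_true(v$pass)
  expect_setequal(v$off_path_active, c("r1", "r6", "r7"))
})

test_that("removing a medium metabolite destroys flux support, not the path", {
  b <- toy_fx()
  p <- solve_shortest_cfp(toy_g(), b$network, medium("A_ext", b$network),
                          cfp_query("A", "F"))
  expect_null(p)
  expect_length(all_simple_paths(toy_g(), "A", "F"), 1)
})

test_that("enumeration terminates exhausted and k = 1 matches the shortest", {
  b <- toy_fx()
  rs <- enumerate_k_shortest(toy_g(), b$network, b$medium,
                             cfp_query("A", "F", k = 5))
  expect_length(rs$paths, 1)
  expect_true(rs$exhausted)
  expect_equal(rs$paths[[1]]$node_sequence, toy_solution()$node_sequence)

  rs1 <- enumerate_k_shortest(toy_g(), b$network, b$medium,
                              cfp_query("A", "F", k = 1))
  expect_false(rs1$exhausted)
  expect_equal(rs1$paths[[1]]$arcs, toy_solution()$arcs)
})

test_that("enumerated paths have non-decreasing lengths and distinct arcs", {
  b <- cached("rn7", random_network(7))
  g <- build_metabolite_graph(b$network, b$carbon)
  rs <- cached("rn7_rs", enumerate_k_shortest(
    g, b$network, b$medium, cfp_query(b$source, b$target, k = 12)))
  lens <- vapply(rs$paths, function(p) p$length, integer(1))
  expect_true(all(diff(lens) >= 0))
  expect_equal(anyDuplicated(arc_family(rs)), 0)
  for (p in rs$paths) {
    expect_true(verify_solution(p, g, b$network, b$medium)$pass)
  }
})

test_that("stoichiometry only removes paths (subset property)", {
  b <- cached("rn7", random_network(7))
  g <- build_metabolite_graph(b$network, b$carbon)
  with_st <- cached("rn7_rs", enumerate_k_shortest(
    g, b$network, b$medium, cfp_query(b$source, b$target, k = 12)))
  without <- enumerate_k_shortest(
    g, b$network, b$medium,
    cfp_query(b$source, b$target, k = 12, use_stoichiometry = FALSE))
  strip_len <- function(fam) sub("^[0-9]+:", "", fam)
  expect_true(all(strip_len(arc_family(with_st)) %in%
                    strip_len(arc_family(without))))
})

test_that("scaling big_M by 10 leaves the solution set unchanged", {
  b <- toy_fx()
  rs_big <- enumerate_k_shortest(toy_g(), b$network, b$medium,
                                 cfp_query("A", "F", k = 5),
                                 solver_config(big_M = 10000))
  base <- cached("toy_rs5", enumerate_k_shortest(
    toy_g(), b$network, b$medium, cfp_query("A", "F", k = 5)))
  expect_equal(arc_family(rs_big), arc_family(base))
})

test_that("the verifier localises broken balances and activity violations", {
  p <- toy_solution()
  b <- toy_fx()
  # force the A-producing uptake to zero: A becomes unbalanced
  broken <- p
  broken$fluxes["r1"] <- 0
  broken$active_reactions <- setdiff(broken$active_reactions, "r1")
  v <- verify_solution(broken, toy_g(), b$network, b$medium)
  expect_false(v$pass)
  expect_equal(v$first_violation, "internal_balance")
  expect_match(v$checks$detail[v$checks$constraint == "internal_balance"],
               "metabolite A")

  # an active reaction below the minimum flux trips the coupling check
  weak <- p
  weak$fluxes["r2"] <- 0.5
  v2 <- verify_solution(weak, toy_g(), b$network, b$medium,
                        use_stoichiometry = FALSE)
  expect_false(v2$pass)
  expect_equal(v2$first_violation, "flux_activity")
})

test_that("a forward/backward cycle of one reaction fails verification", {
  b <- shortcut_fx()
  g <- shortcut_g()
  p <- solve_shortest_cfp(g, b$network, b$medium,
                          cfp_query("X", "T", use_reversibility = FALSE))
  expect_true(all(c("GT__fwd", "GT__rev") %in% p$active_reactions))
  v <- verify_solution(p, g, b$network, b$medium, use_reversibility = TRUE)
  expect_false(v$pass)
  expect_equal(v$first_violation, "reverse_exclusion")
  # under its own (relaxed) constraint set the solution is sound
  expect_true(verify_solution(p, g, b$network, b$medium,
                              use_reversibility = FALSE)$pass)
})

test_that("a returned path never carries a disjoint cycle", {
  for (key in c("toy_sol")) {
    p <- toy_solution()
    expect_equal(nrow(p$arcs), length(p$node_sequence) - 1)
  }
  b <- cached("rn7", random_network(7))
  rs <- cached("rn7_rs", enumerate_k_shortest(
    build_metabolite_graph(b$network, b$carbon), b$network, b$medium,
    cfp_query(b$source, b$target, k = 12)))
  for (p in rs$paths) {
    expect_equal(nrow(p$arcs), length(p$node_sequence) - 1)
    expect_equal(anyDuplicated(p$node_sequence), 0)
  }
})
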