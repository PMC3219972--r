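test_that("splitting a reversible reaction yields a negated, paired copy", {
  net <- metabolic_network(
    tibble::tibble(id = c("A", "B"), is_internal = TRUE),
    tibble::tibble(id = "isom", stoichiometry = list(c(A = -1, B = 1)),
                   reversible = TRUE)
  )
  split <- split_reversible(net)
  expect_equal(nrow(split$reactions), 2)
  expect_false(any(split$reactions$reversible))
  expect_equal(nrow(reverse_pairs(split)), 1)
  expect_equal(reaction_stoich(split, "isom__fwd"), c(A = -1, B = 1))
  expect_equal(reaction_stoich(split, "isom__rev"), c(A = 1, B = -1))
  expect_equal(split$metabolites, net$metabolites)
  # pair registration is symmetric
  rx <- split$reactions
  expect_equal(rx$reverse_of[rx$id == "isom__fwd"], "isom__rev")
  expect_equal(rx$reverse_of[rx$id == "isom__rev"], "isom__fwd")
})

test_that("splitting passes irreversible networks through unchanged", {
  net <- toy_fx()$network
  expect_identical(split_reversible(net), net)
  expect_equal(nrow(reverse_pairs(net)), 0)
})

test_that("split expansion is reversible: reaction counts reconstruct", {
  # acetyl-transfer case: D-Glc + AcCoA <-> AcGlc-D + CoA
  net <- metabolic_network(
    tibble::tibble(id = c("D-Glc", "AcCoA", "AcGlc-D", "CoA"),
                   is_internal = TRUE),
    tibble::tibble(
      id = c("GLCAT", "HEX"),
      stoichiometry = list(
        c("D-Glc" = -1, AcCoA = -1, "AcGlc-D" = 1, CoA = 1),
        c("D-Glc" = -1, "AcGlc-D" = 1)),
      reversible = c(TRUE, FALSE))
  )
  split <- split_reversible(net)
  rp <- reverse_pairs(split)
  expect_equal(nrow(rp), 1)
  expect_setequal(c(rp$fwd, rp$rev), c("GLCAT__fwd", "GLCAT__rev"))
  n_rev <- sum(net$reactions$reversible)
  # re-merging each reverse pair recovers the original reaction count
  expect_equal(nrow(split$reactions) - nrow(rp), nrow(net$reactions))
  expect_equal(nrow(split$reactions), nrow(net$reactions) + n_rev)
})

test_that("network validation rejects malformed input", {
  mets <- tibble::tibble(id = c("A", "B"), is_internal = TRUE)
  expect_error(
    metabolic_network(mets, tibble::tibble(id = "r",
                                           stoichiometry = list(NULL))),
    "empty stoichiometry")
  expect_error(
    metabolic_network(mets, tibble::tibble(
      id = "r", stoichiometry = list(c(A = -1, X = 1)))),
    "unknown metabolite: X")
  expect_error(
    metabolic_network(mets, tibble::tibble(
      id = "r", stoichiometry = list(c(A = -1, B = 0)))),
    "zero stoichiometric coefficient")
  expect_error(
    metabolic_network(
      tibble::tibble(id = c("A", "A"), is_internal = TRUE),
      tibble::tibble(id = "r", stoichiometry = list(c(A = -1)))),
    "duplicated metabolite id")
  expect_error(
    metabolic_network(mets, tibble::tibble(
      id = c("r", "s"),
      stoichiometry = list(c(A = -1, B = 1), c(A = 1, B = -1)),
      reverse_of = c("s", NA))),
    "not symmetric")
})

test_that("medium members must be external metabolites", {
  net <- toy_fx()$network
  expect_error(medium(c("A_ext", "A"), net), "not an external metabolite")
  expect_silent(medium(c("A_ext", "D_ext"), net))
})
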