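test_that("carbon counting parses formulas and two-letter elements", {
  expect_equal(carbon_count(c("C6H12O6", "H2O", "C10H16N5O13P3", "CaCl2",
                              "CO2", "HPO4")),
               c(6L, 0L, 10L, 0L, 1L, 0L))
  expect_true(is.na(carbon_count("C6H12O6)")))
  expect_true(is.na(carbon_count("")))
})

test_that("formula heuristic keeps only carbon-carbon pairs", {
  # ATP + H2O -> ADP + Pi: phosphate and water carry no carbon
  net <- metabolic_network(
    tibble::tibble(
      id = c("ATP", "H2O", "ADP", "Pi"),
      is_internal = TRUE,
      formula = c("C10H16N5O13P3", "H2O", "C10H15N5O10P2", "HPO4")),
    tibble::tibble(id = "ATPase",
                   stoichiometry = list(c(ATP = -1, H2O = -1, ADP = 1,
                                          Pi = 1)))
  )
  tab <- infer_carbon_arcs_from_formulas(net)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$input, "ATP")
  expect_equal(tab$output, "ADP")
  expect_equal(attr(tab, "provenance"), "heuristic")
})

test_that("formula heuristic over-approximates: hexokinase cross pairs", {
  net <- metabolic_network(
    tibble::tibble(
      id = c("D-Glc", "ATP", "G6P", "ADP"),
      is_internal = TRUE,
      formula = c("C6H12O6", "C10H16N5O13P3", "C6H13O9P", "C10H15N5O10P2")),
    tibble::tibble(id = "HEX1",
                   stoichiometry = list(c("D-Glc" = -1, ATP = -1, G6P = 1,
                                          ADP = 1)))
  )
  tab <- infer_carbon_arcs_from_formulas(net)
  # 2 inputs x 2 outputs, all carbon-bearing: cartesian product of 4,
  # including the spurious cross pairs a curated table would drop
  expect_equal(nrow(tab), 4)
  key <- paste(tab$input, tab$output)
  expect_setequal(key, c("D-Glc G6P", "ATP ADP", "D-Glc ADP", "ATP G6P"))
})

test_that("heuristic inference fails loudly on missing formulas", {
  net <- metabolic_network(
    tibble::tibble(id = c("A", "B"), is_internal = TRUE,
                   formula = c("C2H4", NA)),
    tibble::tibble(id = "r", stoichiometry = list(c(A = -1, B = 1)))
  )
  expect_error(infer_carbon_arcs_from_formulas(net), "metabolite B")
})

test_that("carbon entries must be input/output pairs of their reaction", {
  net <- toy_fx()$network
  expect_error(
    carbon_exchange_table(
      tibble::tibble(input = "B", output = "A", reaction = "r2"), net),
    "\\(B, A, r2\\)")
  expect_error(
    carbon_exchange_table(
      tibble::tibble(input = "A", output = "B", reaction = "nope"), net),
    "unknown reaction nope")
  expect_error(
    carbon_exchange_table(
      tibble::tibble(input = "Z", output = "B", reaction = "r2"), net),
    "unknown metabolite Z")
})

test_that("a curated table is a subgraph of the formula heuristic", {
  b <- toy_fx()
  heur <- infer_carbon_arcs_from_formulas(b$network)
  curated_keys <- paste(b$carbon$input, b$carbon$output, b$carbon$reaction)
  heur_keys <- paste(heur$input, heur$output, heur$reaction)
  expect_true(all(curated_keys %in% heur_keys))
})

test_that("carbon TSV and medium files round-trip", {
  b <- toy_fx()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_carbon_tsv(b$carbon, tsv)
  back <- read_carbon_tsv(tsv, network = b$network)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(b$carbon))

  med <- withr::local_tempfile(fileext = ".txt")
  write_medium(b$medium, med)
  expect_equal(as.character(read_medium(med, b$network)),
               as.character(b$medium))
  # comments and blank lines are ignored
  writeLines(c("# comment", "A_ext", "", "D_ext"), med)
  expect_equal(as.character(read_medium(med, b$network)),
               c("A_ext", "D_ext"))
})
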