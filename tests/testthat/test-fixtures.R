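test_that("the toy bundle matches its documented structure", {
  b <- toy_fx()
  expect_equal(nrow(b$network$reactions), 7)
  expect_equal(nrow(b$network$metabolites), 9)
  expect_setequal(internal_metabolites(b$network),
                  c("A", "B", "C", "D", "E", "F"))
  expect_setequal(external_metabolites(b$network),
                  c("A_ext", "D_ext", "F_ext"))
  expect_setequal(as.character(b$medium), c("A_ext", "D_ext"))
})

test_that("glyoxylate bundle switches feasibility with the shunt", {
  with_shunt <- glx_fx(TRUE)
  without <- glx_fx(FALSE)
  expect_setequal(setdiff(with_shunt$network$reactions$id,
                          without$network$reactions$id),
                  c("ICL", "MALS"))
  # graph-level search is fooled either way; only flux support differs
  expect_gt(length(all_simple_paths(glx_g(FALSE), "AcCoA", "G6P")), 0)
  expect_gt(length(all_simple_paths(glx_g(TRUE), "AcCoA", "G6P")), 0)
})

test_that("succinate dehydrogenase cannot run without oxygen", {
  b <- glx_fx(TRUE)
  anoxic <- medium(setdiff(as.character(b$medium), "O2_ext"), b$network)
  oxic_ok <- path_supportable(c("SUCC", "Fum", "L-Mal"), glx_g(TRUE),
                              b$network, b$medium)
  anoxic_ok <- path_supportable(c("SUCC", "Fum", "L-Mal"), glx_g(TRUE),
                                b$network, anoxic)
  expect_true(oxic_ok)
  expect_false(anoxic_ok)
})

test_that("random networks are deterministic in the seed", {
  a <- random_network(42)
  b <- random_network(42)
  expect_equal(a$network$stoichiometry, b$network$stoichiometry)
  expect_equal(tibble::as_tibble(a$carbon), tibble::as_tibble(b$carbon))
  expect_equal(as.character(a$medium), as.character(b$medium))
  c <- random_network(43)
  expect_false(identical(a$network$stoichiometry, c$network$stoichiometry))
})

test_that("p_reversible = 0 produces no reverse pairs", {
  b <- random_network(3, p_reversible = 0)
  expect_equal(nrow(reverse_pairs(b$network)), 0)
})

test_that("the generated backbone guarantees a source-to-target route", {
  for (seed in c(4, 13)) {
    b <- random_network(seed)
    g <- build_metabolite_graph(b$network, b$carbon)
    expect_gt(length(all_simple_paths(g, b$source, b$target)), 0)
  }
})

test_that("fixture bundles round-trip through model JSON and carbon TSV", {
  for (b in list(toy_fx(), glx_fx(TRUE))) {
    dir <- withr::local_tempdir()
    write_model_json(b$network, file.path(dir, "m.json"))
    write_carbon_tsv(b$carbon, file.path(dir, "c.tsv"))
    write_medium(b$medium, file.path(dir, "med.txt"))
    net <- read_model(file.path(dir, "m.json"))
    expect_equal(net$metabolites, b$network$metabolites)
    expect_equal(net$reactions, b$network$reactions)
    expect_equal(net$stoichiometry, b$network$stoichiometry)
    carb <- read_carbon_tsv(file.path(dir, "c.tsv"), network = net)
    expect_equal(tibble::as_tibble(carb), tibble::as_tibble(b$carbon))
    expect_equal(as.character(read_medium(file.path(dir, "med.txt"), net)),
                 as.character(b$medium))
  }
})

test_that("packaged data files equal the in-code constructors", {
  b <- toy_fx()
  net <- read_model(system.file("extdata", "toy_model.json",
                                package = "cfpath"))
  expect_equal(net$stoichiometry, b$network$stoichiometry)
  carb <- read_carbon_tsv(system.file("extdata", "toy_carbon.tsv",
                                      package = "cfpath"), network = net)
  expect_equal(tibble::as_tibble(carb), tibble::as_tibble(b$carbon))
})
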