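#' Packaged example networks
#'
#' Each fixture bundles a (split) metabolic network, a carbon-exchange table,
#' a default growth medium and provenance text, so every part of the package
#' can be exercised without external model files.
#'
#' @name fixtures
NULL

new_fixture_bundle <- function(network, carbon, med, provenance,
                               source = NULL, target = NULL) {
  structure(list(network = network, carbon = carbon, medium = med,
                 provenance = provenance, source = source, target = target),
            class = "fixture_bundle")
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat("<fixture_bundle>\n")
  print(x$network)
  print(x$carbon)
  cat("medium: ", paste(x$medium, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# build a network from compact reaction specs (list of named coefficient
# vectors), split reversibles, and expand an unsplit carbon table
build_bundle <- function(metabolites, reactions, carbon_entries, med,
                         provenance, source = NULL, target = NULL) {
  net <- metabolic_network(metabolites, reactions)
  split <- split_reversible(net)
  carbon <- align_carbon_table(carbon_entries, split)
  new_fixture_bundle(split, carbon, medium(med, split), provenance,
                     source = source, target = target)
}

#' Expand a carbon table written against unsplit reaction ids
#'
#' A curated arc table may reference a reversible reaction by its original id;
#' after [split_reversible()] that id names no reaction.  Each such entry
#' `(i, j, r)` is expanded to `(i, j, r__fwd)` and `(j, i, r__rev)`, so one
#' curated table serves the model before and after splitting.  Entries whose
#' reaction id exists verbatim pass through unchanged.
#'
#' @param entries data frame with columns `input`, `output`, `reaction`.
#' @param network the split `metabolic_network` to validate against.
#' @param provenance provenance label.
#' @return a validated `carbon_exchange_table`.
#' @export
align_carbon_table <- function(entries, network, provenance = "curated") {
  entries <- as_tibble(entries)
  ids <- network$reactions$id
  out <- purrr::pmap(entries, function(input, output, reaction) {
    if (reaction %in% ids) {
      return(tibble(input = input, output = output, reaction = reaction))
    }
    fwd <- paste0(reaction, "__fwd")
    if (fwd %in% ids) {
      i0 <- input
      j0 <- output
      return(tibble(input = c(i0, j0), output = c(j0, i0),
                    reaction = paste0(reaction, c("__fwd", "__rev"))))
    }
    abort(paste0("carbon entry references unknown reaction ", reaction))
  })
  carbon_exchange_table(dplyr::bind_rows(out), network,
                        provenance = provenance)
}

#' Toy linear network (nine metabolites, seven reactions)
#'
#' A minimal network with a single route from A to F: externals
#' `A_ext`, `D_ext`, `F_ext` and internals `A`-`F`, with reactions
#' `r1: A_ext -> A`, `r2: A -> B`, `r3: B -> C`, `r4: C + D -> E`,
#' `r5: E -> F`, `r6: D_ext -> D`, `r7: F -> F_ext`.  The carbon table lists
#' every input/output pair, giving 8 arcs.  With the default medium
#' `{A_ext, D_ext}` the unique carbon flux path from A to F is
#' `A -> B -> C -> E -> F`, and balancing it requires the three off-path
#' reactions `r1`, `r6`, `r7`; removing `D_ext` from the medium leaves the
#' graph path in place but destroys steady-state supportability.  Unit
#' stoichiometric coefficients throughout (the minimal reconstruction
#' consistent with those properties).
#'
#' @return a `fixture_bundle`.
#' @examples
#' toy_network()
#' @export
toy_network <- function() {
  mets <- tibble(
    id = c("A_ext", "D_ext", "F_ext", "A", "B", "C", "D", "E", "F"),
    is_internal = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    formula = "C3H6O3"
  )
  rxns <- tibble(
    id = paste0("r", 1:7),
    stoichiometry = list(
      c(A_ext = -1, A = 1),
      c(A = -1, B = 1),
      c(B = -1, C = 1),
      c(C = -1, D = -1, E = 1),
      c(E = -1, F = 1),
      c(D_ext = -1, D = 1),
      c(F = -1, F_ext = 1)
    )
  )
  carbon <- tibble(
    input = c("A_ext", "A", "B", "C", "D", "E", "D_ext", "F"),
    output = c("A", "B", "C", "E", "E", "F", "D", "F_ext"),
    reaction = c("r1", "r2", "r3", "r4", "r4", "r5", "r6", "r7")
  )
  build_bundle(mets, rxns, carbon, c("A_ext", "D_ext"),
               provenance = paste(
                 "Minimal linear toy network: single A->F route whose",
                 "steady state needs the off-path reactions r1, r6, r7."),
               source = "A", target = "F")
}

#' Fatty-acid-to-sugar network around the glyoxylate shunt
#'
#' A textbook-stoichiometry reconstruction of central carbon metabolism for
#' the classical question whether acetyl units can be converted to sugar:
#' TCA cycle (CS, ACONT, ICDHyr, AKGDH, SUCOAS, SUCDi, FUM, MDH), anaplerotic
#' and gluconeogenic steps (PDH, PYK, PC, PCK1, ME1, a lumped
#' two-PEP-to-G6P gluconeogenesis, G6PP, glucose export), fatty-acid uptake
#' lumped as `FA_ext + CoA -> AcCoA`, and - only when requested - the
#' glyoxylate shunt (ICL, MALS).  Cofactor pairs (NAD/NADH, ATP/ADP/Pi, CoA,
#' CoQ/CoQH2, CO2) are internal and balanced; respiration is lumped into
#' NADH and CoQH2 oxidases consuming external O2, and adenylate energetics
#' into a reversible `ATP <-> ADP + Pi` step.  Water and protons are omitted.
#' Net conversion of AcCoA to G6P is steady-state supportable if and only if
#' the shunt is present: without it the two decarboxylating TCA steps release
#' the two acetyl carbons as CO2 before oxaloacetate is regenerated, and net
#' CO2 fixation is impossible (every carboxylation is paired with an upstream
#' decarboxylation).  The simplified-figure original is not machine readable;
#' reactions follow its enzyme list with conventional stoichiometries.
#'
#' Removing `O2_ext` from the medium shuts down both oxidases, so succinate
#' dehydrogenase (the only CoQ reducer) cannot balance CoQH2 - the anoxic
#' behaviour that silences the oxidative TCA branch.
#'
#' @param with_glyoxylate_shunt include ICL and MALS?
#' @return a `fixture_bundle` (source `"AcCoA"`, target `"G6P"`).
#' @examples
#' glyoxylate_network()
#' glyoxylate_network(with_glyoxylate_shunt = FALSE)
#' @export
glyoxylate_network <- function(with_glyoxylate_shunt = TRUE) {
  internal <- c("AcCoA", "Cit", "ICit", "AKG", "SUCCoA", "SUCC", "Fum",
                "L-Mal", "OAA", "Glx", "Pyr", "PEP", "G6P", "D-Glc", "CO2",
                "CoA", "NAD", "NADH", "ATP", "ADP", "Pi", "CoQ", "CoQH2")
  external <- c("FA_ext", "D-Glc_ext", "CO2_ext", "O2_ext", "Pi_ext")
  mets <- tibble(id = c(internal, external),
                 is_internal = c(rep(TRUE, length(internal)),
                                 rep(FALSE, length(external))))

  rx <- list(
    FAUP  = c("FA_ext" = -1, CoA = -1, AcCoA = 1),
    CS    = c(AcCoA = -1, OAA = -1, Cit = 1, CoA = 1),
    ACONT = c(Cit = -1, ICit = 1),
    ICDHyr = c(ICit = -1, NAD = -1, AKG = 1, CO2 = 1, NADH = 1),
    AKGDH = c(AKG = -1, CoA = -1, NAD = -1, SUCCoA = 1, CO2 = 1, NADH = 1),
    SUCOAS = c(SUCCoA = -1, ADP = -1, Pi = -1, SUCC = 1, CoA = 1, ATP = 1),
    SUCDi = c(SUCC = -1, CoQ = -1, Fum = 1, CoQH2 = 1),
    FUM   = c(Fum = -1, "L-Mal" = 1),
    MDH   = c("L-Mal" = -1, NAD = -1, OAA = 1, NADH = 1),
    PDH   = c(Pyr = -1, CoA = -1, NAD = -1, AcCoA = 1, CO2 = 1, NADH = 1),
    PYK   = c(PEP = -1, ADP = -1, Pyr = 1, ATP = 1),
    PC    = c(Pyr = -1, CO2 = -1, ATP = -1, OAA = 1, ADP = 1, Pi = 1),
    PCK1  = c(OAA = -1, ATP = -1, PEP = 1, CO2 = 1, ADP = 1),
    ME1   = c("L-Mal" = -1, NAD = -1, Pyr = 1, CO2 = 1, NADH = 1),
    GNG   = c(PEP = -2, ATP = -2, NADH = -2, G6P = 1, ADP = 2, NAD = 2, Pi = 1),
    G6PP  = c(G6P = -1, "D-Glc" = 1, Pi = 1),
    GLCex = c("D-Glc" = -1, "D-Glc_ext" = 1),
    NADHOX = c(NADH = -1, "O2_ext" = -0.5, NAD = 1),
    CoQOX = c(CoQH2 = -1, "O2_ext" = -0.5, CoQ = 1),
    ATPM  = c(ATP = -1, ADP = 1, Pi = 1),
    PIt   = c("Pi_ext" = -1, Pi = 1),
    CO2t  = c(CO2 = -1, CO2_ext = 1)
  )
  if (with_glyoxylate_shunt) {
    rx$ICL <- c(ICit = -1, SUCC = 1, Glx = 1)
    rx$MALS <- c(AcCoA = -1, Glx = -1, "L-Mal" = 1, CoA = 1)
  }
  reversible <- names(rx) %in% c("ACONT", "SUCOAS", "FUM", "MDH", "ATPM")
  rxns <- tibble(id = names(rx), stoichiometry = unname(rx),
                 reversible = reversible)

  arc <- function(i, j, r) tibble(input = i, output = j, reaction = r)
  carbon <- dplyr::bind_rows(
    arc("FA_ext", "AcCoA", "FAUP"),
    arc(c("AcCoA", "OAA"), "Cit", "CS"),
    arc("Cit", "ICit", "ACONT"),
    arc("ICit", c("AKG", "CO2"), "ICDHyr"),
    arc("AKG", c("SUCCoA", "CO2"), "AKGDH"),
    arc("SUCCoA", "SUCC", "SUCOAS"),
    arc("SUCC", "Fum", "SUCDi"),
    arc("Fum", "L-Mal", "FUM"),
    arc("L-Mal", "OAA", "MDH"),
    arc("Pyr", c("AcCoA", "CO2"), "PDH"),
    arc("PEP", "Pyr", "PYK"),
    arc(c("Pyr", "CO2"), "OAA", "PC"),
    arc("OAA", c("PEP", "CO2"), "PCK1"),
    arc("L-Mal", c("Pyr", "CO2"), "ME1"),
    arc("PEP", "G6P", "GNG"),
    arc("G6P", "D-Glc", "G6PP"),
    arc("D-Glc", "D-Glc_ext", "GLCex"),
    arc("CO2", "CO2_ext", "CO2t")
  )
  if (with_glyoxylate_shunt) {
    carbon <- dplyr::bind_rows(
      carbon,
      arc("ICit", c("SUCC", "Glx"), "ICL"),
      arc(c("AcCoA", "Glx"), "L-Mal", "MALS")
    )
  }

  build_bundle(mets, rxns, carbon, c("FA_ext", "O2_ext", "Pi_ext"),
               provenance = paste(
                 "Reconstruction of a simplified central-carbon network for",
                 "the fatty-acids-to-sugar question; textbook",
                 "stoichiometries, lumped respiration/energetics, water and",
                 "protons omitted. The glyoxylate shunt (ICL, MALS) is",
                 "included only on request."),
               source = "AcCoA", target = "G6P")
}

#' Reversible acetyl-transfer shortcut network
#'
#' Small fixture reproducing the pathology that motivates the reverse-pair
#' exclusion constraint: a reversible group-transfer reaction
#' `GT: X + Ac <-> XA + C` creates, after splitting, the carbon arcs
#' `X -> XA` (forward direction) and `XA -> Ac` (backward direction).
#' Without the exclusion constraint the shortest route from `X` to `T` is the
#' biochemically meaningless `X -> XA -> Ac -> T`, whose first two steps are
#' a forward/backward cycle of the same reaction; with the constraint the
#' model must take the honest four-step route `X -> Y1 -> Y2 -> Y3 -> T`.
#'
#' @return a `fixture_bundle` (source `"X"`, target `"T"`).
#' @export
acetylation_shortcut_network <- function() {
  internal <- c("X", "XA", "Ac", "C", "T", "Y1", "Y2", "Y3")
  external <- c("X_ext", "Ac_ext", "C_ext", "T_ext")
  mets <- tibble(id = c(internal, external),
                 is_internal = c(rep(TRUE, length(internal)),
                                 rep(FALSE, length(external))))
  rx <- list(
    XUP = c(X_ext = -1, X = 1),
    AUP = c(Ac_ext = -1, Ac = 1),
    GT  = c(X = -1, Ac = -1, XA = 1, C = 1),
    CEX = c(C = -1, C_ext = 1),
    ACT = c(Ac = -1, T = 1),
    R1  = c(X = -1, Y1 = 1),
    R2  = c(Y1 = -1, Y2 = 1),
    R3  = c(Y2 = -1, Y3 = 1),
    R4  = c(Y3 = -1, T = 1),
    TEX = c(T = -1, T_ext = 1)
  )
  rxns <- tibble(id = names(rx), stoichiometry = unname(rx),
                 reversible = names(rx) == "GT")
  carbon <- tibble(
    input = c("X_ext", "Ac_ext", "X", "Ac", "C", "Ac", "X", "Y1", "Y2",
              "Y3", "T"),
    output = c("X", "Ac", "XA", "XA", "C_ext", "T", "Y1", "Y2", "Y3", "T",
               "T_ext"),
    reaction = c("XUP", "AUP", "GT", "GT", "CEX", "ACT", "R1", "R2", "R3",
                 "R4", "TEX")
  )
  build_bundle(mets, rxns, carbon, c("X_ext", "Ac_ext"),
               provenance = paste(
                 "Synthetic fixture for the reversible-reaction shortcut",
                 "pathology (acetyl group transfer style)."),
               source = "X", target = "T")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Seeded random test network
#'
#' Generates a small connected metabolic network fully determined by `seed`:
#' a linear backbone `M01 -> ... -> Mn` (so at least one carbon flux path
#' between the designated source `M01` and target `Mn` always exists), an
#' import reaction for the source tier, export reactions for the target tier
#' and one random intermediate, plus random extra reactions with one or two
#' substrates and products (occasionally with coefficient 2, occasionally
#' reversible) that create shortcut arcs - some steady-state supportable,
#' some not.  The carbon table lists every input/output pair.
#'
#' Sizes are deliberately small so the brute-force oracle stays viable.
#'
#' @param seed integer seed.
#' @param n_internal number of internal metabolites (kept at or below 15).
#' @param n_reactions total reaction count before splitting (at least
#'   `n_internal + 2`).
#' @param p_reversible probability that an extra reaction is reversible.
#' @return a `fixture_bundle` with `source` and `target` set.
#' @export
random_network <- function(seed, n_internal = 9,
                           n_reactions = n_internal + 7,
                           p_reversible = 0.15) {
  if (n_internal > 15) abort("n_internal must stay <= 15 (oracle budget)")
  if (n_reactions < n_internal + 2) {
    abort("n_reactions must be at least n_internal + 2")
  }
  with_seed(seed, {
    ids <- sprintf("M%02d", seq_len(n_internal))
    mets <- tibble(id = c(ids, "S_ext", "T_ext", "W_ext"),
                   is_internal = c(rep(TRUE, n_internal), FALSE, FALSE, FALSE))
    chain <- purrr::map(seq_len(n_internal - 1), function(i) {
      s <- c(-1, 1)
      names(s) <- c(ids[i], ids[i + 1])
      tibble(id = sprintf("RC%02d", i), stoichiometry = list(s),
             reversible = FALSE)
    })
    waste <- sample(ids[-1], 1)
    base <- dplyr::bind_rows(
      tibble(id = "IMP", stoichiometry = list(c(S_ext = -1) |>
               c(setNames(1, ids[1]))), reversible = FALSE),
      dplyr::bind_rows(chain),
      tibble(id = "EXP", stoichiometry = list(setNames(c(-1, 1),
               c(ids[n_internal], "T_ext"))), reversible = FALSE),
      tibble(id = "WEX", stoichiometry = list(setNames(c(-1, 1),
               c(waste, "W_ext"))), reversible = FALSE)
    )
    n_extra <- n_reactions - nrow(base)
    extra <- purrr::map(seq_len(n_extra), function(i) {
      ns <- sample(1:2, 1)
      np <- sample(1:2, 1)
      subs <- sample(ids, ns)
      prods <- sample(setdiff(ids, subs), np)
      coefs <- c(-sample(c(1, 1, 1, 2), ns, replace = TRUE),
                 sample(c(1, 1, 1, 2), np, replace = TRUE))
      s <- setNames(coefs, c(subs, prods))
      tibble(id = sprintf("RX%02d", i), stoichiometry = list(s),
             reversible = stats::runif(1) < p_reversible)
    })
    rxns <- dplyr::bind_rows(base, dplyr::bind_rows(extra))

    carbon <- purrr::pmap(rxns, function(id, stoichiometry, reversible) {
      s <- stoichiometry
      tidyr::expand_grid(input = names(s)[s < 0], output = names(s)[s > 0]) |>
        mutate(reaction = id)
    }) |> dplyr::bind_rows()

    build_bundle(mets, rxns, carbon, "S_ext",
                 provenance = sprintf(
                   "Seeded random test network (seed %d): backbone chain plus %d random reactions.",
                   seed, n_extra),
                 source = ids[1], target = ids[n_internal])
  })
}
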