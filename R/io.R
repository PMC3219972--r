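#' Read a metabolic model
#'
#' Two on-disk encodings are supported.  The JSON dialect mirrors the package
#' data model one-to-one (`metabolites`: id, name, is_internal, formula;
#' `reactions`: id, stoichiometry map, reversible, reverse_of).  The SBML
#' reader covers the subset of SBML Level 2/3 core that stoichiometric
#' models use: species (with `boundaryCondition` and `compartment`),
#' reactions with `listOfReactants` / `listOfProducts` and per-species
#' stoichiometries, and the `reversible` flag.  A species is mapped to an
#' external metabolite when `boundaryCondition="true"` or its compartment is
#' listed in `external_compartments`.  Reversible reactions are read as
#' flagged, not split; call [split_reversible()] explicitly.
#'
#' @param path model file.
#' @param format `"json"` or `"sbml"` (default guessed from the extension).
#' @param external_compartments compartment ids treated as outside the
#'   boundary (SBML only).
#' @return a `metabolic_network`.
#' @export
read_model <- function(path, format = c("auto", "json", "sbml"),
                       external_compartments = c("e", "ext", "extracellular")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) {
      "sbml"
    } else "json"
  }
  switch(format,
         json = read_model_json(path),
         sbml = read_model_sbml(path, external_compartments))
}

read_model_json <- function(path) {
  m <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) abort(paste0("malformed model JSON ", path, ": ",
                                     conditionMessage(e)))
  )
  mets <- purrr::map(m$metabolites, function(x) {
    tibble(id = x$id, name = x$name %||% x$id,
           is_internal = isTRUE(x$is_internal),
           formula = x$formula %||% NA_character_)
  }) |> dplyr::bind_rows()
  rxns <- purrr::map(m$reactions, function(x) {
    tibble(id = x$id,
           stoichiometry = list(unlist(x$stoichiometry)),
           reversible = isTRUE(x$reversible),
           reverse_of = x$reverse_of %||% NA_character_)
  }) |> dplyr::bind_rows()
  metabolic_network(mets, rxns)
}

#' Write a metabolic model to the JSON dialect
#'
#' @param network a `metabolic_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(network, path) {
  mets <- purrr::pmap(network$metabolites, function(id, name, is_internal,
                                                    formula) {
    x <- list(id = id, name = name, is_internal = is_internal)
    if (!is.na(formula)) x$formula <- formula
    x
  })
  rxns <- purrr::pmap(network$reactions, function(id, reversible, reverse_of) {
    s <- reaction_stoich(network, id)
    x <- list(id = id, stoichiometry = as.list(s), reversible = reversible)
    if (!is.na(reverse_of)) x$reverse_of <- reverse_of
    x
  })
  jsonlite::write_json(list(metabolites = mets, reactions = rxns), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

read_model_sbml <- function(path, external_compartments) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) {
                    abort(paste0("malformed SBML ", path, ": ",
                                 conditionMessage(e)))
                  })
  xml2::xml_ns_strip(doc)
  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (length(sp) == 0) abort(paste0("no species found in SBML file ", path))
  boundary <- tolower(dplyr::coalesce(xml2::xml_attr(sp, "boundaryCondition"),
                                      "false")) == "true"
  compartment <- xml2::xml_attr(sp, "compartment")
  mets <- tibble(
    id = xml2::xml_attr(sp, "id"),
    name = dplyr::coalesce(xml2::xml_attr(sp, "name"),
                           xml2::xml_attr(sp, "id")),
    is_internal = !(boundary | compartment %in% external_compartments),
    formula = dplyr::coalesce(xml2::xml_attr(sp, "fbc:chemicalFormula"),
                              xml2::xml_attr(sp, "chemicalFormula"))
  )
  rx <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  rxns <- purrr::map(rx, function(r) {
    rid <- xml2::xml_attr(r, "id")
    coef_of <- function(refs, sign) {
      if (length(refs) == 0) return(numeric())
      st <- xml2::xml_attr(refs, "stoichiometry")
      st <- ifelse(is.na(st), 1, as.numeric(st))
      setNames(sign * st, xml2::xml_attr(refs, "species"))
    }
    subs <- coef_of(xml2::xml_find_all(r, "./listOfReactants/speciesReference"), -1)
    prods <- coef_of(xml2::xml_find_all(r, "./listOfProducts/speciesReference"), 1)
    s <- c(subs, prods)
    dup <- intersect(names(subs), names(prods))
    if (length(dup)) {
      # same species on both sides: net coefficient
      s <- tapply(s, names(s), sum)
      s <- setNames(as.numeric(s), names(s))
      s <- s[abs(s) > .coef_tol]
    }
    tibble(id = rid, stoichiometry = list(s),
           reversible = tolower(dplyr::coalesce(
             xml2::xml_attr(r, "reversible"), "true")) == "true",
           reverse_of = NA_character_)
  }) |> dplyr::bind_rows()
  metabolic_network(mets, rxns)
}

#' Read / write reference pathways (JSON list of id + arc pairs)
#'
#' @param path file path.
#' @return a list of [reference_pathway()] objects.
#' @export
read_reference_pathways <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  purrr::map(x, function(p) {
    reference_pathway(p$id, purrr::map(p$arcs, unlist))
  })
}

#' @rdname read_reference_pathways
#' @param pathways list of `reference_pathway` objects.
#' @export
write_reference_pathways <- function(pathways, path) {
  out <- purrr::map(pathways, function(p) {
    list(id = p$id,
         arcs = purrr::map2(p$arcs$from, p$arcs$to, ~ c(.x, .y)))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Write a result set to a directory
#'
#' Emits `paths.tsv` (k, length, node_sequence, active_reactions),
#' `fluxes.tsv` (k, reaction, flux; non-zero fluxes only), `summary.json`
#' (query, configuration, exhaustion state) and, when requested, `graph.dot`
#' with arc/node attributes scaled by frequency of appearance.  Tab
#' separation and `.` decimal throughout.
#'
#' @param result a `cfp_result_set`.
#' @param dir output directory (created if missing).
#' @param dot also write the frequency-annotated DOT file?
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir, dot = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths_tbl <- tidy(result)
  readr::write_tsv(
    paths_tbl[, c("k", "length", "node_sequence", "active_reactions")],
    file.path(dir, "paths.tsv"))
  fluxes <- purrr::imap(result$paths, function(p, k) {
    fl <- p$fluxes[p$fluxes > 0]
    if (length(fl) == 0) return(tibble(k = integer(), reaction = character(),
                                       flux = numeric()))
    tibble(k = k, reaction = names(fl), flux = unname(fl))
  }) |> dplyr::bind_rows()
  readr::write_tsv(fluxes, file.path(dir, "fluxes.tsv"))
  q <- result$query
  summary <- list(
    query = if (is.null(q)) NULL else {
      list(source = q$source, target = q$target, k = q$k,
           use_stoichiometry = q$use_stoichiometry,
           use_reversibility = q$use_reversibility, objective = q$objective)
    },
    config = unclass(result$config),
    n_paths = length(result$paths),
    exhausted = result$exhausted
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  if (dot) {
    export_frequency_dot(frequency_table(result), file.path(dir, "graph.dot"))
  }
  invisible(dir)
}

#' Read back a result set written by [write_results()]
#'
#' @param dir directory holding `paths.tsv`, `fluxes.tsv`, `summary.json`.
#' @return a `cfp_result_set` (query and paths reconstructed; solver
#'   statuses are not round-tripped).
#' @export
read_results <- function(dir) {
  paths_tbl <- readr::read_tsv(file.path(dir, "paths.tsv"),
                               show_col_types = FALSE,
                               col_types = readr::cols(
                                 k = "i", length = "i", .default = "c"))
  fluxes <- readr::read_tsv(file.path(dir, "fluxes.tsv"),
                            show_col_types = FALSE,
                            col_types = readr::cols(k = "i", reaction = "c",
                                                    flux = "d"))
  s <- jsonlite::read_json(file.path(dir, "summary.json"),
                           simplifyVector = TRUE, simplifyDataFrame = FALSE)
  paths <- purrr::map(seq_len(nrow(paths_tbl)), function(i) {
    nodes <- strsplit(paths_tbl$node_sequence[i], "->", fixed = TRUE)[[1]]
    active <- if (is.na(paths_tbl$active_reactions[i]) ||
                  !nzchar(paths_tbl$active_reactions[i])) {
      character()
    } else strsplit(paths_tbl$active_reactions[i], ",", fixed = TRUE)[[1]]
    fl <- fluxes[fluxes$k == paths_tbl$k[i], ]
    new_flux_path(nodes, active_reactions = active,
                  fluxes = setNames(fl$flux, fl$reaction))
  })
  query <- if (!is.null(s$query)) {
    cfp_query(s$query$source, s$query$target, k = s$query$k,
              use_stoichiometry = s$query$use_stoichiometry,
              use_reversibility = s$query$use_reversibility,
              objective = s$query$objective)
  }
  new_cfp_result_set(query = query, paths = paths, exhausted = s$exhausted)
}

#' Export a frequency table as a DOT graph
#'
#' Arc `penwidth` and node `width` are proportional to frequency of
#' appearance among the paths, the conventional rendering of K-shortest-path
#' inventories.
#'
#' @param freq a `cfp_frequency`.
#' @param path output `.dot` file.
#' @return `path`, invisibly.
#' @export
export_frequency_dot <- function(freq, path) {
  npaths <- max(1L, freq$n_paths)
  lines <- c("digraph cfp {")
  for (i in seq_len(nrow(freq$metabolites))) {
    m <- freq$metabolites[i, ]
    lines <- c(lines, sprintf(
      "  \"%s\" [width=%.3f, label=\"%s (%d)\"];",
      m$metabolite, 0.5 + m$count / npaths, m$metabolite, m$count))
  }
  for (i in seq_len(nrow(freq$arcs))) {
    a <- freq$arcs[i, ]
    lines <- c(lines, sprintf(
      "  \"%s\" -> \"%s\" [penwidth=%.3f, label=\"%d\"];",
      a$from, a$to, 0.5 + 4 * a$count / npaths, a$count))
  }
  writeLines(c(lines, "}"), path)
  invisible(path)
}

#' Write a connectivity curve as TSV (columns `step`, `count`)
#'
#' @param curve a `connectivity_curve`.
#' @param path output file.
#' @export
write_curve_tsv <- function(curve, path) {
  readr::write_tsv(tibble(step = curve$steps, count = curve$n_connected),
                   path)
  invisible(path)
}

#' Write recovery results as TSV
#'
#' @param recovery tibble as produced by [recovery_rate()] (one row per
#'   pathway).
#' @param path output file.
#' @export
write_recovery_tsv <- function(recovery, path) {
  readr::write_tsv(recovery, path)
  invisible(path)
}
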