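#' Carbon-exchange arc table
#'
#' Records, per reaction, which (input, output) metabolite pairs exchange
#' carbon atoms effectively.  Presence of a triple `(i, j, r)` means the arc
#' `i -> j` is supported by reaction `r` in carbon exchange; absent pairs are
#' excluded from the metabolite graph.  Tables are usually curated (atom
#' transfers checked by hand, as in published arc databases); a formula-based
#' over-approximation is available via [infer_carbon_arcs_from_formulas()].
#'
#' @param entries a data frame with character columns `input`, `output`,
#'   `reaction`.
#' @param network optional `metabolic_network`; when supplied every entry is
#'   checked: metabolite and reaction ids must exist, `input` must be a
#'   substrate of the reaction (negative coefficient) and `output` a product
#'   (positive coefficient).  Violations are rejected naming the offending
#'   triple.
#' @param provenance `"curated"` or `"heuristic"`.
#' @return a tibble of class `carbon_exchange_table` with attribute
#'   `provenance`.
#' @export
carbon_exchange_table <- function(entries, network = NULL,
                                  provenance = "curated") {
  entries <- as_tibble(entries)
  need <- c("input", "output", "reaction")
  if (!all(need %in% names(entries))) {
    abort("carbon table needs columns `input`, `output`, `reaction`")
  }
  entries <- distinct(entries[, need])
  if (!is.null(network)) {
    validate_carbon_table(entries, network)
  }
  structure(entries, class = c("carbon_exchange_table", class(tibble())),
            provenance = provenance)
}

validate_carbon_table <- function(entries, network) {
  if (nrow(entries) == 0) return(invisible(entries))
  mets <- network$metabolites$id
  rxns <- network$reactions$id
  for (col in c("input", "output")) {
    bad <- setdiff(entries[[col]], mets)
    if (length(bad)) {
      row <- entries[entries[[col]] == bad[1], ][1, ]
      abort(paste0("carbon entry (", row$input, ", ", row$output, ", ",
                   row$reaction, ") references unknown metabolite ", bad[1]))
    }
  }
  bad <- setdiff(entries$reaction, rxns)
  if (length(bad)) {
    row <- entries[entries$reaction == bad[1], ][1, ]
    abort(paste0("carbon entry (", row$input, ", ", row$output, ", ",
                 row$reaction, ") references unknown reaction ", bad[1]))
  }
  st <- network$stoichiometry
  key <- paste(st$reaction, st$metabolite)
  coef_of <- setNames(st$coef, key)
  cin <- coef_of[paste(entries$reaction, entries$input)]
  cout <- coef_of[paste(entries$reaction, entries$output)]
  ok <- !is.na(cin) & !is.na(cout) & cin < -.coef_tol & cout > .coef_tol
  if (!all(ok)) {
    row <- entries[which(!ok)[1], ]
    abort(paste0("carbon entry (", row$input, ", ", row$output, ", ",
                 row$reaction, ") is not an input/output pair of the ",
                 "reaction (need a negative coefficient for the input and a ",
                 "positive one for the output)"))
  }
  invisible(entries)
}

#' Count carbon atoms in an elemental formula
#'
#' Parses formulas such as `"C6H12O6"`; two-letter element symbols (Cl, Ca,
#' Co, ...) are recognised so their counts never leak into the carbon total.
#'
#' @param formula character vector of formulas.
#' @return integer vector of carbon counts; `NA` for unparseable input.
#' @export
carbon_count <- function(formula) {
  vapply(formula, function(f) {
    if (is.na(f) || !nzchar(f)) return(NA_integer_)
    tokens <- stringr::str_match_all(f, "([A-Z][a-z]?)([0-9]*)")[[1]]
    if (nrow(tokens) == 0 ||
        nchar(paste0(tokens[, 1], collapse = "")) != nchar(f)) {
      return(NA_integer_)
    }
    n <- ifelse(tokens[, 3] == "", 1L, suppressWarnings(as.integer(tokens[, 3])))
    sum(n[tokens[, 2] == "C"])
  }, integer(1), USE.NAMES = FALSE)
}

#' Infer carbon-exchange arcs from elemental formulas
#'
#' Heuristic fallback for networks without a curated arc table: for every
#' reaction, every (input, output) pair in which both metabolites contain at
#' least one carbon atom is emitted.  This over-approximates true atom
#' transfer (e.g. hexokinase yields the spurious pairs D-Glc -> ADP and
#' ATP -> G6P alongside the real D-Glc -> G6P and ATP -> ADP), so the result
#' is flagged `"heuristic"`; prefer a curated table when one exists — every
#' curated table is a subset of this one.
#'
#' @param network a `metabolic_network` whose metabolites all carry parseable
#'   formulas.
#' @return a `carbon_exchange_table` with provenance `"heuristic"`.
#' @export
infer_carbon_arcs_from_formulas <- function(network) {
  mets <- network$metabolites
  nc <- carbon_count(mets$formula)
  if (anyNA(nc)) {
    bad <- mets$id[which(is.na(nc))[1]]
    abort(paste0("metabolite ", bad, " has a missing or unparseable formula"))
  }
  carbons <- setNames(nc, mets$id)
  st <- network$stoichiometry
  entries <- st |>
    dplyr::group_by(.data$reaction) |>
    dplyr::reframe({
      inputs <- .data$metabolite[.data$coef < -.coef_tol]
      outputs <- .data$metabolite[.data$coef > .coef_tol]
      inputs <- inputs[carbons[inputs] >= 1]
      outputs <- outputs[carbons[outputs] >= 1]
      tidyr::expand_grid(input = inputs, output = outputs)
    })
  entries <- entries[, c("input", "output", "reaction")]
  carbon_exchange_table(entries, network, provenance = "heuristic")
}

#' @export
print.carbon_exchange_table <- function(x, ...) {
  cat("<carbon_exchange_table: ", nrow(x), " entries, provenance: ",
      attr(x, "provenance") %||% "unknown", ">\n", sep = "")
  NextMethod()
}

#' Read / write a carbon-exchange arc table as TSV
#'
#' Three tab-separated columns `input_metabolite`, `output_metabolite`,
#' `reaction`, one triple per line; `#` comments allowed.
#'
#' @param path file path.
#' @param network optional network for validation on read.
#' @param provenance provenance label for the loaded table.
#' @return `read_carbon_tsv()` returns a `carbon_exchange_table`;
#'   `write_carbon_tsv()` returns `path` invisibly.
#' @export
read_carbon_tsv <- function(path, network = NULL, provenance = "curated") {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  need <- c("input_metabolite", "output_metabolite", "reaction")
  if (!all(need %in% names(df))) {
    abort(paste0("carbon TSV needs header columns: ",
                 paste(need, collapse = ", ")))
  }
  carbon_exchange_table(
    tibble(input = df$input_metabolite, output = df$output_metabolite,
           reaction = df$reaction),
    network = network, provenance = provenance
  )
}

#' @rdname read_carbon_tsv
#' @param carbon a `carbon_exchange_table`.
#' @export
write_carbon_tsv <- function(carbon, path) {
  df <- tibble(input_metabolite = carbon$input,
               output_metabolite = carbon$output,
               reaction = carbon$reaction)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read / write a growth-medium file (one external metabolite id per line)
#' @inheritParams read_carbon_tsv
#' @export
read_medium <- function(path, network = NULL) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  medium(lines, network)
}

#' @rdname read_medium
#' @param med a medium (character vector of external metabolite ids).
#' @export
write_medium <- function(med, path) {
  writeLines(as.character(med), path)
  invisible(path)
}
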