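#' Construct a stoichiometric metabolic network
#'
#' A network is a set of metabolites partitioned into internal metabolites
#' (inside the system boundary, subject to steady-state balancing) and
#' external metabolites (outside the boundary, not balanced), together with
#' reactions given by signed stoichiometric coefficients: negative for inputs
#' (substrates), positive for outputs (products).  Reversible reactions may be
#' flagged as such and later expanded into two irreversible directions with
#' [split_reversible()], after which all fluxes are non-negative.
#'
#' @param metabolites a data frame with columns `id` (unique, non-empty),
#'   `is_internal` (logical), and optionally `name` and `formula` (elemental
#'   formula such as `"C6H12O6"`).
#' @param reactions a data frame with columns `id` (unique), `stoichiometry`
#'   (a list-column of named numeric vectors, names being metabolite ids), and
#'   optionally `reversible` (logical, default `FALSE`) and `reverse_of`
#'   (character, `NA` unless the reaction is the registered reverse of
#'   another).
#' @return an object of class `metabolic_network`: a list with tibbles
#'   `metabolites`, `reactions` (id, reversible, reverse_of) and
#'   `stoichiometry` (long form: reaction, metabolite, coef).
#' @examples
#' net <- metabolic_network(
#'   metabolites = tibble::tibble(id = c("A_ext", "A", "B"),
#'                                is_internal = c(FALSE, TRUE, TRUE)),
#'   reactions = tibble::tibble(
#'     id = c("uptake", "isom"),
#'     stoichiometry = list(c(A_ext = -1, A = 1), c(A = -1, B = 1)),
#'     reversible = c(FALSE, TRUE))
#' )
#' net
#' @export
metabolic_network <- function(metabolites, reactions) {
  metabolites <- as_tibble(metabolites)
  reactions <- as_tibble(reactions)
  if (!all(c("id", "is_internal") %in% names(metabolites))) {
    abort("metabolites need columns `id` and `is_internal`")
  }
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"formula" %in% names(metabolites)) metabolites$formula <- NA_character_
  metabolites <- metabolites[, c("id", "name", "is_internal", "formula")]
  if (any(!nzchar(metabolites$id)) || anyNA(metabolites$id)) {
    abort("metabolite ids must be non-empty")
  }
  if (anyDuplicated(metabolites$id)) {
    abort(paste0("duplicated metabolite id: ",
                 metabolites$id[duplicated(metabolites$id)][1]))
  }

  if (!all(c("id", "stoichiometry") %in% names(reactions))) {
    abort("reactions need columns `id` and `stoichiometry`")
  }
  if (!"reversible" %in% names(reactions)) reactions$reversible <- FALSE
  if (!"reverse_of" %in% names(reactions)) reactions$reverse_of <- NA_character_
  if (anyDuplicated(reactions$id)) {
    abort(paste0("duplicated reaction id: ",
                 reactions$id[duplicated(reactions$id)][1]))
  }

  stoich <- purrr::map2(reactions$id, reactions$stoichiometry, function(rid, s) {
    if (is.null(s) || length(s) == 0) {
      abort(paste0("reaction ", rid, " has empty stoichiometry"))
    }
    if (is.null(names(s)) || any(!nzchar(names(s)))) {
      abort(paste0("reaction ", rid, " has unnamed stoichiometric entries"))
    }
    tibble(reaction = rid, metabolite = names(s), coef = as.numeric(s))
  })
  stoich <- dplyr::bind_rows(stoich)
  if (any(abs(stoich$coef) <= .coef_tol)) {
    bad <- stoich[abs(stoich$coef) <= .coef_tol, ]
    abort(paste0("zero stoichiometric coefficient for metabolite ",
                 bad$metabolite[1], " in reaction ", bad$reaction[1]))
  }
  unknown <- setdiff(stoich$metabolite, metabolites$id)
  if (length(unknown)) {
    abort(paste0("reaction references unknown metabolite: ", unknown[1]))
  }
  dup <- stoich |> dplyr::count(.data$reaction, .data$metabolite) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    abort(paste0("metabolite ", dup$metabolite[1],
                 " appears twice in reaction ", dup$reaction[1]))
  }

  ro <- reactions$reverse_of
  for (k in seq_along(ro)) {
    if (!is.na(ro[k])) {
      m <- match(ro[k], reactions$id)
      if (is.na(m)) abort(paste0("reverse_of references unknown reaction: ", ro[k]))
      if (is.na(reactions$reverse_of[m]) ||
          reactions$reverse_of[m] != reactions$id[k]) {
        abort(paste0("reverse_of is not symmetric for ", reactions$id[k]))
      }
    }
  }

  structure(
    list(
      metabolites = metabolites,
      reactions = reactions[, c("id", "reversible", "reverse_of")],
      stoichiometry = stoich
    ),
    class = "metabolic_network"
  )
}

# tolerance for sign tests on stoichiometric coefficients
.coef_tol <- 1e-9

#' @export
print.metabolic_network <- function(x, ...) {
  nrev <- sum(x$reactions$reversible)
  cat("<metabolic_network: ", nrow(x$metabolites), " metabolites (",
      sum(x$metabolites$is_internal), " internal), ",
      nrow(x$reactions), " reactions",
      if (nrev) paste0(" (", nrev, " reversible)") else "",
      ", ", nrow(reverse_pairs(x)), " reverse pairs>\n", sep = "")
  invisible(x)
}

#' Internal / external metabolite accessors
#' @param network a `metabolic_network`.
#' @return character vector of metabolite ids.
#' @export
internal_metabolites <- function(network) {
  network$metabolites$id[network$metabolites$is_internal]
}

#' @rdname internal_metabolites
#' @export
external_metabolites <- function(network) {
  network$metabolites$id[!network$metabolites$is_internal]
}

#' Registered reverse-direction reaction pairs
#'
#' The set of unordered pairs of reactions that are reverses of each other
#' (created by [split_reversible()] or declared directly via `reverse_of`).
#' At most one member of each pair may carry flux in a steady-state
#' distribution.
#'
#' @param network a `metabolic_network`.
#' @return a tibble with columns `fwd`, `rev` (one row per unordered pair,
#'   `fwd < rev` lexicographically).
#' @export
reverse_pairs <- function(network) {
  rx <- network$reactions
  paired <- rx[!is.na(rx$reverse_of), c("id", "reverse_of")]
  if (nrow(paired) == 0) {
    return(tibble(fwd = character(), rev = character()))
  }
  a <- pmin(paired$id, paired$reverse_of)
  b <- pmax(paired$id, paired$reverse_of)
  distinct(tibble(fwd = a, rev = b))
}

#' Stoichiometry of one reaction as a named vector
#' @keywords internal
reaction_stoich <- function(network, reaction) {
  s <- network$stoichiometry[network$stoichiometry$reaction == reaction, ]
  setNames(s$coef, s$metabolite)
}

#' Split reversible reactions into irreversible direction pairs
#'
#' Every reaction flagged `reversible` is replaced by two irreversible
#' reactions, `<id>__fwd` (original stoichiometry) and `<id>__rev` (negated
#' stoichiometry), registered as reverses of each other; irreversible
#' reactions pass through unchanged.  After splitting all fluxes are
#' non-negative and the reverse-pair set drives the mutual-exclusion
#' constraint of the path model.
#'
#' @param network a `metabolic_network` (possibly with reversible flags).
#' @return a `metabolic_network` with no reversible flags set.
#' @examples
#' net <- metabolic_network(
#'   metabolites = tibble::tibble(id = c("A", "B"), is_internal = TRUE),
#'   reactions = tibble::tibble(id = "isom",
#'                              stoichiometry = list(c(A = -1, B = 1)),
#'                              reversible = TRUE))
#' split_reversible(net)
#' @export
split_reversible <- function(network) {
  rx <- network$reactions
  if (!any(rx$reversible)) return(network)
  out <- purrr::pmap(rx, function(id, reversible, reverse_of) {
    s <- reaction_stoich(network, id)
    if (!reversible) {
      return(tibble(id = id, stoichiometry = list(s),
                    reversible = FALSE, reverse_of = reverse_of))
    }
    if (!is.na(reverse_of)) {
      abort(paste0("reaction ", id, " is both reversible and paired"))
    }
    new_ids <- paste0(id, c("__fwd", "__rev"))
    tibble(
      id = new_ids,
      stoichiometry = list(s, -s),
      reversible = FALSE,
      reverse_of = rev(new_ids)
    )
  })
  metabolic_network(network$metabolites, dplyr::bind_rows(out))
}

#' Define a growth medium
#'
#' The growth medium is the set of external metabolites the network is allowed
#' to consume (net uptake).  External metabolites outside the medium may only
#' be net produced; internal metabolites are always balanced.
#'
#' @param consumable character vector of external metabolite ids.
#' @param network optional `metabolic_network` to validate against.
#' @return a character vector of class `cfp_medium`.
#' @export
medium <- function(consumable, network = NULL) {
  consumable <- unique(as.character(consumable))
  if (!is.null(network)) {
    ext <- external_metabolites(network)
    bad <- setdiff(consumable, ext)
    if (length(bad)) {
      abort(paste0("medium metabolite is not an external metabolite of the ",
                   "network: ", bad[1]))
    }
  }
  structure(consumable, class = c("cfp_medium", "character"))
}
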