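#' Tidy a result set into one row per path
#'
#' @param x a `cfp_result_set`.
#' @param ... unused.
#' @return a tibble with columns `k`, `length`, `node_sequence` (arrow
#'   separated), `n_active` and `active_reactions` (comma separated).
#' @export
tidy.cfp_result_set <- function(x, ...) {
  if (length(x$paths) == 0) {
    return(tibble(k = integer(), length = integer(),
                  node_sequence = character(), n_active = integer(),
                  active_reactions = character()))
  }
  purrr::imap(x$paths, function(p, k) {
    tibble(k = k, length = p$length,
           node_sequence = paste(p$node_sequence, collapse = "->"),
           n_active = length(p$active_reactions),
           active_reactions = paste(sort(p$active_reactions),
                                    collapse = ","))
  }) |> dplyr::bind_rows()
}

#' One-row summary of a result set
#'
#' @param x a `cfp_result_set`.
#' @param ... unused.
#' @export
glance.cfp_result_set <- function(x, ...) {
  lens <- purrr::map_int(x$paths, ~ .x$length)
  tibble(
    source = x$query$source %||% NA_character_,
    target = x$query$target %||% NA_character_,
    k_requested = x$query$k %||% NA_integer_,
    n_paths = length(x$paths),
    exhausted = x$exhausted,
    min_length = if (length(lens)) min(lens) else NA_integer_,
    max_length = if (length(lens)) max(lens) else NA_integer_,
    use_stoichiometry = x$query$use_stoichiometry %||% NA
  )
}

#' Tidy a flux path into one row per reaction
#'
#' @param x a `flux_path`.
#' @param ... unused.
#' @return tibble with `reaction`, `flux`, `active`, and `on_path` (does the
#'   reaction support one of the path's arcs? only meaningful when the
#'   originating graph is supplied as `graph =`).
#' @param graph optional `metabolite_graph` used to classify reactions as
#'   on-path.
#' @export
tidy.flux_path <- function(x, graph = NULL, ...) {
  rxns <- names(x$fluxes)
  on_path <- if (!is.null(graph)) {
    purrr::map_lgl(rxns, function(r) {
      any(purrr::map2_lgl(x$arcs$from, x$arcs$to,
                          ~ r %in% arc_support(graph, .x, .y)))
    })
  } else NA
  tibble(reaction = rxns, flux = unname(x$fluxes),
         active = rxns %in% x$active_reactions, on_path = on_path)
}

#' @rdname tidy.cfp_result_set
#' @export
tidy.connectivity_curve <- function(x, ...) {
  tibble(steps = x$steps, n_connected = x$n_connected,
         source = attr(x, "source"),
         use_stoichiometry = attr(x, "use_stoichiometry"))
}

#' @rdname glance.cfp_result_set
#' @export
glance.connectivity_curve <- function(x, ...) {
  tibble(source = attr(x, "source"),
         total_reachable = attr(x, "total_reachable"),
         max_steps = if (nrow(x)) max(x$steps) else 0L,
         use_stoichiometry = attr(x, "use_stoichiometry"))
}

#' Plot a connectivity curve
#'
#' @param object a `connectivity_curve` (or a list of them, which are
#'   overlaid — e.g. with and without stoichiometry).
#' @param ... further curves to overlay.
#' @return a ggplot.
#' @export
autoplot.connectivity_curve <- function(object, ...) {
  curves <- c(list(object), purrr::keep(list(...), ~ inherits(
    .x, "connectivity_curve")))
  df <- purrr::map(curves, tidy) |> dplyr::bind_rows() |>
    mutate(constraints = ifelse(.data$use_stoichiometry,
                                "with stoichiometry", "without stoichiometry"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$steps, y = .data$n_connected,
                                   colour = .data$constraints)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "reaction steps from source",
                  y = "metabolites connected",
                  colour = NULL,
                  title = paste0("Connectivity of ",
                                 attr(object, "source"))) +
    ggplot2::theme_minimal()
}

#' Plot arc or metabolite frequencies over K shortest paths
#'
#' @param object a `cfp_frequency`.
#' @param type `"arcs"` or `"metabolites"`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cfp_frequency <- function(object, type = c("arcs", "metabolites"),
                                   ...) {
  type <- match.arg(type)
  if (type == "arcs") {
    df <- object$arcs |>
      mutate(label = paste(.data$from, .data$to, sep = " → "))
  } else {
    df <- object$metabolites |> rename(label = "metabolite")
  }
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$label,
                                                      .data$count),
                                   y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = paste0("appearances among ", object$n_paths,
                                       " paths")) +
    ggplot2::theme_minimal()
}

#' Plot path lengths across an enumeration
#'
#' @param object a `cfp_result_set`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cfp_result_set <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$length)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "k (enumeration order)", y = "path length (arcs)") +
    ggplot2::theme_minimal()
}
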