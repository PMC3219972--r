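#' Minimal mixed-integer linear programming facade
#'
#' The carbon-flux-path formulation is expressed against a deliberately small
#' solver surface: create variables (binary or continuous, with bounds and
#' objective coefficients), add linear constraints, minimise, read back values
#' and a status in `{optimal, infeasible, unbounded, limit, error}`.  Any MILP
#' engine offering these primitives can stand behind it; the bundled backend
#' serialises problems to JSON and solves them with HiGHS through
#' `scipy.optimize.milp` in a Python subprocess, which keeps runs
#' single-threaded and deterministic.  Problems are independent, so batches
#' are solved in one subprocess call.
#'
#' @param name short name for the model (used in error messages).
#' @return `milp_new()` returns an empty model (an environment of class
#'   `milp_model`).
#' @keywords internal
milp_new <- function(name = "milp") {
  mp <- new.env(parent = emptyenv())
  mp$name <- name
  mp$nvar <- 0L
  mp$var_names <- character()
  mp$obj <- numeric()
  mp$lb <- numeric()
  mp$ub <- numeric()
  mp$integer <- integer()
  mp$idx <- new.env(parent = emptyenv())
  mp$con_i <- list()
  mp$con_j <- list()
  mp$con_x <- list()
  mp$cl <- numeric()
  mp$cu <- numeric()
  mp$ncon <- 0L
  class(mp) <- "milp_model"
  mp
}

#' Add variables to a MILP model
#'
#' @param mp a `milp_model`.
#' @param names unique variable names.
#' @param obj,lb,ub objective coefficients and bounds, recycled to length.
#' @param type `"binary"` or `"continuous"`.
#' @return variable indices, invisibly.
#' @keywords internal
milp_add_variables <- function(mp, names, obj = 0, lb = 0, ub = Inf,
                               type = c("continuous", "binary")) {
  type <- match.arg(type)
  n <- length(names)
  if (anyDuplicated(names)) abort("duplicate variable names in MILP model")
  for (nm in names) {
    if (!is.null(mp$idx[[nm]])) abort(paste0("variable already defined: ", nm))
  }
  if (type == "binary") {
    lb <- 0
    ub <- 1
  }
  idx <- mp$nvar + seq_len(n)
  mp$var_names <- c(mp$var_names, names)
  mp$obj <- c(mp$obj, rep_len(obj, n))
  mp$lb <- c(mp$lb, rep_len(lb, n))
  mp$ub <- c(mp$ub, rep_len(ub, n))
  mp$integer <- c(mp$integer, rep_len(if (type == "binary") 1L else 0L, n))
  for (k in seq_len(n)) mp$idx[[names[k]]] <- idx[k]
  mp$nvar <- mp$nvar + n
  invisible(idx)
}

milp_var_index <- function(mp, names) {
  idx <- vapply(names, function(nm) {
    i <- mp$idx[[nm]]
    if (is.null(i)) abort(paste0("unknown MILP variable: ", nm))
    i
  }, integer(1), USE.NAMES = FALSE)
  idx
}

#' Add a linear constraint
#'
#' @param vars variable names with nonzero coefficients.
#' @param coefs coefficients, same length as `vars`.
#' @param sense one of `"<="`, `">="`, `"=="`.
#' @param rhs right-hand side.
#' @keywords internal
milp_add_constraint <- function(mp, vars, coefs, sense, rhs) {
  stopifnot(length(vars) == length(coefs))
  sense <- match.arg(sense, c("<=", ">=", "=="))
  row <- mp$ncon + 1L
  j <- milp_var_index(mp, vars)
  mp$con_i[[row]] <- rep.int(row, length(j))
  mp$con_j[[row]] <- j
  mp$con_x[[row]] <- as.numeric(coefs)
  mp$cl[row] <- if (sense == "<=") -Inf else rhs
  mp$cu[row] <- if (sense == ">=") Inf else rhs
  mp$ncon <- row
  invisible(row)
}

#' Fix variable bounds after creation
#' @keywords internal
milp_set_bounds <- function(mp, names, lb = NULL, ub = NULL) {
  j <- milp_var_index(mp, names)
  if (!is.null(lb)) mp$lb[j] <- rep_len(lb, length(j))
  if (!is.null(ub)) mp$ub[j] <- rep_len(ub, length(j))
  invisible(mp)
}

milp_payload <- function(mp, time_limit = NULL) {
  sent <- function(v) {
    v[v == Inf] <- 1e30
    v[v == -Inf] <- -1e30
    v
  }
  list(
    n = mp$nvar,
    obj = mp$obj,
    lb = sent(mp$lb),
    ub = sent(mp$ub),
    integrality = mp$integer,
    A = list(
      i = unlist(mp$con_i) %||% integer(),
      j = unlist(mp$con_j) %||% integer(),
      x = unlist(mp$con_x) %||% numeric()
    ),
    cl = sent(mp$cl),
    cu = sent(mp$cu),
    time_limit = time_limit
  )
}

cfpath_python <- function() {
  py <- getOption("cfpath.python")
  if (!is.null(py)) return(py)
  for (cand in c("python3", "python")) {
    path <- Sys.which(cand)
    if (nzchar(path)) return(unname(path))
  }
  abort("no python interpreter found on PATH (needed for the MILP backend)")
}

solver_script <- function() {
  path <- system.file("python", "milp_solve.py", package = "cfpath")
  if (!nzchar(path)) abort("bundled MILP backend script not found")
  path
}

#' Solve a batch of MILP models in one backend call
#'
#' @param models list of `milp_model`s.
#' @param time_limit optional per-problem time limit in seconds.
#' @return list with one element per model: `status`, `objective`, and
#'   `values` (named numeric vector, `NULL` unless status is `optimal`).
#' @keywords internal
milp_solve_batch <- function(models, time_limit = NULL) {
  if (length(models) == 0) return(list())
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  payload <- list(problems = lapply(models, milp_payload, time_limit = time_limit))
  jsonlite::write_json(payload, infile, auto_unbox = TRUE, digits = NA,
                       null = "null")
  code <- suppressWarnings(system2(
    cfpath_python(), c(shQuote(solver_script()), shQuote(infile), shQuote(outfile)),
    stdout = NULL, stderr = ""
  ))
  if (code != 0L || !file.exists(outfile)) {
    abort(paste0("MILP backend failed (exit status ", code, ")"))
  }
  res <- jsonlite::read_json(outfile, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  purrr::map2(res$results, models, function(r, mp) {
    values <- NULL
    if (identical(r$status, "optimal")) {
      values <- setNames(unlist(r$x), mp$var_names)
    }
    list(status = r$status,
         objective = if (is.null(r$objective)) NA_real_ else r$objective,
         values = values)
  })
}

#' Solve a single MILP model
#' @keywords internal
milp_solve <- function(mp, time_limit = NULL) {
  milp_solve_batch(list(mp), time_limit = time_limit)[[1]]
}

#' @export
print.milp_model <- function(x, ...) {
  cat("<milp_model '", x$name, "': ", x$nvar, " variables (",
      sum(x$integer), " integer), ", x$ncon, " constraints>\n", sep = "")
  invisible(x)
}
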