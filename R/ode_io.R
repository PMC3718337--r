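## Restricted XPPAUT ".ode" dialect reader/writer.
##
## Supported lines: `par name=value[, ...]`, `init name=value[, ...]`,
## `aux name=expression`, `number name=value`, derivative definitions
## (`dX/dt = expr` or `X' = expr`), comments (`#`), and `done`.  Other
## XPP directives (e.g. `@ ...` option lines) are warned about and
## skipped.  Expressions use ordinary arithmetic plus `sqrt`, `exp`,
## `log`, `abs`, `min`, `max` and `^`.

.ode_funs <- c("sqrt", "exp", "log", "abs", "min", "max", "pmax", "pmin")

#' Read a restricted-dialect .ode file
#'
#' @param file path to the .ode file.
#' @return a list with elements `params` (a [switch_params] of the `par`
#'   and `number` assignments) and `model` (an `ode_file_model`: `init`,
#'   `aux` and `odes` expression text in definition order).  Every symbol
#'   used in an expression must be a parameter, a state variable, an
#'   auxiliary, or a known function; anything else is an error naming the
#'   symbol.
#' @export
read_ode <- function(file) {
  lines <- readLines(file, warn = FALSE)
  pars <- numeric()
  init <- numeric()
  aux <- character()
  odes <- character()

  split_assignments <- function(body, lineno) {
    parts <- strsplit(body, ",", fixed = TRUE)[[1]]
    out <- numeric()
    for (part in parts) {
      kv <- strsplit(part, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2)
        stop("syntax error on line ", lineno, ": expected name=value",
             call. = FALSE)
      key <- trimws(kv[1])
      val <- suppressWarnings(as.numeric(trimws(kv[2])))
      if (!nzchar(key) || is.na(val))
        stop("syntax error on line ", lineno, ": bad assignment '",
             trimws(part), "'", call. = FALSE)
      out[key] <- val
    }
    out
  }

  for (ln in seq_along(lines)) {
    line <- sub("#.*$", "", lines[ln])
    line <- trimws(line)
    if (!nzchar(line)) next
    low <- tolower(line)
    if (low == "done") break
    if (grepl("^(par|param|p)\\s", low)) {
      pars <- c(pars, split_assignments(sub("^\\S+\\s+", "", line), ln))
    } else if (grepl("^(init)\\s", low)) {
      init <- c(init, split_assignments(sub("^\\S+\\s+", "", line), ln))
    } else if (grepl("^number\\s", low)) {
      pars <- c(pars, split_assignments(sub("^\\S+\\s+", "", line), ln))
    } else if (grepl("^aux\\s", low)) {
      body <- sub("^\\S+\\s+", "", line)
      eq <- regexpr("=", body, fixed = TRUE)
      if (eq < 0) stop("syntax error on line ", ln, ": aux needs '='",
                       call. = FALSE)
      aux[trimws(substr(body, 1, eq - 1))] <-
        trimws(substr(body, eq + 1, nchar(body)))
    } else if (grepl("^d[A-Za-z_][A-Za-z0-9_]*/dt\\s*=", line)) {
      var <- sub("^d([A-Za-z_][A-Za-z0-9_]*)/dt\\s*=.*$", "\\1", line)
      odes[var] <- trimws(sub("^[^=]*=", "", line))
    } else if (grepl("^[A-Za-z_][A-Za-z0-9_]*'\\s*=", line)) {
      var <- sub("^([A-Za-z_][A-Za-z0-9_]*)'.*$", "\\1", line)
      odes[var] <- trimws(sub("^[^=]*=", "", line))
    } else if (grepl("^[@!]", line) || grepl("^[a-z]+\\s", low)) {
      warning("skipping unsupported directive on line ", ln, ": ",
              lines[ln], call. = FALSE)
    } else {
      stop("syntax error on line ", ln, ": '", lines[ln], "'",
           call. = FALSE)
    }
  }
  if (!length(odes))
    stop("no derivative definitions found in ", file, call. = FALSE)

  known <- c(names(pars), names(init), names(odes), names(aux))
  for (nm in c(names(aux), names(odes))) {
    expr_text <- if (nm %in% names(aux)) aux[[nm]] else odes[[nm]]
    e <- tryCatch(parse(text = expr_text)[[1]],
                  error = function(err)
                    stop("syntax error in expression for '", nm, "': ",
                         expr_text, call. = FALSE))
    undef <- setdiff(all.vars(e), known)
    if (length(undef))
      stop("undefined symbol '", undef[1], "' in expression for '", nm,
           "'", call. = FALSE)
  }

  model <- structure(list(init = init, aux = aux, odes = odes),
                     class = "ode_file_model")
  list(params = switch_params("custom", pars), model = model)
}

#' @export
print.ode_file_model <- function(x, ...) {
  cat("ode_file_model:", length(x$odes), "ODEs (",
      paste(names(x$odes), collapse = ", "), "),",
      length(x$aux), "aux definitions\n")
  invisible(x)
}

#' Right-hand side function of a parsed .ode model
#'
#' Builds an evaluator for the parsed expressions: auxiliaries are
#' evaluated in definition order, then the derivatives.  Used to check a
#' parsed file against a built-in model by comparing RHS values at
#' randomised states.
#'
#' @param parsed result of [read_ode] (or its `model` element).
#' @param params optional [switch_params]; defaults to the file's
#'   parameters when `parsed` is a full [read_ode] result.
#' @return `function(state)` returning the named derivative vector, with
#'   the state in the order of the file's derivative definitions.
#' @export
ode_rhs_function <- function(parsed, params = NULL) {
  if (inherits(parsed, "ode_file_model")) {
    model <- parsed
    if (is.null(params)) stop("params required", call. = FALSE)
  } else {
    model <- parsed$model
    if (is.null(params)) params <- parsed$params
  }
  pvals <- as.list(params$values)
  aux_exprs <- lapply(model$aux, function(s) parse(text = s)[[1]])
  ode_exprs <- lapply(model$odes, function(s) parse(text = s)[[1]])
  vars <- names(model$odes)
  function(state) {
    env <- list2env(pvals, parent = baseenv())
    for (f in .ode_funs) assign(f, get(f, baseenv()), envir = env)
    sv <- as.numeric(state)
    for (i in seq_along(vars)) assign(vars[i], sv[i], envir = env)
    for (nm in names(aux_exprs))
      assign(nm, eval(aux_exprs[[nm]], env), envir = env)
    stats::setNames(vapply(ode_exprs, eval, numeric(1), envir = env), vars)
  }
}

#' Write a model to the restricted .ode dialect
#'
#' Emits `par`, `init`, `aux` and derivative lines loadable by XPPAUT and
#' by [read_ode].  Algebraic closures (e.g. the TQSSA complex) are
#' written as aux definitions.
#'
#' @param model a `switch_model` (all built-in constructors provide the
#'   required expression text).
#' @param params optional [switch_params]; defaults to the build-time
#'   values.
#' @param init full initial state (defaults to zeros).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ode <- function(model, params = NULL, init = NULL, path) {
  p <- model_plist(model, params)
  if (!length(model$ode_d))
    stop("model '", model$name, "' has no serialisable RHS expressions",
         call. = FALSE)
  if (is.null(init)) init <- stats::setNames(rep(0, length(model$vars)),
                                             model$vars)
  num <- function(v) sprintf("%.17g", v)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("# ", model$name, " model")
  wl("# units: U, concentration (approx. 10 nM); T, time (approx. 1 min)")
  for (nm in model$required) wl("par ", nm, "=", num(p[[nm]]))
  for (i in seq_along(model$vars))
    wl("init ", model$vars[i], "=", num(as.numeric(init)[i]))
  for (nm in names(model$ode_aux)) wl("aux ", nm, "=", model$ode_aux[[nm]])
  for (nm in names(model$ode_d)) wl("d", nm, "/dt=", model$ode_d[[nm]])
  wl("done")
  invisible(path)
}
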