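## Parameter sets for the switch models.
##
## Units follow the models' convention: U, one concentration unit
## (approx. 10 nM); T, one time unit (approx. 1 min).  Bimolecular rate
## constants are U^-1 T^-1, unimolecular T^-1, zeroth-order synthesis
## U T^-1, concentrations and Michaelis constants U.

.unit_table <- c(
  k_as1 = "1/(U T)", k_as2 = "1/(U T)", k_di1 = "1/T", k_di2 = "1/T",
  k_cat1 = "1/T", k_cat2 = "1/T", k_dm1 = "1/T", k_dm2 = "1/T",
  A_T = "U", I_T = "U",
  k_m = "1/(U T)", K_m1 = "U",
  k_s = "U/T", k_d = "1/T", k_as_b = "1/(U T)", k_di_b = "1/T",
  k_p_b = "1/(U T)", k_dp = "1/T", k_cat_b = "1/T", ClbT = "U",
  k_as_n = "1/(U T)", k_di_n = "1/T", k_p_n = "1/(U T)", k_cat_n = "1/T",
  ClnT = "U",
  K_m = "U", k_u = "1/(U T)", k_du = "1/T", k_cat = "1/T", k_aNT = "1/T",
  X_tens = "-", k_ssec = "U/T", k_dsec = "1/T", k_dsec_apc = "1/(U T)",
  APCT = "U", Mad2T = "U",
  k_scyc = "U/T", k_dcyc = "1/T", k_dcyc_apc = "1/(U T)", k_an = "1/(U T)",
  k_inCAPP = "1/T", k_as = "1/(U T)", k_di = "1/T"
)

## Built-in presets.  Totals that the source tables leave "variable" carry
## neutral-state defaults (SIMM family: the engaged neutral point A_T = 1,
## I_T = 4).  APCT and Mad2T are not tabulated anywhere; the defaults
## APCT = 1 U and Mad2T = 2 U are this package's declared assumption,
## chosen so the mitotic-checkpoint models reproduce their published
## steady-state and release behaviour (see the methods vignette).
.presets <- list(
  simm = c(k_as1 = 100, k_as2 = 50, k_di1 = 0.5, k_di2 = 1,
           k_cat1 = 0.5, k_cat2 = 50, k_dm1 = 1, k_dm2 = 1,
           A_T = 1, I_T = 4),
  simm_star = c(k_as1 = 100, k_di1 = 0.5, k_cat1 = 0.5,
                k_dm1 = 1, k_dm2 = 1, k_m = 50, K_m1 = 0.01,
                A_T = 1, I_T = 4),
  sic_clb = c(k_s = 0.2, k_d = 0.05, k_as_b = 100, k_di_b = 0.01,
              k_p_b = 20, k_dp = 0.5, k_cat_b = 0.5, ClbT = 1),
  cln_sic_clb = c(k_s = 0.2, k_d = 0.05, k_as_b = 100, k_di_b = 0.01,
                  k_p_b = 20, k_dp = 0.5, k_cat_b = 0.5,
                  k_as_n = 2, k_di_n = 2, k_p_n = 0.1, k_cat_n = 2,
                  ClbT = 1, ClnT = 0.5),
  mcc_apc = c(K_m = 0.01, k_u = 10, k_du = 5, k_cat = 0.5, k_aNT = 1,
              X_tens = 0, k_ssec = 0.1, k_dsec = 0.05, k_dsec_apc = 0.5,
              APCT = 1, Mad2T = 2),
  cycb_mcc_apc = c(K_m = 0.01, k_u = 10, k_du = 5, k_cat = 0.5,
                   k_aNT = 5, X_tens = 0,
                   k_ssec = 0.1, k_dsec = 0.05, k_dsec_apc = 0.5,
                   k_scyc = 0.01, k_dcyc = 0.01, k_dcyc_apc = 1,
                   k_an = 1, k_inCAPP = 2, k_as = 100, k_di = 0.5,
                   APCT = 1, Mad2T = 2)
)

#' Parameter sets for the switch models
#'
#' Construct a named set of rate constants and total concentrations, either
#' from a built-in preset or from scratch.  Presets carry exactly the
#' symbols of their model; looking up a symbol that is not present is an
#' error, never a silent default.
#'
#' Composite rate constants that the models use as a single number are
#' stored as printed: `k_aNT` is the product of the Mad2-activation rate
#' constant and the total kinetochore number, and `k_inCAPP` the product of
#' the centromere-inactivation rate constant and the counteracting
#' phosphatase concentration.
#'
#' The totals `APCT` and `Mad2T` of the mitotic-checkpoint models are not
#' part of the published rate-constant tables.  The preset defaults
#' (`APCT = 1`, `Mad2T = 2`, in U) are assumptions of this package (see
#' the methods vignette) and can be overridden like any other value.
#'
#' @param preset one of `"simm"`, `"simm_star"`, `"sic_clb"`,
#'   `"cln_sic_clb"`, `"mcc_apc"`, `"cycb_mcc_apc"`, or `"custom"`.
#' @param ... named numeric overrides (or, for `"custom"`, the full set of
#'   values).
#' @return an object of class `switch_params`: a list with elements
#'   `name`, `values` (named numeric vector) and `units`.
#' @examples
#' p <- switch_params("simm", A_T = 2, I_T = 6)
#' param_value(p, "k_as1")
#' @export
switch_params <- function(preset = "custom", ...) {
  over <- c(...)
  if (length(over) && (is.null(names(over)) || any(names(over) == "")))
    stop("parameter overrides must be named", call. = FALSE)
  if (identical(preset, "custom")) {
    values <- if (is.null(over)) numeric(0) else over
  } else {
    if (!preset %in% names(.presets))
      stop("unknown preset '", preset, "'; available: ",
           paste(names(.presets), collapse = ", "), call. = FALSE)
    values <- .presets[[preset]]
    extra <- setdiff(names(over), names(values))
    if (length(extra))
      stop("symbols not in preset '", preset, "': ",
           paste(extra, collapse = ", "), call. = FALSE)
    values[names(over)] <- over
  }
  validate_params(values)
  units <- .unit_table[names(values)]
  names(units) <- names(values)
  units[is.na(units)] <- "?"
  structure(list(name = preset, values = values, units = units),
            class = "switch_params")
}

validate_params <- function(values) {
  if (!is.numeric(values)) stop("parameter values must be numeric", call. = FALSE)
  bad <- names(values)[!is.finite(values) | values < 0]
  if (length(bad))
    stop("parameter values must be finite and nonnegative: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if ("X_tens" %in% names(values) &&
      (values[["X_tens"]] < 0 || values[["X_tens"]] > 1))
    stop("X_tens must lie in [0, 1]", call. = FALSE)
  invisible(values)
}

#' Look up one parameter value
#'
#' @param params a [switch_params] object.
#' @param symbol parameter symbol.
#' @return the numeric value.  A missing symbol is an error.
#' @export
param_value <- function(params, symbol) {
  stopifnot(inherits(params, "switch_params"))
  if (!symbol %in% names(params$values))
    stop("parameter '", symbol, "' not present in set '", params$name, "'",
         call. = FALSE)
  unname(params$values[[symbol]])
}

#' Modify parameter values
#'
#' Returns a copy of `params` with the given values replaced or added.
#'
#' @param params a [switch_params] object.
#' @param ... named numeric replacements.
#' @export
set_params <- function(params, ...) {
  stopifnot(inherits(params, "switch_params"))
  over <- c(...)
  values <- params$values
  values[names(over)] <- over
  validate_params(values)
  units <- .unit_table[names(values)]
  names(units) <- names(values)
  units[is.na(units)] <- "?"
  structure(list(name = params$name, values = values, units = units),
            class = "switch_params")
}

#' Derived kinetic constants
#'
#' Computes the constants that are defined in terms of elementary rate
#' constants, for whichever parents are present in `params`:
#' `K_m1 = (k_di1 + k_cat1)/k_as1`, `K_m2 = (k_di2 + k_cat2)/k_as2`,
#' `k_m = k_cat2 * k_as2/(k_cat2 + k_di2)` (the mass-action rate constant
#' that replaces the second Michaelis-Menten step in the simplified
#' motif), and `K_m = (k_di + k_cat)/k_as`.
#'
#' @param params a [switch_params] object.
#' @return named numeric vector of the derivable constants.
#' @export
derived_constants <- function(params) {
  stopifnot(inherits(params, "switch_params"))
  v <- params$values
  out <- c()
  has <- function(...) all(c(...) %in% names(v))
  if (has("k_di1", "k_cat1", "k_as1"))
    out["K_m1"] <- (v[["k_di1"]] + v[["k_cat1"]]) / v[["k_as1"]]
  if (has("k_di2", "k_cat2", "k_as2")) {
    out["K_m2"] <- (v[["k_di2"]] + v[["k_cat2"]]) / v[["k_as2"]]
    out["k_m"] <- v[["k_cat2"]] * v[["k_as2"]] / (v[["k_cat2"]] + v[["k_di2"]])
  }
  if (has("k_di", "k_cat", "k_as"))
    out["K_m"] <- (v[["k_di"]] + v[["k_cat"]]) / v[["k_as"]]
  out
}

#' @export
print.switch_params <- function(x, ...) {
  cat("Parameter set '", x$name, "' (U ~ 10 nM, T ~ 1 min)\n", sep = "")
  df <- data.frame(value = unname(x$values), unit = unname(x$units),
                   row.names = names(x$values))
  print(df)
  invisible(x)
}

#' List the built-in parameter presets
#'
#' @return character vector of preset names.
#' @export
preset_names <- function() names(.presets)

## internal: plain named list for fast rhs evaluation
param_list <- function(params) as.list(params$values)
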