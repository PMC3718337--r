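## Robustness analyses: partial processivity of the dual modification,
## disengagement-threshold scans, and the joint
## sensitivity-and-irreversibility criterion of the CycB-coupled model.

#' SIMM variant with partially processive dual modification
#'
#' A fraction `p_frac` of the catalytic turnover of the tight A:I complex
#' proceeds processively (releasing the doubly modified form directly,
#' `A:I -> A + IMM`), while `1 - p_frac` releases the singly modified
#' form as in the distributive motif.  `p_frac = 0` reduces exactly to
#' [build_simm].  Bistability survives moderate processivity (around 20%)
#' but is lost as `p_frac` approaches 1, because processive modification
#' removes the distributive step the double-negative feedback needs.
#'
#' @param params a [switch_params] with the SIMM symbols.
#' @param p_frac processive fraction in \[0, 1\].
#' @return a `switch_model`.
#' @export
processive_fraction_model <- function(params, p_frac) {
  if (!is.numeric(p_frac) || length(p_frac) != 1 ||
      !is.finite(p_frac) || p_frac < 0 || p_frac > 1)
    stop("p_frac must be a number in [0, 1]", call. = FALSE)
  p <- need_params(params, c("k_as1", "k_as2", "k_di1", "k_di2", "k_cat1",
                             "k_cat2", "k_dm1", "k_dm2", "A_T", "I_T"))
  simm_core(params, p, p_processive = p_frac,
            name = if (p_frac == 0) "simm" else "simm_processive")
}

#' Scan the disengagement threshold over rate-constant perturbations
#'
#' For each symbol and each point of a multiplicative grid spanning
#' `[value/fold_range, value*fold_range]`, recomputes the checkpoint
#' disengagement threshold (the fold at which the engaged branch of the
#' MCC-APC model disappears as `X_tens` increases) via [find_threshold].
#' Grid points where the engaged branch never disappears in `[0, 1]` (or
#' never exists) are marked instead of failing.
#'
#' @param params a [switch_params] with preset `"mcc_apc"` symbols.
#' @param symbols rate constants to scan (each perturbed singly).
#' @param fold_range multiplicative half-range (default 2-fold up/down).
#' @param n_grid grid points per symbol (log-spaced).
#' @return a `param_scan` object: data.frame `grid` with columns
#'   `symbol`, `value`, `multiplier`, `X_disengage`, `note`; summary in
#'   `summary` (min/max over evaluated points).
#' @export
scan_disengage_threshold <- function(params = switch_params("mcc_apc"),
                                     symbols = c("K_m", "k_u", "k_du",
                                                 "k_cat", "k_aNT"),
                                     fold_range = 2, n_grid = 5) {
  stopifnot(fold_range >= 1, n_grid >= 1)
  rows <- list()
  for (sym in symbols) {
    base <- param_value(params, sym)
    mult <- if (n_grid == 1) 1
            else exp(seq(-log(fold_range), log(fold_range),
                         length.out = n_grid))
    for (mu in mult) {
      pp <- set_params(params, X_tens = 0)
      pp <- set_params(pp, stats::setNames(base * mu, sym))
      m <- build_mcc_apc(pp)
      fold <- tryCatch(
        find_threshold(m, sweep_symbol = "X_tens", from = 0, to = 1,
                       start_label = "engaged", n_coarse = 20),
        error = function(e) NULL)
      rows[[length(rows) + 1]] <- data.frame(
        symbol = sym, value = base * mu, multiplier = mu,
        X_disengage = if (!is.null(fold) && fold$found) fold$value
                      else NA_real_,
        note = if (is.null(fold)) "no engaged state"
               else if (fold$found) "" else "monostable",
        stringsAsFactors = FALSE)
    }
  }
  grid <- do.call(rbind, rows)
  ok <- !is.na(grid$X_disengage)
  structure(list(
    quantity = "X_disengage",
    grid = grid,
    summary = list(
      min = if (any(ok)) min(grid$X_disengage[ok]) else NA_real_,
      max = if (any(ok)) max(grid$X_disengage[ok]) else NA_real_,
      n_evaluated = sum(ok), n_marked = sum(!ok))
  ), class = "param_scan")
}

#' @export
print.param_scan <- function(x, ...) {
  cat("parameter scan of", x$quantity, "\n")
  print(x$grid, row.names = FALSE)
  cat(sprintf("summary: min %.4g, max %.4g (%d evaluated, %d marked)\n",
              x$summary$min, x$summary$max, x$summary$n_evaluated,
              x$summary$n_marked))
  invisible(x)
}

#' Export a parameter scan as TSV
#' @param x a `param_scan`.
#' @param path output file path.
#' @export
write_scan_tsv <- function(x, path) {
  utils::write.table(x$grid, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Map the sensitivity-and-irreversibility region of the CycB model
#'
#' Declared operationalisation of the two checkpoint requirements for
#' [build_cycb_mcc_apc]: *sensitivity* -- the engaged branch persists
#' until `X_disengage > 0.95`; *irreversibility* -- after disengagement
#' there is no re-engagement fold for `X_tens` anywhere in `[0, 1]`
#' (the disengaged branch survives the whole down-sweep).  Each symbol is
#' perturbed singly on a multiplicative grid; the fraction of grid points
#' passing both criteria measures the robustness of the mechanism.
#'
#' @param params a [switch_params] with preset `"cycb_mcc_apc"` symbols.
#' @param symbols rate constants to scan.
#' @param fold_range multiplicative half-range.
#' @param n_grid grid points per symbol.
#' @param sensitivity_min threshold defining sensitivity.
#' @return a `param_scan` with logical columns `sensitive`,
#'   `irreversible`, `passes`; `summary$fraction_passing`.
#' @export
sensitivity_irreversibility_region <- function(
    params = switch_params("cycb_mcc_apc"),
    symbols = c("k_u", "k_du", "k_cat", "k_aNT", "k_an", "k_inCAPP"),
    fold_range = 2, n_grid = 3, sensitivity_min = 0.95) {
  stopifnot(fold_range >= 1, n_grid >= 1)
  rows <- list()
  for (sym in symbols) {
    base <- param_value(params, sym)
    mult <- if (n_grid == 1) 1
            else exp(seq(-log(fold_range), log(fold_range),
                         length.out = n_grid))
    for (mu in mult) {
      pp <- set_params(params, stats::setNames(base * mu, sym))
      res <- tryCatch(
        cycb_criteria(pp, sensitivity_min),
        error = function(e) list(sens = NA, irr = NA, xd = NA_real_))
      rows[[length(rows) + 1]] <- data.frame(
        symbol = sym, value = base * mu, multiplier = mu,
        X_disengage = res$xd, sensitive = res$sens,
        irreversible = res$irr,
        passes = isTRUE(res$sens) && isTRUE(res$irr),
        stringsAsFactors = FALSE)
    }
  }
  grid <- do.call(rbind, rows)
  structure(list(
    quantity = "sensitivity+irreversibility",
    grid = grid,
    summary = list(fraction_passing = mean(grid$passes),
                   n = nrow(grid))
  ), class = "param_scan")
}

## internal: evaluate both criteria at one parameter point
cycb_criteria <- function(pp, sensitivity_min) {
  m <- build_cycb_mcc_apc(set_params(pp, X_tens = 0))
  up <- find_threshold(m, sweep_symbol = "X_tens", from = 0, to = 1,
                       start_label = "engaged", n_coarse = 20)
  sens <- up$found && up$value > sensitivity_min
  ## down-sweep from the disengaged state: irreversible iff no fold
  down <- find_threshold(m, sweep_symbol = "X_tens", from = 1, to = 0,
                         start_label = "disengaged", n_coarse = 20)
  irr <- !down$found
  list(sens = sens, irr = irr, xd = if (up$found) up$value else NA_real_)
}
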