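## Model definitions: mass-action ODE systems for the bistable switch
## motifs and their cell-cycle instantiations.
##
## Each constructor returns a `switch_model` object holding the
## right-hand side (RHS), the linear conservation laws, the variable
## elimination used for root finding (conserved directions are removed by
## substituting the conservation identities, so Newton iterations act on a
## nonsingular reduced system), an admissibility test, a checkpoint-state
## classifier, and the expression text used for .ode export.

new_switch_model <- function(name, vars, required, rhs, p,
                             conserved = NULL,
                             free_names = vars,
                             lift = NULL,
                             box, activity, observable,
                             derived = NULL,
                             guesses,
                             ode_aux = character(),
                             ode_d = character(),
                             total_state = NULL,
                             engaged_below = 0.1, disengaged_above = 0.5) {
  if (is.null(lift)) lift <- function(y, p) y
  structure(list(
    name = name, vars = vars, required = required, rhs = rhs,
    params = p,
    conserved = conserved, free_names = free_names,
    free_idx = match(free_names, vars), lift = lift,
    box = box, activity = activity, observable = observable,
    derived = derived, guesses = guesses,
    ode_aux = ode_aux, ode_d = ode_d,
    total_state = total_state,
    engaged_below = engaged_below, disengaged_above = disengaged_above
  ), class = "switch_model")
}

need_params <- function(params, symbols) {
  stopifnot(inherits(params, "switch_params"))
  missing <- setdiff(symbols, names(params$values))
  if (length(missing))
    stop("missing parameter symbol(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  validate_params(params$values)
  param_list(params)
}

#' @export
print.switch_model <- function(x, ...) {
  cat("<switch_model> ", x$name, "\n", sep = "")
  cat("  state:     ", paste(x$vars, collapse = ", "), "\n", sep = "")
  cat("  reduced:   ", paste(x$free_names, collapse = ", "), "\n", sep = "")
  cat("  parameters:", paste(x$required, collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate a model right-hand side
#'
#' @param model a `switch_model`.
#' @param state numeric vector in the order of `model$vars` (names, if
#'   present, are checked).
#' @param params a [switch_params] object; defaults to the set the model
#'   was built with.
#' @return named derivative vector in U/T.
#' @export
model_rhs <- function(model, state, params = NULL) {
  p <- if (is.null(params)) model$params else need_params(params, model$required)
  x <- as.numeric(state)
  if (length(x) != length(model$vars))
    stop("state must have ", length(model$vars), " components (",
         paste(model$vars, collapse = ", "), ")", call. = FALSE)
  if (!is.null(names(state)) && !identical(names(state), model$vars))
    x <- as.numeric(state[model$vars])
  stats::setNames(model$rhs(x, p), model$vars)
}

#' Conserved quantities of a model at a state
#'
#' Returns the values of the model's linear conservation laws (e.g. total
#' enzyme and total substrate pools).  Along any trajectory these are
#' constant; `conservation_rate` returns their time-derivatives under the
#' RHS, which are zero to machine precision.
#'
#' @inheritParams model_rhs
#' @return named numeric vector (length 0 for models without conservation
#'   laws, i.e. the open synthesis/degradation systems).
#' @export
conserved_quantities <- function(model, state, params = NULL) {
  p <- if (is.null(params)) model$params else need_params(params, model$required)
  if (is.null(model$conserved)) return(stats::setNames(numeric(0), character(0)))
  model$conserved(as.numeric(state), p)
}

#' @rdname conserved_quantities
#' @export
conservation_rate <- function(model, state, params = NULL) {
  p <- if (is.null(params)) model$params else need_params(params, model$required)
  if (is.null(model$conserved)) return(stats::setNames(numeric(0), character(0)))
  x <- as.numeric(state)
  f <- model$rhs(x, p)
  ## conserved quantities are linear in the state, so a directional
  ## difference along the RHS is exact for any step; an O(1) step avoids
  ## floating-point cancellation
  eps <- 1 / max(1, max(abs(f)))
  (model$conserved(x + eps * f, p) - model$conserved(x - eps * f, p)) / (2 * eps)
}

#' Classify a state as checkpoint engaged or disengaged
#'
#' The classifier uses the fraction of free (functional) activator:
#' engaged when it is below `model$engaged_below`, disengaged above
#' `model$disengaged_above`, intermediate otherwise.
#'
#' @inheritParams model_rhs
#' @return `"engaged"`, `"disengaged"` or `"intermediate"`.
#' @export
classify_state <- function(model, state, params = NULL) {
  p <- if (is.null(params)) model$params else need_params(params, model$required)
  a <- model$activity(as.numeric(state), p)
  if (a < model$engaged_below) "engaged"
  else if (a > model$disengaged_above) "disengaged"
  else "intermediate"
}

## internal: admissibility of a full state (nonnegative pools and derived
## free species), with solver-overshoot slack
admissible_state <- function(model, x, p, tol = 1e-8) {
  if (any(!is.finite(x))) return(FALSE)
  if (any(x < -tol)) return(FALSE)
  if (!is.null(model$derived)) {
    d <- model$derived(x, p)
    if (any(!is.finite(d)) || any(d < -tol)) return(FALSE)
  }
  TRUE
}

## ---------------------------------------------------------------------
## SIMM: full two-step distributive modification with explicit complexes
## ---------------------------------------------------------------------

#' Build the SIMM motif model
#'
#' The substrate-inhibitor-multiply-modified (SIMM) motif: an inhibitor I
#' is modified in two Michaelis-Menten steps by the activator enzyme A
#' that it stoichiometrically inhibits.  Reactions (mass action):
#' `A + I <-> A:I -> A + IM` (`k_as1`, `k_di1`, `k_cat1`),
#' `A + IM <-> A:IM -> A + IMM` (`k_as2`, `k_di2`, `k_cat2`),
#' de-modification `IM -> I` (`k_dm1`), `IMM -> IM` (`k_dm2`).
#' State: `I`, `I_M`, `I_MM`, `C = [A:I]`, `C_M = [A:IM]`; free enzyme
#' `A = A_T - C - C_M`.  Two conservation laws hold:
#' `A_T = A + C + C_M` and `I_T = I + C + I_M + C_M + I_MM`.
#'
#' @param params a [switch_params] object containing the SIMM symbols
#'   (preset `"simm"`), including the totals `A_T` and `I_T`.
#' @return a `switch_model`.
#' @examples
#' m <- build_simm(switch_params("simm"))
#' model_rhs(m, c(I = 4, I_M = 0, I_MM = 0, C = 0, C_M = 0))
#' @export
build_simm <- function(params) {
  p <- need_params(params, c("k_as1", "k_as2", "k_di1", "k_di2", "k_cat1",
                             "k_cat2", "k_dm1", "k_dm2", "A_T", "I_T"))
  simm_core(params, p, p_processive = 0, name = "simm")
}

## shared by build_simm (p_processive = 0) and the partial-processivity
## variant: a fraction p_processive of A:I catalysis releases IMM directly
simm_core <- function(params, p, p_processive, name) {
  q <- p_processive
  rhs <- function(x, p) {
    I <- x[1]; IM <- x[2]; IMM <- x[3]; C <- x[4]; CM <- x[5]
    A <- p$A_T - C - CM
    c(-p$k_as1 * A * I + p$k_di1 * C + p$k_dm1 * IM,
      (1 - q) * p$k_cat1 * C - p$k_as2 * A * IM + p$k_di2 * CM +
        p$k_dm2 * IMM - p$k_dm1 * IM,
      p$k_cat2 * CM + q * p$k_cat1 * C - p$k_dm2 * IMM,
      p$k_as1 * A * I - (p$k_di1 + p$k_cat1) * C,
      p$k_as2 * A * IM - (p$k_di2 + p$k_cat2) * CM)
  }
  if (q == 0) {
    d_IM <- "k_cat1*C - k_as2*A*I_M + k_di2*C_M + k_dm2*I_MM - k_dm1*I_M"
    d_IMM <- "k_cat2*C_M - k_dm2*I_MM"
  } else {
    ## processive fraction baked into the expression text
    d_IM <- sprintf(
      "%.17g*k_cat1*C - k_as2*A*I_M + k_di2*C_M + k_dm2*I_MM - k_dm1*I_M",
      1 - q)
    d_IMM <- sprintf("k_cat2*C_M + %.17g*k_cat1*C - k_dm2*I_MM", q)
  }
  new_switch_model(
    name = name,
    vars = c("I", "I_M", "I_MM", "C", "C_M"),
    required = c("k_as1", "k_as2", "k_di1", "k_di2", "k_cat1", "k_cat2",
                 "k_dm1", "k_dm2", "A_T", "I_T"),
    rhs = rhs, p = p,
    conserved = function(x, p)
      c(A_total = (p$A_T - x[4] - x[5]) + x[4] + x[5],
        I_total = x[1] + x[4] + x[2] + x[5] + x[3]),
    free_names = c("I_M", "I_MM", "C", "C_M"),
    lift = function(y, p)
      c(p$I_T - y[3] - y[1] - y[4] - y[2], y),
    box = function(p) {
      m <- min(p$A_T, p$I_T)
      rbind(lower = c(0, 0, 0, 0), upper = c(p$I_T, p$I_T, m, m))
    },
    activity = function(x, p)
      if (p$A_T <= 0) 0 else (p$A_T - x[4] - x[5]) / p$A_T,
    observable = function(x, p) p$A_T - x[4] - x[5],
    derived = function(x, p) c(A = p$A_T - x[4] - x[5]),
    guesses = function(p) {
      m <- min(p$A_T, p$I_T)
      list(engaged = c(0, 0, 0.98 * m, 0.001),
           disengaged = c(0.02 * p$I_T, 0.9 * p$I_T, 0.001, 0.001),
           mid = c(0.2 * p$I_T, 0.4 * p$I_T, 0.5 * m, 0.05 * m))
    },
    total_state = c(I_T = "I"),
    ode_aux = c(A = "A_T - C - C_M"),
    ode_d = c(I = "-k_as1*A*I + k_di1*C + k_dm1*I_M",
              I_M = d_IM,
              I_MM = d_IMM,
              C = "k_as1*A*I - (k_di1 + k_cat1)*C",
              C_M = "k_as2*A*I_M - (k_di2 + k_cat2)*C_M")
  )
}

## ---------------------------------------------------------------------
## SIMM*: second modification collapsed to a mass-action step
## ---------------------------------------------------------------------

#' Build the simplified SIMM* motif model
#'
#' Identical to [build_simm] for the first (tight, slow) modification, but
#' the second modification is replaced by the bimolecular mass-action step
#' `A + IM -> A + IMM` with rate constant `k_m = k_cat2*k_as2/(k_cat2 +
#' k_di2)`, valid because the second step's Michaelis constant is large.
#' State: `I`, `I_M`, `I_MM`, `C`; `A = A_T - C`.  Conservation:
#' `A_T = A + C`, `I_T = I + C + I_M + I_MM`.
#'
#' @param params a [switch_params] with the first-modification symbols plus
#'   `k_m` (preset `"simm_star"`).
#' @return a `switch_model`.
#' @export
build_simm_star <- function(params) {
  p <- need_params(params, c("k_as1", "k_di1", "k_cat1", "k_dm1", "k_dm2",
                             "k_m", "A_T", "I_T"))
  rhs <- function(x, p) {
    I <- x[1]; IM <- x[2]; IMM <- x[3]; C <- x[4]
    A <- p$A_T - C
    c(-p$k_as1 * A * I + p$k_di1 * C + p$k_dm1 * IM,
      p$k_cat1 * C - p$k_m * A * IM + p$k_dm2 * IMM - p$k_dm1 * IM,
      p$k_m * A * IM - p$k_dm2 * IMM,
      p$k_as1 * A * I - (p$k_di1 + p$k_cat1) * C)
  }
  new_switch_model(
    name = "simm_star",
    vars = c("I", "I_M", "I_MM", "C"),
    required = c("k_as1", "k_di1", "k_cat1", "k_dm1", "k_dm2", "k_m",
                 "A_T", "I_T"),
    rhs = rhs, p = p,
    conserved = function(x, p)
      c(A_total = (p$A_T - x[4]) + x[4],
        I_total = x[1] + x[4] + x[2] + x[3]),
    free_names = c("I_M", "I_MM", "C"),
    lift = function(y, p) c(p$I_T - y[3] - y[1] - y[2], y),
    box = function(p) {
      m <- min(p$A_T, p$I_T)
      rbind(lower = c(0, 0, 0), upper = c(p$I_T, p$I_T, m))
    },
    activity = function(x, p)
      if (p$A_T <= 0) 0 else (p$A_T - x[4]) / p$A_T,
    observable = function(x, p) p$A_T - x[4],
    derived = function(x, p) c(A = p$A_T - x[4]),
    guesses = function(p) {
      m <- min(p$A_T, p$I_T)
      list(engaged = c(0, 0, 0.98 * m),
           disengaged = c(0.02 * p$I_T, 0.9 * p$I_T, 0.001),
           mid = c(0.2 * p$I_T, 0.4 * p$I_T, 0.5 * m))
    },
    total_state = c(I_T = "I"),
    ode_aux = c(A = "A_T - C"),
    ode_d = c(I = "-k_as1*A*I + k_di1*C + k_dm1*I_M",
              I_M = "k_cat1*C - k_m*A*I_M + k_dm2*I_MM - k_dm1*I_M",
              I_MM = "k_m*A*I_M - k_dm2*I_MM",
              C = "k_as1*A*I - (k_di1 + k_cat1)*C")
  )
}

## ---------------------------------------------------------------------
## TQSSA reduction of SIMM*
## ---------------------------------------------------------------------

#' Tight-binding complex concentration under the TQSSA
#'
#' Solves the total quasi-steady-state quadratic
#' `C^2 - (A_T + Ihat + K_m1)*C + A_T*Ihat = 0` for the enzyme-substrate
#' complex, taking the smaller root -- the only root satisfying
#' `0 <= C <= min(A_T, Ihat)`.  Evaluated in the numerically stable
#' product form `2*A_T*Ihat / (b + sqrt(b^2 - 4*A_T*Ihat))` with
#' `b = A_T + Ihat + K_m1`.
#'
#' @param Ihat total functional inhibitor (free + complexed), in U.
#' @param A_T total enzyme, in U.
#' @param K_m1 Michaelis constant of the tight first modification, in U.
#' @return complex concentration `C`, in U (vectorised over `Ihat`).
#' @export
tqssa_complex <- function(Ihat, A_T, K_m1) {
  if (any(!is.finite(c(Ihat, A_T, K_m1))) || any(c(Ihat, A_T, K_m1) < 0))
    stop("tqssa_complex: arguments must be finite and nonnegative",
         call. = FALSE)
  tb_root(Ihat, A_T, K_m1)
}

## internal: the same smaller root without argument validation; the
## product form continues smoothly to slightly negative totals, which
## keeps Newton Jacobians nonsingular near the admissible boundary
tb_root <- function(S, ET, Km) {
  b <- ET + S + Km
  disc <- pmax(b * b - 4 * ET * S, 0)
  2 * ET * S / (b + sqrt(disc))
}

#' Build the TQSSA-reduced two-variable switch model
#'
#' Reduces [build_simm_star] to two slow variables by a total
#' quasi-steady-state assumption on the tight complex: `Ihat = I + C`
#' (functional inhibitor) and `I_MM`, with the algebraic closure
#' `C = tqssa_complex(Ihat, A_T, K_m1)`, `A = A_T - C` and
#' `I_M = I_T - Ihat - I_MM`:
#' `dIhat/dt = -k_cat1*C + k_dm1*I_M`,
#' `dI_MM/dt = k_m*A*I_M - k_dm2*I_MM`.
#'
#' @param params a [switch_params] containing `K_m1`, `k_cat1`, `k_dm1`,
#'   `k_m`, `k_dm2`, `A_T`, `I_T` (preset `"simm_star"` works).
#' @return a `switch_model` with state `(Ihat, I_MM)`.
#' @export
build_tqssa <- function(params) {
  p <- need_params(params, c("K_m1", "k_cat1", "k_dm1", "k_m", "k_dm2",
                             "A_T", "I_T"))
  rhs <- function(x, p) {
    C <- tb_root(x[1], p$A_T, p$K_m1)
    IM <- p$I_T - x[1] - x[2]
    c(-p$k_cat1 * C + p$k_dm1 * IM,
      p$k_m * (p$A_T - C) * IM - p$k_dm2 * x[2])
  }
  new_switch_model(
    name = "tqssa",
    vars = c("Ihat", "I_MM"),
    required = c("K_m1", "k_cat1", "k_dm1", "k_m", "k_dm2", "A_T", "I_T"),
    rhs = rhs, p = p,
    conserved = NULL,
    box = function(p) rbind(lower = c(0, 0), upper = c(p$I_T, p$I_T)),
    activity = function(x, p)
      if (p$A_T <= 0) 0
      else (p$A_T - tb_root(x[1], p$A_T, p$K_m1)) / p$A_T,
    observable = function(x, p)
      p$A_T - tb_root(x[1], p$A_T, p$K_m1),
    derived = function(x, p) {
      C <- tb_root(x[1], p$A_T, p$K_m1)
      c(C = C, A = p$A_T - C, I = x[1] - C, I_M = p$I_T - x[1] - x[2])
    },
    guesses = function(p)
      list(engaged = c(0.95 * p$I_T, 0.01),
           disengaged = c(0.02 * p$I_T, 0.9 * p$I_T),
           mid = c(0.4 * p$I_T, 0.3 * p$I_T)),
    ode_aux = c(bq = "A_T + Ihat + K_m1",
                C = "2*A_T*Ihat/(bq + sqrt(bq^2 - 4*A_T*Ihat))",
                A = "A_T - C",
                I_M = "I_T - Ihat - I_MM"),
    ode_d = c(Ihat = "-k_cat1*C + k_dm1*I_M",
              I_MM = "k_m*A*I_M - k_dm2*I_MM")
  )
}

## ---------------------------------------------------------------------
## Sic1-Clb: CKI phosphorylation switch at the G1/S transition
## ---------------------------------------------------------------------

#' Build the Sic1-Clb switch model
#'
#' The SIMM* motif applied to the budding-yeast CKI Sic1 and Clb:Cdk1
#' kinase, supplemented with Sic1 synthesis (`k_s`) and background
#' degradation of all Sic1 forms (`k_d`).  State: total Sic1 `SicT`
#' (excluding the doubly phosphorylated form, which is degraded
#' immediately), the inhibitory trimer `ClbSic = [Clb:Sic]`, and
#' `SicP = [SicP]`.  Free species: `[Sic] = SicT - ClbSic - SicP`,
#' `[Clb] = ClbT - ClbSic`.  The second phosphorylation
#' `k_p_b*[Clb]*[SicP]` is a pure sink (rapid degradation of SicPP).
#' `[ClbT]` is the bifurcation parameter.
#'
#' @param params a [switch_params] with preset `"sic_clb"` symbols.
#' @return a `switch_model`.
#' @export
build_sic_clb <- function(params) {
  p <- need_params(params, c("k_s", "k_d", "k_as_b", "k_di_b", "k_p_b",
                             "k_dp", "k_cat_b", "ClbT"))
  rhs <- function(x, p) {
    SicT <- x[1]; CS <- x[2]; SP <- x[3]
    Sic <- SicT - CS - SP
    Clb <- p$ClbT - CS
    c(p$k_s - p$k_d * SicT - p$k_p_b * Clb * SP,
      p$k_as_b * Clb * Sic - (p$k_di_b + p$k_cat_b + p$k_d) * CS,
      p$k_cat_b * CS - (p$k_dp + p$k_d) * SP - p$k_p_b * Clb * SP)
  }
  new_switch_model(
    name = "sic_clb",
    vars = c("SicT", "ClbSic", "SicP"),
    required = c("k_s", "k_d", "k_as_b", "k_di_b", "k_p_b", "k_dp",
                 "k_cat_b", "ClbT"),
    rhs = rhs, p = p,
    conserved = NULL,
    box = function(p) {
      top <- 1.5 * p$k_s / p$k_d
      rbind(lower = c(0, 0, 0),
            upper = c(top, max(min(p$ClbT, top), 1e-6), 0.5 * top))
    },
    activity = function(x, p)
      if (p$ClbT <= 0) 0 else (p$ClbT - x[2]) / p$ClbT,
    observable = function(x, p) x[1],
    derived = function(x, p)
      c(Sic = x[1] - x[2] - x[3], Clb = p$ClbT - x[2]),
    guesses = function(p) {
      top <- p$k_s / p$k_d
      list(engaged = c(0.95 * top, 0.95 * min(p$ClbT, top), 0.01),
           disengaged = c(0.05 * top, 0.01 * min(p$ClbT, top), 0.02),
           mid = c(0.4 * top, 0.6 * min(p$ClbT, top), 0.05))
    },
    ode_aux = c(Sic = "SicT - ClbSic - SicP", Clb = "ClbT - ClbSic"),
    ode_d = c(SicT = "k_s - k_d*SicT - k_p_b*Clb*SicP",
              ClbSic = "k_as_b*Clb*Sic - (k_di_b + k_cat_b + k_d)*ClbSic",
              SicP = "k_cat_b*ClbSic - (k_dp + k_d)*SicP - k_p_b*Clb*SicP")
  )
}

## ---------------------------------------------------------------------
## Cln-Sic1-Clb: the full G1/S transition model
## ---------------------------------------------------------------------

#' Build the Cln-Sic1-Clb G1/S transition model
#'
#' Extends [build_sic_clb] with a Cln module: Sic1 binds Cln:Cdk1 weakly
#' and is processed fast (`k_as_n`, `k_di_n`, `k_cat_n`), so Cln kinase is
#' effectively not inhibited by Sic1, and Cln kinase also catalyses the
#' second, degradation-triggering phosphorylation (`k_p_n`).  State adds
#' `ClnSic = [Cln:Sic]`; free species
#' `[Sic] = SicT - ClbSic - ClnSic - SicP`, `[Cln] = ClnT - ClnSic`.
#' `[ClbT]` and `[ClnT]` are the two control parameters.
#'
#' @param params a [switch_params] with preset `"cln_sic_clb"` symbols.
#' @return a `switch_model`.
#' @export
build_cln_sic_clb <- function(params) {
  p <- need_params(params, c("k_s", "k_d", "k_as_b", "k_di_b", "k_p_b",
                             "k_dp", "k_cat_b", "k_as_n", "k_di_n",
                             "k_p_n", "k_cat_n", "ClbT", "ClnT"))
  rhs <- function(x, p) {
    SicT <- x[1]; CS <- x[2]; CN <- x[3]; SP <- x[4]
    Sic <- SicT - CS - CN - SP
    Clb <- p$ClbT - CS
    Cln <- p$ClnT - CN
    kp <- p$k_p_b * Clb + p$k_p_n * Cln
    c(p$k_s - p$k_d * SicT - kp * SP,
      p$k_as_b * Clb * Sic - (p$k_di_b + p$k_cat_b + p$k_d) * CS,
      p$k_as_n * Cln * Sic - (p$k_di_n + p$k_cat_n + p$k_d) * CN,
      p$k_cat_b * CS + p$k_cat_n * CN - (p$k_dp + p$k_d) * SP - kp * SP)
  }
  new_switch_model(
    name = "cln_sic_clb",
    vars = c("SicT", "ClbSic", "ClnSic", "SicP"),
    required = c("k_s", "k_d", "k_as_b", "k_di_b", "k_p_b", "k_dp",
                 "k_cat_b", "k_as_n", "k_di_n", "k_p_n", "k_cat_n",
                 "ClbT", "ClnT"),
    rhs = rhs, p = p,
    conserved = NULL,
    box = function(p) {
      top <- 1.5 * p$k_s / p$k_d
      rbind(lower = c(0, 0, 0, 0),
            upper = c(top, max(min(p$ClbT, top), 1e-6),
                      max(min(p$ClnT, top), 1e-6), 0.5 * top))
    },
    activity = function(x, p)
      if (p$ClbT <= 0) 0 else (p$ClbT - x[2]) / p$ClbT,
    observable = function(x, p) x[1],
    derived = function(x, p)
      c(Sic = x[1] - x[2] - x[3] - x[4], Clb = p$ClbT - x[2],
        Cln = p$ClnT - x[3]),
    guesses = function(p) {
      top <- p$k_s / p$k_d
      list(engaged = c(0.9 * top, 0.95 * min(p$ClbT, top),
                       0.3 * min(p$ClnT, top), 0.01),
           disengaged = c(0.05 * top, 0.01 * min(p$ClbT, top),
                          0.005 * min(p$ClnT, top), 0.02),
           mid = c(0.4 * top, 0.6 * min(p$ClbT, top),
                   0.1 * min(p$ClnT, top), 0.05))
    },
    ode_aux = c(Sic = "SicT - ClbSic - ClnSic - SicP",
                Clb = "ClbT - ClbSic", Cln = "ClnT - ClnSic"),
    ode_d = c(
      SicT = "k_s - k_d*SicT - (k_p_b*Clb + k_p_n*Cln)*SicP",
      ClbSic = "k_as_b*Clb*Sic - (k_di_b + k_cat_b + k_d)*ClbSic",
      ClnSic = "k_as_n*Cln*Sic - (k_di_n + k_cat_n + k_d)*ClnSic",
      SicP = paste0("k_cat_b*ClbSic + k_cat_n*ClnSic - (k_dp + k_d)*SicP",
                    " - (k_p_b*Clb + k_p_n*Cln)*SicP"))
  )
}

## ---------------------------------------------------------------------
## MCC-APC: the mitotic (spindle assembly) checkpoint
## ---------------------------------------------------------------------

#' Build the MCC-APC mitotic checkpoint model
#'
#' The SIMM* motif applied to the mitotic checkpoint complex (MCC,
#' inhibitor) and the anaphase-promoting complex (APC, activator).  MCC is
#' assembled from the free Mad2 pool by tensionless kinetochores at rate
#' `k_aNT*(1 - X_tens)*[Mad2]`; the tight APC:MCC complex is eliminated by
#' a TQSSA closure ([tqssa_complex] with Michaelis constant `K_m` between
#' total APC and functional MCC `[MCC] + [APC:MCC] = MCCT - MCCU`);
#' APC-catalysed mono-ubiquitination `APC:MCC -> APC + MCCU` (`k_cat`) is
#' reversed by a de-ubiquitinase (`k_du`), while the second,
#' poly-ubiquitination step `k_u*[APC]*[MCCU]` destroys the Cdc20 subunit
#' and returns Mad2 to the free pool.  Securin is synthesised (`k_ssec`)
#' and degraded basally (`k_dsec`) and by free APC (`k_dsec_apc`) as an
#' anaphase indicator.
#'
#' State: `MCCT = [MCC] + [APC:MCC] + [MCCU]`, `MCCU`, `Sec`; totals
#' `APCT` and `Mad2T` are parameters (defaults are assumptions, see
#' [switch_params]).
#'
#' @param params a [switch_params] with preset `"mcc_apc"` symbols.
#' @return a `switch_model`.
#' @export
build_mcc_apc <- function(params) {
  p <- need_params(params, c("K_m", "k_u", "k_du", "k_cat", "k_aNT",
                             "X_tens", "k_ssec", "k_dsec", "k_dsec_apc",
                             "APCT", "Mad2T"))
  if (p$X_tens > 1) stop("X_tens must lie in [0, 1]", call. = FALSE)
  rhs <- function(x, p) {
    Mhat <- x[1] - x[2]
    CM <- tb_root(Mhat, p$APCT, p$K_m)
    APC <- p$APCT - CM
    c(p$k_aNT * (1 - p$X_tens) * (p$Mad2T - x[1]) - p$k_u * APC * x[2],
      p$k_cat * CM - p$k_du * x[2] - p$k_u * APC * x[2],
      p$k_ssec - p$k_dsec * x[3] - p$k_dsec_apc * APC * x[3])
  }
  new_switch_model(
    name = "mcc_apc",
    vars = c("MCCT", "MCCU", "Sec"),
    required = c("K_m", "k_u", "k_du", "k_cat", "k_aNT", "X_tens",
                 "k_ssec", "k_dsec", "k_dsec_apc", "APCT", "Mad2T"),
    rhs = rhs, p = p,
    conserved = NULL,
    box = function(p)
      rbind(lower = c(0, 0, 0),
            upper = c(p$Mad2T, 0.5 * p$Mad2T, p$k_ssec / p$k_dsec)),
    activity = function(x, p) {
      CM <- tb_root(x[1] - x[2], p$APCT, p$K_m)
      (p$APCT - CM) / p$APCT
    },
    observable = function(x, p) x[1],
    derived = function(x, p) {
      Mhat <- x[1] - x[2]
      CM <- tb_root(max(Mhat, 0), p$APCT, p$K_m)
      c(MCC_functional = Mhat, ApcMcc = CM, APC = p$APCT - CM,
        MCC = Mhat - CM, Mad2 = p$Mad2T - x[1])
    },
    guesses = function(p)
      list(engaged = c(0.995 * p$Mad2T, 0.05, 1.5),
           disengaged = c(0.01 * p$Mad2T, 0.003, 0.2),
           mid = c(0.5 * p$Mad2T, 0.05, 0.5)),
    ode_aux = c(Mhat = "MCCT - MCCU",
                bq = "APCT + Mhat + K_m",
                ApcMcc = "2*APCT*Mhat/(bq + sqrt(bq^2 - 4*APCT*Mhat))",
                APC = "APCT - ApcMcc"),
    ode_d = c(
      MCCT = "k_aNT*(1 - X_tens)*(Mad2T - MCCT) - k_u*APC*MCCU",
      MCCU = "k_cat*ApcMcc - k_du*MCCU - k_u*APC*MCCU",
      Sec = "k_ssec - k_dsec*Sec - k_dsec_apc*APC*Sec")
  )
}

## ---------------------------------------------------------------------
## CycB-MCC-APC: irreversibility of the metaphase-anaphase transition
## ---------------------------------------------------------------------

#' Build the CycB-MCC-APC model
#'
#' Extends [build_mcc_apc] so that the metaphase-to-anaphase transition
#' becomes irreversible.  The APC:MCC complex is now an explicit dynamical
#' variable (`k_as`, `k_di`, `k_cat`); cyclin B is synthesised (`k_scyc`)
#' and degraded basally (`k_dcyc`) and by free APC (`k_dcyc_apc`); and the
#' fraction `X0A` of tensionless centromeres that actively catalyse MCC
#' assembly requires CycB kinase for its activation
#' (`dX0A/dt = k_an*[CycB]*((1 - X_tens) - X0A) - k_inCAPP*X0A`), with the
#' counteracting phosphatase activity stored as the composite `k_inCAPP`.
#' MCC assembly scales with `X0A`: rate `k_aNT*X0A*[Mad2]`.  Once APC
#' destroys CycB, tensionless kinetochores can no longer reactivate the
#' MCC, so the checkpoint cannot re-engage when `X_tens` returns to zero.
#'
#' State: `MCCT`, `MCCU`, `ApcMcc = [APC:MCC]`, `CycB`, `Sec`, `X0A`;
#' `[APC] = APCT - ApcMcc`, `[MCC] = MCCT - ApcMcc - MCCU`.
#'
#' @param params a [switch_params] with preset `"cycb_mcc_apc"` symbols.
#' @return a `switch_model`.
#' @export
build_cycb_mcc_apc <- function(params) {
  p <- need_params(params, c("K_m", "k_u", "k_du", "k_cat", "k_aNT",
                             "X_tens", "k_ssec", "k_dsec", "k_dsec_apc",
                             "k_scyc", "k_dcyc", "k_dcyc_apc", "k_an",
                             "k_inCAPP", "k_as", "k_di", "APCT", "Mad2T"))
  if (p$X_tens > 1) stop("X_tens must lie in [0, 1]", call. = FALSE)
  rhs <- function(x, p) {
    MCCT <- x[1]; MCCU <- x[2]; CM <- x[3]; CycB <- x[4]; Sec <- x[5]
    X0A <- x[6]
    APC <- p$APCT - CM
    MCC <- MCCT - CM - MCCU
    c(p$k_aNT * X0A * (p$Mad2T - MCCT) - p$k_u * APC * MCCU,
      p$k_cat * CM - p$k_du * MCCU - p$k_u * APC * MCCU,
      p$k_as * APC * MCC - (p$k_di + p$k_cat) * CM,
      p$k_scyc - p$k_dcyc * CycB - p$k_dcyc_apc * APC * CycB,
      p$k_ssec - p$k_dsec * Sec - p$k_dsec_apc * APC * Sec,
      p$k_an * CycB * ((1 - p$X_tens) - X0A) - p$k_inCAPP * X0A)
  }
  new_switch_model(
    name = "cycb_mcc_apc",
    vars = c("MCCT", "MCCU", "ApcMcc", "CycB", "Sec", "X0A"),
    required = c("K_m", "k_u", "k_du", "k_cat", "k_aNT", "X_tens",
                 "k_ssec", "k_dsec", "k_dsec_apc", "k_scyc", "k_dcyc",
                 "k_dcyc_apc", "k_an", "k_inCAPP", "k_as", "k_di",
                 "APCT", "Mad2T"),
    rhs = rhs, p = p,
    conserved = NULL,
    box = function(p)
      rbind(lower = c(0, 0, 0, 0, 0, 0),
            upper = c(p$Mad2T, 0.5 * p$Mad2T, p$APCT,
                      p$k_scyc / p$k_dcyc, p$k_ssec / p$k_dsec, 1)),
    activity = function(x, p) (p$APCT - x[3]) / p$APCT,
    observable = function(x, p) x[1],
    derived = function(x, p)
      c(APC = p$APCT - x[3], MCC = x[1] - x[3] - x[2],
        MCC_functional = x[1] - x[2], Mad2 = p$Mad2T - x[1]),
    guesses = function(p) {
      cycb_top <- p$k_scyc / p$k_dcyc
      list(engaged = c(0.995 * p$Mad2T, 0.05, 0.95 * p$APCT,
                       0.95 * cycb_top, 1.5, 0.3),
           disengaged = c(0.01 * p$Mad2T, 0.002, 0.002 * p$APCT,
                          0.01 * cycb_top, 0.2, 0.002),
           mid = c(0.5 * p$Mad2T, 0.05, 0.5 * p$APCT,
                   0.3 * cycb_top, 0.5, 0.05))
    },
    ode_aux = c(APC = "APCT - ApcMcc", MCC = "MCCT - ApcMcc - MCCU"),
    ode_d = c(
      MCCT = "k_aNT*X0A*(Mad2T - MCCT) - k_u*APC*MCCU",
      MCCU = "k_cat*ApcMcc - k_du*MCCU - k_u*APC*MCCU",
      ApcMcc = "k_as*APC*MCC - (k_di + k_cat)*ApcMcc",
      CycB = "k_scyc - k_dcyc*CycB - k_dcyc_apc*APC*CycB",
      Sec = "k_ssec - k_dsec*Sec - k_dsec_apc*APC*Sec",
      X0A = "k_an*CycB*((1 - X_tens) - X0A) - k_inCAPP*X0A")
  )
}

## internal: which state variable absorbs a change in a conserved-total
## parameter (NA when the parameter enters the RHS directly)
total_state_index <- function(model, sym) {
  ts <- model$total_state
  if (is.null(ts) || !sym %in% names(ts)) return(NA_integer_)
  match(ts[[sym]], model$vars)
}

## internal: carry a state across a change of a conserved-total parameter
rebase_state <- function(model, x, p_old, p_new) {
  ts <- model$total_state
  if (is.null(ts)) return(x)
  for (sym in names(ts)) {
    delta <- p_new[[sym]] - p_old[[sym]]
    if (delta != 0) {
      i <- match(ts[[sym]], model$vars)
      x[i] <- max(x[i] + delta, 0)
    }
  }
  x
}
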