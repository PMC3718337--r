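## Shared fixtures: every model with its preset, and a generator of
## random admissible states for property-style checks.

model_builders <- list(
  simm = build_simm,
  simm_star = build_simm_star,
  tqssa = build_tqssa,
  sic_clb = build_sic_clb,
  cln_sic_clb = build_cln_sic_clb,
  mcc_apc = build_mcc_apc,
  cycb_mcc_apc = build_cycb_mcc_apc
)

preset_for <- c(simm = "simm", simm_star = "simm_star",
                tqssa = "simm_star", sic_clb = "sic_clb",
                cln_sic_clb = "cln_sic_clb", mcc_apc = "mcc_apc",
                cycb_mcc_apc = "cycb_mcc_apc")

build_preset_model <- function(name, ...) {
  model_builders[[name]](switch_params(preset_for[[name]], ...))
}

## random admissible full state for a model (pools consistent with the
## totals and derived free species nonnegative)
random_admissible_state <- function(model, p = model$params) {
  repeat {
    x <- switch(model$name,
      simm = , simm_processive = {
        w <- stats::runif(5); w <- w / sum(w) * stats::runif(1, 0, p$I_T)
        ## C + C_M additionally bounded by A_T
        sc <- min(1, 0.9 * p$A_T / max(w[4] + w[5], 1e-12))
        c(w[1] + (1 - sc) * (w[4] + w[5]), w[2], w[3], sc * w[4], sc * w[5])
      },
      simm_star = {
        w <- stats::runif(4); w <- w / sum(w) * stats::runif(1, 0, p$I_T)
        sc <- min(1, 0.9 * p$A_T / max(w[4], 1e-12))
        c(w[1] + (1 - sc) * w[4], w[2], w[3], sc * w[4])
      },
      tqssa = {
        w <- stats::runif(2, 0, 1); tot <- stats::runif(1, 0, p$I_T)
        c(w[1], w[2]) / sum(w) * tot
      },
      sic_clb = {
        st <- stats::runif(1, 0, 1.2 * p$k_s / p$k_d)
        parts <- stats::runif(3); parts <- parts / sum(parts) * st
        cs <- min(parts[2], 0.95 * p$ClbT)
        c(st - (parts[2] - cs), cs, parts[3])
      },
      cln_sic_clb = {
        st <- stats::runif(1, 0, 1.2 * p$k_s / p$k_d)
        parts <- stats::runif(4); parts <- parts / sum(parts) * st
        cs <- min(parts[2], 0.95 * p$ClbT)
        cn <- min(parts[3], 0.95 * p$ClnT)
        c(st - (parts[2] - cs) - (parts[3] - cn), cs, cn, parts[4])
      },
      mcc_apc = {
        mt <- stats::runif(1, 0, p$Mad2T)
        c(mt, stats::runif(1, 0, mt), stats::runif(1, 0, 2))
      },
      cycb_mcc_apc = {
        mt <- stats::runif(1, 0, p$Mad2T)
        mu <- stats::runif(1, 0, mt)
        cm <- stats::runif(1, 0, min(p$APCT, mt - mu))
        c(mt, mu, cm, stats::runif(1, 0, p$k_scyc / p$k_dcyc),
          stats::runif(1, 0, 2), stats::runif(1, 0, 1))
      },
      stop("no random-state rule for ", model$name))
    if (simmswitch:::admissible_state(model, x, p, tol = 0)) return(x)
  }
}

## random admissible state on the conservation manifold of the preset
## totals (so integration oracles relax to the attractors of the same
## parameter point the root finder analysed)
random_on_manifold <- function(model, p = model$params) {
  if (is.null(model$conserved)) return(random_admissible_state(model, p))
  repeat {
    x <- random_admissible_state(model, p)
    if (sum(x) <= 0) next
    x <- x * p$I_T / sum(x)
    if (simmswitch:::admissible_state(model, x, p, tol = 0)) return(x)
  }
}

## perturb a state without leaving the conservation manifold: after the
## noise, pools are rescaled so the conserved total is unchanged
perturb_on_manifold <- function(model, state, sd = 1e-3) {
  x <- pmax(as.numeric(state) + stats::rnorm(length(state), 0, sd), 0)
  if (!is.null(model$conserved) && sum(x) > 0)
    x <- x * sum(as.numeric(state)) / sum(x)
  x
}
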