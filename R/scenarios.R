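## Time-course scenarios: event-driven simulation, the budding-yeast
## G1/S cycle, and mitotic-checkpoint release in vitro and in vivo.

#' Piecewise-constant parameter event schedule
#'
#' @param times event times (strictly increasing, within the horizon).
#' @param symbols parameter symbol changed at each event.
#' @param values new value at each event.
#' @param horizon total simulated time (T units).
#' @return an `event_schedule` object.
#' @export
event_schedule <- function(times = numeric(), symbols = character(),
                           values = numeric(), horizon) {
  stopifnot(length(times) == length(symbols),
            length(times) == length(values), horizon > 0)
  if (length(times)) {
    if (any(diff(times) <= 0))
      stop("event times must be strictly increasing", call. = FALSE)
    if (any(times < 0) || any(times >= horizon))
      stop("event times must lie within [0, horizon)", call. = FALSE)
  }
  structure(list(times = times, symbols = symbols, values = values,
                 horizon = horizon),
            class = "event_schedule")
}

#' @export
print.event_schedule <- function(x, ...) {
  cat("event schedule, horizon", x$horizon, "T\n")
  if (length(x$times))
    print(data.frame(time = x$times, symbol = x$symbols, value = x$values))
  else cat("  (no events)\n")
  invisible(x)
}

#' Simulate a model under an event schedule
#'
#' Stiff integration restarted at each event with the updated parameter
#' value; dense output at `n_out` (>= 200) sample times.
#'
#' @param model a `switch_model`.
#' @param params optional [switch_params].
#' @param schedule an [event_schedule].
#' @param init full initial state.
#' @param n_out number of output samples over the horizon.
#' @return a `switch_trajectory`: data.frame with `time`, the state
#'   variables, the model's derived quantities and the driven parameter
#'   values; event times in attribute `events`.
#' @export
simulate_schedule <- function(model, params = NULL, schedule, init,
                              n_out = 400) {
  stopifnot(inherits(schedule, "event_schedule"), n_out >= 200)
  p <- model_plist(model, params)
  x <- as.numeric(init)
  if (!admissible_state(model, x, p, tol = 1e-4))
    stop("initial state is not admissible", call. = FALSE)

  bounds <- c(0, schedule$times, schedule$horizon)
  times_out <- seq(0, schedule$horizon, length.out = n_out)
  driven <- unique(schedule$symbols)
  rows <- list()
  for (seg in seq_len(length(bounds) - 1)) {
    t0 <- bounds[seg]; t1 <- bounds[seg + 1]
    if (seg > 1) {
      sym <- schedule$symbols[seg - 1]
      val <- schedule$values[seg - 1]
      ## a stepped conserved total is applied to the state: new inhibitor
      ## arrives unmodified; removal scales all pools proportionally
      i <- total_state_index(model, sym)
      if (!is.na(i)) {
        delta <- val - p[[sym]]
        if (delta >= 0) x[i] <- x[i] + delta
        else if (sum(x) > 0) x <- x * max(1 + delta / sum(x), 0)
      }
      p[[sym]] <- val
    }
    tt <- unique(c(t0, times_out[times_out >= t0 & times_out <= t1], t1))
    sol <- tryCatch(
      deSolve::lsoda(x, tt - t0,
                     function(t, y, parms) list(model$rhs(pmax(y, 0), p)),
                     NULL, rtol = 1e-9, atol = 1e-11),
      error = function(e)
        stop("solver failure in segment ", seg, " [", t0, ", ", t1, "]: ",
             conditionMessage(e), call. = FALSE))
    x <- pmax(as.numeric(sol[nrow(sol), -1]), 0)
    seg_df <- as.data.frame(sol)
    names(seg_df) <- c("time", model$vars)
    seg_df$time <- seg_df$time + t0
    if (!is.null(model$derived)) {
      dv <- do.call(rbind, lapply(seq_len(nrow(seg_df)), function(i)
        model$derived(as.numeric(seg_df[i, model$vars]), p)))
      seg_df <- cbind(seg_df, as.data.frame(dv))
    }
    for (s in driven) seg_df[[s]] <- p[[s]]
    rows[[seg]] <- seg_df
  }
  traj <- do.call(rbind, rows)
  traj <- traj[!duplicated(traj$time), ]
  rownames(traj) <- NULL
  structure(traj, events = schedule$times, model = model$name,
            class = c("switch_trajectory", "data.frame"))
}

#' @export
print.switch_trajectory <- function(x, ...) {
  cat("trajectory (", attr(x, "model"), "), ", nrow(x), " samples, t in [",
      min(x$time), ", ", max(x$time), "]\n", sep = "")
  ev <- attr(x, "events")
  if (length(ev)) cat("  events at t =", paste(ev, collapse = ", "), "\n")
  utils::str(unclass(x), max.level = 0)
  invisible(x)
}

#' @export
plot.switch_trajectory <- function(x, columns = NULL, ...) {
  if (is.null(columns))
    columns <- setdiff(names(x), "time")[1:min(4, ncol(x) - 1)]
  graphics::matplot(x$time, as.matrix(x[columns]), type = "l", lty = 1,
                    xlab = "time (T)", ylab = "concentration (U)", ...)
  graphics::legend("topright", legend = columns, col = seq_along(columns),
                   lty = 1, bty = "n")
  ev <- attr(x, "events")
  if (length(ev)) graphics::abline(v = ev, col = "grey70", lty = 3)
  invisible(x)
}

#' Export a trajectory as TSV
#' @param x a `switch_trajectory`.
#' @param path output file path.
#' @export
write_trajectory_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Detect the first threshold crossing of a trajectory observable
#'
#' @param traj a `switch_trajectory` (or any data.frame with `time`).
#' @param observable column name, or a function of the trajectory
#'   data.frame returning one numeric value per row.
#' @param threshold crossing level.
#' @param direction `"below"` (first time the observable falls to or
#'   below the threshold) or `"above"`.
#' @return crossing time (linear interpolation between samples), or `NA`
#'   if no crossing occurs.
#' @export
detect_transition <- function(traj, observable, threshold,
                              direction = c("below", "above")) {
  direction <- match.arg(direction)
  v <- if (is.function(observable)) observable(traj)
       else traj[[observable]]
  if (is.null(v)) stop("observable not found in trajectory", call. = FALSE)
  hit <- if (direction == "below") v <= threshold else v >= threshold
  i <- which(hit)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1) return(traj$time[1])
  t0 <- traj$time[i - 1]; t1 <- traj$time[i]
  v0 <- v[i - 1]; v1 <- v[i]
  if (v1 == v0) return(t1)
  t0 + (threshold - v0) * (t1 - t0) / (v1 - v0)
}

#' Cyclin synthesis/degradation programme for the G1/S scenario
#'
#' The cyclin rates of the G1/S time course are a convention of this
#' package (they are not part of the published rate-constant tables):
#' chosen once so that the projected (`ClbT`, `ClnT`) path traverses the
#' control-plane bistable region in the canonical cell-cycle loop --
#' engage, disengage through the upper fold while Cln rises, stay
#' disengaged while Cln falls at high Clb, re-engage only when Clb falls
#' at division.
#'
#' @return a list of rates (U/T and 1/T) and the three event times.
#' @export
g1s_cyclin_defaults <- function() {
  list(k_s_cln = 0.012,  # Cln synthesis while the Start programme is on
       k_d_cln0 = 0.01,  # basal Cln turnover
       k_d_cln1 = 0.25,  # Cln degradation after synthesis shut-off (t_cln)
       k_s_clb = 0.06,   # Clb synthesis from Start until division
       k_d_clb0 = 0.01,  # basal Clb turnover
       k_d_clb1 = 0.1,   # Clb degradation after division (t_div)
       t_cln_off = 30, t_div = 50)
}

#' Simulate the budding-yeast G1/S cycle
#'
#' Augments [build_cln_sic_clb] with two extra ODEs for the cyclin totals
#' `ClnT` and `ClbT`: both syntheses are on from t = 0 (Start); at
#' `t_cln_off` Cln synthesis stops and its degradation is turned on; at
#' `t_div` (cell division) Clb synthesis stops and its degradation is
#' turned up.  Reports the G1/S transition time (first time free active
#' Clb kinase exceeds half of `ClbT`) and whether the checkpoint
#' re-engages by the end of the horizon.
#'
#' @param params a [switch_params] for the Cln-Sic1-Clb model (preset
#'   `"cln_sic_clb"`); `ClbT`/`ClnT` values in it are ignored (they are
#'   dynamic here, starting at 0).
#' @param cyclin_dynamics rate list as from [g1s_cyclin_defaults].
#' @param horizon total simulated time.
#' @param n_out output samples.
#' @return a `switch_trajectory` with extra columns `ClbT`, `ClnT` and
#'   attributes `transition_time` (G1/S, NA if the checkpoint never
#'   disengages -- reported as a scenario failure, not an error) and
#'   `final_label`.
#' @export
g1s_cycle_scenario <- function(params = switch_params("cln_sic_clb"),
                               cyclin_dynamics = g1s_cyclin_defaults(),
                               horizon = 90, n_out = 450) {
  cd <- cyclin_dynamics
  p <- need_params(params, setdiff(build_cln_sic_clb(params)$required,
                                   c("ClbT", "ClnT")))
  core <- build_cln_sic_clb(params)
  ## state: SicT, ClbSic, ClnSic, SicP, ClbT, ClnT
  rhs6 <- function(t, y, parms) {
    y <- pmax(y, 0)
    pp <- p
    pp$ClbT <- max(y[5], y[2])   # totals cannot fall below the bound pool
    pp$ClnT <- max(y[6], y[3])
    d4 <- core$rhs(y[1:4], pp)
    dClb <- if (t < cd$t_div) cd$k_s_clb - cd$k_d_clb0 * y[5]
            else -cd$k_d_clb1 * y[5]
    dCln <- if (t < cd$t_cln_off) cd$k_s_cln - cd$k_d_cln0 * y[6]
            else -cd$k_d_cln1 * y[6]
    list(c(d4, dClb, dCln))
  }
  ## engaged G1 start: Sic1 at its synthesis/turnover balance, no cyclins
  init <- c(p$k_s / p$k_d, 0, 0, 0, 0, 0)
  tt <- sort(unique(c(seq(0, horizon, length.out = n_out),
                      cd$t_cln_off, cd$t_div)))
  sol <- deSolve::lsoda(init, tt, rhs6, NULL, rtol = 1e-9, atol = 1e-11)
  traj <- as.data.frame(sol)
  names(traj) <- c("time", "SicT", "ClbSic", "ClnSic", "SicP",
                   "ClbT", "ClnT")
  traj$Clb_free <- pmax(traj$ClbT - traj$ClbSic, 0)
  traj$Cln_free <- pmax(traj$ClnT - traj$ClnSic, 0)
  traj <- structure(traj, events = c(cd$t_cln_off, cd$t_div),
                    model = "g1s_cycle",
                    class = c("switch_trajectory", "data.frame"))
  trans <- detect_transition(
    traj, function(d) ifelse(d$ClbT > 1e-9, d$Clb_free / pmax(d$ClbT, 1e-12), 0),
    0.5, "above")
  final <- utils::tail(traj, 1)
  pp <- p; pp$ClbT <- max(final$ClbT, 1e-12); pp$ClnT <- final$ClnT
  final_label <- classify_state_raw(
    core, as.numeric(final[c("SicT", "ClbSic", "ClnSic", "SicP")]), pp)
  attr(traj, "transition_time") <- trans
  attr(traj, "final_label") <- final_label
  traj
}

#' Simulate in-vitro release of the mitotic checkpoint
#'
#' Starts from the engaged steady state of [build_mcc_apc] at
#' `X_tens = 0` and steps `X_tens` to 1 at t = 0 (all chromosomes come
#' under tension; no new MCC is assembled).  The excess of functional MCC
#' (`[MCC] + [APC:MCC]`) over total APC must first be ubiquitinated away
#' -- a long lag caused by the rapid de-ubiquitination of MCCU -- before
#' free APC rises and securin is degraded.
#'
#' @param params a [switch_params] with preset `"mcc_apc"` symbols.
#' @param horizon simulated time after the tension step.
#' @param n_out output samples.
#' @return a `switch_trajectory` (columns include the functional pool
#'   `MCC_functional`, free `APC` and `Sec`) with attribute `lag_time`:
#'   the first time functional MCC falls to the total APC level.
#' @export
mitotic_release_in_vitro <- function(params = switch_params("mcc_apc"),
                                     horizon = 120, n_out = 480) {
  m <- build_mcc_apc(set_params(params, X_tens = 0))
  eng <- integrate_to_steady_state(m, c(0.995 * m$params$Mad2T, 0.05, 1.5),
                                   t_max = 2000, tol = 1e-10)
  m1 <- build_mcc_apc(set_params(params, X_tens = 1))
  sched <- event_schedule(horizon = horizon)
  traj <- simulate_schedule(m1, schedule = sched, init = as.numeric(eng),
                            n_out = n_out)
  attr(traj, "lag_time") <- detect_transition(
    traj, "MCC_functional", m1$params$APCT, "below")
  attr(traj, "initial_state") <- eng
  traj
}

#' Default tension ramp for the in-vivo release scenario
#'
#' Chromosome alignment carries `X_tens` from 0 to 1, it is held there
#' while the checkpoint disengages, then anaphase returns it to 0.
#'
#' @param t_up end of the alignment ramp.
#' @param t_hold start of the anaphase down-ramp.
#' @param t_down end of the down-ramp.
#' @return data.frame with columns `time`, `X_tens` (vertices of a
#'   piecewise-linear ramp).
#' @export
tension_ramp <- function(t_up = 20, t_hold = 80, t_down = 100) {
  data.frame(time = c(0, t_up, t_hold, t_down),
             X_tens = c(0, 1, 1, 0))
}

#' Simulate in-vivo release of the mitotic checkpoint
#'
#' Runs [build_cycb_mcc_apc] (or [build_mcc_apc], for comparison) through
#' a piecewise-linear tension ramp.  In the CycB-coupled model the
#' checkpoint does not re-engage as `X_tens` decreases: APC has degraded
#' cyclin B, so tensionless kinetochores can no longer reactivate MCC
#' assembly.  In the basic MCC-APC model the same ramp re-engages the
#' checkpoint on the way down.
#'
#' @param params a [switch_params]; preset `"cycb_mcc_apc"` by default.
#' @param ramp data.frame of (`time`, `X_tens`) vertices, as from
#'   [tension_ramp].
#' @param model_builder [build_cycb_mcc_apc] or [build_mcc_apc].
#' @param horizon total simulated time (>= max ramp time).
#' @param n_out output samples.
#' @return a `switch_trajectory` with attribute `final_label`.
#' @export
mitotic_release_in_vivo <- function(params = switch_params("cycb_mcc_apc"),
                                    ramp = tension_ramp(),
                                    model_builder = build_cycb_mcc_apc,
                                    horizon = max(ramp$time) + 60,
                                    n_out = 480) {
  m0 <- model_builder(set_params(params, X_tens = 0))
  g <- m0$guesses(m0$params)
  eng <- integrate_to_steady_state(m0, g$engaged, t_max = 4000, tol = 1e-10)
  p <- m0$params
  xt <- function(t) {
    if (t >= max(ramp$time)) return(ramp$X_tens[nrow(ramp)])
    stats::approx(ramp$time, ramp$X_tens, xout = t, rule = 2)$y
  }
  fun <- function(t, y, parms) {
    pp <- p
    pp$X_tens <- min(max(xt(t), 0), 1)
    list(m0$rhs(pmax(y, 0), pp))
  }
  tt <- sort(unique(c(seq(0, horizon, length.out = n_out), ramp$time)))
  sol <- deSolve::lsoda(as.numeric(eng), tt, fun, NULL,
                        rtol = 1e-9, atol = 1e-11)
  traj <- as.data.frame(sol)
  names(traj) <- c("time", m0$vars)
  traj$X_tens <- vapply(traj$time, xt, numeric(1))
  if (!is.null(m0$derived)) {
    dv <- do.call(rbind, lapply(seq_len(nrow(traj)), function(i)
      m0$derived(as.numeric(traj[i, m0$vars]), p)))
    traj <- cbind(traj, as.data.frame(dv))
  }
  traj <- structure(traj, events = ramp$time, model = m0$name,
                    class = c("switch_trajectory", "data.frame"))
  pe <- p; pe$X_tens <- xt(horizon)
  attr(traj, "final_label") <-
    classify_state_raw(m0, as.numeric(traj[nrow(traj), m0$vars]), pe)
  traj
}
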