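test_that("event schedules are validated", {
  expect_error(event_schedule(c(5, 5), c("a", "a"), c(1, 2), 10),
               "strictly increasing")
  expect_error(event_schedule(c(5, 12), c("a", "a"), c(1, 2), 10),
               "within")
  s <- event_schedule(c(2, 4), c("I_T", "I_T"), c(2, 4), 10)
  expect_s3_class(s, "event_schedule")
})

test_that("an empty schedule from a steady state is a constant trajectory", {
  m <- build_preset_model("simm")
  ss <- find_steady_states(m, n_starts = 16)
  eng <- Filter(function(s) s$label == "engaged" && isTRUE(s$stable), ss)[[1]]
  traj <- simulate_schedule(m, schedule = event_schedule(horizon = 30),
                            init = as.numeric(eng$state))
  rng <- apply(as.matrix(traj[m$vars]), 2, function(v) diff(range(v)))
  expect_lt(max(rng), 1e-6)
  expect_gte(nrow(traj), 200)
})

test_that("a transient drop of total inhibitor locks the switch off", {
  ## abrupt inhibitor degradation at t = 10, then the signal relaxes and
  ## synthesis restores the total gradually (a bolus of unmodified
  ## inhibitor would overwhelm the enzyme; the lock-off is a property of
  ## the slow return path, which is how the signal acts)
  m <- build_preset_model("simm")
  ss <- find_steady_states(m, n_starts = 16)
  eng <- Filter(function(s) s$label == "engaged" && isTRUE(s$stable), ss)[[1]]
  restore <- seq(30, 120, by = 10)
  sched <- event_schedule(
    times = c(10, restore),
    symbols = rep("I_T", 1 + length(restore)),
    values = c(2, 2 + cumsum(rep(0.2, length(restore)))),
    horizon = 180)
  traj <- simulate_schedule(m, schedule = sched,
                            init = as.numeric(eng$state))
  xf <- as.numeric(traj[nrow(traj), m$vars])
  expect_equal(classify_state(m, xf), "disengaged")
  ## the total returned to its neutral value, yet the state did not
  expect_equal(sum(xf), 4, tolerance = 1e-6)
})

test_that("conserved sums hold piecewise between events", {
  m <- build_preset_model("simm")
  sched <- event_schedule(times = 15, symbols = "I_T", values = 2.2,
                          horizon = 30)
  traj <- simulate_schedule(m, schedule = sched, init = c(4, 0, 0, 0, 0))
  tot <- rowSums(as.matrix(traj[m$vars]))
  seg1 <- traj$time < 15
  expect_lt(max(abs(tot[seg1] - 4)), 1e-8)
  expect_lt(max(abs(tot[!seg1 & traj$time > 15] - 2.2)), 1e-8)
})

test_that("in-vitro checkpoint release shows the published lag and acceleration", {
  traj <- mitotic_release_in_vitro()
  lag <- attr(traj, "lag_time")
  ## functional MCC reaches the APC level after tens of minutes
  expect_equal(lag, 45, tolerance = 0.2)
  ## after the lag the loss of functional MCC accelerates:
  ## the log-decline steepens (negative second derivative)
  d <- as.data.frame(traj)
  post <- d[d$time > lag & d$time < lag + 20 & d$MCC_functional > 1e-6, ]
  lf <- log(post$MCC_functional)
  slope_early <- (lf[5] - lf[1]) / (post$time[5] - post$time[1])
  n <- nrow(post)
  slope_late <- (lf[n] - lf[n - 4]) / (post$time[n] - post$time[n - 4])
  expect_lt(slope_late, slope_early)
})

test_that("the release lag is caused by de-ubiquitination", {
  base <- mitotic_release_in_vitro()
  no_du <- mitotic_release_in_vitro(switch_params("mcc_apc", k_du = 0))
  expect_lt(attr(no_du, "lag_time"), attr(base, "lag_time"))
  ## monotone in the recycling and destruction rates around the preset
  lag_at <- function(k_du = 5, k_u = 10)
    attr(mitotic_release_in_vitro(
      switch_params("mcc_apc", k_du = k_du, k_u = k_u)), "lag_time")
  lags_du <- c(lag_at(k_du = 2.5), lag_at(k_du = 5), lag_at(k_du = 7.5),
               lag_at(k_du = 10))
  expect_true(all(diff(lags_du) > 0))
  lags_u <- c(lag_at(k_u = 5), lag_at(k_u = 10), lag_at(k_u = 15),
              lag_at(k_u = 20))
  expect_true(all(diff(lags_u) < 0))
})

test_that("in-vivo release is irreversible only with CycB coupling", {
  tv <- mitotic_release_in_vivo()
  expect_equal(attr(tv, "final_label"), "disengaged")
  d <- as.data.frame(tv)
  expect_lt(d$CycB[nrow(d)], 0.05)    # cyclin B destroyed by APC
  ## the uncoupled checkpoint re-engages on the way down
  tm <- mitotic_release_in_vivo(switch_params("mcc_apc"),
                                model_builder = build_mcc_apc)
  expect_equal(attr(tm, "final_label"), "engaged")
  ## a ramp that never reaches the threshold never disengages
  low <- mitotic_release_in_vivo(
    ramp = data.frame(time = c(0, 20, 60), X_tens = c(0, 0.85, 0)))
  expect_equal(attr(low, "final_label"), "engaged")
})

test_that("irreversibility of the in-vivo switch is structural, not kinetic", {
  ## tension is held long enough to complete release in both cases; the
  ## anaphase down-ramp is 40x faster in one than the other
  fast <- mitotic_release_in_vivo(ramp = tension_ramp(5, 70, 75),
                                  horizon = 130)
  slow <- mitotic_release_in_vivo(ramp = tension_ramp(5, 70, 270),
                                  horizon = 330)
  expect_equal(attr(fast, "final_label"), "disengaged")
  expect_equal(attr(slow, "final_label"), "disengaged")
})

test_that("the G1/S cycle disengages on cue and resets at division", {
  traj <- g1s_cycle_scenario()
  trans <- attr(traj, "transition_time")
  cd <- g1s_cyclin_defaults()
  expect_false(is.na(trans))
  expect_lt(trans, cd$t_cln_off)      # switches while both cyclins rise
  expect_equal(attr(traj, "final_label"), "engaged")
  d <- as.data.frame(traj)
  ## Sic1 collapses at the transition and re-accumulates after division
  expect_lt(min(d$SicT), 0.6)
  expect_gt(d$SicT[nrow(d)], 2.5)
  ## zero cyclin synthesis: the checkpoint never disengages
  cd0 <- cd; cd0$k_s_cln <- 0; cd0$k_s_clb <- 0
  t0 <- g1s_cycle_scenario(cyclin_dynamics = cd0)
  expect_true(is.na(attr(t0, "transition_time")))
})

test_that("the projected cyclin path crosses the fold locus as it switches", {
  ## control plane of the G1/S model in the (ClbT, ClnT) plane
  m <- build_preset_model("cln_sic_clb")
  pl <- map_control_plane(m, symbol_x = "ClnT", symbol_y = "ClbT",
                          range_x = c(0, 0.4), range_y = c(0.3, 1.4),
                          n_grid = 5, n_y = 12, n_starts = 12)
  traj <- as.data.frame(g1s_cycle_scenario())
  l <- pl$loci[!is.na(pl$loci$y_upper), ]
  ## time at which the rising path crosses the upper fold locus
  pre <- traj[traj$time <= g1s_cyclin_defaults()$t_cln_off, ]
  fold_at <- stats::approx(l$x, l$y_upper, xout = pmin(pre$ClnT, max(l$x)),
                           rule = 2)$y
  crossings <- which(diff(sign(pre$ClbT - fold_at)) > 0)
  expect_length(crossings, 1)
  t_cross <- pre$time[crossings[1]]
  ## disengagement follows the crossing after the slow escape from the
  ## vanished state (the crossing must precede detection, not lag it)
  trans <- attr(g1s_cycle_scenario(), "transition_time")
  expect_gt(trans, t_cross - 1)
  expect_lt(trans - t_cross, 25)
})

test_that("transition detection interpolates and reports misses", {
  traj <- data.frame(time = 0:10, y = seq(0, 5, length.out = 11))
  expect_equal(detect_transition(traj, "y", 2.25, "above"), 4.5)
  expect_true(is.na(detect_transition(traj, "y", 99, "above")))
  expect_true(is.na(detect_transition(traj, "y", -1, "below")))
  ## step observable: crossing within one sample of the step
  stp <- data.frame(time = 0:10, y = c(rep(0, 6), rep(1, 5)))
  expect_lt(abs(detect_transition(stp, "y", 0.5, "above") - 5.5), 1)
  ## internal consistency with the in-vitro lag report
  tr <- mitotic_release_in_vitro()
  expect_equal(detect_transition(tr, "MCC_functional", 1, "below"),
               attr(tr, "lag_time"))
})
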