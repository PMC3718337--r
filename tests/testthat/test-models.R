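test_that("conservation laws are annihilated by the RHS at random states", {
  set.seed(42)
  for (nm in c("simm", "simm_star")) {
    m <- build_preset_model(nm)
    for (i in 1:50) {
      x <- random_admissible_state(m)
      rate <- conservation_rate(m, x)
      expect_lt(max(abs(rate)), 1e-10)
      ## and the conserved values are what the pools sum to
      q <- conserved_quantities(m, x)
      expect_equal(unname(q["A_total"]), m$params$A_T, tolerance = 1e-12)
    }
  }
})

test_that("conserved totals are constant along integrated trajectories", {
  set.seed(7)
  for (nm in c("simm", "simm_star")) {
    m <- build_preset_model(nm)
    x0 <- random_admissible_state(m)
    sched <- event_schedule(horizon = 20)
    traj <- simulate_schedule(m, schedule = sched, init = x0)
    q <- apply(as.matrix(traj[m$vars]), 1, function(r)
      conserved_quantities(m, as.numeric(r))["I_total"])
    expect_lt(max(abs(q - q[1])), 1e-8)
  }
})

test_that("single-flux and no-enzyme limits match mass action", {
  ## only the first binding flux is active from the pure-I state
  m <- build_simm(switch_params("simm", A_T = 1.5, I_T = 4))
  d <- model_rhs(m, c(I = 4, I_M = 0, I_MM = 0, C = 0, C_M = 0))
  expect_equal(unname(d["I"]), -100 * 1.5 * 4)
  expect_equal(unname(d["C"]), 100 * 1.5 * 4)
  expect_equal(unname(d[c("I_M", "I_MM", "C_M")]), c(0, 0, 0))

  ## no enzyme: pure de-modification decay, everything returns to I
  ms <- build_simm_star(switch_params("simm_star", A_T = 0))
  x <- integrate_to_steady_state(ms, c(0, 1, 3, 0), t_max = 2000,
                                 tol = 1e-10)
  expect_equal(unname(x[["I"]]), 4, tolerance = 1e-6)
  expect_lt(x[["I_MM"]], 1e-8)
})

test_that("Sic1 balance without kinase gives the synthesis/turnover level", {
  m <- build_sic_clb(switch_params("sic_clb", ClbT = 0))
  ss <- find_steady_states(m, n_starts = 16)
  expect_length(ss, 1)
  expect_equal(unname(ss[[1]]$state[["SicT"]]), 0.2 / 0.05,
               tolerance = 1e-7)
  expect_lt(ss[[1]]$state[["ClbSic"]], 1e-9)
  expect_lt(ss[[1]]$state[["SicP"]], 1e-9)
})

test_that("Cln module ablation reduces the G1/S model to Sic-Clb", {
  m4 <- build_cln_sic_clb(switch_params("cln_sic_clb", ClnT = 0))
  m3 <- build_sic_clb(switch_params("sic_clb"))
  set.seed(11)
  for (i in 1:20) {
    x3 <- random_admissible_state(m3)
    x4 <- c(x3[1], x3[2], 0, x3[3])   # insert empty Cln:Sic pool
    d4 <- m4$rhs(x4, m4$params)
    d3 <- m3$rhs(x3, m3$params)
    expect_equal(d4[c(1, 2, 4)], d3, tolerance = 1e-12)
    expect_equal(d4[3], 0, tolerance = 1e-12)
  }
})

test_that("checkpoint-absent limit of the MCC-APC model", {
  p <- switch_params("mcc_apc", X_tens = 1)
  m <- build_mcc_apc(p)
  ## no MCC production, APC fully free, securin at its open-loop balance
  x <- integrate_to_steady_state(m, c(0, 0, 2), t_max = 2000, tol = 1e-10)
  expect_lt(x[["MCCT"]], 1e-8)
  sec_ss <- 0.1 / (0.05 + 0.5 * 1)
  expect_equal(unname(x[["Sec"]]), sec_ss, tolerance = 1e-6)
  d <- simmswitch:::model_plist(m)
  expect_equal(unname(m$derived(as.numeric(x), d)[["APC"]]), 1,
               tolerance = 1e-7)
})

test_that("nonnegativity along trajectories from admissible starts", {
  set.seed(3)
  for (nm in names(model_builders)) {
    m <- build_preset_model(nm)
    x0 <- random_admissible_state(m)
    traj <- simulate_schedule(m, schedule = event_schedule(horizon = 50),
                              init = x0)
    expect_gt(min(as.matrix(traj[m$vars])), -1e-8)
  }
})

test_that("dimensionless observables survive a concentration rescaling", {
  ## multiply all concentrations by 10, divide bimolecular constants by 10
  s <- 10
  m0 <- build_simm(switch_params("simm"))
  m1 <- build_simm(switch_params("simm", A_T = 1 * s, I_T = 4 * s,
                                 k_as1 = 100 / s, k_as2 = 50 / s))
  ss0 <- find_steady_states(m0, n_starts = 32)
  ss1 <- find_steady_states(m1, n_starts = 32)
  expect_length(ss1, length(ss0))
  obs0 <- vapply(ss0, `[[`, numeric(1), "observable")
  obs1 <- vapply(ss1, `[[`, numeric(1), "observable")
  expect_equal(obs1 / s, obs0, tolerance = 1e-6)
})

test_that("missing symbols and invalid states are rejected", {
  expect_error(build_simm(switch_params("simm_star")), "missing parameter")
  expect_error(build_mcc_apc(switch_params("sic_clb")), "missing parameter")
  m <- build_simm(switch_params("simm"))
  expect_error(model_rhs(m, c(1, 2, 3)), "components")
})
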