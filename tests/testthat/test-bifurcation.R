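test_that("sweep and quasi-static continuation agree on the SIMM folds", {
  m <- build_preset_model("simm")
  sw <- sweep_signal_response(m, sweep_symbol = "I_T", range = c(1.8, 3.2),
                              n_points = 15, n_starts = 16)
  expect_equal(nrow(sw$folds), 1)
  expect_equal(sw$folds$vanishing, "engaged")
  th <- find_threshold(m, sweep_symbol = "I_T", from = 4, to = 1.5,
                       start_label = "engaged")
  expect_true(th$found)
  ## two independent routes to the same saddle-node
  expect_equal(th$value, sw$folds$value, tolerance = 1e-3)

  th_a <- find_threshold(m, sweep_symbol = "A_T", from = 1, to = 2.5,
                         start_label = "engaged")
  expect_true(th_a$found)
  expect_equal(th_a$value, 1.637, tolerance = 1e-2)
})

test_that("a sweep confined to a monostable region has no folds", {
  m <- build_preset_model("simm")
  sw <- sweep_signal_response(m, sweep_symbol = "A_T", range = c(2, 3),
                              n_points = 10, n_starts = 12)
  expect_equal(nrow(sw$folds), 0)
  expect_equal(length(unique(sw$points$branch)), 1)
  expect_true(all(sw$points$stable))
})

test_that("branches are stability-homogeneous and root counts odd inside the fold pair", {
  m <- build_preset_model("simm")
  sw <- sweep_signal_response(m, sweep_symbol = "A_T", range = c(0.5, 2.2),
                              n_points = 18, n_starts = 16)
  for (b in unique(sw$points$branch))
    expect_length(unique(sw$points$stable[sw$points$branch == b]), 1)
  expect_equal(nrow(sw$folds), 2)
  counts <- table(sw$points$A_T)
  expect_true(all(counts %in% c(1, 3)))
  inside <- as.numeric(names(counts)) > min(sw$folds$value) &
            as.numeric(names(counts)) < max(sw$folds$value)
  expect_true(all(counts[inside] == 3))
  expect_true(all(counts[!inside] == 1))
})

test_that("the control plane brackets the neutral point and matches the root-count oracle", {
  m <- build_preset_model("simm")
  pl <- map_control_plane(m, symbol_x = "I_T", symbol_y = "A_T",
                          range_x = c(2.5, 5.5), range_y = c(0.3, 2.8),
                          n_grid = 6, n_y = 11, n_starts = 12)
  expect_equal(plane_membership(pl, 4, 1), "bistable")
  l <- pl$loci
  expect_true(all(l$y_upper >= l$y_lower, na.rm = TRUE))
  ## membership equals the parity of the root count at probe points
  set.seed(8)
  for (i in 1:8) {
    x <- stats::runif(1, 2.6, 5.4); y <- stats::runif(1, 0.35, 2.7)
    memb <- plane_membership(pl, x, y)
    n <- length(find_steady_states(
      build_simm(switch_params("simm", I_T = x, A_T = y)), n_starts = 24))
    if (identical(memb, "bistable")) expect_equal(n, 3)
    else if (!is.na(memb)) expect_equal(n, 1)
  }
})

test_that("simplified and full motifs share fold thresholds within 5%", {
  for (at in c(0.5, 1, 2)) {
    m_full <- build_preset_model("simm", A_T = at)
    m_star <- build_preset_model("simm_star", A_T = at)
    f_full <- find_threshold(m_full, sweep_symbol = "I_T",
                             from = 4 * at, to = 0.5 * at,
                             start_label = "engaged")
    f_star <- find_threshold(m_star, sweep_symbol = "I_T",
                             from = 4 * at, to = 0.5 * at,
                             start_label = "engaged")
    expect_true(f_full$found && f_star$found)
    expect_lt(abs(f_star$value - f_full$value) / f_full$value, 0.05)
  }
})

test_that("irreversible switching and resetting along control-plane paths", {
  m <- build_preset_model("simm")
  ## crossing the upper boundary and returning locks disengagement
  h_b <- hysteresis_protocol(m, path = data.frame(I_T = c(4, 2, 4)),
                             dwell = 150, start_label = "engaged")
  expect_equal(h_b$label, c("engaged", "disengaged", "disengaged"))
  h_c <- hysteresis_protocol(m, path = data.frame(A_T = c(1, 2, 1)),
                             dwell = 150, start_label = "engaged")
  expect_equal(h_c$label, c("engaged", "disengaged", "disengaged"))
  ## crossing the lower boundary resets the checkpoint
  h_r <- hysteresis_protocol(m, path = data.frame(I_T = c(4, 6.5, 4)),
                             dwell = 150, start_label = "disengaged")
  expect_equal(h_r$label, c("disengaged", "engaged", "engaged"))
  ## a loop inside one monostable region changes nothing
  h_0 <- hysteresis_protocol(m, path = data.frame(I_T = c(8, 7, 8)),
                             dwell = 100, start_label = "engaged")
  expect_equal(unique(h_0$label), "engaged")
  expect_true(all(h_b$settled))
})

test_that("mitotic checkpoint thresholds: disengage near 1, re-engage below", {
  m <- build_preset_model("mcc_apc")
  up <- find_threshold(m, sweep_symbol = "X_tens", from = 0, to = 1,
                       start_label = "engaged")
  dn <- find_threshold(m, sweep_symbol = "X_tens", from = 1, to = 0,
                       start_label = "disengaged")
  expect_true(up$found && dn$found)
  expect_equal(up$value, 0.97, tolerance = 0.021)
  expect_equal(dn$value, 0.89, tolerance = 0.021)
  expect_gt(up$value, dn$value)  # a genuine bistable window
})

test_that("CycB coupling removes the re-engagement fold entirely", {
  m <- build_preset_model("cycb_mcc_apc")
  dn <- find_threshold(m, sweep_symbol = "X_tens", from = 1, to = 0,
                       start_label = "disengaged")
  expect_false(dn$found)
  expect_true(is.na(dn$value))
})
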