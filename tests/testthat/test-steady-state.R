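test_that("root sets match the published phase-plane counts", {
  ss <- find_steady_states(build_preset_model("simm_star", A_T = 2, I_T = 6))
  expect_length(ss, 3)
  expect_equal(vapply(ss, function(s) isTRUE(s$stable), logical(1)),
               c(TRUE, FALSE, TRUE))
  ss1 <- find_steady_states(build_preset_model("simm_star", A_T = 3, I_T = 6))
  expect_length(ss1, 1)
  expect_true(isTRUE(ss1[[1]]$stable))
  for (s in c(ss, ss1)) expect_lt(s$residual, 1e-9)
})

test_that("results are deterministic given the seed", {
  m <- build_preset_model("simm")
  a <- as.data.frame(find_steady_states(m, n_starts = 24, seed = 5))
  b <- as.data.frame(find_steady_states(m, n_starts = 24, seed = 5))
  expect_identical(a, b)
})

test_that("Newton roots and the integration oracle agree both ways", {
  set.seed(19)
  for (nm in c("simm", "mcc_apc", "sic_clb")) {
    m <- build_preset_model(nm)
    ss <- find_steady_states(m, n_starts = 32)
    stable <- Filter(function(s) isTRUE(s$stable), ss)
    ## every stable Newton root is recovered by relaxing a perturbed start
    for (s in stable) {
      x0 <- perturb_on_manifold(m, s$state)
      xf <- integrate_to_steady_state(m, x0, t_max = 3000, tol = 1e-10)
      expect_equal(as.numeric(xf), as.numeric(s$state), tolerance = 1e-5)
    }
    ## every attractor reached from random starts appears in the root list
    root_mat <- do.call(rbind, lapply(stable, function(s) as.numeric(s$state)))
    for (i in 1:10) {
      x0 <- random_on_manifold(m)
      xf <- integrate_to_steady_state(m, x0, t_max = 5000, tol = 1e-9)
      d <- apply(root_mat, 1, function(r)
        max(abs(r - as.numeric(xf))) / max(1, max(abs(r))))
      expect_lt(min(d), 1e-4)
    }
  }
})

test_that("the middle root of a bistable triple is a genuine separatrix", {
  m <- build_preset_model("simm_star", A_T = 2, I_T = 6)
  ss <- find_steady_states(m, n_starts = 32)
  mid <- ss[[2]]
  expect_false(isTRUE(mid$stable))
  ## perturbed integration leaves it for one of the outer attractors
  set.seed(2)
  x0 <- perturb_on_manifold(m, mid$state)
  xf <- integrate_to_steady_state(m, x0, t_max = 4000, tol = 1e-9)
  d_outer <- min(
    max(abs(as.numeric(xf) - as.numeric(ss[[1]]$state))),
    max(abs(as.numeric(xf) - as.numeric(ss[[3]]$state))))
  expect_lt(d_outer, 1e-5)
})

test_that("classify_stability enforces its root precondition", {
  m <- build_preset_model("simm")
  ss <- find_steady_states(m, n_starts = 16)
  r <- classify_stability(m, ss[[1]]$state)
  expect_identical(r$stable, ss[[1]]$stable)
  expect_error(classify_stability(m, as.numeric(ss[[1]]$state) + 0.1),
               "not a steady state")
})

test_that("integration from a root returns immediately, timeouts flagged", {
  m <- build_preset_model("simm")
  ss <- find_steady_states(m, n_starts = 16)
  x <- integrate_to_steady_state(m, as.numeric(ss[[1]]$state))
  expect_true(attr(x, "converged"))
  expect_equal(attr(x, "time"), 0)
  ## an impossible tolerance cannot converge in the time allowed
  x2 <- integrate_to_steady_state(m, random_admissible_state(m),
                                  t_max = 0.25, tol = 1e-300)
  expect_false(attr(x2, "converged"))
})

test_that("steady states export as TSV with stable column order", {
  m <- build_preset_model("simm_star", A_T = 2, I_T = 6)
  ss <- find_steady_states(m)
  f <- tempfile(fileext = ".tsv")
  write_steady_states_tsv(ss, f)
  df <- utils::read.delim(f)
  expect_equal(nrow(df), 3)
  expect_equal(names(df)[1:4], c("I", "I_M", "I_MM", "C"))
  expect_true(all(c("stable", "label", "max_re_eig") %in% names(df)))
})
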