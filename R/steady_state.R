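## Steady-state location and stability classification.
##
## Root finding operates on the reduced system (conserved directions
## eliminated through the conservation identities), so the Jacobian at a
## hyperbolic root is nonsingular.  Stability is judged on the reduced
## Jacobian's spectrum with margin `stability_eps`.

## internal: resolve plain parameter list
model_plist <- function(model, params = NULL) {
  if (is.null(params)) model$params
  else need_params(params, model$required)
}

## internal: reduced RHS closure
reduced_rhs <- function(model, p) {
  idx <- model$free_idx
  function(y) model$rhs(model$lift(y, p), p)[idx]
}

## internal: central-difference Jacobian, step scaled to coordinate size
num_jacobian <- function(f, y, rel_step = 1e-7) {
  n <- length(y)
  J <- matrix(0, n, n)
  for (i in seq_len(n)) {
    h <- rel_step * max(1, abs(y[i]))
    yp <- y; yp[i] <- y[i] + h
    ym <- y; ym[i] <- y[i] - h
    J[, i] <- (f(yp) - f(ym)) / (2 * h)
  }
  J
}

## internal: damped (backtracking) Newton iteration
newton_solve <- function(f, y0, tol = 1e-11, maxit = 60) {
  y <- y0
  r <- f(y)
  if (any(!is.finite(r))) return(list(ok = FALSE))
  for (it in seq_len(maxit)) {
    nr <- max(abs(r))
    if (nr < tol) return(list(root = y, ok = TRUE))
    J <- num_jacobian(f, y)
    step <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(list(ok = FALSE))
    lambda <- 1
    repeat {
      yn <- y + lambda * step
      rn <- f(yn)
      if ((all(is.finite(rn)) && max(abs(rn)) < nr) || lambda < 1e-7) break
      lambda <- lambda / 2
    }
    y <- yn; r <- rn
    if (lambda < 1e-7) break
  }
  list(root = y, ok = max(abs(f(y))) < 10 * tol)
}

## internal: build one steady-state record from a reduced root
make_steady_state <- function(model, y, p,
                              stability_eps = 1e-6) {
  x <- model$lift(y, p)
  f <- reduced_rhs(model, p)
  J <- num_jacobian(f, y)
  ev <- tryCatch(eigen(J, only.values = TRUE)$values,
                 error = function(e) rep(NA_complex_, length(y)))
  mre <- suppressWarnings(max(Re(ev)))
  degenerate <- !is.finite(mre) || abs(mre) <= stability_eps
  stable <- if (degenerate) NA else mre < -stability_eps
  structure(list(
    state = stats::setNames(x, model$vars),
    residual = max(abs(model$rhs(x, p))),
    eigenvalues = ev,
    stable = stable,
    degenerate = degenerate,
    label = classify_state_raw(model, x, p),
    observable = model$observable(x, p)
  ), class = "steady_state")
}

classify_state_raw <- function(model, x, p) {
  a <- model$activity(x, p)
  if (a < model$engaged_below) "engaged"
  else if (a > model$disengaged_above) "disengaged"
  else "intermediate"
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("steady state [%s, %s]: ", x$label,
              if (isTRUE(x$stable)) "stable"
              else if (isFALSE(x$stable)) "unstable" else "degenerate"))
  cat(paste(sprintf("%s=%.5g", names(x$state), x$state), collapse = ", "))
  cat(sprintf("\n  residual %.2e, max Re(eig) %.4g\n",
              x$residual, max(Re(x$eigenvalues))))
  invisible(x)
}

#' Locate all steady states of a model
#'
#' Multi-start damped-Newton search on the reduced system.  Start points
#' are a Latin-hypercube sample of the admissible box plus the model's
#' engaged/disengaged corner guesses and any user-supplied warm starts.
#' Roots are deduplicated at relative tolerance `dedup_tol` and sorted by
#' the model's primary observable.  Deterministic for a given `seed`.
#'
#' @param model a `switch_model`.
#' @param params optional [switch_params] overriding the build-time set.
#' @param n_starts number of Latin-hypercube start points (>= 1).
#' @param seed integer seed for start-point sampling.
#' @param extra_starts optional list of reduced-coordinate start vectors
#'   (warm starts, e.g. roots found at a neighbouring parameter value).
#' @param dedup_tol relative deduplication tolerance.
#' @param dedup_abs absolute deduplication floor; near a fold the locus
#'   of near-zero residual flattens, and candidate roots closer than this
#'   are one root.
#' @param residual_tol maximum admissible residual (max-norm of the RHS).
#' @param stability_eps margin for the stable/unstable call; eigenvalue
#'   real parts within the margin flag the root degenerate.
#' @return an object of class `steady_state_list`: a list of
#'   `steady_state` records (`state`, `residual`, `eigenvalues`, `stable`,
#'   `degenerate`, `label`).  Empty if no root was found.
#' @examples
#' m <- build_simm_star(switch_params("simm_star", A_T = 2, I_T = 6))
#' ss <- find_steady_states(m)
#' length(ss)          # 3: engaged, intermediate, disengaged
#' @export
find_steady_states <- function(model, params = NULL, n_starts = 64,
                               seed = 0, extra_starts = NULL,
                               dedup_tol = 1e-6, dedup_abs = 5e-5,
                               residual_tol = 1e-9,
                               stability_eps = 1e-6) {
  stopifnot(n_starts >= 1)
  p <- model_plist(model, params)
  f <- reduced_rhs(model, p)
  box <- model$box(p)
  d <- ncol(box)
  span <- box["upper", ] - box["lower", ]

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  u <- lhs::randomLHS(n_starts, d)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())

  starts <- lapply(seq_len(n_starts), function(i)
    box["lower", ] + u[i, ] * span)
  starts <- c(starts, unname(model$guesses(p)), as.list(extra_starts))

  roots <- list()
  for (s in starts) {
    if (length(s) != d) next
    res <- newton_solve(f, as.numeric(s))
    if (!res$ok) next
    y <- res$root
    y[abs(y) < 1e-13] <- 0
    x <- model$lift(y, p)
    if (!admissible_state(model, x, p, tol = 1e-7)) next
    if (max(abs(model$rhs(x, p))) > residual_tol) next
    dup <- any(vapply(roots, function(r)
      max(abs(r - y)) < max(dedup_tol * max(1, max(abs(y))), dedup_abs),
      logical(1)))
    if (!dup) roots[[length(roots) + 1]] <- y
  }

  out <- lapply(roots, make_steady_state, model = model, p = p,
                stability_eps = stability_eps)
  ord <- order(vapply(out, `[[`, numeric(1), "observable"))
  structure(out[ord], class = "steady_state_list")
}

#' @export
print.steady_state_list <- function(x, ...) {
  cat(length(x), "steady state(s)\n")
  for (s in x) print(s)
  invisible(x)
}

#' @export
as.data.frame.steady_state_list <- function(x, ...) {
  if (!length(x)) return(data.frame())
  states <- do.call(rbind, lapply(x, function(s) as.data.frame(t(s$state))))
  cbind(states,
        residual = vapply(x, `[[`, numeric(1), "residual"),
        max_re_eig = vapply(x, function(s) max(Re(s$eigenvalues)), numeric(1)),
        stable = vapply(x, `[[`, logical(1), "stable"),
        degenerate = vapply(x, `[[`, logical(1), "degenerate"),
        label = vapply(x, `[[`, character(1), "label"))
}

#' Classify the stability of a steady state
#'
#' Computes the reduced-system Jacobian by central finite differences at a
#' state that must already be a root (residual below `residual_tol`), and
#' classifies it by the sign of the leading eigenvalue real part.
#'
#' @param model a `switch_model`.
#' @param state full state vector (a root of the RHS).
#' @param params optional [switch_params].
#' @param residual_tol precondition: residual must be below this.
#' @param stability_eps stability margin.
#' @return a `steady_state` record.
#' @export
classify_stability <- function(model, state, params = NULL,
                               residual_tol = 1e-9, stability_eps = 1e-6) {
  p <- model_plist(model, params)
  x <- as.numeric(state)
  if (max(abs(model$rhs(x, p))) > residual_tol)
    stop("state is not a steady state (residual ",
         format(max(abs(model$rhs(x, p)))), " > ", residual_tol, ")",
         call. = FALSE)
  make_steady_state(model, x[model$free_idx], p,
                    stability_eps = stability_eps)
}

#' Integrate a model until it settles at a steady state
#'
#' Stiff integration (deSolve::lsoda) in growing time chunks until the
#' max-norm of the RHS drops below `tol` or `t_max` is reached.  Serves as
#' the brute-force oracle for [find_steady_states] and the work-horse of
#' the quasi-static continuation protocols.
#'
#' @param model a `switch_model`.
#' @param init full initial state (admissible).
#' @param params optional [switch_params].
#' @param t_max maximum integration time (T units).
#' @param tol convergence tolerance on the RHS max-norm (U/T).
#' @return the final state, named, with attributes `converged` (logical;
#'   `FALSE` flags a timeout) and `time` (time used).
#' @export
integrate_to_steady_state <- function(model, init, params = NULL,
                                      t_max = 5000, tol = 1e-9) {
  p <- model_plist(model, params)
  x <- as.numeric(init)
  ## generous slack: quasi-static protocols hand over states with
  ## solver-overshoot inconsistencies of order 1e-5
  if (!admissible_state(model, x, p, tol = 1e-4))
    stop("initial state is not admissible", call. = FALSE)
  t_used <- 0
  chunk <- 10
  while (t_used < t_max) {
    if (max(abs(model$rhs(x, p))) < tol) break
    chunk <- min(chunk, t_max - t_used)
    ## near a fold the relaxation is critically slow; a chunk that hits
    ## maxsteps simply continues in the next chunk, so the solver's
    ## early-return warning carries no information here
    sol <- suppressWarnings(deSolve::lsoda(
      y = x, times = c(0, chunk),
      func = function(t, y, parms) list(model$rhs(pmax(y, 0), p)),
      rtol = 1e-10, atol = 1e-12, maxsteps = 200000))
    x <- pmax(as.numeric(sol[nrow(sol), -1]), 0)
    t_used <- t_used + chunk
    chunk <- min(chunk * 2, 100)
  }
  converged <- max(abs(model$rhs(x, p))) < tol
  structure(stats::setNames(x, model$vars),
            converged = converged, time = t_used)
}

#' Export steady states as TSV
#'
#' One row per root: state values, leading eigenvalue real part, stability
#' flag and checkpoint label.
#'
#' @param x a `steady_state_list`.
#' @param path output file path.
#' @export
write_steady_states_tsv <- function(x, path) {
  df <- as.data.frame(x)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
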