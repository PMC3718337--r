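## Signal-response curves (1-parameter bifurcation diagrams with fold
## points), control planes (2-parameter bistable regions) and
## hysteresis protocols.
##
## Fold location uses root-count bisection over parameter grids rather
## than pseudo-arclength continuation -- adequate for these small
## (<= 6-variable) S-shaped systems and much simpler to make robust.

## internal: root set at one plain parameter list
find_roots_plist <- function(model, p, n_starts = 24, seed = 0,
                             warm = NULL, stability_eps = 1e-6) {
  m2 <- model
  m2$params <- p
  find_steady_states(m2, params = NULL, n_starts = n_starts, seed = seed,
                     extra_starts = warm, stability_eps = stability_eps)
}

reduced_coords <- function(model, ss)
  lapply(ss, function(s) as.numeric(s$state)[model$free_idx])

#' Sweep a signal-response curve
#'
#' Computes the steady-state branches of `model` as one parameter is swept
#' over a range, locating fold (saddle-node) points by bisection on the
#' root count between adjacent grid values.  Branches are assembled by
#' nearest-neighbour continuation and are stability-homogeneous.
#'
#' @param model a `switch_model`.
#' @param params optional [switch_params].
#' @param sweep_symbol parameter to sweep.
#' @param range length-2 numeric range.
#' @param n_points number of grid points (>= 10).
#' @param n_starts multi-start budget per grid value (warm starts from the
#'   neighbouring grid value are added automatically).
#' @param seed seed for start sampling.
#' @param fold_tol relative parameter tolerance for fold bisection.
#' @param refine_max maximum number of local grid refinements (factor 4)
#'   when the root count changes by more than 2 between neighbours.
#' @return an object of class `bifurcation_diagram` with elements
#'   `points` (data.frame: parameter value, state columns, `observable`,
#'   `stable`, `label`, `branch`) and `folds` (data.frame: `symbol`,
#'   `value`, `vanishing` -- the label of the stable branch that
#'   disappears there).
#' @examples
#' \donttest{
#' m <- build_simm(switch_params("simm"))
#' sw <- sweep_signal_response(m, sweep_symbol = "I_T", range = c(1.5, 6))
#' sw$folds
#' }
#' @export
sweep_signal_response <- function(model, params = NULL, sweep_symbol,
                                  range, n_points = 40, n_starts = 24,
                                  seed = 0, fold_tol = 1e-4,
                                  refine_max = 2) {
  stopifnot(n_points >= 10, length(range) == 2)
  p <- model_plist(model, params)
  grid <- seq(range[1], range[2], length.out = n_points)

  scan <- vector("list", length(grid))
  warm <- NULL
  for (i in seq_along(grid)) {
    p[[sweep_symbol]] <- grid[i]
    ss <- find_roots_plist(model, p, n_starts, seed, warm)
    scan[[i]] <- ss
    warm <- reduced_coords(model, ss)
  }
  counts <- lengths(scan)

  ## refine where the count jumps by more than 2 (grid too coarse)
  refine <- 0
  while (any(abs(diff(counts)) > 2) && refine < refine_max) {
    refine <- refine + 1
    j <- which(abs(diff(counts)) > 2)[1]
    newg <- seq(grid[j], grid[j + 1], length.out = 6)[2:5]
    ins <- lapply(newg, function(v) {
      p[[sweep_symbol]] <- v
      find_roots_plist(model, p, n_starts, seed,
                       reduced_coords(model, scan[[j]]))
    })
    grid <- append(grid, newg, after = j)
    scan <- append(scan, ins, after = j)
    counts <- lengths(scan)
  }
  if (any(abs(diff(counts)) > 2))
    stop("root count changes by more than 2 between adjacent grid values; ",
         "increase n_points", call. = FALSE)

  ## bisect each count change to locate the fold
  folds <- data.frame(symbol = character(), value = numeric(),
                      vanishing = character(), stringsAsFactors = FALSE)
  for (j in which(diff(counts) != 0)) {
    lo <- grid[j]; hi <- grid[j + 1]
    c_lo <- counts[j]
    ss_many <- if (counts[j] > counts[j + 1]) scan[[j]] else scan[[j + 1]]
    warm <- reduced_coords(model, ss_many)
    while (abs(hi - lo) > fold_tol * max(1, abs(hi), abs(lo))) {
      mid <- (lo + hi) / 2
      p[[sweep_symbol]] <- mid
      n_mid <- length(find_roots_plist(model, p, n_starts, seed, warm))
      if (n_mid == c_lo) lo <- mid else hi <- mid
    }
    fold_value <- (lo + hi) / 2
    ## the branch that disappears: the stable root on the many-root side
    ## that has no close partner on the few-root side
    ss_few <- if (counts[j] > counts[j + 1]) scan[[j + 1]] else scan[[j]]
    few_obs <- vapply(ss_few, `[[`, numeric(1), "observable")
    vanish <- "unknown"
    for (s in ss_many) {
      if (!isTRUE(s$stable)) next
      if (!length(few_obs) ||
          min(abs(few_obs - s$observable)) >
            0.2 * max(1e-8, abs(s$observable), max(abs(few_obs)))) {
        vanish <- s$label
        break
      }
    }
    folds <- rbind(folds, data.frame(symbol = sweep_symbol,
                                     value = fold_value,
                                     vanishing = vanish,
                                     stringsAsFactors = FALSE))
  }

  ## assemble branch membership by nearest-neighbour continuation
  pts <- list()
  branch_states <- list()   # branch id -> last reduced root
  branch_stable <- logical()
  next_id <- 0L
  for (i in seq_along(grid)) {
    for (s in scan[[i]]) {
      y <- as.numeric(s$state)[model$free_idx]
      id <- NA_integer_
      if (length(branch_states)) {
        cand <- which(branch_stable == isTRUE(s$stable))
        if (length(cand)) {
          dists <- vapply(cand, function(k)
            max(abs(branch_states[[k]] - y)) / max(1, max(abs(y))),
            numeric(1))
          k <- cand[which.min(dists)]
          if (min(dists) < 0.25) id <- k
        }
      }
      if (is.na(id)) {
        next_id <- next_id + 1L
        id <- next_id
      }
      branch_states[[id]] <- y
      branch_stable[id] <- isTRUE(s$stable)
      row <- as.data.frame(t(s$state))
      row[[sweep_symbol]] <- grid[i]
      row$observable <- s$observable
      row$stable <- s$stable
      row$label <- s$label
      row$branch <- id
      pts[[length(pts) + 1]] <- row
    }
  }
  points <- do.call(rbind, pts)
  points <- points[, c(sweep_symbol, model$vars, "observable", "stable",
                       "label", "branch")]

  structure(list(model = model$name, symbol = sweep_symbol, range = range,
                 points = points, folds = folds),
            class = "bifurcation_diagram")
}

#' @export
print.bifurcation_diagram <- function(x, ...) {
  cat("Signal-response sweep of '", x$symbol, "' over [",
      x$range[1], ", ", x$range[2], "] (", x$model, ")\n", sep = "")
  cat(" ", nrow(x$points), "branch points,", nrow(x$folds), "fold(s)\n")
  if (nrow(x$folds)) print(x$folds)
  invisible(x)
}

#' @export
plot.bifurcation_diagram <- function(x, ...) {
  pts <- x$points
  graphics::plot(pts[[x$symbol]], pts$observable, type = "n",
                 xlab = paste(x$symbol, "(U)"), ylab = "observable (U)", ...)
  for (b in unique(pts$branch)) {
    sel <- pts$branch == b
    graphics::lines(pts[[x$symbol]][sel], pts$observable[sel],
                    lty = if (isTRUE(pts$stable[sel][1])) 1 else 2)
  }
  if (nrow(x$folds))
    graphics::abline(v = x$folds$value, col = "grey60", lty = 3)
  invisible(x)
}

#' Export a bifurcation diagram as TSV
#' @param x a `bifurcation_diagram`.
#' @param path output file path.
#' @export
write_diagram_tsv <- function(x, path) {
  utils::write.table(x$points, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Quasi-static threshold (fold) detection along an occupied branch
#'
#' Tracks the branch occupied by the system while a parameter drifts
#' quasi-statically from `from` to `to`: at each step, the previous
#' settled state is relaxed to steady state at the new parameter value.
#' The fold is bracketed where the settled state's checkpoint label
#' changes, then bisected.  This is a genuinely different route to the
#' fold than the root counting of [sweep_signal_response]; the two must
#' agree within tolerance.
#'
#' @param model a `switch_model`.
#' @param params optional [switch_params].
#' @param sweep_symbol parameter to vary.
#' @param from,to start and end of the sweep (direction implied).
#' @param init full state on the occupied stable branch at `from`; if
#'   `NULL`, the branch is selected by `start_label`.
#' @param start_label `"engaged"` or `"disengaged"`; used to pick the
#'   occupied branch when `init` is `NULL`.
#' @param n_coarse number of coarse quasi-static steps.
#' @param fold_tol relative parameter tolerance of the bisection.
#' @param settle_t maximum settling time per step (T units).
#' @return an object of class `fold_point`: list with `symbol`, `value`
#'   (NA if no fold in range), `vanishing` (starting label), `found`.
#' @export
find_threshold <- function(model, params = NULL, sweep_symbol, from, to,
                           init = NULL, start_label = NULL,
                           n_coarse = 25, fold_tol = 1e-4,
                           settle_t = 4000) {
  p <- model_plist(model, params)
  p[[sweep_symbol]] <- from
  if (is.null(init)) {
    ss <- find_roots_plist(model, p, n_starts = 32, seed = 0)
    stab <- Filter(function(s) isTRUE(s$stable), ss)
    if (!length(stab))
      stop("no stable steady state at the range start", call. = FALSE)
    if (!is.null(start_label))
      stab <- Filter(function(s) s$label == start_label, stab)
    if (!length(stab))
      stop("no stable '", start_label, "' state at the range start",
           call. = FALSE)
    init <- stab[[1]]$state
  }
  m2 <- model
  v_cur <- from
  settle <- function(x, v) {
    pp <- p; pp[[sweep_symbol]] <- v
    p_old <- p; p_old[[sweep_symbol]] <- v_cur
    x <- rebase_state(model, x, p_old, pp)
    m2$params <- pp
    out <- integrate_to_steady_state(m2, x, t_max = settle_t, tol = 1e-9)
    v_cur <<- v
    out
  }
  x <- settle(as.numeric(init), from)
  label0 <- {
    pp <- p; pp[[sweep_symbol]] <- from
    classify_state_raw(model, as.numeric(x), pp)
  }
  if (label0 == "intermediate")
    stop("starting state has no well-defined checkpoint label",
         call. = FALSE)
  opposite <- if (label0 == "engaged") "disengaged" else "engaged"
  ## the occupied branch may drift through "intermediate" while it still
  ## exists; the fold is where the settled state lands on the opposite
  ## attractor
  steps <- seq(from, to, length.out = n_coarse + 1)[-1]
  lo <- from; hi <- NA
  for (v in steps) {
    xn <- settle(x, v)
    pp <- p; pp[[sweep_symbol]] <- v
    if (classify_state_raw(model, as.numeric(xn), pp) == opposite) {
      hi <- v
      break
    }
    x <- xn; lo <- v
  }
  if (is.na(hi))
    return(structure(list(symbol = sweep_symbol, value = NA_real_,
                          vanishing = label0, found = FALSE),
                     class = "fold_point"))
  while (abs(hi - lo) > fold_tol * max(1, abs(hi), abs(lo))) {
    mid <- (lo + hi) / 2
    v_cur <- lo
    xm <- settle(x, mid)
    pp <- p; pp[[sweep_symbol]] <- mid
    if (classify_state_raw(model, as.numeric(xm), pp) != opposite) {
      lo <- mid; x <- xm
    } else hi <- mid
  }
  structure(list(symbol = sweep_symbol, value = (lo + hi) / 2,
                 vanishing = label0, found = TRUE),
            class = "fold_point")
}

#' @export
print.fold_point <- function(x, ...) {
  if (x$found)
    cat(sprintf("fold: %s = %.6g (the %s branch disappears)\n",
                x$symbol, x$value, x$vanishing))
  else cat("no fold found in range (started", x$vanishing, ")\n")
  invisible(x)
}

#' Map a two-parameter control plane
#'
#' For each value of the first parameter on a grid, performs a
#' one-parameter fold search in the second parameter (root-count sweep
#' plus bisection) and assembles the lower and upper fold loci bounding
#' the bistable region.
#'
#' @param model a `switch_model`.
#' @param params optional [switch_params].
#' @param symbol_x,symbol_y the two control parameters.
#' @param range_x,range_y length-2 ranges.
#' @param n_grid grid resolution along x (>= 5 columns; the y fold search
#'   uses `n_y` points plus bisection).
#' @param n_y points of the y root-count sweep per column.
#' @param n_starts multi-start budget per point.
#' @param fold_tol relative bisection tolerance.
#' @return an object of class `control_plane`: data.frame `loci` with
#'   columns `x`, `y_lower`, `y_upper` (NA where the column is
#'   monostable), labels of the monostable sides, and the inputs needed by
#'   [plane_membership].
#' @export
map_control_plane <- function(model, params = NULL, symbol_x, symbol_y,
                              range_x, range_y, n_grid = 20, n_y = 21,
                              n_starts = 16, fold_tol = 1e-3) {
  stopifnot(n_grid >= 5)
  p <- model_plist(model, params)
  xs <- seq(range_x[1], range_x[2], length.out = n_grid)
  ys <- seq(range_y[1], range_y[2], length.out = n_y)

  loci <- data.frame(x = xs, y_lower = NA_real_, y_upper = NA_real_,
                     label_low = NA_character_, label_high = NA_character_,
                     stringsAsFactors = FALSE)
  for (i in seq_along(xs)) {
    p[[symbol_x]] <- xs[i]
    warm <- NULL
    counts <- integer(n_y)
    scans <- vector("list", n_y)
    for (j in seq_along(ys)) {
      p[[symbol_y]] <- ys[j]
      ss <- find_roots_plist(model, p, n_starts, seed = 0, warm = warm)
      scans[[j]] <- ss
      counts[j] <- length(ss)
      warm <- reduced_coords(model, ss)
    }
    bi <- which(counts >= 3)
    ## labels of the monostable ends of the column
    lab_at <- function(j) {
      ss <- scans[[j]]
      if (length(ss) == 1) ss[[1]]$label else NA_character_
    }
    loci$label_low[i] <- lab_at(1)
    loci$label_high[i] <- lab_at(n_y)
    if (!length(bi)) next
    bisect_y <- function(j_in, j_out) {
      lo <- ys[j_in]; hi <- ys[j_out]
      warm <- reduced_coords(model, scans[[j_in]])
      while (abs(hi - lo) > fold_tol * max(1, abs(hi), abs(lo))) {
        mid <- (lo + hi) / 2
        p[[symbol_y]] <- mid
        if (length(find_roots_plist(model, p, n_starts, 0, warm)) >= 3)
          lo <- mid else hi <- mid
      }
      (lo + hi) / 2
    }
    loci$y_lower[i] <- if (min(bi) == 1) ys[1]
                       else bisect_y(min(bi), min(bi) - 1)
    loci$y_upper[i] <- if (max(bi) == n_y) ys[n_y]
                       else bisect_y(max(bi), max(bi) + 1)
  }
  structure(list(model = model$name, symbol_x = symbol_x,
                 symbol_y = symbol_y, range_x = range_x, range_y = range_y,
                 loci = loci),
            class = "control_plane")
}

#' @export
print.control_plane <- function(x, ...) {
  cat("Control plane (", x$symbol_x, ", ", x$symbol_y, ") for ",
      x$model, "\n", sep = "")
  n_bi <- sum(!is.na(x$loci$y_lower))
  cat(" ", n_bi, "of", nrow(x$loci), "columns contain a bistable interval\n")
  invisible(x)
}

#' @export
plot.control_plane <- function(x, ...) {
  l <- x$loci
  graphics::plot(NA, xlim = x$range_x, ylim = x$range_y,
                 xlab = paste(x$symbol_x, "(U)"),
                 ylab = paste(x$symbol_y, "(U)"), ...)
  ok <- !is.na(l$y_lower)
  graphics::lines(l$x[ok], l$y_lower[ok], lwd = 2)
  graphics::lines(l$x[ok], l$y_upper[ok], lwd = 2)
  invisible(x)
}

#' Classify a point of a control plane
#'
#' Uses the fold loci: between the loci the point is `"bistable"`;
#' outside, the label of the adjoining monostable side is returned.
#'
#' @param plane a `control_plane`.
#' @param x,y coordinates of the probe point.
#' @return `"bistable"`, `"monostable-engaged"` or
#'   `"monostable-disengaged"` (possibly `NA` outside mapped columns).
#' @export
plane_membership <- function(plane, x, y) {
  l <- plane$loci
  ok <- !is.na(l$y_lower)
  side <- function(lab) {
    if (is.na(lab)) return(NA_character_)
    paste0("monostable-", lab)
  }
  nearest <- which.min(abs(l$x - x))
  if (any(ok)) {
    lo <- stats::approx(l$x[ok], l$y_lower[ok], xout = x, rule = 1)$y
    hi <- stats::approx(l$x[ok], l$y_upper[ok], xout = x, rule = 1)$y
    if (!is.na(lo) && !is.na(hi)) {
      if (y >= lo && y <= hi) return("bistable")
      if (y < lo) return(side(l$label_low[nearest]))
      return(side(l$label_high[nearest]))
    }
  }
  ## monostable column: pick the recorded end label on the matching side
  mid <- (plane$range_y[1] + plane$range_y[2]) / 2
  side(if (y <= mid) l$label_low[nearest] else l$label_high[nearest])
}

#' Export control-plane loci as TSV
#' @param x a `control_plane`.
#' @param path output file path.
#' @export
write_plane_tsv <- function(x, path) {
  utils::write.table(x$loci, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run a hysteresis protocol along a parameter path
#'
#' Integrates the full ODEs while the parameters move piecewise-linearly
#' between the vertices of `path`, taking `dwell` time units per segment,
#' and records the occupied state's checkpoint label at each vertex.
#' Crossing the upper boundary of the bistable region and returning
#' leaves the system disengaged (irreversible transition); crossing the
#' lower boundary resets it.
#'
#' @param model a `switch_model`.
#' @param params optional [switch_params] (values not on the path stay
#'   fixed).
#' @param path data.frame or matrix; one column per driven parameter
#'   symbol, one row per vertex.
#' @param dwell time per segment (T units).
#' @param init full state at the first vertex; if `NULL` the stable state
#'   with label `start_label` is used.
#' @param start_label label selecting the initial branch when `init` is
#'   `NULL` and the first vertex is bistable.
#' @param settle_tol residual above which a vertex is flagged unsettled.
#' @return data.frame: vertex index, driven parameter values, `label`,
#'   `residual`, `settled`.
#' @export
hysteresis_protocol <- function(model, params = NULL, path, dwell = 300,
                                init = NULL, start_label = "engaged",
                                settle_tol = 1e-6) {
  p <- model_plist(model, params)
  path <- as.data.frame(path)
  syms <- colnames(path)
  stopifnot(nrow(path) >= 2, length(syms) >= 1)
  for (s in syms) p[[s]] <- path[1, s]
  if (is.null(init)) {
    ss <- find_roots_plist(model, p, n_starts = 32, seed = 0)
    stab <- Filter(function(s) isTRUE(s$stable), ss)
    pick <- Filter(function(s) s$label == start_label, stab)
    if (!length(pick)) pick <- stab
    if (!length(pick))
      stop("no stable state at the first path vertex", call. = FALSE)
    init <- pick[[1]]$state
  }
  x <- as.numeric(init)
  out <- data.frame(vertex = seq_len(nrow(path)))
  for (s in syms) out[[s]] <- path[[s]]
  out$label <- NA_character_
  out$residual <- NA_real_
  out$settled <- NA

  record <- function(i, x, p) {
    out$label[i] <<- classify_state_raw(model, x, p)
    out$residual[i] <<- max(abs(model$rhs(x, p)))
    out$settled[i] <<- out$residual[i] < settle_tol
  }
  ## settle at the first vertex
  m2 <- model; m2$params <- p
  x <- as.numeric(integrate_to_steady_state(m2, x, t_max = dwell * 4,
                                            tol = 1e-10))
  record(1, x, p)
  for (k in seq_len(nrow(path) - 1)) {
    p0 <- unlist(path[k, , drop = FALSE])
    p1 <- unlist(path[k + 1, , drop = FALSE])
    ## a driven conserved total enters the flow as synthesis of the free
    ## form (increase) or proportional removal from all pools (decrease)
    driven_tot <- Filter(function(s) !is.na(total_state_index(model, s)),
                         syms)
    fun <- function(t, y, parms) {
      pp <- p
      w <- t / dwell
      for (s in syms) pp[[s]] <- (1 - w) * p0[[s]] + w * p1[[s]]
      y <- pmax(y, 0)
      dx <- model$rhs(y, pp)
      for (s in driven_tot) {
        slope <- (p1[[s]] - p0[[s]]) / dwell
        if (slope > 0) {
          i <- total_state_index(model, s)
          dx[i] <- dx[i] + slope
        } else if (slope < 0 && sum(y) > 0) {
          dx <- dx + slope * y / sum(y)
        }
      }
      list(dx)
    }
    sol <- deSolve::lsoda(x, c(0, dwell), fun, NULL,
                          rtol = 1e-9, atol = 1e-11)
    x <- pmax(as.numeric(sol[nrow(sol), -1]), 0)
    for (s in syms) p[[s]] <- p1[[s]]
    ## extra relaxation at the vertex itself
    m2$params <- p
    x <- as.numeric(integrate_to_steady_state(m2, x, t_max = dwell,
                                              tol = 1e-10))
    record(k + 1, x, p)
  }
  out
}
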