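#' Integrate one cell's network ODEs
#'
#' Adaptive Dormand-Prince RK5(4) integration of the sigmoidal network for a
#' single cell under a piecewise-constant signal schedule. Integration
#' restarts at every schedule breakpoint, so signal steps are resolved
#' exactly. With `t_end = 0` the initial state is returned unchanged.
#'
#' @param spec a [network_spec()] or [sample_cell()] result.
#' @param x0 initial state; default all species at 0.01, a naive-like state
#'   well inside the low basin.
#' @param schedule a [signal_schedule()]; default all signals zero.
#' @param t_end end time (time units, about 1 h each).
#' @param out_times times at which to record the state; default 201 evenly
#'   spaced samples.
#' @param rtol,atol relative/absolute local error tolerances.
#' @param ss_tol if > 0, stop early once `max |dX/dt| < ss_tol` in the final
#'   schedule segment (the state is then held constant at later sample
#'   times).
#' @return a `trajectory`: list with `time`, `states`
#'   (`length(time)` x n matrix), `final`, `converged`, `t_stop`, and the
#'   applied `schedule`.
#' @examples
#' m <- th_model("symmetric")
#' tr <- integrate_cell(m, t_end = 50)       # settles at the naive state
#' tail(tr$states, 1)
#' @export
integrate_cell <- function(spec, x0 = rep(0.01, n_species(spec)),
                           schedule = signal_schedule(spec), t_end,
                           out_times = NULL, rtol = 1e-8, atol = 1e-10,
                           ss_tol = 0) {
  stopifnot(t_end >= 0, length(x0) == n_species(spec))
  if (is.null(out_times))
    out_times <- seq(0, t_end, length.out = if (t_end > 0) 201 else 1)
  stopifnot(!is.unsorted(out_times), all(out_times >= 0),
            all(out_times <= t_end + 1e-9))
  res <- cpp_integrate(spec$gamma, spec$sigma, spec$beta, spec$weights,
                       as.numeric(x0), schedule$start, schedule$values,
                       t_end, as.numeric(out_times), rtol, atol, ss_tol)
  states <- res$states
  colnames(states) <- spec$species
  structure(list(time = out_times, states = states,
                 final = stats::setNames(res$final, spec$species),
                 converged = res$converged, t_stop = res$t_stop,
                 schedule = schedule),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d samples on [0, %g], final state:\n",
              length(x$time), max(x$time)))
  print(round(x$final, 4))
  invisible(x)
}

# Settle to steady state under constant signals; returns endpoint only.
settle <- function(spec, x0, signals = NULL, t_max = 500, ss_tol = 1e-8,
                   rtol = 1e-9, atol = 1e-12) {
  sched <- constant_schedule(spec, signals)
  res <- cpp_integrate(spec$gamma, spec$sigma, spec$beta, spec$weights,
                       as.numeric(x0), sched$start, sched$values, t_max,
                       numeric(0), rtol, atol, ss_tol)
  list(state = stats::setNames(res$final, spec$species),
       converged = res$converged)
}

#' Enumerate steady states by multi-start search
#'
#' Finds the fixed points \eqn{X_i = F(\sigma_i W_i)} of a network at fixed
#' signal levels: starting points (a regular grid in the unit box for up to
#' 2 species, otherwise a Latin-hypercube sample plus the box corners) are
#' relaxed by a short integration and refined by damped Newton iteration on
#' the fixed-point map, using the analytic Jacobian. Converged roots are
#' deduplicated by Euclidean distance and classified by the eigenvalues of
#' the ODE Jacobian: stable if all real parts < `-tol_eig`, marginal if any
#' real part lies within `tol_eig` of zero (this happens only at bifurcation
#' points), unstable otherwise. Starts whose Newton iteration fails are
#' dropped, never fatal.
#'
#' @inheritParams integrate_cell
#' @param signals named numeric vector of constant signal levels.
#' @param n_starts number of starting points (>= 1).
#' @param seed optional seed for the Latin-hypercube starts (unused for the
#'   2-species grid).
#' @param tol_ss residual tolerance on `max |dX/dt|` at a root.
#' @param dedupe_tol Euclidean distance under which two roots are merged.
#' @param tol_eig half-width of the "marginal" band around zero eigenvalue
#'   real parts.
#' @param extra_starts optional matrix of additional starting points.
#' @return a `steady_states` object: data.frame-like list with matrix
#'   `states`, logical `stable`, character `stability`
#'   (stable/unstable/marginal), list `eigenvalues`, and `phenotype` calls
#'   (see [classify_phenotype()]).
#' @examples
#' m <- th_model("symmetric")
#' find_steady_states(m, signals = c(TGFb = 0.5))   # tristable
#' @export
find_steady_states <- function(spec, signals = NULL, n_starts = 64,
                               seed = NULL, tol_ss = 1e-9, dedupe_tol = 1e-3,
                               tol_eig = 1e-8, extra_starts = NULL) {
  n <- n_species(spec)
  s <- signal_values(spec, signals)
  starts <- steady_starts(n, n_starts, seed)
  if (!is.null(extra_starts))
    starts <- rbind(starts, matrix(extra_starts, ncol = n))
  # short relaxation pulls starts toward attractors (and near saddles,
  # slow manifolds), then Newton polishes both stable and unstable roots
  sched <- constant_schedule(spec, s)
  cells <- matrix(pack_cell(spec), nrow(starts), length(pack_cell(spec)),
                  byrow = TRUE)
  relaxed <- cpp_settle_cells(cells, n, length(spec$signals), sched$start,
                              sched$values, 15, starts, 1e-6, 1e-9, 0)$final
  cand <- rbind(starts, relaxed)
  roots <- list()
  for (k in seq_len(nrow(cand))) {
    x <- newton_fp(spec, cand[k, ], s)
    if (is.null(x)) next
    if (max(abs(net_rhs(spec, x, s))) > tol_ss) next
    if (length(roots) == 0 ||
        min(vapply(roots, function(r) sqrt(sum((r - x)^2)), 0)) > dedupe_tol)
      roots[[length(roots) + 1]] <- x
  }
  states <- do.call(rbind, roots)
  if (is.null(states)) states <- matrix(numeric(), 0, n)
  colnames(states) <- spec$species
  ord <- do.call(order, as.data.frame(states))
  states <- states[ord, , drop = FALSE]
  eig <- lapply(seq_len(nrow(states)), function(i)
    eigen(net_jacobian(spec, states[i, ], s), only.values = TRUE)$values)
  stability <- vapply(eig, function(ev) {
    re <- Re(ev)
    if (any(abs(re) <= tol_eig)) "marginal"
    else if (all(re < 0)) "stable"
    else "unstable"
  }, "")
  structure(list(states = states, stable = stability == "stable",
                 stability = stability, eigenvalues = eig,
                 phenotype = apply(states, 1, function(x)
                   classify_phenotype(x, spec)$class),
                 signals = s),
            class = "steady_states")
}

#' @export
print.steady_states <- function(x, ...) {
  cat(sprintf("<steady_states> %d found (%d stable) at signals: %s\n",
              nrow(x$states), sum(x$stable),
              paste(sprintf("%s=%g", names(x$signals), x$signals),
                    collapse = ", ")))
  if (nrow(x$states))
    print(data.frame(round(x$states, 4), stability = x$stability,
                     phenotype = x$phenotype), ...)
  invisible(x)
}

steady_starts <- function(n, n_starts, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  if (n <= 2) {
    g <- max(2L, ceiling(sqrt(n_starts)))
    as.matrix(expand.grid(seq(0.02, 0.98, length.out = g),
                          seq(0.02, 0.98, length.out = g)))[, seq_len(n),
                                                            drop = FALSE]
  } else {
    # Latin hypercube + box corners of the regulator subspace
    lhs <- vapply(seq_len(n), function(j)
      (sample.int(n_starts) - stats::runif(n_starts)) / n_starts,
      numeric(n_starts))
    corners <- as.matrix(expand.grid(rep(list(c(0.02, 0.98)),
                                         min(n, 4))))
    if (ncol(corners) < n)
      corners <- cbind(corners, matrix(0.02, nrow(corners),
                                       n - ncol(corners)))
    rbind(lhs, corners)
  }
}

# Damped Newton on the fixed-point map; NULL on failure.
newton_fp <- function(spec, x0, s_full, maxit = 60, tol = 1e-12) {
  x <- as.numeric(x0)
  for (it in seq_len(maxit)) {
    g <- fp_fun(spec, x, s_full)
    if (max(abs(g)) < tol) return(x)
    J <- fp_jac(spec, x, s_full)
    step <- tryCatch(solve(J, -g), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lambda <- 1
    g0 <- sum(g^2)
    repeat {
      xn <- x + lambda * step
      if (sum(fp_fun(spec, xn, s_full)^2) < g0 || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    x <- xn
    if (any(!is.finite(x)) || any(abs(x) > 10)) return(NULL)
  }
  if (max(abs(fp_fun(spec, x, s_full))) < 1e-9) x else NULL
}

#' Nullclines of a two-species network
#'
#' For each of the two dynamic species the nullcline is the locus
#' \eqn{X_i = F(\sigma_i W_i)} in the unit square. Sampled by scanning the
#' other species' value on a regular grid and collecting every root of the
#' scalar equation (an S-shaped nullcline can have up to three branches at
#' a given abscissa). Fixed points are the intersections of the two curves.
#'
#' @inheritParams find_steady_states
#' @param resolution number of grid values per axis.
#' @return list of two data.frames (one per species), each with the two
#'   species' coordinates, plus the signal vector as an attribute.
#' @export
nullclines <- function(spec, signals = NULL, resolution = 301) {
  if (n_species(spec) != 2)
    stop("nullclines are implemented for 2-species networks only")
  s <- signal_values(spec, signals)
  grid <- seq(0, 1, length.out = resolution)
  one <- function(i) {
    j <- 3 - i
    pts <- lapply(grid, function(v) {
      # roots in x_i of F(sigma_i W_i(x_i, x_j = v)) - x_i = 0
      h <- function(z) {
        x <- numeric(2); x[i] <- z; x[j] <- v
        sigmoid(spec$sigma[i] * net_input(spec, i, x, s)) - z
      }
      zs <- seq(0, 1, length.out = 101)
      hv <- vapply(zs, h, 0)
      roots <- c()
      for (k in seq_len(length(zs) - 1))
        if (hv[k] == 0 || hv[k] * hv[k + 1] < 0)
          roots <- c(roots, stats::uniroot(h, c(zs[k], zs[k + 1]),
                                           tol = 1e-10)$root)
      if (hv[length(zs)] == 0) roots <- c(roots, 1)
      if (!length(roots)) return(NULL)
      out <- matrix(0, length(roots), 2)
      out[, i] <- roots; out[, j] <- v
      out
    })
    df <- as.data.frame(do.call(rbind, pts))
    names(df) <- spec$species
    df
  }
  structure(list(one(1), one(2)), names = spec$species, signals = s,
            class = "nullclines")
}

#' Basins of attraction on a lattice (two-species networks)
#'
#' Integrates from every point of a `grid_n` x `grid_n` lattice over the
#' unit square to steady state and labels each lattice point by the stable
#' state it converges to. Points that fail to converge, or converge to a
#' state not matching any known stable state, are labelled 0 ("unresolved")
#' and counted.
#'
#' @inheritParams find_steady_states
#' @param grid_n lattice resolution per axis.
#' @param t_max settling horizon per lattice point.
#' @return a `basin_map`: list with `grid` (lattice coordinates), `label`
#'   (`grid_n` x `grid_n` integer matrix, row index = first species),
#'   `attractors` (stable states, rows matching labels), `n_unresolved`.
#' @export
basin_map <- function(spec, signals = NULL, grid_n = 50, t_max = 400) {
  if (n_species(spec) != 2)
    stop("basin_map is implemented for 2-species networks only")
  s <- signal_values(spec, signals)
  ss <- find_steady_states(spec, s)
  att <- ss$states[ss$stable, , drop = FALSE]
  if (nrow(att) == 0) stop("no stable state at these signal levels")
  g <- seq(0, 1, length.out = grid_n)
  starts <- as.matrix(expand.grid(x1 = g, x2 = g))
  sched <- constant_schedule(spec, s)
  # settle each start with the shared parameter row
  cells <- matrix(pack_cell(spec), nrow(starts), length(pack_cell(spec)),
                  byrow = TRUE)
  res <- cpp_settle_cells(cells, 2L, length(spec$signals), sched$start,
                          sched$values, t_max, starts, 1e-9, 1e-12, 1e-8)
  lab <- integer(nrow(starts))
  for (k in seq_len(nrow(starts))) {
    d <- sqrt(colSums((t(att) - res$final[k, ])^2))
    lab[k] <- if (res$converged[k] && min(d) < 1e-2) which.min(d) else 0L
  }
  structure(list(grid = g,
                 label = matrix(lab, grid_n, grid_n),
                 attractors = att, n_unresolved = sum(lab == 0L),
                 signals = s),
            class = "basin_map")
}

#' @export
print.basin_map <- function(x, ...) {
  shares <- table(factor(x$label, levels = 0:nrow(x$attractors)))
  cat(sprintf("<basin_map> %dx%d lattice, %d attractors, %d unresolved\n",
              length(x$grid), length(x$grid), nrow(x$attractors),
              x$n_unresolved))
  print(round(shares / sum(shares), 3))
  invisible(x)
}
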