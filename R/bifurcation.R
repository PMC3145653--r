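#' One-parameter continuation of steady states
#'
#' Traces every steady-state branch of the "average cell" (or any sampled
#' cell) as one signal concentration varies. Branches are discovered by a
#' dense multi-start steady-state scan over a regular signal grid (robust
#' for the perfect pitchforks of the symmetric models, which analytic
#' branch-point continuation handles poorly once the symmetry is broken)
#' and assembled by nearest-neighbour linking of states at consecutive
#' grid values. Two kinds of special points are then located and refined by
#' bisection with Newton root tracking to a signal tolerance of about
#' `1e-3`:
#'
#' * stability changes interior to a branch (an eigenvalue real part
#'   crossing zero, i.e. a sign change of the Jacobian determinant or a
#'   transverse destabilization), and
#' * branch end points interior to the scan range, where a root ceases to
#'   exist or merges with another branch (folds and pitchfork stems).
#'
#' Each special point is classified (see [classify_special_point()]) as a
#' `pitchfork` -- only possible in a model with an exact interaction
#' symmetry, when the critical eigenvector is antisymmetric under the
#' species swap at a swap-invariant state -- or a `fold` (saddle-node)
#' otherwise.
#'
#' @inheritParams find_steady_states
#' @param signal_name which signal to vary (default `"TGFb"`).
#' @param range numeric length-2, scanned signal interval (within `[0, 2]`).
#' @param fixed_signals named values for the other signals (e.g.
#'   `c(IL6 = 10)` for polarized continuation).
#' @param step signal grid step for branch discovery.
#' @param n_starts multi-start count per grid value.
#' @param link_tol state-space distance under which consecutive-grid states
#'   are linked into one branch.
#' @return a `branch_set`: list of branches, each with `signal`, `states`,
#'   `stability`, and a `special` data.frame (`signal`, `kind`,
#'   `point_index`, state at the special point).
#' @examples
#' \donttest{
#' br <- continue_branches(th_model("symmetric"), range = c(0, 1),
#'                         step = 0.01)
#' branch_special_points(br)
#' }
#' @export
continue_branches <- function(spec, signal_name = "TGFb", range = c(0, 1),
                              fixed_signals = NULL, step = 0.01,
                              n_starts = 64, link_tol = 0.15) {
  stopifnot(signal_name %in% spec$signals, step > 0,
            range[1] >= 0, range[2] <= 2)
  if (range[1] > range[2]) return(structure(list(), class = "branch_set",
                                            signal_name = signal_name))
  s_grid <- seq(range[1], range[2], by = step)
  if (abs(s_grid[length(s_grid)] - range[2]) > 1e-12)
    s_grid <- c(s_grid, range[2])
  fixed <- signal_values(spec, fixed_signals)

  open <- list()   # growing branches
  closed <- list()
  prev <- NULL
  for (gi in seq_along(s_grid)) {
    s <- s_grid[gi]
    sigs <- fixed; sigs[signal_name] <- s
    ss <- find_steady_states(spec, sigs, n_starts = n_starts, seed = 1L,
                             extra_starts = prev)
    prev <- ss$states
    m <- nrow(ss$states)
    used_state <- rep(FALSE, m)
    matched_branch <- rep(FALSE, length(open))
    if (length(open) && m) {
      last <- t(vapply(open, function(b) b$states[nrow(b$states), ],
                       numeric(ncol(ss$states))))
      d <- as.matrix(stats::dist(rbind(last, ss$states)))
      d <- d[seq_along(open), length(open) + seq_len(m), drop = FALSE]
      repeat {
        d_open <- d
        d_open[matched_branch, ] <- Inf
        d_open[, used_state] <- Inf
        if (!length(d_open) || min(d_open) > link_tol) break
        k <- arrayInd(which.min(d_open), dim(d_open))
        bi <- k[1]; si <- k[2]
        open[[bi]]$signal <- c(open[[bi]]$signal, s)
        open[[bi]]$grid_index <- c(open[[bi]]$grid_index, gi)
        open[[bi]]$states <- rbind(open[[bi]]$states, ss$states[si, ])
        open[[bi]]$stability <- c(open[[bi]]$stability, ss$stability[si])
        matched_branch[bi] <- TRUE
        used_state[si] <- TRUE
      }
    }
    # retire branches that found no continuation
    if (any(!matched_branch)) {
      closed <- c(closed, open[!matched_branch])
      open <- open[matched_branch]
    }
    # new branches for unmatched states
    for (si in which(!used_state)) {
      open[[length(open) + 1]] <- list(
        signal = s, grid_index = gi,
        states = ss$states[si, , drop = FALSE],
        stability = ss$stability[si])
    }
  }
  branches <- c(closed, open)
  branches <- branches[order(vapply(branches, function(b) b$signal[1], 0))]
  branches <- lapply(branches, function(b) {
    b$special <- locate_special_points(spec, b, signal_name, fixed,
                                       s_grid, step)
    class(b) <- "branch"
    b
  })
  structure(branches, class = "branch_set", signal_name = signal_name,
            fixed = fixed, range = range, step = step, spec_name = spec$name)
}

#' @export
print.branch_set <- function(x, ...) {
  cat(sprintf("<branch_set> %d branches of '%s' vs %s on [%g, %g]\n",
              length(x), attr(x, "spec_name"), attr(x, "signal_name"),
              attr(x, "range")[1], attr(x, "range")[2]))
  for (i in seq_along(x)) {
    b <- x[[i]]
    cat(sprintf("  branch %d: s in [%.3f, %.3f], %d pts, %s%s\n", i,
                min(b$signal), max(b$signal), length(b$signal),
                paste(unique(b$stability), collapse = "/"),
                if (nrow(b$special))
                  paste0("; special: ",
                         paste(sprintf("%s@%.4f", b$special$kind,
                                       b$special$signal), collapse = ", "))
                else ""))
  }
  invisible(x)
}

# ---- special-point machinery ------------------------------------------

# Newton-track a root from (s_from, x) to s_to in small substeps; returns
# list(x, ok). A jump larger than jump_tol or Newton failure means the root
# ceased to exist along the way.
track_root <- function(spec, x, sigs, signal_name, s_from, s_to,
                       substep = 5e-4, jump_tol = 0.08) {
  n_sub <- max(1L, ceiling(abs(s_to - s_from) / substep))
  for (s in seq(s_from, s_to, length.out = n_sub + 1)[-1]) {
    sigs[signal_name] <- s
    xn <- newton_fp(spec, x, sigs)
    if (is.null(xn) || sqrt(sum((xn - x)^2)) > jump_tol)
      return(list(x = x, ok = FALSE, s_last = s))
    x <- xn
  }
  list(x = x, ok = TRUE)
}

is_stable_at <- function(spec, x, sigs, tol_eig = 1e-8) {
  re <- Re(eigen(net_jacobian(spec, x, sigs), only.values = TRUE)$values)
  all(re < -tol_eig)
}

# kind of a special point: pitchfork iff the model has an exact swap
# symmetry, the state is (near) swap-invariant, and the critical
# eigenvector is antisymmetric under the swap; fold otherwise.
special_kind <- function(spec, x, sigs) {
  if (is.null(spec$swap)) return("fold")
  if (max(abs(x - x[spec$swap])) > 0.05) return("fold")
  J <- net_jacobian(spec, x, sigs)
  e <- eigen(J)
  i <- which.min(abs(Re(e$values)))
  v <- Re(e$vectors[, i])
  v <- v / max(abs(v))
  anti <- max(abs(v + v[spec$swap]))
  sym <- max(abs(v - v[spec$swap]))
  if (anti < sym) "pitchfork" else "fold"
}

locate_special_points <- function(spec, b, signal_name, fixed, s_grid,
                                  step, tol = 2e-4) {
  sp <- list()
  sigs <- fixed
  npts <- length(b$signal)
  # (a) stability changes interior to the branch
  if (npts >= 2) {
    st <- b$stability == "stable"
    for (k in which(st[-npts] != st[-1])) {
      lo <- b$signal[k]; hi <- b$signal[k + 1]
      x <- b$states[k, ]
      stab_lo <- st[k]
      while (hi - lo > tol) {
        mid <- (lo + hi) / 2
        tr <- track_root(spec, x, sigs, signal_name, lo, mid)
        if (!tr$ok) { hi <- mid; next }   # root vanished: treat as boundary
        sigs[signal_name] <- mid
        if (is_stable_at(spec, tr$x, sigs) == stab_lo) {
          lo <- mid; x <- tr$x
        } else hi <- mid
      }
      sigs[signal_name] <- lo
      sp[[length(sp) + 1]] <- data.frame(
        signal = (lo + hi) / 2, kind = special_kind(spec, x, sigs),
        point_index = k, t(x))
    }
  }
  # (b) branch end points interior to the scan range (root disappears or
  # merges): march the root forward/backward in substeps until it fails.
  ends <- list()
  if (b$grid_index[npts] < length(s_grid))
    ends <- c(ends, list(list(idx = npts, dir = +1)))
  if (b$grid_index[1] > 1)
    ends <- c(ends, list(list(idx = 1L, dir = -1)))
  for (e in ends) {
    s0 <- b$signal[e$idx]
    x <- b$states[e$idx, ]
    target <- s0 + e$dir * step
    tr <- track_root(spec, x, sigs, signal_name, s0, target,
                     substep = min(tol, step / 8))
    s_star <- if (tr$ok) target else tr$s_last
    sigs[signal_name] <- s_star
    sp[[length(sp) + 1]] <- data.frame(
      signal = s_star, kind = special_kind(spec, tr$x, sigs),
      point_index = e$idx, t(tr$x))
  }
  out <- if (length(sp)) do.call(rbind, sp) else
    data.frame(signal = numeric(), kind = character(),
               point_index = integer())
  if (nrow(out)) names(out)[-(1:3)] <- spec$species
  out
}

#' Classify a special point on a branch
#'
#' Returns `"pitchfork"` if the detected special point at `index` is a
#' symmetric branching point (possible only in models with an exact
#' interaction symmetry: the state is swap-invariant and the critical
#' eigenvector antisymmetric), `"fold"` for a saddle-node, and `"none"` if
#' no special point was detected at that branch point.
#'
#' @param branch one element of a [continue_branches()] result.
#' @param index index of a point along the branch.
#' @return `"fold"`, `"pitchfork"`, or `"none"`.
#' @export
classify_special_point <- function(branch, index) {
  stopifnot(inherits(branch, "branch"),
            index >= 1, index <= length(branch$signal))
  hit <- which(branch$special$point_index == index)
  if (!length(hit)) "none" else branch$special$kind[hit[1]]
}

#' @rdname continue_branches
#' @param branches a `branch_set`.
#' @return `branch_special_points()` returns one data.frame of all special
#'   points (`branch`, `signal`, `kind`, state columns);
#'   `branch_table()` flattens a branch set into the exportable table
#'   (`branch`, `signal`, species columns, `stable`, `special_point`).
#' @export
branch_special_points <- function(branches) {
  out <- lapply(seq_along(branches), function(i) {
    sp <- branches[[i]]$special
    if (nrow(sp)) cbind(branch = i, sp) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(branch = integer(), signal = numeric(),
                      kind = character(), point_index = integer())
  out
}

#' @rdname continue_branches
#' @export
branch_table <- function(branches) {
  rows <- lapply(seq_along(branches), function(i) {
    b <- branches[[i]]
    df <- data.frame(branch = i, signal = b$signal,
                     as.data.frame(b$states),
                     stable = b$stability == "stable",
                     special_point = vapply(seq_along(b$signal),
                                            function(k)
                                              classify_special_point(b, k),
                                            ""))
    df
  })
  do.call(rbind, rows)
}

#' Onset signals of the differentiated stable branches
#'
#' Convenience summaries of a symmetric-model branch set: the pitchfork at
#' which the naive (symmetric low/low) branch destabilizes and the two
#' single-positive lineage branches emanate, and the smallest signal at
#' which a stable double-expressing state (both master regulators above
#' `threshold`) exists, refined to the adjacent special point when one lies
#' within one grid step.
#'
#' @param branches a `branch_set` from [continue_branches()].
#' @param spec the network the branches were computed for.
#' @param threshold expression threshold for the double-expressing call.
#' @return named numeric vector with `pitchfork` and `double_onset`
#'   (`NA` if not present in the scanned range).
#' @export
branch_onsets <- function(branches, spec, threshold = 0.5) {
  sp <- branch_special_points(branches)
  pf <- sp$signal[sp$kind == "pitchfork"]
  # the lineage-branching pitchfork is the one on the naive (low/low) branch
  pitchfork <- if (length(pf)) min(pf) else NA_real_
  dbl <- NA_real_
  cand <- Inf
  for (i in seq_along(branches)) {
    b <- branches[[i]]
    ok <- b$stability == "stable" &
      apply(b$states, 1, function(x)
        classify_phenotype(x, spec, threshold)$class == "double")
    if (any(ok)) cand <- min(cand, min(b$signal[ok]))
  }
  if (is.finite(cand)) {
    # the refined onset is the closest special point just below the first
    # stable grid point (the branch becomes stable there)
    near <- sp$signal[sp$signal <= cand + 1e-9 &
                        sp$signal >= cand - 2 * attr(branches, "step")]
    dbl <- if (length(near)) max(near) else cand
  }
  c(pitchfork = pitchfork, double_onset = dbl)
}
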