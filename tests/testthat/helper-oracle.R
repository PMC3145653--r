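# Independent integration oracle: fixed-step classic RK4 in plain R,
# vectorized over many initial conditions. Shares no code with the
# package's adaptive C++ integrator; used to cross-validate steady-state
# enumeration, basins and branch stability.

oracle_rhs_mat <- function(spec, X, s) {
  n <- length(spec$species)
  Wsp <- spec$weights[, seq_len(n), drop = FALSE]
  off <- spec$beta + drop(spec$weights[, -seq_len(n), drop = FALSE] %*% s)
  U <- sweep(X %*% t(Wsp), 2, off, "+")
  U <- sweep(U, 2, spec$sigma, "*")
  FF <- 1 / (1 + exp(-U))
  sweep(FF - X, 2, spec$gamma, "*")
}

# integrate a matrix of starts (rows) to t_end; returns endpoint matrix
oracle_integrate <- function(spec, X0, signals, t_end, dt = 0.02) {
  s <- rep(0, length(spec$signals))
  names(s) <- spec$signals
  if (length(signals)) s[names(signals)] <- signals
  X <- as.matrix(X0)
  for (k in seq_len(round(t_end / dt))) {
    k1 <- oracle_rhs_mat(spec, X, s)
    k2 <- oracle_rhs_mat(spec, X + dt / 2 * k1, s)
    k3 <- oracle_rhs_mat(spec, X + dt / 2 * k2, s)
    k4 <- oracle_rhs_mat(spec, X + dt * k3, s)
    X <- X + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  X
}

# distinct endpoints of a dense lattice of starts (the attractor set).
# The per-axis offsets differ slightly so that no start sits exactly on an
# invariant diagonal (symmetric flows keep exact-diagonal starts on the
# diagonal forever, which would report transversally unstable saddles as
# endpoints).
oracle_attractors <- function(spec, signals, grid_n = 15, t_end = 150,
                              dt = 0.02, merge_tol = 0.02) {
  axes <- lapply(seq_along(spec$species), function(j)
    seq(0.011 * j, 1 - 0.007 * j, length.out = grid_n))
  X0 <- as.matrix(expand.grid(axes))
  ends <- oracle_integrate(spec, X0, signals, t_end, dt)
  dedupe_rows(ends, merge_tol)
}

dedupe_rows <- function(m, tol) {
  keep <- NULL
  for (k in seq_len(nrow(m))) {
    x <- m[k, ]
    if (is.null(keep) ||
        min(sqrt(colSums((t(keep) - x)^2))) > tol)
      keep <- rbind(keep, x)
  }
  keep <- keep[do.call(order, as.data.frame(keep)), , drop = FALSE]
  unname(keep)
}

# nearest-row distance between two state sets
set_distance <- function(a, b) {
  if (nrow(a) != nrow(b)) return(Inf)
  max(vapply(seq_len(nrow(a)), function(k)
    min(sqrt(colSums((t(b) - a[k, ])^2))), 0))
}
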