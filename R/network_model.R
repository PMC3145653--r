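#' Logistic activation function
#'
#' The transfer function of the network formalism. Each species relaxes
#' toward `sigmoid(sigma_i * W_i)`, where `W_i` is the species' net
#' regulatory input (see [net_input()]). `sigmoid()` is the standard
#' logistic, strictly increasing from 0 to 1 with `sigmoid(0) = 0.5`.
#'
#' @param u numeric vector of net inputs (finite).
#' @return numeric vector of the same length, values in (0, 1).
#' @examples
#' sigmoid(0)                 # 0.5
#' sigmoid(5 * -0.8)          # basal drive of the naive state, ~0.018
#' @export
sigmoid <- function(u) 1 / (1 + exp(-u))

#' @rdname sigmoid
#' @details `dsigmoid()` is the derivative, `sigmoid(u) * (1 - sigmoid(u))`,
#'   used for analytic Jacobians.
#' @export
dsigmoid <- function(u) {
  f <- sigmoid(u)
  f * (1 - f)
}

#' Construct a sigmoidal regulatory-network specification
#'
#' A `network_spec` fixes the topology and basal kinetic parameters of a
#' sigmoidal-ODE gene network
#' \deqn{dX_i/dt = \gamma_i [F(\sigma_i W_i) - X_i], \quad
#'       W_i = \beta_i + \sum_j \omega_{ij} X_j + \sum_k \omega_{ik} s_k}
#' where \eqn{F} is the logistic function, \eqn{X_j} the dynamic species
#' activities (dimensionless, nominal range 0 to 1) and \eqn{s_k} the
#' external signal concentrations. One time unit corresponds to roughly one
#' hour. Absent interactions must be hard zeros in `weights`; they stay zero
#' under cell-to-cell parameter sampling. Signal concentrations are not
#' parameters of the cell and are never sampled.
#'
#' @param species character vector of dynamic species names (ordered).
#' @param signals character vector of external signal names (may be empty).
#' @param gamma per-species relaxation rates (1 / time unit), all > 0.
#' @param sigma per-species sigmoid steepness, all > 0.
#' @param beta per-species basal activation state (may be negative).
#' @param weights numeric matrix, `length(species)` rows and
#'   `length(species) + length(signals)` columns: `weights[i, j]` is the
#'   influence of species/signal `j` on species `i`.
#' @param name optional model name.
#' @param swap optional integer permutation of species expressing an exact
#'   interaction symmetry (used to classify pitchforks); `NULL` if none.
#' @return an object of class `network_spec`.
#' @seealso [th_model()] for the built-in models, [read_network_spec()].
#' @export
network_spec <- function(species, signals = character(), gamma, sigma, beta,
                         weights, name = "custom", swap = NULL) {
  n <- length(species)
  stopifnot(n >= 1, !anyDuplicated(c(species, signals)))
  gamma <- as.numeric(gamma); sigma <- as.numeric(sigma)
  beta <- as.numeric(beta)
  if (length(gamma) != n || length(sigma) != n || length(beta) != n)
    stop("gamma, sigma, beta must have one entry per species")
  if (any(gamma <= 0) || any(sigma <= 0))
    stop("gamma and sigma must be strictly positive")
  weights <- as.matrix(weights)
  if (nrow(weights) != n || ncol(weights) != n + length(signals))
    stop("weights must be n_species x (n_species + n_signals)")
  if (any(!is.finite(weights))) stop("weights must be finite (use 0, not NA)")
  dimnames(weights) <- list(species, c(species, signals))
  names(gamma) <- names(sigma) <- names(beta) <- species
  if (!is.null(swap)) {
    stopifnot(length(swap) == n, sort(swap) == seq_len(n))
    swap <- as.integer(swap)
  }
  structure(
    list(species = species, signals = signals, gamma = gamma, sigma = sigma,
         beta = beta, weights = weights, name = name, swap = swap),
    class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec> %s: %d species (%s), signals: %s\n",
              x$name, length(x$species), paste(x$species, collapse = ", "),
              if (length(x$signals)) paste(x$signals, collapse = ", ")
              else "none"))
  tab <- data.frame(gamma = x$gamma, sigma = x$sigma, beta = x$beta)
  print(tab, ...)
  cat("weights (row <- column):\n")
  print(x$weights, ...)
  invisible(x)
}

#' @export
format.network_spec <- function(x, ...) {
  sprintf("<network_spec %s: %d species>", x$name, length(x$species))
}

n_species <- function(spec) length(spec$species)

species_index <- function(spec, species) {
  i <- if (is.character(species)) match(species, spec$species)
  else as.integer(species)
  if (any(is.na(i)) || any(i < 1) || any(i > n_species(spec)))
    stop("species index out of range")
  i
}

# Signal values as a full named vector in spec order; missing names -> 0.
signal_values <- function(spec, signals = NULL) {
  s <- stats::setNames(numeric(length(spec$signals)), spec$signals)
  if (length(signals)) {
    if (is.null(names(signals)) && length(signals) == length(spec$signals)) {
      s[] <- signals
    } else {
      bad <- setdiff(names(signals), spec$signals)
      if (length(bad)) stop("unknown signal(s): ", paste(bad, collapse = ", "))
      s[names(signals)] <- signals
    }
  }
  s
}

#' Net regulatory input of one species
#'
#' Computes \eqn{W_i = \beta_i + \sum_j \omega_{ij} X_j +
#' \sum_k \omega_{ik} s_k}: the basal activation state plus the weighted sum
#' of all species activities and external signal concentrations. Signals
#' enter linearly, scaled by their weight.
#'
#' @param spec a [network_spec()] (or a sampled cell, see [sample_cell()]).
#' @param i species index or name.
#' @param x state vector (species activities).
#' @param signals named numeric vector of signal concentrations (missing
#'   signals default to 0).
#' @return numeric scalar (vector if `i` has several entries).
#' @examples
#' m <- th_model("symmetric")
#' net_input(m, "RORgt", c(0, 0))            # -0.8, the basal state
#' @export
net_input <- function(spec, i, x, signals = NULL) {
  i <- species_index(spec, i)
  s <- signal_values(spec, signals)
  stopifnot(length(x) == n_species(spec))
  unname(drop(spec$beta[i] + spec$weights[i, , drop = FALSE] %*% c(x, s)))
}

#' Right-hand side of the network ODEs
#'
#' \eqn{dX_i/dt = \gamma_i [F(\sigma_i W_i) - X_i]}. The derivative is zero
#' exactly at fixed points \eqn{X_i = F(\sigma_i W_i)}. Because
#' \eqn{0 < F < 1}, the unit box is forward-invariant: the flow points
#' inward on its boundary.
#'
#' @inheritParams net_input
#' @param x state vector.
#' @return derivative vector, one entry per species.
#' @export
net_rhs <- function(spec, x, signals = NULL) {
  s <- signal_values(spec, signals)
  u <- spec$beta + drop(spec$weights %*% c(x, s))
  unname(spec$gamma * (sigmoid(spec$sigma * u) - x))
}

# Jacobian of net_rhs at x (analytic): diag(gamma) %*% (D %*% Wx - I),
# D = diag(sigma_i F'(sigma_i W_i)), Wx = species block of the weights.
net_jacobian <- function(spec, x, signals = NULL) {
  n <- n_species(spec)
  s <- signal_values(spec, signals)
  u <- spec$sigma * (spec$beta + drop(spec$weights %*% c(x, s)))
  d <- spec$sigma * dsigmoid(u)
  Wx <- spec$weights[, seq_len(n), drop = FALSE]
  unname(spec$gamma * (d * Wx - diag(n)))
}

# The fixed-point map g(x) = F(sigma W) - x (gamma-free; same roots as rhs)
# and its Jacobian, used by Newton refinement.
fp_fun <- function(spec, x, s_full) {
  u <- spec$sigma * (spec$beta + drop(spec$weights %*% c(x, s_full)))
  sigmoid(u) - x
}

fp_jac <- function(spec, x, s_full) {
  n <- n_species(spec)
  u <- spec$sigma * (spec$beta + drop(spec$weights %*% c(x, s_full)))
  d <- spec$sigma * dsigmoid(u)
  d * spec$weights[, seq_len(n), drop = FALSE] - diag(n)
}
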