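#' Cell-to-cell parameter variability
#'
#' `sample_cell()` draws one cell's realized kinetic parameters around the
#' basal values of a network: every gamma, sigma, beta and non-zero
#' interaction weight is drawn independently from a normal distribution
#' with mean equal to the basal value and coefficient of variation `cv`
#' (sd = cv * |basal|). Structural zeros in the weight matrix (absent
#' interactions) are never sampled and stay exactly zero; external signal
#' concentrations are experiment inputs and are likewise exempt. Draws that
#' would flip the sign of a parameter are redrawn -- at cv = 0.05 a flip is
#' a ~16-sigma event, so this is a numerical safeguard rather than a change
#' of distribution.
#'
#' Sampling uses R's RNG stream; call `set.seed()` (or pass `seed`) for
#' reproducibility.
#'
#' `average_cell()` returns the cell with every parameter at its basal
#' value, the "average cell" to which bifurcation analysis applies.
#'
#' @param spec a [network_spec()].
#' @param cv coefficient of variation (>= 0); 0 reproduces the average cell.
#' @param seed optional integer seed (local to this call).
#' @param index optional cell index stored as provenance.
#' @return a `cell_params` object: a `network_spec`-shaped parameter set
#'   with attributes `base` (model name), `cv`, and `index`.
#' @examples
#' set.seed(1)
#' cell <- sample_cell(th_model("symmetric"), cv = 0.05)
#' @export
sample_cell <- function(spec, cv = 0.05, seed = NULL, index = NA_integer_) {
  stopifnot(inherits(spec, "network_spec"), cv >= 0)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  cell <- spec
  if (cv > 0) {
    cell$gamma <- draw_signed(spec$gamma, cv)
    cell$sigma <- draw_signed(spec$sigma, cv)
    cell$beta <- draw_signed(spec$beta, cv)
    nz <- spec$weights != 0
    w <- spec$weights
    w[nz] <- draw_signed(spec$weights[nz], cv)
    cell$weights <- w
  }
  class(cell) <- c("cell_params", "network_spec")
  attr(cell, "base") <- spec$name
  attr(cell, "cv") <- cv
  attr(cell, "index") <- index
  cell
}

# sign-preserving normal draw, sd = cv * |mean|
draw_signed <- function(mu, cv) {
  x <- stats::rnorm(length(mu), mu, cv * abs(mu))
  bad <- sign(x) != sign(mu) & mu != 0
  guard <- 0L
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mu[bad], cv * abs(mu[bad]))
    bad <- sign(x) != sign(mu) & mu != 0
    if ((guard <- guard + 1L) > 100L) stop("sign-preserving resample failed")
  }
  names(x) <- names(mu)
  x
}

#' @rdname sample_cell
#' @export
average_cell <- function(spec) sample_cell(spec, cv = 0)

#' @export
print.cell_params <- function(x, ...) {
  cat(sprintf("<cell_params> from model '%s' (cv = %g, index = %s)\n",
              attr(x, "base"), attr(x, "cv"), attr(x, "index")))
  NextMethod()
}

# Pack one cell into the flat parameter row used by the C++ integrator:
# [gamma, sigma, beta, vec(weights)] (column-major weights).
pack_cell <- function(cell) {
  c(cell$gamma, cell$sigma, cell$beta, as.numeric(cell$weights))
}

# Sample n cells and pack them into a matrix, one row per cell.
pack_population <- function(spec, n_cells, cv) {
  t(vapply(seq_len(n_cells),
           function(i) pack_cell(sample_cell(spec, cv, index = i)),
           numeric(3 * n_species(spec) + length(spec$weights))))
}
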