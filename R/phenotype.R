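#' Phenotype classification of a cell state
#'
#' A protein is "expressed" when its activity exceeds `threshold` (default
#' 0.5, half of the nominal maximum). The two master regulators partition
#' states into four classes: `naive` (neither RORgt nor Foxp3 expressed),
#' `ror_only`, `foxp3_only`, and `double` (both expressed). Two derived
#' flags are also reported: `foxp3_expressing` (Foxp3 above threshold,
#' regardless of RORgt) and, for networks carrying an IL-17 readout,
#' `il17_producing`.
#'
#' @param state named state vector (must contain `RORgt` and `Foxp3`).
#' @param spec the [network_spec()] the state belongs to.
#' @param threshold expression threshold (dimensionless units).
#' @return list with `class` (one of [phenotype_levels()]),
#'   `foxp3_expressing`, `il17_producing` (`NA` if the network has no IL-17
#'   species).
#' @examples
#' m <- th_model("symmetric")
#' classify_phenotype(c(RORgt = 0.9, Foxp3 = 0.1), m)$class
#' @export
classify_phenotype <- function(state, spec, threshold = 0.5) {
  idx <- match(c("RORgt", "Foxp3"), spec$species)
  if (anyNA(idx))
    stop("phenotype calls need species 'RORgt' and 'Foxp3'")
  r <- state[idx[1]] > threshold
  f <- state[idx[2]] > threshold
  cls <- if (r && f) "double" else if (r) "ror_only" else if (f) "foxp3_only"
  else "naive"
  il17 <- match("IL17", spec$species)
  list(class = cls,
       foxp3_expressing = unname(f),
       il17_producing = if (is.na(il17)) NA else
         unname(state[il17] > threshold))
}

#' @rdname classify_phenotype
#' @export
phenotype_levels <- function() c("naive", "ror_only", "foxp3_only", "double")

# Vectorized fraction table for a matrix of final states (rows = cells).
# Unsettled cells are excluded from the denominators and counted.
phenotype_fractions <- function(states, settled, spec, threshold = 0.5) {
  idx <- match(c("RORgt", "Foxp3"), spec$species)
  il17 <- match("IL17", spec$species)
  ok <- which(settled)
  n <- length(ok)
  r <- states[ok, idx[1]] > threshold
  f <- states[ok, idx[2]] > threshold
  cls <- ifelse(r & f, "double",
                ifelse(r, "ror_only", ifelse(f, "foxp3_only", "naive")))
  frac <- as.numeric(table(factor(cls, levels = phenotype_levels()))) /
    max(n, 1)
  out <- data.frame(
    n = nrow(states), n_settled = n,
    frac_naive = frac[1], frac_ror_only = frac[2],
    frac_foxp3_only = frac[3], frac_double = frac[4],
    frac_foxp3_expr = if (n) mean(f) else NA_real_,
    frac_il17 = if (is.na(il17)) NA_real_
    else if (n) mean(states[ok, il17] > threshold) else NA_real_)
  out
}
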