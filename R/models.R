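#' Built-in TH17/iTreg network models
#'
#' Returns one of the three registered networks for the reciprocal
#' differentiation of TH17 and induced-Treg cells, with their published
#' basal parameter values:
#'
#' * `"symmetric"` -- the two-gene circuit: RORgt and Foxp3 each
#'   autoactivate, mutually inhibit, and are activated directly by TGF-beta.
#'   All corresponding interactions have identical strengths, so the system
#'   has an exact RORgt/Foxp3 exchange symmetry.
#' * `"symmetric_intermediates"` -- the same circuit with TGF-beta routed
#'   through two intermediate transducers (an unknown intermediate UI to
#'   RORgt, a generalized Smad to Foxp3), which saturates the effective
#'   TGF-beta drive at high signal.
#' * `"asymmetric"` -- the broken-symmetry six-species model: the direct
#'   inhibition of RORgt by Foxp3 is removed, Foxp3 instead represses the
#'   effector cytokine IL-17, and two polarizing inputs are added (IL-6
#'   acting through STAT3, and all-trans retinoic acid ATRA acting directly
#'   on RORgt, Foxp3 and IL-17). IL-17 is a pure readout with no outgoing
#'   edges.
#'
#' Species activities are dimensionless in nominal range 0 to 1; one time
#' unit is roughly one hour. Signal concentrations (TGF-beta, IL-6, ATRA)
#' are experiment inputs, not cell parameters, and are exempt from
#' cell-to-cell variability.
#'
#' @param name one of `"symmetric"`, `"symmetric_intermediates"`,
#'   `"asymmetric"`.
#' @return a [network_spec()].
#' @examples
#' m <- th_model("symmetric")
#' net_rhs(m, c(0.019, 0.019), c(TGFb = 0))
#' @export
th_model <- function(name = c("symmetric", "symmetric_intermediates",
                              "asymmetric")) {
  name <- match.arg(name)
  switch(name,
    symmetric = {
      W <- rbind(
        RORgt = c(1.24, -0.4, 1.2),
        Foxp3 = c(-0.4, 1.24, 1.2))
      network_spec(
        species = c("RORgt", "Foxp3"), signals = "TGFb",
        gamma = c(1, 1), sigma = c(5, 5), beta = c(-0.8, -0.8),
        weights = W, name = "symmetric", swap = c(2L, 1L))
    },
    symmetric_intermediates = {
      #          RORgt Foxp3   UI  Smad TGFb
      W <- rbind(
        RORgt = c(1.2, -0.4, 0.62, 0,    0),
        Foxp3 = c(-0.4, 1.2, 0,    0.62, 0),
        UI    = c(0,    0,   0,    0,    1.2),
        Smad  = c(0,    0,   0,    0,    1.2))
      network_spec(
        species = c("RORgt", "Foxp3", "UI", "Smad"), signals = "TGFb",
        gamma = c(1, 1, 1, 1), sigma = c(5, 5, 10, 10),
        beta = c(-0.8, -0.8, -0.2, -0.2),
        weights = W, name = "symmetric_intermediates",
        swap = c(2L, 1L, 4L, 3L))
    },
    asymmetric = {
      #          RORgt Foxp3   UI   Smad IL17 STAT3 TGFb IL6  ATRA
      W <- rbind(
        RORgt = c(0.70,  0,    0.86, 0,    0,  0.2,  0,   0,  -0.04),
        Foxp3 = c(-0.54, 1.28, 0,    0.68, 0, -0.1,  0,   0,   0.035),
        UI    = c(0,     0,    0,    0,    0,  0,    1,   0,   0),
        Smad  = c(0,     0,    0,    0,    0,  0,    1,   0,   0),
        IL17  = c(0.22, -0.8,  0,    0,    0,  0.6,  0,   0,  -0.1),
        STAT3 = c(0,     0,    0,    0,    0,  0,    0,   0.2, 0))
      network_spec(
        species = c("RORgt", "Foxp3", "UI", "Smad", "IL17", "STAT3"),
        signals = c("TGFb", "IL6", "ATRA"),
        gamma = c(1, 1, 1, 1, 1, 0.1),
        sigma = c(7, 5, 12, 20, 30, 10),
        beta = c(-0.84, -0.92, -0.23, -0.225, -0.82, -0.4),
        weights = W, name = "asymmetric", swap = NULL)
    })
}

#' @rdname th_model
#' @export
th_models <- function() c("symmetric", "symmetric_intermediates", "asymmetric")
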