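#' Read and write network definitions as JSON config files
#'
#' A network config is a JSON object with fields `name`, `signals`,
#' `species` (array of `{name, gamma, sigma, beta}`), `edges` (array of
#' `{source, target, weight}`; `source` may be a species or a signal;
#' absent pairs are zero) and optionally `swap` (an integer permutation
#' encoding an exact interaction symmetry). Writing and re-reading a spec
#' reproduces its parameter values exactly at double precision.
#'
#' @param path file path.
#' @return `read_network_spec()` returns a [network_spec()];
#'   `write_network_spec()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".json")
#' write_network_spec(th_model("symmetric"), f)
#' identical(read_network_spec(f), th_model("symmetric"))
#' @export
read_network_spec <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  sp <- cfg$species
  stopifnot(is.data.frame(sp), all(c("name", "gamma", "sigma", "beta")
                                   %in% names(sp)))
  signals <- as.character(cfg$signals %||% character())
  n <- nrow(sp)
  W <- matrix(0, n, n + length(signals),
              dimnames = list(sp$name, c(sp$name, signals)))
  ed <- cfg$edges
  if (!is.null(ed) && nrow(ed)) {
    bad <- setdiff(unique(c(ed$source, ed$target)), colnames(W))
    if (length(bad)) stop("edge references unknown node(s): ",
                          paste(bad, collapse = ", "))
    if (any(!ed$target %in% sp$name)) stop("edge target must be a species")
    W[cbind(match(ed$target, sp$name), match(ed$source, colnames(W)))] <-
      ed$weight
  }
  network_spec(species = sp$name, signals = signals, gamma = sp$gamma,
               sigma = sp$sigma, beta = sp$beta, weights = W,
               name = cfg$name %||% "config",
               swap = if (length(cfg$swap)) as.integer(cfg$swap) else NULL)
}

#' @rdname read_network_spec
#' @param spec a [network_spec()].
#' @export
write_network_spec <- function(spec, path) {
  nz <- which(spec$weights != 0, arr.ind = TRUE)
  edges <- data.frame(
    source = colnames(spec$weights)[nz[, "col"]],
    target = spec$species[nz[, "row"]],
    weight = spec$weights[nz])
  edges <- edges[order(match(edges$target, spec$species),
                       match(edges$source, colnames(spec$weights))), ]
  cfg <- list(
    name = spec$name,
    signals = spec$signals,
    species = data.frame(name = spec$species, gamma = unname(spec$gamma),
                         sigma = unname(spec$sigma),
                         beta = unname(spec$beta)),
    edges = edges)
  if (!is.null(spec$swap)) cfg$swap <- spec$swap
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
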