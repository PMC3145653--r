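#' Piecewise-constant signal schedules
#'
#' A `signal_schedule` gives the value of every external signal as a
#' piecewise-constant function of time. It is built from switching events:
#' at each listed `time`, the named `signal` jumps to `value` and holds it
#' until its next event. Signals start at 0 unless an event at time 0 says
#' otherwise. The ODE integrator restarts at every breakpoint so signal
#' discontinuities are handled exactly.
#'
#' @param spec a [network_spec()] (defines the signal set).
#' @param events a `data.frame` with columns `time`, `signal`, `value`
#'   (values >= 0), or `NULL` for an all-zero schedule. Constant signals can
#'   instead be given via `...` as named scalars, e.g. `TGFb = 0.5`.
#' @param ... named constant signal levels (alternative to `events`).
#' @return a `signal_schedule`: breakpoint times plus a matrix of per-segment
#'   signal values.
#' @examples
#' m <- th_model("asymmetric")
#' # classic reprogramming protocol: induce at t = 10, add IL-6 at t = 80
#' sched <- signal_schedule(m, data.frame(
#'   time = c(10, 80), signal = c("TGFb", "IL6"), value = c(0.28, 10)))
#' @export
signal_schedule <- function(spec, events = NULL, ...) {
  consts <- list(...)
  if (length(consts)) {
    stopifnot(is.null(events))
    events <- data.frame(time = 0, signal = names(consts),
                         value = as.numeric(unlist(consts)))
  }
  if (is.null(events))
    events <- data.frame(time = numeric(), signal = character(),
                         value = numeric())
  stopifnot(all(c("time", "signal", "value") %in% names(events)))
  bad <- setdiff(events$signal, spec$signals)
  if (length(bad)) stop("unknown signal(s): ", paste(bad, collapse = ", "))
  if (any(events$value < 0)) stop("signal values must be >= 0")
  if (any(events$time < 0)) stop("event times must be >= 0")
  events <- events[order(events$time), , drop = FALSE]
  starts <- sort(unique(c(0, events$time)))
  vals <- matrix(0, length(starts), length(spec$signals),
                 dimnames = list(NULL, spec$signals))
  cur <- stats::setNames(numeric(length(spec$signals)), spec$signals)
  for (k in seq_along(starts)) {
    ev <- events[events$time == starts[k], , drop = FALSE]
    if (nrow(ev)) cur[ev$signal] <- ev$value
    vals[k, ] <- cur
  }
  structure(list(start = starts, values = vals, signals = spec$signals,
                 events = events),
            class = "signal_schedule")
}

#' @export
print.signal_schedule <- function(x, ...) {
  cat("<signal_schedule> segments:\n")
  print(cbind(t_start = x$start, x$values), ...)
  invisible(x)
}

#' @rdname signal_schedule
#' @param schedule a `signal_schedule`.
#' @param t time point.
#' @return `signals_at()` returns the named signal vector in force at `t`.
#' @export
signals_at <- function(schedule, t) {
  k <- findInterval(t, schedule$start)
  stats::setNames(schedule$values[max(k, 1L), ], schedule$signals)
}

# constant-signal helper used throughout the analysis layer
constant_schedule <- function(spec, signals = NULL) {
  s <- signal_values(spec, signals)
  sched <- signal_schedule(spec)
  sched$values[1, ] <- s
  sched
}
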