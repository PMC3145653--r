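#' Run a differentiation protocol for one cell
#'
#' Integrates a single cell through a signal schedule that must begin with
#' an all-zero equilibration phase (the cell first finds its own naive
#' low/low steady state, as in the induced-differentiation experiments),
#' then calls the terminal phenotype. A cell whose dynamics have not
#' converged (`max |dX/dt| >= ss_tol`) by `t_end` is flagged unsettled; the
#' population layer excludes such cells from fraction denominators.
#'
#' @param spec a [network_spec()].
#' @param cell a [sample_cell()] result (default: the average cell).
#' @param schedule a [signal_schedule()] starting with all signals 0.
#' @param t_end simulation horizon; default: last breakpoint + 500 time
#'   units.
#' @param ss_tol steady-state criterion on `max |dX/dt|`.
#' @param ... passed to [integrate_cell()].
#' @return list with `trajectory`, `phenotype` (see [classify_phenotype()]),
#'   and `settled`.
#' @export
run_protocol <- function(spec, cell = average_cell(spec),
                         schedule = signal_schedule(spec), t_end = NULL,
                         ss_tol = 1e-8, rtol = 1e-9, atol = 1e-12, ...) {
  if (any(schedule$values[1, ] != 0))
    stop("protocol schedules must start with an all-zero equilibration phase")
  if (is.null(t_end)) t_end <- max(schedule$start) + 500
  tr <- integrate_cell(cell, schedule = schedule, t_end = t_end,
                       ss_tol = ss_tol, rtol = rtol, atol = atol, ...)
  list(trajectory = tr,
       phenotype = classify_phenotype(tr$final, spec),
       settled = tr$converged)
}

# Shared engine: sample a population, push it through a schedule, return
# final states + settled flags. Uses the current RNG stream.
population_finals <- function(spec, n_cells, cv, schedule, t_end,
                              x0 = 0.01, rtol = 1e-9, atol = 1e-12,
                              ss_tol = 1e-8) {
  # rtol must sit well below ss_tol: the adaptive stepper otherwise hovers
  # at tolerance-level distance from the attractor and the |dX/dt| < ss_tol
  # early exit never fires (biasing fractions toward fast-converging fates)
  cells <- pack_population(spec, n_cells, cv)
  x0m <- matrix(x0, 1, n_species(spec))
  res <- cpp_settle_cells(cells, n_species(spec), length(spec$signals),
                          schedule$start, schedule$values, t_end, x0m,
                          rtol, atol, ss_tol)
  colnames(res$final) <- spec$species
  list(states = res$final, settled = res$converged)
}

induction_schedule <- function(spec, tgfb, fixed_signals = NULL,
                               t_induce = 10) {
  ev <- data.frame(time = t_induce, signal = "TGFb", value = tgfb)
  if (length(fixed_signals))
    ev <- rbind(ev, data.frame(time = t_induce, signal = names(fixed_signals),
                               value = as.numeric(fixed_signals)))
  signal_schedule(spec, ev)
}

#' Population signal-response curve
#'
#' For each TGF-beta concentration on a grid, simulates induced
#' differentiation of an independently sampled heterogeneous population:
#' every cell equilibrates for 10 time units at zero signal from small
#' initial values (0.01), the inducing signals are switched on, and the
#' simulation runs to steady state (or the 500-time-unit cap). Reported per
#' condition: fractions of naive, RORgt-only, Foxp3-only and
#' double-expressing cells, plus the Foxp3-expressing and (for networks
#' with IL-17) IL-17-producing flags. Unsettled cells are excluded from
#' denominators and counted in `n_settled`.
#'
#' @param spec a [network_spec()] with a `TGFb` signal.
#' @param tgfb numeric grid of TGF-beta concentrations.
#' @param n_cells cells per grid point.
#' @param cv cell-to-cell coefficient of variation.
#' @param fixed_signals named vector of polarizing signals (e.g.
#'   `c(IL6 = 10)`) applied together with TGF-beta at induction.
#' @param seed integer seed (one stream across the whole grid).
#' @param t_induce equilibration duration before induction.
#' @param t_settle induction horizon (cap; early exit at steady state).
#' @return data.frame, one row per grid value: `TGFb`, any fixed signals,
#'   `n`, `n_settled`, and the `frac_*` columns.
#' @examples
#' \donttest{
#' sr <- signal_response(th_model("symmetric"), c(0.3, 0.5), n_cells = 100,
#'                       seed = 1)
#' }
#' @export
signal_response <- function(spec, tgfb, n_cells = 1000, cv = 0.05,
                            fixed_signals = NULL, seed = NULL,
                            t_induce = 10, t_settle = 500) {
  stopifnot(length(tgfb) >= 1, "TGFb" %in% spec$signals)
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(tgfb, function(v) {
    sched <- induction_schedule(spec, v, fixed_signals, t_induce)
    fin <- population_finals(spec, n_cells, cv, sched,
                             t_end = t_induce + t_settle)
    fr <- phenotype_fractions(fin$states, fin$settled, spec)
    row <- data.frame(TGFb = v)
    if (length(fixed_signals)) row <- cbind(row, as.list(fixed_signals))
    cbind(row, fr)
  })
  out <- do.call(rbind, rows)
  n_unsettled <- sum(out$n - out$n_settled)
  if (n_unsettled > 0)
    warning(sprintf("%d of %d cell runs did not settle by t = %g",
                    n_unsettled, sum(out$n), t_induce + t_settle))
  out
}

#' iTreg-to-TH17 reprogramming time course
#'
#' Simulates the classic reprogramming experiment on the asymmetric
#' network: a heterogeneous population equilibrates at zero signal for 10
#' time units, differentiation is induced with TGF-beta (default 0.28
#' units, optionally plus ATRA), and at `t_reprogram` (default 80) IL-6 is
#' raised to reprogram the Foxp3-expressing cells. Phenotype fractions are
#' recorded on a uniform time grid.
#'
#' @inheritParams signal_response
#' @param tgfb inducing TGF-beta concentration (from t = 10 on).
#' @param il6 IL-6 concentration applied from `t_reprogram` on.
#' @param atra ATRA concentration applied together with TGF-beta (0 or 1.5
#'   in the reference protocols).
#' @param t_reprogram time at which IL-6 is added.
#' @param t_end end of the recorded time course.
#' @param dt_out spacing of the recorded time grid.
#' @return data.frame, one row per sample time: `time`, signal levels, `n`,
#'   `n_settled` (cells settled by the end of the run, reported on every
#'   row), and the `frac_*` columns over time.
#' @export
reprogram <- function(spec, n_cells = 1000, cv = 0.05, tgfb = 0.28,
                      il6 = 10, atra = 0, seed = NULL, t_induce = 10,
                      t_reprogram = 80, t_end = 250, dt_out = 2) {
  stopifnot(all(c("TGFb", "IL6", "ATRA") %in% spec$signals))
  if (!is.null(seed)) set.seed(seed)
  ev <- data.frame(time = c(t_induce, t_reprogram),
                   signal = c("TGFb", "IL6"), value = c(tgfb, il6))
  if (atra > 0)
    ev <- rbind(ev, data.frame(time = t_induce, signal = "ATRA",
                               value = atra))
  sched <- signal_schedule(spec, ev)
  times <- seq(0, t_end, by = dt_out)
  cells <- pack_population(spec, n_cells, cv)
  res <- cpp_timecourse_cells(cells, n_species(spec), length(spec$signals),
                              sched$start, sched$values, t_end,
                              matrix(0.01, 1, n_species(spec)), times,
                              1e-9, 1e-12, 1e-8)
  n <- n_species(spec)
  rows <- lapply(seq_along(times), function(k) {
    states <- res$states[, (k - 1) * n + seq_len(n), drop = FALSE]
    colnames(states) <- spec$species
    # convergence only meaningful for the terminal fractions; at interior
    # times every cell is a valid observation
    fr <- phenotype_fractions(states, rep(TRUE, nrow(states)), spec)
    fr$n_settled <- sum(res$converged)
    cbind(data.frame(time = times[k], TGFb = tgfb, IL6 = il6, ATRA = atra),
          fr)
  })
  do.call(rbind, rows)
}

#' Reprogramming outcome over an IL-6 x ATRA concentration grid
#'
#' For every (ATRA used at induction, IL-6 used for reprogramming) pair,
#' runs the [reprogram()] protocol to steady state and reports the terminal
#' Foxp3-expressing and IL-17-producing percentages (plus the full
#' phenotype fractions). The `(il6 = 0, atra = 0)` corner is plain induced
#' differentiation.
#'
#' @inheritParams reprogram
#' @param il6_grid,atra_grid signal concentration grids (>= 0).
#' @return data.frame, one row per (IL6, ATRA) pair.
#' @export
il6_atra_grid <- function(spec, il6_grid, atra_grid, n_cells = 1000,
                          cv = 0.05, tgfb = 0.28, seed = NULL,
                          t_induce = 10, t_reprogram = 80, t_settle = 500) {
  stopifnot(length(il6_grid) >= 1, length(atra_grid) >= 1)
  if (!is.null(seed)) set.seed(seed)
  combos <- expand.grid(IL6 = il6_grid, ATRA = atra_grid,
                        KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(k) {
    il6 <- combos$IL6[k]; atra <- combos$ATRA[k]
    ev <- data.frame(time = c(t_induce, t_reprogram),
                     signal = c("TGFb", "IL6"), value = c(tgfb, il6))
    if (atra > 0)
      ev <- rbind(ev, data.frame(time = t_induce, signal = "ATRA",
                                 value = atra))
    sched <- signal_schedule(spec, ev)
    fin <- population_finals(spec, n_cells, cv, sched,
                             t_end = t_reprogram + t_settle)
    fr <- phenotype_fractions(fin$states, fin$settled, spec)
    cbind(data.frame(IL6 = il6, ATRA = atra, TGFb = tgfb), fr)
  })
  do.call(rbind, rows)
}
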