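#' Steady-state ICaL activation curve
#'
#' \eqn{d_\infty(V) = 1/(1 + \exp((V_{a05} - V)/S_a))}; strictly increasing
#' in V with values in (0, 1).
#'
#' @param V membrane potential (mV), vectorised
#' @param p a [gate_params()] object
#' @return activation open fraction
#' @export
d_inf <- function(V, p) {
  stopifnot(inherits(p, "gate_params"))
  1 / (1 + exp((p$va05 - V) / p$sa))
}

#' Steady-state ICaL voltage-inactivation curve
#'
#' \eqn{f_\infty(V) = (1-\phi)/(1 + \exp((V - V_{ina05})/S_{ina})) + \phi},
#' strictly decreasing in V; the optional floor \eqn{\phi} models channels
#' with incomplete voltage-dependent inactivation.
#'
#' @inheritParams d_inf
#' @return inactivation-gate availability
#' @export
f_inf <- function(V, p) {
  stopifnot(inherits(p, "gate_params"))
  (1 - p$ts_floor) / (1 + exp((V - p$vina05) / p$sina)) + p$ts_floor
}

#' Initial (resting) TP06 state
#'
#' Returns the 21-variable state vector at the published TP06 resting state,
#' with the wild-type and mutant ICaL gates both initialised to the TP06
#' d/f resting values.
#'
#' @return named numeric vector: `V`, ionic concentrations (`Ki`, `Nai`,
#'   `Cai`, `CaSS`, `CaSR`), 14 gating variables (including `d_wt`, `f_wt`,
#'   `d_ts`, `f_ts`; `f2` and `fCass` are shared between variants), and the
#'   ryanodine-receptor adaptation variable `Rbar`
#' @export
tp06_initial_state <- function() .tp06_initial_state_cpp()

#' Membrane currents at a given state
#'
#' Evaluates all TP06 currents (pA/pF), including the two ICaL variant
#' components and their mixture.
#'
#' @param state a 21-entry state vector, see [tp06_initial_state()]
#' @param phenotype a [cell_phenotype()]
#' @param mutation a [mutation_setting()]
#' @return named vector of currents; `Iion` is the total
#' @export
tp06_currents <- function(state, phenotype = cell_phenotype(),
                          mutation = mutation_setting()) {
  .tp06_currents_cpp(state, .pack_params(mutation, phenotype$iks_factor,
                                         phenotype$base_cell_type))
}

#' Mixed wild-type/mutant L-type calcium current
#'
#' \eqn{I_{CaL} = (1-\rho) I_{CaL}^{WT} + \rho I_{CaL}^{TS}}, each variant
#' using the TP06 GHK-type driving term with its own d and f gates and the
#' shared f2 and fCass gates and maximal conductance.
#'
#' @inheritParams tp06_currents
#' @return list with components `ICaL` (mixture), `ICaL_wt`, `ICaL_ts`
#' @export
i_cal_mixed <- function(state, mutation = mutation_setting(),
                        phenotype = cell_phenotype()) {
  cur <- tp06_currents(state, phenotype, mutation)
  list(ICaL = unname(cur[["ICaL"]]), ICaL_wt = unname(cur[["ICaL_wt"]]),
       ICaL_ts = unname(cur[["ICaL_ts"]]))
}

#' Full TP06 right-hand side
#'
#' Time derivative of every state variable at the given state: gate dynamics
#' \eqn{(w_\infty(V) - w)/\tau_w(V)} (mutant gates use their own steady-state
#' curves with unchanged TP06 time constants), concentration fluxes with
#' instantaneous-buffer factors, and
#' \eqn{dV/dt = -I_{ion} + i_{app}}.
#'
#' @inheritParams tp06_currents
#' @param i_app applied current (pA/pF)
#' @return named derivative vector (units per ms)
#' @export
tp06_rhs <- function(state, phenotype = cell_phenotype(),
                     mutation = mutation_setting(), i_app = 0) {
  if (any(!is.finite(state)))
    stop("non-finite state variable passed to tp06_rhs")
  .tp06_rhs_cpp(state, .pack_params(mutation, phenotype$iks_factor,
                                    phenotype$base_cell_type), i_app)
}

#' Paced single-cell (space-clamped) run
#'
#' Integrates the cell model with the same splitting used by the tissue
#' solver (Rush-Larsen gates at frozen V, forward concentration update,
#' forward V step), pacing with rectangular current pulses.
#'
#' @inheritParams tp06_currents
#' @param bcl basic cycle length (ms)
#' @param n_beats number of stimuli; `0` returns the initial state only
#' @param tau time step (ms)
#' @param stim_amplitude,stim_duration stimulus strength (pA/pF) and width (ms)
#' @param record_dt sampling interval of the stored trace (ms)
#' @param tail_ms extra time simulated after the last cycle (ms)
#' @param state0 optional initial state (defaults to [tp06_initial_state()])
#' @return object of class `cell_trace`: data frame `trace` (time, V, Cai),
#'   full state matrix `states`, `final_state`, the marker list of the last
#'   beat (`acti`, `repo`, `apd`, `ead`, via [trace_markers()]), and a
#'   `captured` flag
#' @export
run_single_cell <- function(phenotype = cell_phenotype(),
                            mutation = mutation_setting(),
                            bcl = 1000, n_beats = 8, tau = 0.05,
                            stim_amplitude = 52, stim_duration = 1,
                            record_dt = 1, tail_ms = 0,
                            state0 = tp06_initial_state()) {
  stopifnot(n_beats >= 0, bcl > 0, tau > 0)
  params <- .pack_params(mutation, phenotype$iks_factor,
                         phenotype$base_cell_type)
  if (n_beats == 0) {
    return(structure(list(
      time = 0, states = matrix(state0, nrow = 1,
                                dimnames = list(NULL, names(state0))),
      final_state = state0, markers = NULL, captured = NA,
      bcl = bcl, n_beats = 0), class = "cell_trace"))
  }
  t_end <- n_beats * bcl + tail_ms
  res <- .cell_run_cpp(state0, params, tau, t_end,
                       seq(0, by = bcl, length.out = n_beats),
                       rep(stim_duration, n_beats),
                       rep(stim_amplitude, n_beats), record_dt)
  last <- res$time >= (n_beats - 1) * bcl
  mk <- if (sum(last) >= 5) {
    trace_markers(res$time[last] - (n_beats - 1) * bcl, res$states[last, 1])
  } else NULL
  captured <- !is.null(mk) && is.finite(mk$acti) &&
    max(res$states[last, 1]) > 0
  structure(list(time = res$time, states = res$states,
                 final_state = res$final_state, markers = mk,
                 captured = captured, bcl = bcl, n_beats = n_beats),
            class = "cell_trace")
}

#' @exportS3Method base::print
print.cell_trace <- function(x, ...) {
  cat(sprintf("Paced cell trace: %d beat(s) at BCL %g ms\n", x$n_beats, x$bcl))
  if (!is.null(x$markers)) {
    cat(sprintf("  last beat: ACTI %.1f ms, REPO %.1f ms, APD %.1f ms%s\n",
                x$markers$acti, x$markers$repo, x$markers$apd,
                if (isTRUE(x$markers$ead)) " [EAD]" else ""))
  }
  invisible(x)
}
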