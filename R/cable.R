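#' Advance a 1D cable
#'
#' Semi-implicit monodomain cable integration (Rush-Larsen/forward ODE stage,
#' implicit tridiagonal diffusion step). Phenotype may vary per node through
#' `iks_factor` (and `rho`), enabling transmural ENDO|MID|EPI cables.
#'
#' @param cable a [build_cable()] object
#' @param states 21 x n state matrix (e.g. recycled [tp06_initial_state()])
#' @param mutation a [mutation_setting()]
#' @param iks_factor scalar or per-node IKs multiplier
#' @param t_end duration (ms)
#' @param stim_onsets,stim_duration,stim_amplitude stimulus train applied to
#'   `stim_nodes` (amplitude in mA/cm^3)
#' @param stim_nodes stimulated node indices (default: first three nodes,
#'   a 0.06 cm footprint at default spacing)
#' @param probes node indices to record
#' @param record_dt sampling interval (ms)
#' @param tau time step (ms)
#' @param cm volumetric capacitance (mF/cm^3)
#' @param rho scalar or per-node heterozygosis (defaults to the mutation's)
#' @param base_cell_type TP06 base formulation
#' @param event_threshold,event_slope upstroke event detection
#' @return list: `time`, `traces` (one column per probe), upstroke `events`,
#'   `final_states`
#' @export
cable_advance <- function(cable, states, mutation = mutation_setting(),
                          iks_factor = 1, t_end = 1000,
                          stim_onsets = 0, stim_duration = 1,
                          stim_amplitude = 350,
                          stim_nodes = 1:3,
                          probes = ceiling(cable$n_nodes / 2),
                          record_dt = 1, tau = 0.05, cm = 1,
                          rho = mutation$rho,
                          base_cell_type = "epi",
                          event_threshold = -20, event_slope = 10) {
  stopifnot(inherits(cable, "lqt8_cable"), nrow(states) == 21,
            ncol(states) == cable$n_nodes)
  deff <- if (cable$n_nodes == 1L) 0 else cable$sigma * 1e-3 / cm
  ct <- c(epi = 0L, endo = 1L, M = 2L)[[base_cell_type]]
  ns <- length(stim_onsets)
  .cable_run_cpp(states, .pack_gates(mutation), rho, iks_factor, ct,
                 deff, cable$h, tau, t_end,
                 as.integer(stim_nodes) - 1L, stim_onsets,
                 rep(stim_duration, length.out = ns),
                 rep(stim_amplitude / cm, length.out = ns),
                 as.integer(probes) - 1L, record_dt,
                 event_threshold, event_slope)
}

#' Paced single-phenotype cable run with APD measurement
#'
#' Paces one end of a uniform cable to quasi-steady state and measures the
#' activation/repolarization markers of the last beat at a mid-cable site.
#'
#' @inheritParams cable_advance
#' @param bcl basic cycle length (ms)
#' @param n_beats number of paced beats (the default 8 reaches quasi-steady
#'   state for these phenotypes)
#' @param measure_node recording site (default mid-cable)
#' @return object of class `cell_trace` (see [run_single_cell()]) with the
#'   mid-cable trace and last-beat markers
#' @export
run_cable_pacing <- function(cable = build_cable(),
                             mutation = mutation_setting(),
                             iks_factor = 1, bcl = 1000, n_beats = 8,
                             tau = 0.05, record_dt = 1,
                             stim_amplitude = 350, stim_duration = 1,
                             measure_node = ceiling(cable$n_nodes / 2),
                             base_cell_type = "epi") {
  states <- matrix(rep(tp06_initial_state(), cable$n_nodes), nrow = 21)
  res <- cable_advance(cable, states, mutation, iks_factor,
                       t_end = n_beats * bcl,
                       stim_onsets = seq(0, by = bcl, length.out = n_beats),
                       stim_duration = stim_duration,
                       stim_amplitude = stim_amplitude,
                       probes = measure_node, record_dt = record_dt,
                       tau = tau, base_cell_type = base_cell_type)
  last <- res$time >= (n_beats - 1) * bcl
  v <- res$traces[last, 1]
  mk <- trace_markers(res$time[last] - (n_beats - 1) * bcl, v)
  structure(list(time = res$time, states = NULL, traces = res$traces,
                 final_states = res$final_states,
                 markers = mk, captured = is.finite(mk$acti) && max(v) > 0,
                 bcl = bcl, n_beats = n_beats), class = "cell_trace")
}

#' Write a two-column time/voltage trace
#'
#' @param time,v trace samples
#' @param path output file
#' @export
write_trace <- function(time, v, path) {
  utils::write.table(data.frame(time = time, v = v), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
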