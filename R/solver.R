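#' Solver configuration
#'
#' Time step, tissue model and linear-solver contracts of the
#' operator-splitting integrator.
#'
#' @param tau time step (ms)
#' @param model `"monodomain"` (harmonic-mean tensor) or `"bidomain"`
#' @param cm volumetric membrane capacitance (mF/cm^3); the default 1
#'   corresponds to a surface-to-volume ratio of 1000 /cm at 1 uF/cm^2
#' @param rtol_parabolic,rtol_elliptic relative residual tolerances of the
#'   conjugate-gradient solves
#' @param maxit maximum CG iterations
#' @param event_threshold,event_slope upstroke-event detection: potential
#'   level (mV) and minimal dV/dt (mV/ms)
#' @return object of class `solver_config`
#' @export
solver_config <- function(tau = 0.05,
                          model = c("monodomain", "bidomain"),
                          cm = 1,
                          rtol_parabolic = 1e-10, rtol_elliptic = 1e-8,
                          maxit = 10000,
                          event_threshold = -20, event_slope = 10) {
  model <- match.arg(model)
  stopifnot(tau > 0, cm > 0)
  structure(list(tau = tau, model = model, cm = cm,
                 rtol_parabolic = rtol_parabolic,
                 rtol_elliptic = rtol_elliptic, maxit = maxit,
                 event_threshold = event_threshold,
                 event_slope = event_slope),
            class = "solver_config")
}

# conductivities are assembled in mS/cm; dividing by c_m (mF/cm^3) and by
# 1000 brings the diffusion operator to the pA/pF current scale of the
# membrane model (cm^2/ms diffusivity).
.kscale <- function(config) 1e-3 / config$cm

#' Set up a tissue reaction-diffusion problem
#'
#' Assembles the finite-element operators, resolves the per-node phenotype
#' (IKs factor by transmural layer) and pre-builds the parabolic system
#' matrix for the configured time step.
#'
#' @param mesh an `lqt8_mesh`
#' @param mutation a [mutation_setting()]
#' @param het_setting `"HOM"`, `"HET1"` or `"HET2"`
#' @param sigma a [conductivity_set()]
#' @param config a [solver_config()]
#' @param base_cell_type TP06 base formulation shared by all layers
#' @param fem optional pre-assembled [assemble_fem()] result (reused across
#'   problems on the same mesh)
#' @return object of class `tissue_problem`
#' @export
tissue_problem <- function(mesh, mutation = mutation_setting(),
                           het_setting = c("HOM", "HET1", "HET2"),
                           sigma = conductivity_set(),
                           config = solver_config(),
                           base_cell_type = "epi",
                           fem = NULL) {
  het_setting <- match.arg(het_setting)
  if (is.null(fem)) fem <- assemble_fem(mesh, sigma)
  sc <- .kscale(config)
  Ki_s <- fem$Ki * sc
  Kie_s <- fem$Kie * sc
  Km_s <- fem$Km * sc
  Kpar <- if (config$model == "bidomain") Ki_s else Km_s
  A_par <- fem$M / config$tau + Kpar
  iks <- vapply(as.character(mesh$layer), iks_factor_for, numeric(1),
                het_setting = het_setting)
  structure(list(
    mesh = mesh, config = config, mutation = mutation,
    het_setting = het_setting, sigma = sigma,
    base_cell_type = base_cell_type,
    gates = .pack_gates(mutation),
    rho = mutation$rho,
    iks_factor = unname(iks),
    cell_type = c(epi = 0L, endo = 1L, M = 2L)[[base_cell_type]],
    fem = fem,
    M = as(fem$M, "CsparseMatrix"),
    Mlump = fem$Mlump,
    Ki_s = as(Ki_s, "CsparseMatrix"),
    Kie_s = as(Kie_s, "CsparseMatrix"),
    Km_s = as(Km_s, "CsparseMatrix"),
    A_par = as(A_par, "CsparseMatrix")
  ), class = "tissue_problem")
}

#' Initial tissue state
#'
#' @param problem a [tissue_problem()]
#' @param state0 optional single-cell state recycled over nodes
#' @return object of class `tissue_state`: state matrix (21 x n), `v`, `ue`,
#'   time `t`
#' @export
tissue_state <- function(problem, state0 = tp06_initial_state()) {
  n <- problem$mesh$n_nodes
  states <- matrix(rep(state0, n), nrow = length(state0),
                   dimnames = list(names(state0), NULL))
  structure(list(states = states, v = states[1, ], ue = numeric(n), t = 0),
            class = "tissue_state")
}

#' ODE stage of the operator splitting
#'
#' Advances gates (Rush-Larsen, membrane potential frozen at v^n) and ionic
#' concentrations of every node by one time step and returns the ionic
#' current evaluated at (v^n, w^{n+1}, c^{n+1}).
#'
#' @param problem a [tissue_problem()]
#' @param states 21 x n state matrix (not modified)
#' @param istim applied current per node (pA/pF), scalar or vector
#' @param tau time step (ms); defaults to the problem's
#' @return list with the updated `states` and the per-node current `iion`
#' @export
step_odes <- function(problem, states, istim = 0, tau = problem$config$tau) {
  states <- states + 0  # force a copy; the kernel updates in place
  iion <- .cells_step_cpp(states, problem$gates, problem$rho,
                          problem$iks_factor, problem$cell_type, tau,
                          as.numeric(istim))
  list(states = states, iion = iion)
}

#' Elliptic (extracellular) stage
#'
#' Solves \eqn{-\nabla\cdot(D_i + D_e)\nabla u_e = \nabla\cdot D_i \nabla v}
#' in weak form with insulated boundaries, fixing the zero-mean gauge with
#' mass-lumped weights.
#'
#' @inheritParams step_odes
#' @param v transmembrane potential per node (mV)
#' @param ue0 warm-start guess
#' @return extracellular potential `ue` (mV, zero mean)
#' @export
solve_elliptic <- function(problem, v, ue0 = NULL) {
  rhs <- as.numeric(-problem$Ki_s %*% v)
  if (is.null(ue0)) ue0 <- numeric(length(v))
  res <- .pcg_cpp(problem$Kie_s, rhs, ue0, problem$config$rtol_elliptic,
                  problem$config$maxit, TRUE, problem$Mlump)
  res$x
}

#' Parabolic (transmembrane) stage
#'
#' Solves the implicit diffusion step
#' \eqn{(M/\tau + K)\, v^{n+1} = M(v^n/\tau - i_{ion} + i_{app}) - K_i u_e}.
#'
#' @inheritParams solve_elliptic
#' @param iion ionic current per node (pA/pF) at (v^n, w^{n+1}, c^{n+1})
#' @param istim applied current per node (pA/pF)
#' @param ue extracellular potential (bidomain only)
#' @return updated transmembrane potential `v`
#' @export
solve_parabolic <- function(problem, v, iion, istim = 0, ue = NULL) {
  tau <- problem$config$tau
  work <- v / tau - iion + istim
  rhs <- as.numeric(problem$M %*% work)
  if (problem$config$model == "bidomain") {
    if (is.null(ue)) stop("bidomain parabolic step requires ue")
    rhs <- rhs - as.numeric(problem$Ki_s %*% ue)
  }
  res <- .pcg_cpp(problem$A_par, rhs, v, problem$config$rtol_parabolic,
                  problem$config$maxit, FALSE, numeric(0))
  res$x
}

#' Advance a tissue state in time
#'
#' Applies the double operator splitting per step, in order: ODE stage
#' (gates, concentrations), elliptic stage (bidomain only), parabolic stage.
#' The default engine runs the fused compiled loop; `engine = "r"` composes
#' the exported stage functions (useful for verification, slow).
#'
#' @param problem a [tissue_problem()]
#' @param state a [tissue_state()]
#' @param t_end duration to simulate (ms, relative to the state's clock)
#' @param stimuli list of stimuli, each a list with `nodes` (node indices),
#'   `onset` (ms, relative), `duration` (ms) and `amplitude` (mA/cm^3)
#' @param probes node indices whose potential traces are recorded
#' @param record_dt trace sampling interval (ms)
#' @param snapshot_dt if positive, full potential fields are stored at this
#'   cadence
#' @param engine `"cpp"` or `"r"`
#' @return list: updated `state`, `time`/`traces`, upstroke `events`
#'   (data frame node/time, relative ms), optional `snapshots`, CG iteration
#'   counts
#' @export
advance <- function(problem, state, t_end, stimuli = list(),
                    probes = integer(0), record_dt = 1,
                    snapshot_dt = 0, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  cfg <- problem$config
  stim_ptr <- c(0L, cumsum(vapply(stimuli, function(s) length(s$nodes), 1L)))
  stim_nodes <- as.integer(unlist(lapply(stimuli, `[[`, "nodes"))) - 1L
  stim_t0 <- vapply(stimuli, `[[`, 1, "onset")
  stim_dur <- vapply(stimuli, `[[`, 1, "duration")
  stim_amp <- vapply(stimuli, `[[`, 1, "amplitude") / cfg$cm
  if (engine == "cpp") {
    res <- .tissue_run_cpp(
      state$states, problem$gates, problem$rho, problem$iks_factor,
      rep(problem$cell_type, problem$mesh$n_nodes),
      problem$A_par, problem$M,
      if (cfg$model == "bidomain") problem$Ki_s else NULL,
      if (cfg$model == "bidomain") problem$Kie_s else NULL,
      cfg$model == "bidomain", cfg$tau, t_end,
      stim_ptr, stim_nodes, stim_t0, stim_dur, stim_amp,
      as.integer(probes) - 1L, record_dt, state$ue,
      cfg$rtol_parabolic, cfg$rtol_elliptic, cfg$maxit,
      cfg$event_threshold, cfg$event_slope, snapshot_dt)
    new_state <- structure(list(states = res$final_states,
                                v = res$final_states[1, ],
                                ue = res$ue, t = state$t + t_end),
                           class = "tissue_state")
    return(list(state = new_state, time = res$time, traces = res$traces,
                events = res$events, snapshots = res$snapshots,
                snapshot_times = res$snapshot_times,
                cg_iterations = res$cg_iterations))
  }
  # reference R engine
  states <- state$states + 0
  n <- ncol(states)
  v <- states[1, ]
  ue <- state$ue
  nstep <- round(t_end / cfg$tau)
  every <- max(1L, round(record_dt / cfg$tau))
  times <- traces <- NULL
  events <- data.frame(node = integer(0), time = numeric(0))
  above <- rep(FALSE, n)
  rec_t <- c(0); rec_v <- list(v[probes])
  for (s in seq_len(nstep)) {
    t <- (s - 1) * cfg$tau
    istim <- numeric(n)
    for (k in seq_along(stimuli)) {
      if (t >= stim_t0[k] && t < stim_t0[k] + stim_dur[k])
        istim[stimuli[[k]]$nodes] <- istim[stimuli[[k]]$nodes] + stim_amp[k]
    }
    od <- step_odes(problem, states, istim)
    states <- od$states
    if (cfg$model == "bidomain") ue <- solve_elliptic(problem, v, ue)
    vnew <- solve_parabolic(problem, v, od$iion, istim,
                            if (cfg$model == "bidomain") ue else NULL)
    up <- !above & vnew > cfg$event_threshold &
      (vnew - v) / cfg$tau > cfg$event_slope
    if (any(up))
      events <- rbind(events, data.frame(node = which(up), time = t + cfg$tau))
    above[up] <- TRUE
    above[above & vnew < cfg$event_threshold - 10] <- FALSE
    v <- vnew
    states[1, ] <- v
    if (s %% every == 0) {
      rec_t <- c(rec_t, s * cfg$tau)
      rec_v[[length(rec_v) + 1L]] <- v[probes]
    }
  }
  new_state <- structure(list(states = states, v = v, ue = ue,
                              t = state$t + t_end), class = "tissue_state")
  list(state = new_state, time = rec_t,
       traces = do.call(rbind, rec_v), events = events,
       snapshots = NULL, snapshot_times = NULL, cg_iterations = NULL)
}

#' @exportS3Method base::print
print.tissue_problem <- function(x, ...) {
  cat(sprintf("Tissue problem: %s, %d nodes, rho = %g, %s IKs heterogeneity\n",
              x$config$model, x$mesh$n_nodes, x$rho, x$het_setting))
  invisible(x)
}

#' @exportS3Method base::print
print.tissue_state <- function(x, ...) {
  cat(sprintf("Tissue state at t = %g ms: V in [%.1f, %.1f] mV\n",
              x$t, min(x$v), max(x$v)))
  invisible(x)
}
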