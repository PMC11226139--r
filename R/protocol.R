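#' Programmed ventricular stimulation plan
#'
#' The S1-S2-S3-S4 protocol: a train of `n_s1` pacing stimuli at basic cycle
#' length `bcl_s1`, then up to three extrastimuli whose coupling intervals
#' are decremented until an arrhythmia is induced or capture is lost. S2
#' starts 380 ms after the last S1; S3 (and S4) start 350 ms after the
#' previously accepted extrastimulus.
#'
#' @param n_s1 number of S1 stimuli
#' @param bcl_s1 S1 cycle length (ms)
#' @param s2_initial,s3_initial,s4_initial initial coupling intervals (ms)
#' @param decrement coupling-interval step (ms)
#' @param observation window after the last stimulus used for the
#'   sustained/nonsustained classification (ms)
#' @param attempt_window simulated window per search attempt (ms; defaults
#'   to `observation`, may be shortened for desk-scale runs)
#' @param capture_window time allowed for capture outside the stimulus
#'   footprint (ms)
#' @param block_window time allowed for the wavefront to reach the opposite
#'   surface before a conduction block is flagged (ms)
#' @param direct_window activations later than this after a stimulus count
#'   as re-activations (reentry) rather than the direct wave (ms)
#' @param sustained_tail reentry is sustained if re-activations persist into
#'   the final `sustained_tail` ms of the observation window
#' @param max_level deepest extrastimulus level searched (2 = S2 only,
#'   4 = full S2-S3-S4 protocol)
#' @return object of class `pvs_plan`
#' @export
pvs_plan <- function(n_s1 = 8, bcl_s1 = 500, s2_initial = 380,
                     s3_initial = 350, s4_initial = 350, decrement = 10,
                     observation = 4000, attempt_window = observation,
                     capture_window = 50, block_window = 150,
                     direct_window = 300, sustained_tail = 500,
                     max_level = 4) {
  stopifnot(decrement > 0, n_s1 >= 0, s2_initial > 0,
            max_level %in% 2:4)
  structure(list(n_s1 = n_s1, bcl_s1 = bcl_s1, s2_initial = s2_initial,
                 s3_initial = s3_initial, s4_initial = s4_initial,
                 decrement = decrement, observation = observation,
                 attempt_window = attempt_window,
                 capture_window = capture_window,
                 block_window = block_window,
                 direct_window = direct_window,
                 sustained_tail = sustained_tail, max_level = max_level),
            class = "pvs_plan")
}

#' Stimulation footprint on a mesh surface
#'
#' Selects the nodes of a box-shaped stimulation footprint (default
#' 0.12 x 0.12 x 0.06 cm^3) on the endocardial or epicardial surface, at a
#' central location equidistant from apex and base.
#'
#' @param mesh an `lqt8_mesh`
#' @param site `"endocardial"` or `"epicardial"`
#' @param size footprint edge lengths (cm): circumferential, apex-base,
#'   transmural depth
#' @return integer node indices
#' @export
stimulus_footprint <- function(mesh, site = c("endocardial", "epicardial"),
                               size = c(0.12, 0.12, 0.06)) {
  site <- match.arg(site)
  g <- mesh$grid
  if (mesh$type == "ellipsoid") {
    spec <- mesh$spec
    phi_c <- mean(spec$phi_range)
    theta_c <- mean(spec$theta_range)
    r_mid <- (spec$a1 + spec$a2) / 2
    c_mid <- (spec$c1 + spec$c2) / 2
    dphi <- size[1] / r_mid / 2
    dtheta <- size[2] / c_mid / 2
    depth <- size[3]
    rsel <- if (site == "endocardial") mesh$r <= depth / (spec$a2 - spec$a1) + 1e-9
            else mesh$r >= 1 - depth / (spec$a2 - spec$a1) - 1e-9
    np <- length(g$phi); nt <- length(g$theta); nr <- length(g$r)
    full <- expand.grid(i = seq_len(np), j = seq_len(nt), k = seq_len(nr))
    sel <- which(abs(g$phi[full$i] - phi_c) <= dphi &
                 abs(g$theta[full$j] - theta_c) <= dtheta & rsel)
  } else if (mesh$type == "slab") {
    xc <- mean(range(g$x)); yc <- mean(range(g$y))
    zmax <- max(g$z)
    np <- length(g$x); nt <- length(g$y); nr <- length(g$z)
    full <- expand.grid(i = seq_len(np), j = seq_len(nt), k = seq_len(nr))
    zsel <- if (site == "endocardial") g$z[full$k] <= size[3] + 1e-9
            else g$z[full$k] >= zmax - size[3] - 1e-9
    sel <- which(abs(g$x[full$i] - xc) <= size[1] / 2 + 1e-9 &
                 abs(g$y[full$j] - yc) <= size[2] / 2 + 1e-9 & zsel)
  } else stop("unsupported mesh type")
  if (!length(sel)) stop("empty stimulus footprint; refine the mesh")
  sel
}

#' Simulation backend for the stimulation protocol
#'
#' Wraps either a 1D cable or a 3D tissue problem behind the uniform
#' interface the protocol engine uses: an initial state, an `advance`
#' closure, the stimulated footprint and the two surfaces used for
#' conduction-block detection.
#'
#' @param x a [build_cable()] or [tissue_problem()] object
#' @param ... backend-specific arguments
#' @return object of class `pvs_sim`
#' @export
pvs_sim <- function(x, ...) UseMethod("pvs_sim")

#' @rdname pvs_sim
#' @param mutation,iks_factor,base_cell_type,tau,cm cable phenotype and
#'   integration parameters (see [cable_advance()])
#' @param stim_nodes stimulated nodes (default: first three)
#' @param stim_amplitude,stim_duration stimulus pulse (mA/cm^3, ms)
#' @export
pvs_sim.lqt8_cable <- function(x, mutation = mutation_setting(),
                               iks_factor = 1, base_cell_type = "epi",
                               tau = 0.05, cm = 1, stim_nodes = 1:3,
                               stim_amplitude = 350, stim_duration = 1, ...) {
  n <- x$n_nodes
  init <- function() {
    list(states = matrix(rep(tp06_initial_state(), n), nrow = 21), t = 0)
  }
  adv <- function(state, t_end, stim_onsets) {
    res <- cable_advance(x, state$states, mutation, iks_factor,
                         t_end = t_end, stim_onsets = stim_onsets,
                         stim_duration = stim_duration,
                         stim_amplitude = stim_amplitude,
                         stim_nodes = stim_nodes, probes = integer(0),
                         tau = tau, cm = cm,
                         base_cell_type = base_cell_type)
    list(state = list(states = res$final_states, t = state$t + t_end),
         events = res$events)
  }
  far <- if (min(stim_nodes) <= n / 2) (n - 2):n else 1:3
  near <- setdiff(.neighbourhood_1d(stim_nodes, n, 5L), stim_nodes)
  # established propagation: at least 0.3 cm beyond the footprint (marginal
  # capture failures at the refractory limit die within ~0.2 cm)
  dist_nodes <- ceiling(0.3 / x$h)
  progress <- which(vapply(seq_len(n), function(i)
    min(abs(i - as.numeric(stim_nodes))), numeric(1)) >= dist_nodes)
  structure(list(initial_state = init, advance = adv,
                 footprint = stim_nodes, capture_set = near,
                 progress_set = progress, far_surface = far, n_nodes = n),
            class = "pvs_sim")
}

.neighbourhood_1d <- function(nodes, n, width) {
  out <- unique(unlist(lapply(nodes, function(i)
    max(1L, i - width):min(n, i + width))))
  sort(out)
}

#' @rdname pvs_sim
#' @param site stimulation surface for tissue problems
#' @export
pvs_sim.tissue_problem <- function(x, site = c("endocardial", "epicardial"),
                                   stim_amplitude = 350, stim_duration = 1,
                                   footprint_size = c(0.12, 0.12, 0.06),
                                   ...) {
  site <- match.arg(site)
  fp <- stimulus_footprint(x$mesh, site, footprint_size)
  far <- if (site == "endocardial") x$mesh$surfaces$epi else
    x$mesh$surfaces$endo
  # capture ring: nodes just outside the footprint (within 0.1 cm, widened
  # to the local node spacing on coarse meshes)
  ctr <- colMeans(x$mesh$coords[fp, , drop = FALSE])
  d2 <- rowSums((x$mesh$coords - rep(ctr, each = nrow(x$mesh$coords)))^2)
  r_fp <- sqrt(max(rowSums(
    (x$mesh$coords[fp, , drop = FALSE] -
       rep(ctr, each = length(fp)))^2)))
  ring <- max(0.1, 1.5 * max(x$mesh$h))
  near <- setdiff(which(d2 <= (r_fp + ring)^2), fp)
  if (!length(near))
    near <- setdiff(order(d2)[seq_len(min(6L, length(d2)))], fp)
  progress <- which(x$mesh$layer == "MID")
  init <- function() tissue_state(x)
  adv <- function(state, t_end, stim_onsets) {
    stimuli <- lapply(stim_onsets, function(t0)
      list(nodes = fp, onset = t0, duration = stim_duration,
           amplitude = stim_amplitude))
    res <- advance(x, state, t_end, stimuli)
    list(state = res$state, events = res$events)
  }
  structure(list(initial_state = init, advance = adv,
                 footprint = fp, capture_set = near, progress_set = progress,
                 far_surface = far, n_nodes = x$mesh$n_nodes),
            class = "pvs_sim")
}

#' Deliver the S1 pacing train
#'
#' Applies `n_s1` stimuli at the plan's basic cycle length, verifying
#' capture after every beat. Returns the state immediately before the final
#' S1 stimulus (the reference time for the S2 coupling interval) or, for
#' `n_s1 = 0`, the input state unchanged.
#'
#' @param sim a [pvs_sim()] backend
#' @param plan a [pvs_plan()]
#' @param state optional starting state (defaults to the backend's initial
#'   state)
#' @return list: `state` (before the last S1), `capture` logical vector per
#'   beat
#' @export
run_pacing <- function(sim, plan = pvs_plan(), state = NULL) {
  if (is.null(state)) state <- sim$initial_state()
  if (plan$n_s1 == 0) return(list(state = state, capture = logical(0)))
  capture <- logical(plan$n_s1 - 1)
  if (plan$n_s1 > 1) {
    for (b in seq_len(plan$n_s1 - 1)) {
      res <- sim$advance(state, plan$bcl_s1, 0)
      capture[b] <- .captured(res$events, sim$capture_set, plan$capture_window)
      if (!capture[b])
        stop("S1 stimulus ", b, " failed to capture")
      state <- res$state
    }
  }
  list(state = state, capture = capture)
}

.captured <- function(events, capture_set, window) {
  any(events$time <= window & events$node %in% capture_set)
}

# intramural conduction block: the wavefront reaches the mid-wall progress
# set but never the opposite surface within the window (excludes marginal
# near-field capture failures in homogeneous media)
.blocked <- function(events, progress_set, far_surface, window) {
  any(events$node %in% progress_set & events$time <= window) &&
    !any(events$node %in% far_surface & events$time <= window)
}

#' Classify a single stimulation attempt
#'
#' Applies the protocol's three detectors to the upstroke-event log of one
#' attempt (time 0 = stimulus onset): capture (a new upstroke in the ring
#' just outside the footprint within the capture window), intramural
#' conduction block (the wavefront reaches the mid-wall progress set but not
#' the opposite surface within the block window), and reentry
#' ([classify_reentry()]).
#'
#' @param events data frame `node`, `time` from the attempt
#' @param sim the [pvs_sim()] backend that produced the events
#' @param plan a [pvs_plan()]
#' @param window observation window used for the reentry classification
#'   (defaults to the plan's attempt window)
#' @return list with `captured`, `block`, `reentry`
#' @export
classify_attempt <- function(events, sim, plan = pvs_plan(),
                             window = plan$attempt_window) {
  captured <- .captured(events, sim$capture_set, plan$capture_window)
  block <- captured &&
    .blocked(events, sim$progress_set, sim$far_surface, plan$block_window)
  reentry <- if (captured)
    classify_reentry(events, window, plan$direct_window, plan$sustained_tail)
  else "none"
  list(captured = captured, block = block, reentry = reentry)
}

#' Classify reentry from an activation-event log
#'
#' Given upstroke events recorded after a stimulus (time 0 = stimulus
#' onset), activations later than `direct_window` are re-activations
#' (reentrant excitation). The outcome is `"none"` if there are none,
#' `"sustained"` if re-activations persist into the final `sustained_tail`
#' ms of the observation window, `"nonsustained"` otherwise.
#'
#' @param events data frame with columns `node`, `time` (ms after stimulus)
#' @param window length of the observation window (ms)
#' @param direct_window,sustained_tail see [pvs_plan()]
#' @return `"none"`, `"nonsustained"` or `"sustained"`
#' @export
classify_reentry <- function(events, window, direct_window = 300,
                             sustained_tail = 500) {
  re <- events$time[events$time > direct_window]
  if (!length(re)) return("none")
  if (max(re) >= window - sustained_tail) "sustained" else "nonsustained"
}

#' S2-S3-S4 extrastimulus search
#'
#' Starting from a paced state, decrements each extrastimulus coupling
#' interval from its initial value until an arrhythmia (reentrant
#' re-activation) is induced or the stimulus fails to capture; each accepted
#' extrastimulus is then fixed and the next one searched. Every attempt
#' restarts from a checkpoint of the accepted previous stimulus, so the
#' search is deterministic and repeatable.
#'
#' @param sim a [pvs_sim()] backend
#' @param paced output of [run_pacing()] (state before the last S1)
#' @param plan a [pvs_plan()]
#' @return object of class `protocol_outcome`: attempt log (`attempts`),
#'   final `classification`, accepted coupling intervals, and the event log
#'   of the inducing attempt (if any)
#' @export
pvs_search <- function(sim, paced, plan = pvs_plan()) {
  attempts <- list()
  couplings <- c(S2 = NA_real_, S3 = NA_real_, S4 = NA_real_)
  classification <- "none"
  inducing_events <- NULL

  # checkpoint: state immediately before the previous accepted stimulus
  checkpoint <- paced$state
  initials <- c(S2 = plan$s2_initial, S3 = plan$s3_initial,
                S4 = plan$s4_initial)
  for (level in c("S2", "S3", "S4")[seq_len(plan$max_level - 1L)]) {
    ci <- initials[[level]]
    accepted_state <- NULL
    accepted_ci <- NA_real_
    repeat {
      # previous stimulus at t=0, candidate extrastimulus at t=ci
      pre <- sim$advance(checkpoint, ci, 0)
      att <- sim$advance(pre$state, plan$attempt_window, 0)
      verdict <- classify_attempt(att$events, sim, plan)
      captured <- verdict$captured
      cls <- verdict$reentry
      attempts[[length(attempts) + 1L]] <- data.frame(
        level = level, coupling = ci, captured = captured,
        block = verdict$block, reentry = cls)
      if (captured && cls != "none") {
        classification <- cls
        couplings[[level]] <- ci
        inducing_events <- att$events
        out <- structure(list(attempts = do.call(rbind, attempts),
                              classification = classification,
                              couplings = couplings,
                              inducing_events = inducing_events,
                              plan = plan),
                         class = "protocol_outcome")
        return(out)
      }
      if (!captured) break
      accepted_state <- pre$state
      accepted_ci <- ci
      ci <- ci - plan$decrement
      if (ci <= 0) break
    }
    if (is.null(accepted_state)) break  # this level never captured
    couplings[[level]] <- accepted_ci
    checkpoint <- accepted_state
  }
  structure(list(attempts = do.call(rbind, attempts),
                 classification = classification, couplings = couplings,
                 inducing_events = inducing_events, plan = plan),
            class = "protocol_outcome")
}

#' @exportS3Method base::print
print.protocol_outcome <- function(x, ...) {
  cat(sprintf("PVS outcome: %s (%d attempts)\n", x$classification,
              nrow(x$attempts)))
  cat("  couplings:",
      paste(names(x$couplings), x$couplings, sep = "=", collapse = " "),
      "\n")
  if (any(x$attempts$block))
    cat("  conduction block observed at couplings:",
        paste(x$attempts$coupling[x$attempts$block], collapse = ", "), "\n")
  invisible(x)
}
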