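#' Published reference action potential durations
#'
#' The study's reference APD values (ms) of WT, TS-11% and TS-50% endo-,
#' mid- and epicardial cells at BCL = 1000 ms for the two transmural
#' heterogeneity settings, with the reported EAD occurrences
#' (TS-50%-HET1 midmyocardial and TS-50%-HET2 sub-endocardial cells).
#'
#' @return data frame: `setting`, `het_setting`, `rho`, `layer`,
#'   `iks_factor`, `apd_ref`, `ead_ref`
#' @export
lqt8_reference_apd <- function() {
  ref <- rbind(
    data.frame(setting = "WT-HET1",     rho = 0,    het = "HET1",
               layer = c("ENDO", "MID", "EPI"), apd_ref = c(266, 334, 261)),
    data.frame(setting = "TS-11%-HET1", rho = 0.11, het = "HET1",
               layer = c("ENDO", "MID", "EPI"), apd_ref = c(282, 367, 276)),
    data.frame(setting = "TS-50%-HET1", rho = 0.5,  het = "HET1",
               layer = c("ENDO", "MID", "EPI"), apd_ref = c(336, 596, 328)),
    data.frame(setting = "WT-HET2",     rho = 0,    het = "HET2",
               layer = c("ENDO", "MID", "EPI"), apd_ref = c(310, 278, 261)),
    data.frame(setting = "TS-11%-HET2", rho = 0.11, het = "HET2",
               layer = c("ENDO", "MID", "EPI"), apd_ref = c(336, 296, 276)),
    data.frame(setting = "TS-50%-HET2", rho = 0.5,  het = "HET2",
               layer = c("ENDO", "MID", "EPI"), apd_ref = c(535, 355, 328)))
  names(ref)[names(ref) == "het"] <- "het_setting"
  ref$iks_factor <- mapply(iks_factor_for, ref$layer, ref$het_setting)
  ref$ead_ref <- (ref$setting == "TS-50%-HET1" & ref$layer == "MID") |
    (ref$setting == "TS-50%-HET2" & ref$layer == "ENDO")
  ref
}

#' APD report over all phenotype-setting combinations
#'
#' Paces a single-phenotype preparation for every combination of mutation
#' level (WT, TS-11%, TS-50%), heterogeneity setting (HET1, HET2) and
#' transmural layer, measures the last-beat APD by the max-slope/min-slope
#' markers, flags EADs, and reports deltas against the published reference
#' values.
#'
#' @param scale `"cable1d"` (paced 1D cable, the reference protocol) or
#'   `"cell0d"` (space-clamped)
#' @param bcl pacing cycle length (ms)
#' @param n_beats conditioning beats (quasi-steady state)
#' @param cable cable geometry for `"cable1d"`
#' @param tau time step (ms)
#' @param ts_floor non-inactivating fraction of the mutant channels (model
#'   extension; 0 = plain sigmoid inactivation)
#' @param base_cell_type TP06 base formulation
#' @return data frame of class `table1_report` with measured `apd`, `ead`,
#'   reference values and relative deltas
#' @export
run_table1 <- function(scale = c("cable1d", "cell0d"), bcl = 1000,
                       n_beats = 8, cable = build_cable(), tau = 0.05,
                       ts_floor = 0, base_cell_type = "epi") {
  scale <- match.arg(scale)
  ref <- lqt8_reference_apd()
  cache <- new.env(parent = emptyenv())
  measure <- function(rho, iksf) {
    key <- sprintf("%g_%g", rho, iksf)
    if (!is.null(cache[[key]])) return(cache[[key]])
    mut <- mutation_setting(rho, ts_params = gate_params_ts(ts_floor))
    tr <- if (scale == "cable1d") {
      run_cable_pacing(cable, mut, iksf, bcl = bcl, n_beats = n_beats,
                       tau = tau, base_cell_type = base_cell_type)
    } else {
      phen <- cell_phenotype("ENDO", "HOM", base_cell_type)
      phen$iks_factor <- iksf
      run_single_cell(phen, mut, bcl = bcl, n_beats = n_beats, tau = tau)
    }
    out <- list(apd = tr$markers$apd, ead = tr$markers$ead,
                captured = tr$captured)
    cache[[key]] <- out
    out
  }
  ref$apd <- NA_real_; ref$ead <- NA; ref$captured <- NA
  for (i in seq_len(nrow(ref))) {
    m <- measure(ref$rho[i], ref$iks_factor[i])
    ref$apd[i] <- m$apd; ref$ead[i] <- m$ead; ref$captured[i] <- m$captured
  }
  ref$delta_pct <- 100 * (ref$apd - ref$apd_ref) / ref$apd_ref
  class(ref) <- c("table1_report", class(ref))
  attr(ref, "scale") <- scale
  ref
}

#' @exportS3Method base::print
print.table1_report <- function(x, ...) {
  cat(sprintf("APD report (%s, ms):\n", attr(x, "scale")))
  df <- as.data.frame(x)
  df$apd <- round(df$apd, 1)
  df$delta_pct <- sprintf("%+.1f%%", df$delta_pct)
  print(df[, c("setting", "layer", "iks_factor", "apd", "apd_ref",
               "delta_pct", "ead", "ead_ref")], row.names = FALSE)
  invisible(x)
}

#' Full programmed-stimulation pipeline on a tissue problem
#'
#' Runs the S1 pacing train, records the last paced beat on the needle
#' array, computes the dispersion summary, then performs the S2-S3-S4
#' extrastimulus search and classifies the outcome.
#'
#' @param problem a [tissue_problem()]
#' @param plan a [pvs_plan()]
#' @param site stimulation surface (`"endocardial"` for HOM/HET1,
#'   `"epicardial"` for HET2)
#' @param needles a [needle_array()] (defaults to a layout scaled to the
#'   mesh)
#' @param marker_window recording window for the post-S1 markers (ms)
#' @return list: `outcome` ([pvs_search()] result), `dispersion`
#'   ([dispersion_summary()]), `markers`, the paced state
#' @export
run_pvs <- function(problem, plan = pvs_plan(),
                    site = c("endocardial", "epicardial"),
                    needles = NULL, marker_window = plan$bcl_s1) {
  site <- match.arg(site)
  sim <- pvs_sim(problem, site = site)
  paced <- run_pacing(sim, plan)
  dispersion <- markers <- NULL
  if (problem$mesh$type == "ellipsoid") {
    if (is.null(needles)) needles <- needle_array(problem$mesh)
    fp <- sim$footprint
    rec <- advance(problem, paced$state, marker_window,
                   stimuli = list(list(nodes = fp, onset = 0, duration = 1,
                                       amplitude = 350)),
                   probes = needles$node, record_dt = 1)
    markers <- tissue_markers(rec$time, rec$traces, needles)
    dispersion <- dispersion_summary(markers)
  }
  outcome <- pvs_search(sim, paced, plan)
  list(outcome = outcome, dispersion = dispersion, markers = markers,
       paced_state = paced$state)
}
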