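#' ICaL gating-curve parameters
#'
#' Midpoints and slopes of the steady-state activation (`d_inf`) and
#' voltage-dependent inactivation (`f_inf`) curves of an L-type calcium
#' channel variant:
#' \deqn{d_\infty(V) = 1/(1 + e^{(V_{a05} - V)/S_a}), \qquad
#'       f_\infty(V) = (1-\phi)/(1 + e^{(V - V_{ina05})/S_{ina}}) + \phi}
#' where \eqn{\phi} (`ts_floor`) is an optional non-inactivating fraction
#' (0 by default, giving a plain sigmoid).
#'
#' @param va05 activation half-open voltage (mV)
#' @param sa activation slope factor (mV, positive)
#' @param vina05 inactivation half-open voltage (mV)
#' @param sina inactivation slope factor (mV, positive)
#' @param ts_floor non-inactivating channel fraction in \[0, 1); relevant for
#'   mutant channels with incomplete voltage-dependent inactivation
#' @return an object of class `gate_params`
#' @seealso [gate_params_wt()], [gate_params_ts()], [gate_params_tp06()]
#' @export
gate_params <- function(va05, sa, vina05, sina, ts_floor = 0) {
  stopifnot(sa > 0, sina > 0, ts_floor >= 0, ts_floor < 1)
  structure(list(va05 = va05, sa = sa, vina05 = vina05, sina = sina,
                 ts_floor = ts_floor),
            class = "gate_params")
}

#' @rdname gate_params
#' @details `gate_params_wt()` returns the wild-type calibration used in this
#'   study (activation midpoint -4 mV), `gate_params_ts()` the G406R mutant
#'   calibration (activation left-shifted to -8 mV, inactivation right-shifted
#'   to 0 mV and flattened to slope 12), and `gate_params_tp06()` the original
#'   TP06 curves (activation midpoint -8 mV); with `gate_params_tp06()` and
#'   heterozygosis 0 the mixed current degenerates to the unmodified TP06
#'   ICaL.
#' @export
gate_params_wt <- function() gate_params(-4.0, 7.5, -20.0, 7.0)

#' @rdname gate_params
#' @export
gate_params_ts <- function(ts_floor = 0) gate_params(-8.0, 7.5, 0.0, 12.0,
                                                     ts_floor = ts_floor)

#' @rdname gate_params
#' @export
gate_params_tp06 <- function() gate_params(-8.0, 7.5, -20.0, 7.0)

#' G406R heterozygosis setting for the ICaL mixture
#'
#' Describes the mixed L-type calcium current
#' \deqn{I_{CaL} = (1-\rho)\, I_{CaL}^{WT} + \rho\, I_{CaL}^{TS}}
#' where `rho` is the fraction of channels carrying the G406R mutation.
#' `rho = 0.11` corresponds to the TS-11% setting (mutant exon-8A protein
#' only) and `rho = 0.5` to TS-50% (mutant exon-8 and exon-8A protein).
#'
#' @param rho heterozygosis fraction in \[0, 1\]
#' @param wt_params,ts_params [gate_params()] of the wild-type and mutant
#'   channels
#' @return an object of class `mutation_setting`
#' @export
mutation_setting <- function(rho = 0,
                             wt_params = gate_params_wt(),
                             ts_params = gate_params_ts()) {
  stopifnot(is.numeric(rho), length(rho) == 1L, rho >= 0, rho <= 1,
            inherits(wt_params, "gate_params"),
            inherits(ts_params, "gate_params"))
  structure(list(rho = rho, wt_params = wt_params, ts_params = ts_params),
            class = "mutation_setting")
}

#' Transmural cell phenotype
#'
#' A ventricular cell is characterised by its transmural layer and the IKs
#' scaling factor of its heterogeneity setting:
#' * `HET1`: IKs of ENDO/MID/EPI cells multiplied by 1.3 / 0.5 / 1.4
#'   (midmyocardial M cells have the longest action potential);
#' * `HET2`: factors 0.7 / 1.1 / 1.4 (sub-endocardial cells longest);
#' * `HOM`: every cell carries the ENDO calibration with factor 1.3.
#'
#' All layers share a common TP06 base formulation (`base_cell_type`,
#' epicardial by default); layers differ only through the IKs factor.
#'
#' @param layer one of `"ENDO"`, `"MID"`, `"EPI"`
#' @param het_setting one of `"HOM"`, `"HET1"`, `"HET2"`
#' @param base_cell_type TP06 base formulation: `"epi"`, `"endo"` or `"M"`
#' @return an object of class `cell_phenotype` with the resolved `iks_factor`
#' @export
cell_phenotype <- function(layer = c("ENDO", "MID", "EPI"),
                           het_setting = c("HOM", "HET1", "HET2"),
                           base_cell_type = c("epi", "endo", "M")) {
  layer <- match.arg(layer)
  het_setting <- match.arg(het_setting)
  base_cell_type <- match.arg(base_cell_type)
  structure(list(layer = layer, het_setting = het_setting,
                 iks_factor = iks_factor_for(layer, het_setting),
                 base_cell_type = base_cell_type),
            class = "cell_phenotype")
}

#' IKs scaling factor of a transmural layer
#'
#' @inheritParams cell_phenotype
#' @return scalar multiplier applied to the TP06 IKs conductance
#' @export
iks_factor_for <- function(layer, het_setting) {
  factors <- list(
    HOM  = c(ENDO = 1.3, MID = 1.3, EPI = 1.3),
    HET1 = c(ENDO = 1.3, MID = 0.5, EPI = 1.4),
    HET2 = c(ENDO = 0.7, MID = 1.1, EPI = 1.4)
  )
  unname(factors[[het_setting]][layer])
}

#' The nine simulation settings
#'
#' Returns the nine named settings of the study: wild type and two
#' heterozygosis levels, each homogeneous or with one of the two transmural
#' heterogeneity patterns.
#'
#' @return named list; each element carries `rho` and `het_setting`
#' @export
lqt8_presets <- function() {
  rhos <- c(`WT` = 0, `TS-11%` = 0.11, `TS-50%` = 0.5)
  hets <- c("HOM", "HET1", "HET2")
  out <- list()
  for (h in hets) {
    for (m in names(rhos)) {
      nm <- paste0(m, "-", h)
      out[[nm]] <- list(name = nm, rho = unname(rhos[[m]]), het_setting = h)
    }
  }
  out
}

#' Resolve a preset name like "TS-50%-HET1"
#'
#' @param name one of the nine setting names from [lqt8_presets()]
#' @return the matching preset entry
#' @export
lqt8_preset <- function(name) {
  p <- lqt8_presets()
  if (!name %in% names(p))
    stop("unknown preset '", name, "'; available: ",
         paste(names(p), collapse = ", "))
  p[[name]]
}

# pack cell parameters into the flat numeric layout the C++ kernels expect:
# c(rho, wt gates (4), ts gates (4), iks_factor, cell_type_code, ts_floor)
.pack_params <- function(mut, iks_factor, base_cell_type = "epi") {
  ct <- c(epi = 0, endo = 1, M = 2)[[base_cell_type]]
  c(mut$rho,
    mut$wt_params$va05, mut$wt_params$sa,
    mut$wt_params$vina05, mut$wt_params$sina,
    mut$ts_params$va05, mut$ts_params$sa,
    mut$ts_params$vina05, mut$ts_params$sina,
    iks_factor, ct, mut$ts_params$ts_floor)
}

# flat 9-entry gate vector for the cable/tissue kernels
.pack_gates <- function(mut) {
  c(mut$wt_params$va05, mut$wt_params$sa,
    mut$wt_params$vina05, mut$wt_params$sina,
    mut$ts_params$va05, mut$ts_params$sa,
    mut$ts_params$vina05, mut$ts_params$sina,
    mut$ts_params$ts_floor)
}

#' @exportS3Method base::print
print.gate_params <- function(x, ...) {
  cat(sprintf(
    "ICaL gate parameters: d_inf(V1/2 = %g mV, slope %g), f_inf(V1/2 = %g mV, slope %g)%s\n",
    x$va05, x$sa, x$vina05, x$sina,
    if (x$ts_floor > 0) sprintf(", non-inactivating fraction %g", x$ts_floor)
    else ""))
  invisible(x)
}

#' @exportS3Method base::print
print.mutation_setting <- function(x, ...) {
  cat(sprintf("G406R mixture: rho = %g\n", x$rho))
  cat("  WT: "); print(x$wt_params)
  cat("  TS: "); print(x$ts_params)
  invisible(x)
}

#' @exportS3Method base::print
print.cell_phenotype <- function(x, ...) {
  cat(sprintf("%s cell, %s setting (IKs factor %g, TP06 %s base)\n",
              x$layer, x$het_setting, x$iks_factor, x$base_cell_type))
  invisible(x)
}
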