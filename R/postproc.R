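#' Activation time of a transmembrane-potential trace
#'
#' The activation marker (ACTI) is the instant of maximal slope during the
#' depolarization phase, located by central differences on the stored
#' sampling grid. A trace that never crosses `threshold` has no upstroke and
#' yields `NA` (missing marker).
#'
#' @param time sample times (ms), uniformly spaced
#' @param v membrane potential samples (mV)
#' @param threshold upstroke detection level (mV)
#' @return ACTI in ms, or `NA_real_` if the trace has no upstroke
#' @export
activation_time <- function(time, v, threshold = -20) {
  stopifnot(length(time) == length(v), length(v) >= 3)
  if (max(v) <= threshold) return(NA_real_)
  dv <- .central_diff(time, v)
  ipk <- which.max(v)
  win <- seq_len(max(ipk - 1L, 2L))  # up to the global maximum
  i <- win[which.max(dv[win])]
  time[i]
}

#' Repolarization time of a transmembrane-potential trace
#'
#' The repolarization marker (REPO) is the instant of minimal slope during
#' the final repolarization phase. For traces bearing early
#' afterdepolarizations the search window opens after the last local voltage
#' maximum above `ead_level`, so the marker lands on terminal repolarization
#' rather than on the EAD downslope. A trace that does not repolarize below
#' `complete_level` within the window yields `NA`.
#'
#' @inheritParams activation_time
#' @param ead_level level (mV) above which a local maximum counts as a hump
#' @param complete_level level (mV) the trace must reach for repolarization
#'   to be considered complete
#' @return REPO in ms, or `NA_real_`
#' @export
repolarization_time <- function(time, v, ead_level = -40,
                                complete_level = -70) {
  stopifnot(length(time) == length(v), length(v) >= 3)
  n <- length(v)
  maxima <- .local_maxima(v)
  maxima <- maxima[v[maxima] > ead_level]
  start <- if (length(maxima)) max(maxima) else 1L
  if (min(v[start:n]) > complete_level) return(NA_real_)
  dv <- .central_diff(time, v)
  win <- seq.int(max(start, 2L), n - 1L)
  i <- win[which.min(dv[win])]
  time[i]
}

#' Activation, repolarization and APD markers of one beat
#'
#' Convenience wrapper computing ACTI, REPO, APD = REPO - ACTI and an early
#' afterdepolarization flag for a single-beat window.
#'
#' @inheritParams repolarization_time
#' @return list with `acti`, `repo`, `apd` (ms; `NA` when missing) and
#'   logical `ead`
#' @export
trace_markers <- function(time, v, threshold = -20, ead_level = -40,
                          complete_level = -70) {
  acti <- activation_time(time, v, threshold)
  repo <- repolarization_time(time, v, ead_level, complete_level)
  list(acti = acti, repo = repo, apd = repo - acti,
       ead = detect_ead(time, v, acti, ead_level = ead_level))
}

#' Early-afterdepolarization detection
#'
#' Flags a secondary depolarization before terminal repolarization: a local
#' voltage minimum followed by a local maximum, with the minimum occurring at
#' least `notch_exclusion` ms after activation (excluding the physiological
#' spike-notch-dome complex) and a rise of at least `min_rise` mV.
#'
#' @inheritParams activation_time
#' @param acti activation time (ms); computed from the trace if `NULL`
#' @param ead_level the secondary maximum must exceed this level (mV)
#' @param notch_exclusion dead time after activation (ms)
#' @param min_rise minimal amplitude of the secondary rise (mV)
#' @return logical
#' @export
detect_ead <- function(time, v, acti = NULL, ead_level = -40,
                       notch_exclusion = 50, min_rise = 2) {
  if (is.null(acti)) acti <- activation_time(time, v)
  if (!is.finite(acti)) return(FALSE)
  minima <- .local_minima(v)
  maxima <- .local_maxima(v)
  for (im in minima) {
    if (time[im] <= acti + notch_exclusion) next
    nxt <- maxima[maxima > im]
    if (!length(nxt)) next
    iM <- nxt[1]
    if (v[iM] > ead_level && v[iM] - v[im] >= min_rise) return(TRUE)
  }
  FALSE
}

.central_diff <- function(time, v) {
  n <- length(v)
  dv <- rep(NA_real_, n)
  dv[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (time[3:n] - time[1:(n - 2)])
  dv[1] <- dv[2]; dv[n] <- dv[n - 1]
  dv
}

.local_maxima <- function(v) which(diff(sign(diff(v))) < 0) + 1L
.local_minima <- function(v) which(diff(sign(diff(v))) > 0) + 1L

#' Virtual transmural needle-electrode array
#'
#' Places a matrix of `n_phi x n_theta` exploring needles over the
#' left-ventricular mesh, each carrying `n_sites` recording sites equally
#' spaced along the transmural epi-to-endocardial direction (site 1 on the
#' epicardium). The default 64 x 33 x 7 layout gives 14784 recording sites.
#'
#' @param mesh an ellipsoid mesh from [build_ellipsoid_mesh()]
#' @param n_phi needles around the circumference (equispaced in phi)
#' @param n_theta needles in the apex-base direction (equispaced in theta)
#' @param n_sites recording sites per needle (equispaced in r, both surfaces
#'   included)
#' @return data frame with columns `needle`, `site`, `node`, `phi`, `theta`,
#'   `r`; class `needle_array`
#' @export
needle_array <- function(mesh, n_phi = 64, n_theta = 33, n_sites = 7) {
  stopifnot(inherits(mesh, "lqt8_mesh"), mesh$type == "ellipsoid")
  g <- mesh$grid
  span_phi <- if (mesh$periodic) diff(mesh$spec$phi_range) else
    diff(range(g$phi))
  phis <- mesh$spec$phi_range[1] + (seq_len(n_phi) - 1) * span_phi / n_phi
  thetas <- seq(min(g$theta), max(g$theta), length.out = n_theta)
  rs <- seq(1, 0, length.out = n_sites)  # epi (r=1) to endo (r=0)
  ip <- vapply(phis, function(p) which.min(abs(g$phi - p)), 1L)
  it <- vapply(thetas, function(p) which.min(abs(g$theta - p)), 1L)
  ir <- vapply(rs, function(p) which.min(abs(g$r - p)), 1L)
  needles <- expand.grid(ip = seq_len(n_phi), it = seq_len(n_theta))
  out <- do.call(rbind, lapply(seq_len(nrow(needles)), function(k) {
    data.frame(needle = k, site = seq_len(n_sites),
               node = mesh$node_index(ip[needles$ip[k]], it[needles$it[k]], ir),
               phi = g$phi[ip[needles$ip[k]]],
               theta = g$theta[it[needles$it[k]]],
               r = g$r[ir])
  }))
  class(out) <- c("needle_array", class(out))
  out
}

#' Dispersion statistics of activation/repolarization markers
#'
#' Computes the five dispersion measures over a marker table:
#' \itemize{
#' \item `dAT_tot`, `dRT_tot`, `dAPD_tot`: max - min of ACTI, REPO and APD
#'   over all recording sites;
#' \item `dRT_trans`, `dAPD_trans`: mean (and SD) over needles of the
#'   per-needle max - min of REPO and APD.
#' }
#' Missing markers are excluded, with their count reported.
#'
#' @param markers data frame with columns `needle`, `acti`, `repo`, `apd`
#'   (one row per recording site), e.g. from [tissue_markers()] or
#'   [make_marker_field()]
#' @return object of class `dispersion_summary`
#' @export
dispersion_summary <- function(markers) {
  stopifnot(all(c("needle", "acti", "repo", "apd") %in% names(markers)))
  n_missing <- sum(!stats::complete.cases(markers[, c("acti", "repo", "apd")]))
  ok <- function(x) x[is.finite(x)]
  if (!length(ok(markers$acti)))
    stop("all markers missing; nothing to aggregate")
  rng <- function(x) {
    x <- ok(x)
    if (!length(x)) NA_real_ else max(x) - min(x)
  }
  per_needle <- function(col) {
    vals <- tapply(markers[[col]], markers$needle, rng)
    vals <- vals[is.finite(vals)]
    c(mean = mean(vals), sd = if (length(vals) > 1) stats::sd(vals) else 0)
  }
  rt <- per_needle("repo"); ad <- per_needle("apd")
  structure(list(
    dAT_tot = rng(markers$acti),
    dRT_tot = rng(markers$repo),
    dRT_trans = rt[["mean"]], dRT_trans_sd = rt[["sd"]],
    dAPD_tot = rng(markers$apd),
    dAPD_trans = ad[["mean"]], dAPD_trans_sd = ad[["sd"]],
    n_sites = nrow(markers), n_missing = n_missing
  ), class = "dispersion_summary")
}

#' @exportS3Method base::print
print.dispersion_summary <- function(x, ...) {
  cat("Dispersion of activation/repolarization (ms):\n")
  cat(sprintf("  dAT_tot   %6.1f\n", x$dAT_tot))
  cat(sprintf("  dRT_tot   %6.1f\n", x$dRT_tot))
  cat(sprintf("  dRT_trans %6.1f +/- %.1f\n", x$dRT_trans, x$dRT_trans_sd))
  cat(sprintf("  dAPD_tot  %6.1f\n", x$dAPD_tot))
  cat(sprintf("  dAPD_trans%6.1f +/- %.1f\n", x$dAPD_trans, x$dAPD_trans_sd))
  if (x$n_missing > 0)
    cat(sprintf("  (%d of %d sites with missing markers excluded)\n",
                x$n_missing, x$n_sites))
  invisible(x)
}

#' Max - min dispersion over a surface section
#'
#' @param values marker values (ms) on the section's nodes; `NA` excluded
#' @return max - min (ms)
#' @export
section_dispersion <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("empty section: no finite marker values")
  max(values) - min(values)
}

#' Markers at every site of a needle array from recorded traces
#'
#' @param time sample times (ms)
#' @param traces matrix of potentials, one column per recording site
#' @param array a [needle_array()] (or any data frame with `needle`, `site`
#'   rows matching the trace columns)
#' @inheritParams trace_markers
#' @return marker data frame (one row per site) suitable for
#'   [dispersion_summary()]
#' @export
tissue_markers <- function(time, traces, array, threshold = -20,
                           ead_level = -40, complete_level = -70) {
  stopifnot(ncol(traces) == nrow(array))
  mk <- lapply(seq_len(ncol(traces)), function(j) {
    m <- trace_markers(time, traces[, j], threshold, ead_level, complete_level)
    data.frame(needle = array$needle[j], site = array$site[j],
               node = array$node[j], acti = m$acti, repo = m$repo,
               apd = m$apd, ead = m$ead)
  })
  do.call(rbind, mk)
}

#' Write / read a marker table as delimited text
#'
#' @param markers marker data frame
#' @param path file path
#' @return `read_marker_table` returns the marker data frame
#' @export
write_marker_table <- function(markers, path) {
  utils::write.table(markers, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_marker_table
#' @export
read_marker_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}
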