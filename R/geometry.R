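#' Truncated-ellipsoid left-ventricle specification
#'
#' Parametrization of the idealized LV: the image of a Cartesian periodic
#' slab under ellipsoidal coordinates
#' \deqn{x = a(r)\cos\theta\cos\phi,\; y = b(r)\cos\theta\sin\phi,\;
#'       z = c(r)\sin\theta}
#' with linearly interpolated semi-axes \eqn{a(r) = a_1 + r (a_2 - a_1)}
#' (same for b, c); r = 0 is the endocardium, r = 1 the epicardium. The default
#' geometry (semi-axes 1.5/2.7 and 4.4/5 cm, phi covering a full period,
#' theta in \[-3pi/8, pi/8\]) together with a 512 x 256 x 48 element grid
#' gives the full-resolution 6,447,616-node problem.
#'
#' @param a1,b1,c1 endocardial semi-axes (cm)
#' @param a2,b2,c2 epicardial semi-axes (cm)
#' @param phi_range,theta_range angular extents (rad)
#' @param n_phi,n_theta,n_r element counts in the circumferential, apex-base
#'   and transmural directions
#' @return object of class `ellipsoid_spec`
#' @export
ellipsoid_spec <- function(a1 = 1.5, b1 = 1.5, c1 = 4.4,
                           a2 = 2.7, b2 = 2.7, c2 = 5.0,
                           phi_range = c(-pi / 2, 3 * pi / 2),
                           theta_range = c(-3 * pi / 8, pi / 8),
                           n_phi = 512, n_theta = 256, n_r = 48) {
  stopifnot(a2 > a1, b2 > b1, c2 > c1, n_phi >= 4, n_theta >= 1, n_r >= 1,
            diff(phi_range) > 0, diff(theta_range) > 0)
  structure(list(a1 = a1, b1 = b1, c1 = c1, a2 = a2, b2 = b2, c2 = c2,
                 phi_range = phi_range, theta_range = theta_range,
                 n_phi = n_phi, n_theta = n_theta, n_r = n_r),
            class = "ellipsoid_spec")
}

#' Transmural layer label from depth
#'
#' Layers of equal depth: `ENDO` for r <= 1/3, `MID` for 1/3 < r <= 2/3,
#' `EPI` for r > 2/3 (nodes on a boundary belong to the deeper layer, toward
#' the endocardium).
#'
#' @param r transmural coordinate in \[0, 1\] (0 = endocardium)
#' @return factor with levels ENDO, MID, EPI
#' @export
layer_from_depth <- function(r) {
  factor(ifelse(r <= 1 / 3, "ENDO", ifelse(r <= 2 / 3, "MID", "EPI")),
         levels = c("ENDO", "MID", "EPI"))
}

#' Rule-based fiber direction
#'
#' Fibers rotate transmurally, linearly with depth and counterclockwise from
#' epicardium to endocardium, for a total sweep of `total_rotation` degrees.
#' The angle is measured from the circumferential direction within the local
#' tangent plane.
#'
#' @param r transmural coordinate (0 = endo, 1 = epi)
#' @param frame 2 x 3 matrix whose rows are the orthonormal circumferential
#'   and meridional (apex-base) tangent vectors
#' @param total_rotation total transmural sweep (degrees)
#' @param epi_angle fiber angle on the epicardium (degrees)
#' @return unit fiber vector (length 3)
#' @export
fiber_direction <- function(r, frame, total_rotation = 120,
                            epi_angle = -60) {
  stopifnot(is.matrix(frame), nrow(frame) == 2, ncol(frame) == 3)
  alpha <- (epi_angle + (1 - r) * total_rotation) * pi / 180
  v <- cos(alpha) * frame[1, ] + sin(alpha) * frame[2, ]
  v / sqrt(sum(v^2))
}

#' Transversely isotropic conductivity coefficients
#'
#' Longitudinal (along-fiber) and transverse conductivities of the intra-
#' and extracellular media. Defaults are the study values, printed in mS and
#' interpreted as mS/cm.
#'
#' @param sigma_l_i,sigma_l_e longitudinal intra-/extracellular (mS/cm)
#' @param sigma_t_i,sigma_t_e transverse intra-/extracellular (mS/cm)
#' @return object of class `conductivity_set`
#' @export
conductivity_set <- function(sigma_l_i = 3, sigma_l_e = 2,
                             sigma_t_i = 0.31525, sigma_t_e = 1.3514) {
  stopifnot(sigma_l_i > 0, sigma_l_e > 0, sigma_t_i > 0, sigma_t_e > 0)
  structure(list(sigma_l_i = sigma_l_i, sigma_l_e = sigma_l_e,
                 sigma_t_i = sigma_t_i, sigma_t_e = sigma_t_e),
            class = "conductivity_set")
}

#' Conductivity tensors along a fiber direction
#'
#' \eqn{D = \sigma_t I + (\sigma_l - \sigma_t)\, a_l a_l^T} for each medium;
#' the eigenvalues are \eqn{\{\sigma_l, \sigma_t, \sigma_t\}} with fiber
#' eigenvector \eqn{a_l}.
#'
#' @param sigma a [conductivity_set()]
#' @param a_l unit fiber vector
#' @return list with 3 x 3 matrices `Di` and `De`
#' @export
conductivity_tensor <- function(sigma, a_l) {
  stopifnot(inherits(sigma, "conductivity_set"),
            abs(sum(a_l^2) - 1) < 1e-8)
  outer_l <- tcrossprod(a_l)
  list(Di = sigma$sigma_t_i * diag(3) +
         (sigma$sigma_l_i - sigma$sigma_t_i) * outer_l,
       De = sigma$sigma_t_e * diag(3) +
         (sigma$sigma_l_e - sigma$sigma_t_e) * outer_l)
}

#' Build the truncated-ellipsoid Q1 hexahedral mesh
#'
#' Structured grid of `n_phi x n_theta x n_r` isoparametric Q1 hexahedra.
#' When `phi_range` spans a full period the circumferential seam is closed
#' (nodes at phi_min and phi_max identified), giving
#' `n_phi * (n_theta + 1) * (n_r + 1)` nodes; otherwise
#' `(n_phi + 1)(n_theta + 1)(n_r + 1)`. Per-element fibers follow
#' [fiber_direction()] evaluated at the element centroid.
#'
#' @param spec an [ellipsoid_spec()]
#' @param total_rotation,epi_angle fiber rule, see [fiber_direction()]
#' @param connectivity build the element table (set `FALSE` to construct
#'   only nodes/labels of very large meshes)
#' @return object of class `lqt8_mesh` with fields `coords` (n x 3, cm),
#'   `elems` (ne x 8, VTK hexahedron ordering), `fibers` (ne x 3), per-node
#'   `r` and `layer`, surface node sets, and the structured parametric grid
#' @export
build_ellipsoid_mesh <- function(spec = ellipsoid_spec(),
                                 total_rotation = 120, epi_angle = -60,
                                 connectivity = TRUE) {
  periodic <- isTRUE(all.equal(diff(spec$phi_range), 2 * pi, tolerance = 1e-9))
  Ni <- if (periodic) spec$n_phi else spec$n_phi + 1L
  Nj <- spec$n_theta + 1L
  Nk <- spec$n_r + 1L
  phi <- spec$phi_range[1] +
    (seq_len(Ni) - 1) * diff(spec$phi_range) / spec$n_phi
  theta <- seq(spec$theta_range[1], spec$theta_range[2], length.out = Nj)
  rr <- seq(0, 1, length.out = Nk)

  idx <- function(i, j, k) i + (j - 1L) * Ni + (k - 1L) * (Ni * Nj)

  grid <- expand.grid(i = seq_len(Ni), j = seq_len(Nj), k = seq_len(Nk))
  ph <- phi[grid$i]; th <- theta[grid$j]; r <- rr[grid$k]
  a <- spec$a1 + r * (spec$a2 - spec$a1)
  b <- spec$b1 + r * (spec$b2 - spec$b1)
  cc <- spec$c1 + r * (spec$c2 - spec$c1)
  coords <- cbind(x = a * cos(th) * cos(ph),
                  y = b * cos(th) * sin(ph),
                  z = cc * sin(th))

  elems <- fibers <- NULL
  if (connectivity) {
    eg <- expand.grid(i = seq_len(spec$n_phi), j = seq_len(spec$n_theta),
                      k = seq_len(spec$n_r))
    i1 <- if (periodic) (eg$i %% Ni) + 1L else eg$i + 1L
    elems <- cbind(idx(eg$i, eg$j,     eg$k),     idx(i1, eg$j,     eg$k),
                   idx(i1,   eg$j + 1L, eg$k),     idx(eg$i, eg$j + 1L, eg$k),
                   idx(eg$i, eg$j,     eg$k + 1L), idx(i1, eg$j,     eg$k + 1L),
                   idx(i1,   eg$j + 1L, eg$k + 1L), idx(eg$i, eg$j + 1L, eg$k + 1L))
    storage.mode(elems) <- "integer"
    # centroid parametric coordinates
    phc <- phi[eg$i] + diff(spec$phi_range) / spec$n_phi / 2
    thc <- (theta[eg$j] + theta[eg$j + 1L]) / 2
    rc <- (rr[eg$k] + rr[eg$k + 1L]) / 2
    fibers <- .ellipsoid_fibers(spec, phc, thc, rc, total_rotation, epi_angle)
  }

  structure(list(
    coords = coords, elems = elems, fibers = fibers,
    r = r, layer = layer_from_depth(r),
    surfaces = list(endo = which(grid$k == 1L), epi = which(grid$k == Nk)),
    grid = list(phi = phi, theta = theta, r = rr),
    node_index = idx, periodic = periodic, spec = spec,
    n_nodes = nrow(coords), type = "ellipsoid",
    h = c(diff(spec$phi_range) / spec$n_phi * mean(c(spec$a1, spec$a2)),
          diff(spec$theta_range) / spec$n_theta * mean(c(spec$c1, spec$c2)),
          (spec$a2 - spec$a1) / spec$n_r)
  ), class = "lqt8_mesh")
}

# circumferential/meridional tangent frame + rotated fiber, vectorised
.ellipsoid_fibers <- function(spec, ph, th, r, total_rotation, epi_angle) {
  a <- spec$a1 + r * (spec$a2 - spec$a1)
  b <- spec$b1 + r * (spec$b2 - spec$b1)
  cc <- spec$c1 + r * (spec$c2 - spec$c1)
  # d/dphi and d/dtheta of the parametrization
  tphi <- cbind(-a * cos(th) * sin(ph), b * cos(th) * cos(ph), 0)
  ttheta <- cbind(-a * sin(th) * cos(ph), -b * sin(th) * sin(ph), cc * cos(th))
  nrm <- sqrt(rowSums(tphi^2))
  e1 <- tphi / nrm
  # Gram-Schmidt
  proj <- rowSums(ttheta * e1)
  e2 <- ttheta - proj * e1
  e2 <- e2 / sqrt(rowSums(e2^2))
  alpha <- (epi_angle + (1 - r) * total_rotation) * pi / 180
  f <- cos(alpha) * e1 + sin(alpha) * e2
  f / sqrt(rowSums(f^2))
}

#' Build a Cartesian slab mesh
#'
#' Rectangular Q1 hexahedral slab with the z direction transmural
#' (`z = 0` endocardial face) and the same linear transmural fiber rotation
#' as the ellipsoid, fibers lying in the x-y plane.
#'
#' @param n integer vector `c(nx, ny, nz)` of element counts
#' @param h element size(s) in cm (scalar or length 3)
#' @param total_rotation,epi_angle fiber rule
#' @return an `lqt8_mesh` of type `"slab"`
#' @export
build_slab_mesh <- function(n = c(20, 20, 10), h = 0.02,
                            total_rotation = 120, epi_angle = -60) {
  stopifnot(length(n) == 3, all(n >= 1))
  h <- rep(h, length.out = 3)
  Ni <- n[1] + 1L; Nj <- n[2] + 1L; Nk <- n[3] + 1L
  idx <- function(i, j, k) i + (j - 1L) * Ni + (k - 1L) * (Ni * Nj)
  grid <- expand.grid(i = seq_len(Ni), j = seq_len(Nj), k = seq_len(Nk))
  coords <- cbind(x = (grid$i - 1) * h[1], y = (grid$j - 1) * h[2],
                  z = (grid$k - 1) * h[3])
  r <- (grid$k - 1) / n[3]
  eg <- expand.grid(i = seq_len(n[1]), j = seq_len(n[2]), k = seq_len(n[3]))
  elems <- cbind(idx(eg$i, eg$j, eg$k),          idx(eg$i + 1L, eg$j, eg$k),
                 idx(eg$i + 1L, eg$j + 1L, eg$k), idx(eg$i, eg$j + 1L, eg$k),
                 idx(eg$i, eg$j, eg$k + 1L),      idx(eg$i + 1L, eg$j, eg$k + 1L),
                 idx(eg$i + 1L, eg$j + 1L, eg$k + 1L),
                 idx(eg$i, eg$j + 1L, eg$k + 1L))
  storage.mode(elems) <- "integer"
  rc <- (eg$k - 0.5) / n[3]
  alpha <- (epi_angle + (1 - rc) * total_rotation) * pi / 180
  fibers <- cbind(cos(alpha), sin(alpha), 0)
  structure(list(
    coords = coords, elems = elems, fibers = fibers,
    r = r, layer = layer_from_depth(r),
    surfaces = list(endo = which(grid$k == 1L), epi = which(grid$k == Nk)),
    grid = list(x = (seq_len(Ni) - 1) * h[1], y = (seq_len(Nj) - 1) * h[2],
                z = (seq_len(Nk) - 1) * h[3]),
    node_index = idx, periodic = FALSE, n_nodes = nrow(coords),
    type = "slab", h = h
  ), class = "lqt8_mesh")
}

#' Build a 1D cable
#'
#' Uniform 1D grid for cable simulations (the paper's single-phenotype and
#' transmural-cable runs). Supports per-node phenotype assignment through
#' `iks_factor`/`rho` vectors in the cable runners.
#'
#' @param n_elems number of elements (>= 2)
#' @param h node spacing (cm)
#' @param sigma conductivity (mS/cm)
#' @return object of class `lqt8_cable`
#' @export
build_cable <- function(n_elems = 100, h = 0.02, sigma = 2) {
  stopifnot(n_elems >= 2, h > 0, sigma > 0)
  n_nodes <- n_elems + 1L
  structure(list(n_nodes = n_nodes, n_elems = as.integer(n_elems), h = h,
                 sigma = sigma, x = (seq_len(n_nodes) - 1) * h,
                 length = n_elems * h, type = "cable"),
            class = "lqt8_cable")
}

#' @exportS3Method base::print
print.lqt8_mesh <- function(x, ...) {
  cat(sprintf("Q1 hexahedral mesh (%s): %d nodes, %s elements%s\n",
              x$type, x$n_nodes,
              if (is.null(x$elems)) "no" else format(nrow(x$elems)),
              if (isTRUE(x$periodic)) ", periodic in phi" else ""))
  invisible(x)
}

#' @exportS3Method base::print
print.lqt8_cable <- function(x, ...) {
  cat(sprintf("1D cable: %d nodes, h = %g cm (length %g cm), sigma = %g mS/cm\n",
              x$n_nodes, x$h, x$length, x$sigma))
  invisible(x)
}

#' Element Jacobian determinants at the element centre
#'
#' @param mesh an `lqt8_mesh`
#' @param elements optional subset of element indices
#' @return numeric vector of det(J) at the centre of each (selected) element
#' @export
element_jacobians <- function(mesh, elements = NULL) {
  stopifnot(inherits(mesh, "lqt8_mesh"), !is.null(mesh$elems))
  el <- if (is.null(elements)) mesh$elems else
    mesh$elems[elements, , drop = FALSE]
  dN <- .q1_dshape(0, 0, 0)
  J11 <- J12 <- J13 <- J21 <- J22 <- J23 <- J31 <- J32 <- J33 <- 0
  for (a in 1:8) {
    xyz <- mesh$coords[el[, a], , drop = FALSE]
    J11 <- J11 + dN[a, 1] * xyz[, 1]; J12 <- J12 + dN[a, 1] * xyz[, 2]
    J13 <- J13 + dN[a, 1] * xyz[, 3]
    J21 <- J21 + dN[a, 2] * xyz[, 1]; J22 <- J22 + dN[a, 2] * xyz[, 2]
    J23 <- J23 + dN[a, 2] * xyz[, 3]
    J31 <- J31 + dN[a, 3] * xyz[, 1]; J32 <- J32 + dN[a, 3] * xyz[, 2]
    J33 <- J33 + dN[a, 3] * xyz[, 3]
  }
  J11 * (J22 * J33 - J23 * J32) - J12 * (J21 * J33 - J23 * J31) +
    J13 * (J21 * J32 - J22 * J31)
}
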