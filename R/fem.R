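# Q1 (trilinear) hexahedral finite elements: shape functions on [-1,1]^3 in
# VTK node ordering, 2x2x2 Gauss quadrature, vectorised assembly over
# elements.

.q1_signs <- matrix(c(-1, -1, -1,  1, -1, -1,  1, 1, -1, -1, 1, -1,
                      -1, -1,  1,  1, -1,  1,  1, 1,  1, -1, 1,  1),
                    ncol = 3, byrow = TRUE)

.q1_shape <- function(xi, eta, ze) {
  s <- .q1_signs
  (1 + s[, 1] * xi) * (1 + s[, 2] * eta) * (1 + s[, 3] * ze) / 8
}

.q1_dshape <- function(xi, eta, ze) {
  s <- .q1_signs
  cbind(s[, 1] * (1 + s[, 2] * eta) * (1 + s[, 3] * ze),
        (1 + s[, 1] * xi) * s[, 2] * (1 + s[, 3] * ze),
        (1 + s[, 1] * xi) * (1 + s[, 2] * eta) * s[, 3]) / 8
}

.gauss_pts <- (function() {
  g <- 1 / sqrt(3)
  as.matrix(expand.grid(xi = c(-g, g), eta = c(-g, g), ze = c(-g, g)))
})()

# packed symmetric tensor (xx, yy, zz, xy, xz, yz) from fiber directions
.packed_tensor <- function(fibers, sigma_l, sigma_t) {
  d <- sigma_l - sigma_t
  cbind(xx = sigma_t + d * fibers[, 1]^2,
        yy = sigma_t + d * fibers[, 2]^2,
        zz = sigma_t + d * fibers[, 3]^2,
        xy = d * fibers[, 1] * fibers[, 2],
        xz = d * fibers[, 1] * fibers[, 3],
        yz = d * fibers[, 2] * fibers[, 3])
}

#' Per-element conductivity tensors of a mesh
#'
#' Builds the packed symmetric intra-/extracellular tensors from the mesh
#' fibers, plus the monodomain (harmonic mean) tensor
#' \eqn{D_m = D_i (D_i + D_e)^{-1} D_e}, which for coaxial transversely
#' isotropic media reduces to harmonic means of the eigenvalues.
#'
#' @param mesh an `lqt8_mesh` with fibers
#' @param sigma a [conductivity_set()]
#' @return list of `ne x 6` matrices `Di`, `De`, `Dm` (columns xx, yy, zz,
#'   xy, xz, yz)
#' @export
element_tensors <- function(mesh, sigma = conductivity_set()) {
  stopifnot(inherits(mesh, "lqt8_mesh"), !is.null(mesh$fibers))
  hm <- function(a, b) a * b / (a + b)
  list(Di = .packed_tensor(mesh$fibers, sigma$sigma_l_i, sigma$sigma_t_i),
       De = .packed_tensor(mesh$fibers, sigma$sigma_l_e, sigma$sigma_t_e),
       Dm = .packed_tensor(mesh$fibers,
                           hm(sigma$sigma_l_i, sigma$sigma_l_e),
                           hm(sigma$sigma_t_i, sigma$sigma_t_e)))
}

# core assembly: returns list(M, K) as dgCMatrix; Dpack is ne x 6 (or NULL to
# skip the stiffness part)
.assemble_q1 <- function(mesh, Dpack = NULL, mass = TRUE) {
  el <- mesh$elems
  ne <- nrow(el)
  n <- mesh$n_nodes
  X <- mesh$coords
  Kacc <- if (!is.null(Dpack)) vector("list", 36) else NULL
  Macc <- if (mass) vector("list", 36) else NULL
  pair_id <- function(a, b) (a - 1) * 8 + b - (a - 1) * a / 2  # a <= b
  if (!is.null(Kacc)) for (q in seq_len(36)) Kacc[[q]] <- numeric(ne)
  if (!is.null(Macc)) for (q in seq_len(36)) Macc[[q]] <- numeric(ne)

  Xa <- lapply(1:8, function(a) X[el[, a], , drop = FALSE])
  for (g in seq_len(nrow(.gauss_pts))) {
    gp <- .gauss_pts[g, ]
    dN <- .q1_dshape(gp[1], gp[2], gp[3])
    N <- .q1_shape(gp[1], gp[2], gp[3])
    J <- array(0, c(ne, 3, 3))
    for (a in 1:8) for (b in 1:3) for (cc in 1:3)
      J[, b, cc] <- J[, b, cc] + dN[a, b] * Xa[[a]][, cc]
    detJ <- J[, 1, 1] * (J[, 2, 2] * J[, 3, 3] - J[, 2, 3] * J[, 3, 2]) -
            J[, 1, 2] * (J[, 2, 1] * J[, 3, 3] - J[, 2, 3] * J[, 3, 1]) +
            J[, 1, 3] * (J[, 2, 1] * J[, 3, 2] - J[, 2, 2] * J[, 3, 1])
    if (any(detJ <= 0)) stop("non-positive element Jacobian in assembly")
    # inverse via cofactors: Jinv[b,cc] = cof(J)[cc,b] / detJ
    Jinv <- array(0, c(ne, 3, 3))
    Jinv[, 1, 1] <- (J[, 2, 2] * J[, 3, 3] - J[, 2, 3] * J[, 3, 2]) / detJ
    Jinv[, 1, 2] <- (J[, 1, 3] * J[, 3, 2] - J[, 1, 2] * J[, 3, 3]) / detJ
    Jinv[, 1, 3] <- (J[, 1, 2] * J[, 2, 3] - J[, 1, 3] * J[, 2, 2]) / detJ
    Jinv[, 2, 1] <- (J[, 2, 3] * J[, 3, 1] - J[, 2, 1] * J[, 3, 3]) / detJ
    Jinv[, 2, 2] <- (J[, 1, 1] * J[, 3, 3] - J[, 1, 3] * J[, 3, 1]) / detJ
    Jinv[, 2, 3] <- (J[, 1, 3] * J[, 2, 1] - J[, 1, 1] * J[, 2, 3]) / detJ
    Jinv[, 3, 1] <- (J[, 2, 1] * J[, 3, 2] - J[, 2, 2] * J[, 3, 1]) / detJ
    Jinv[, 3, 2] <- (J[, 1, 2] * J[, 3, 1] - J[, 1, 1] * J[, 3, 2]) / detJ
    Jinv[, 3, 3] <- (J[, 1, 1] * J[, 2, 2] - J[, 1, 2] * J[, 2, 1]) / detJ

    if (!is.null(Dpack)) {
      gradN <- vector("list", 8)  # each ne x 3
      for (a in 1:8) {
        ga <- matrix(0, ne, 3)
        for (cc in 1:3) for (b in 1:3)
          ga[, cc] <- ga[, cc] + dN[a, b] * Jinv[, b, cc]
        gradN[[a]] <- ga
      }
      # D gradN_m for each m, then dot with gradN_a
      DG <- vector("list", 8)
      for (m in 1:8) {
        gm <- gradN[[m]]
        DG[[m]] <- cbind(
          Dpack[, 1] * gm[, 1] + Dpack[, 4] * gm[, 2] + Dpack[, 5] * gm[, 3],
          Dpack[, 4] * gm[, 1] + Dpack[, 2] * gm[, 2] + Dpack[, 6] * gm[, 3],
          Dpack[, 5] * gm[, 1] + Dpack[, 6] * gm[, 2] + Dpack[, 3] * gm[, 3])
      }
      for (a in 1:8) for (m in a:8) {
        q <- pair_id(a, m)
        Kacc[[q]] <- Kacc[[q]] +
          rowSums(gradN[[a]] * DG[[m]]) * detJ
      }
    }
    if (mass) {
      for (a in 1:8) for (m in a:8) {
        q <- pair_id(a, m)
        Macc[[q]] <- Macc[[q]] + N[a] * N[m] * detJ
      }
    }
  }

  build <- function(acc) {
    ii <- jj <- xx <- vector("list", 64)
    q <- 0
    for (a in 1:8) for (m in a:8) {
      pid <- pair_id(a, m)
      q <- q + 1
      ii[[q]] <- el[, a]; jj[[q]] <- el[, m]; xx[[q]] <- acc[[pid]]
      if (m > a) {
        q <- q + 1
        ii[[q]] <- el[, m]; jj[[q]] <- el[, a]; xx[[q]] <- acc[[pid]]
      }
    }
    Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                         dims = c(n, n))
  }
  list(M = if (mass) build(Macc) else NULL,
       K = if (!is.null(Dpack)) build(Kacc) else NULL)
}

#' Assemble finite-element matrices of the Bidomain problem
#'
#' Builds the consistent mass matrix and the stiffness matrices
#' \eqn{K(D_i)}, \eqn{K(D_i + D_e)} and the monodomain \eqn{K(D_m)} on a Q1
#' hexahedral mesh with pure Neumann (insulated) boundary conditions. All
#' stiffness matrices have exact zero row sums (constants lie in the null
#' space); the mass-matrix row sums are the nodal volumes.
#'
#' @param mesh an `lqt8_mesh`
#' @param sigma a [conductivity_set()]
#' @param lumped also return the lumped (row-sum) mass vector
#' @return object of class `fem_system`: sparse matrices `M`, `Ki`, `Kie`,
#'   `Km` (dgCMatrix), lumped mass vector `Mlump`, and the generating `sigma`
#' @export
assemble_fem <- function(mesh, sigma = conductivity_set(), lumped = TRUE) {
  stopifnot(inherits(mesh, "lqt8_mesh"))
  tens <- element_tensors(mesh, sigma)
  base <- .assemble_q1(mesh, tens$Di, mass = TRUE)
  Kie <- .assemble_q1(mesh, tens$Di + tens$De, mass = FALSE)$K
  Km <- .assemble_q1(mesh, tens$Dm, mass = FALSE)$K
  M <- base$M
  if (any(Matrix::diag(M) <= 0)) stop("mass matrix is not positive definite")
  structure(list(M = M, Ki = base$K, Kie = Kie, Km = Km,
                 Mlump = if (lumped) Matrix::rowSums(M) else NULL,
                 sigma = sigma, n_nodes = mesh$n_nodes),
            class = "fem_system")
}

#' Assemble a single stiffness matrix for a given tensor field
#'
#' @param mesh an `lqt8_mesh`
#' @param D either a single 3 x 3 symmetric tensor (recycled over elements)
#'   or an `ne x 6` packed matrix (xx, yy, zz, xy, xz, yz)
#' @return sparse stiffness matrix
#' @export
assemble_stiffness <- function(mesh, D) {
  if (is.matrix(D) && all(dim(D) == c(3, 3))) {
    D <- matrix(rep(c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3]),
                    each = nrow(mesh$elems)), ncol = 6)
  }
  .assemble_q1(mesh, D, mass = FALSE)$K
}

#' Assemble the consistent mass matrix
#'
#' @param mesh an `lqt8_mesh`
#' @return sparse mass matrix (entries in cm^3)
#' @export
assemble_mass <- function(mesh) .assemble_q1(mesh, NULL, mass = TRUE)$M

#' Mesh volume by quadrature
#'
#' Sum of element volumes via 2x2x2 Gauss quadrature of the isoparametric
#' Jacobian.
#'
#' @param mesh an `lqt8_mesh`
#' @return volume (cm^3)
#' @export
mesh_volume <- function(mesh) {
  el <- mesh$elems
  ne <- nrow(el)
  Xa <- lapply(1:8, function(a) mesh$coords[el[, a], , drop = FALSE])
  vol <- numeric(ne)
  for (g in seq_len(nrow(.gauss_pts))) {
    gp <- .gauss_pts[g, ]
    dN <- .q1_dshape(gp[1], gp[2], gp[3])
    J <- array(0, c(ne, 3, 3))
    for (a in 1:8) for (b in 1:3) for (cc in 1:3)
      J[, b, cc] <- J[, b, cc] + dN[a, b] * Xa[[a]][, cc]
    vol <- vol +
      J[, 1, 1] * (J[, 2, 2] * J[, 3, 3] - J[, 2, 3] * J[, 3, 2]) -
      J[, 1, 2] * (J[, 2, 1] * J[, 3, 3] - J[, 2, 3] * J[, 3, 1]) +
      J[, 1, 3] * (J[, 2, 1] * J[, 3, 2] - J[, 2, 2] * J[, 3, 1])
  }
  sum(vol)
}

#' @exportS3Method base::print
print.fem_system <- function(x, ...) {
  cat(sprintf("FEM system: %d nodes, %d stored nonzeros per matrix\n",
              x$n_nodes, length(x$Ki@x)))
  invisible(x)
}
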