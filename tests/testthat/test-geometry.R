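test_that("ellipsoid mesh node counts follow the periodic identification", {
  m <- build_ellipsoid_mesh(ellipsoid_spec(n_phi = 4, n_theta = 1, n_r = 1))
  expect_true(m$periodic)
  expect_equal(m$n_nodes, 4 * 2 * 2)
  # non-periodic wedge
  m2 <- build_ellipsoid_mesh(ellipsoid_spec(phi_range = c(0, pi),
                                            n_phi = 4, n_theta = 2, n_r = 2))
  expect_false(m2$periodic)
  expect_equal(m2$n_nodes, 5 * 3 * 3)
})

test_that("endocardial surface nodes lie on the inner ellipsoid", {
  m <- build_ellipsoid_mesh(ellipsoid_spec(n_phi = 16, n_theta = 6, n_r = 3))
  en <- m$coords[m$surfaces$endo, ]
  resid <- (en[, 1] / 1.5)^2 + (en[, 2] / 1.5)^2 + (en[, 3] / 4.4)^2 - 1
  expect_lt(max(abs(resid)), 1e-12)
  ep <- m$coords[m$surfaces$epi, ]
  resid2 <- (ep[, 1] / 2.7)^2 + (ep[, 2] / 2.7)^2 + (ep[, 3] / 5)^2 - 1
  expect_lt(max(abs(resid2)), 1e-12)
})

test_that("periodic seam shares nodes instead of duplicating a ring", {
  m <- build_ellipsoid_mesh(ellipsoid_spec(n_phi = 8, n_theta = 2, n_r = 2))
  # every node id must be referenced by elements on both sides of the seam
  counts <- tabulate(m$elems, nbins = m$n_nodes)
  expect_true(all(counts >= 1))
  # total distinct coordinates match node count (no duplicated positions)
  expect_equal(nrow(unique(round(m$coords, 10))), m$n_nodes)
  expect_true(all(element_jacobians(m) > 0))
})

test_that("fibers rotate linearly through 120 degrees and stay unit length", {
  frame <- rbind(c(1, 0, 0), c(0, 1, 0))
  f_epi <- fiber_direction(1, frame)
  f_endo <- fiber_direction(0, frame)
  ang <- function(v) atan2(v[2], v[1]) * 180 / pi
  expect_equal(ang(f_endo) - ang(f_epi), 120)
  f_mid <- fiber_direction(0.5, frame)
  expect_equal(ang(f_mid), (ang(f_endo) + ang(f_epi)) / 2)
  expect_equal(sum(f_mid^2), 1, tolerance = 1e-12)
  # same law on the built ellipsoid: per-element fiber norms are 1
  m <- build_ellipsoid_mesh(ellipsoid_spec(n_phi = 16, n_theta = 4, n_r = 3))
  expect_equal(max(abs(rowSums(m$fibers^2) - 1)), 0, tolerance = 1e-12)
})

test_that("conductivity tensors have the stated eigenstructure", {
  sig <- conductivity_set()
  set.seed(7)
  for (k in 1:100) {
    a <- rnorm(3); a <- a / sqrt(sum(a^2))
    D <- conductivity_tensor(sig, a)
    ev <- eigen(D$Di, symmetric = TRUE)
    expect_equal(sort(ev$values),
                 sort(c(sig$sigma_l_i, sig$sigma_t_i, sig$sigma_t_i)),
                 tolerance = 1e-12)
    # fiber direction is the eigenvector of the longitudinal eigenvalue
    vmax <- ev$vectors[, which.max(ev$values)]
    expect_equal(abs(sum(vmax * a)), 1, tolerance = 1e-10)
    expect_equal(sum(diag(D$Di)), sig$sigma_l_i + 2 * sig$sigma_t_i,
                 tolerance = 1e-12)
  }
  # isotropic degeneration
  iso <- conductivity_set(sigma_l_i = 2, sigma_l_e = 2,
                          sigma_t_i = 2, sigma_t_e = 2)
  D <- conductivity_tensor(iso, c(0, 0, 1))
  expect_equal(D$Di, 2 * diag(3))
})

test_that("mesh volume converges monotonically to the parametric volume", {
  spec0 <- ellipsoid_spec(n_phi = 8, n_theta = 4, n_r = 2)
  v_exact <- ellipsoid_volume_quadrature(spec0)
  errs <- vapply(c(1, 2, 4), function(f) {
    sp <- ellipsoid_spec(n_phi = 8 * f, n_theta = 4 * f, n_r = 2 * f)
    abs(mesh_volume(build_ellipsoid_mesh(sp)) - v_exact)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3] / v_exact, 0.01)
})

test_that("layer labels split the wall into equal-depth thirds with the stated tie-break", {
  expect_equal(as.character(layer_from_depth(c(0, 1 / 3, 0.34, 2 / 3, 0.67, 1))),
               c("ENDO", "ENDO", "MID", "MID", "EPI", "EPI"))
  m <- build_slab_mesh(c(2, 2, 6), h = 0.1)
  expect_equal(as.vector(table(m$layer)), c(3 * 9, 2 * 9, 2 * 9))
})

test_that("cable construction spans the requested domain", {
  cab <- build_cable(100, 0.02)
  expect_equal(cab$n_nodes, 101)
  expect_equal(cab$length, 2)
  cab2 <- build_cable(200, 0.01)
  expect_equal(cab2$length, cab$length)
  expect_error(build_cable(1), ">= 2")
})

test_that("degenerate ellipsoid specifications are rejected", {
  expect_error(ellipsoid_spec(a2 = 1.5), "a2 > a1")
  expect_error(ellipsoid_spec(c2 = 4.4), "c2 > c1")
})
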