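test_that("unit-cube Q1 element matrices match independent quadrature", {
  m <- build_slab_mesh(c(1, 1, 1), h = 1)
  # assembled matrices are in global node numbering; permute the
  # element-local oracle through the element connectivity
  el <- m$elems[1, ]
  K <- as.matrix(assemble_stiffness(m, diag(3)))[el, el]
  M <- as.matrix(assemble_mass(m))[el, el]
  oracle <- q1_unit_cube_matrices()
  expect_equal(K, oracle$K, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(M, oracle$M, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("stiffness matrices annihilate constants and scale linearly", {
  mesh <- build_slab_mesh(c(3, 2, 2), h = c(0.03, 0.02, 0.025))
  fs <- assemble_fem(mesh)
  ones <- rep(1, mesh$n_nodes)
  expect_lt(max(abs(fs$Ki %*% ones)), 1e-10)
  expect_lt(max(abs(fs$Kie %*% ones)), 1e-10)
  K1 <- assemble_stiffness(mesh, diag(3))
  K2 <- assemble_stiffness(mesh, 2 * diag(3))
  expect_equal(as.matrix(K2), 2 * as.matrix(K1), tolerance = 1e-13)
  # mass row sums are nodal volumes; total is the mesh volume
  expect_equal(sum(fs$Mlump), mesh_volume(mesh), tolerance = 1e-12)
  expect_true(all(Matrix::diag(fs$M) > 0))
})

test_that("ODE stage is an O(tau) perturbation and exact at one node", {
  mesh <- build_slab_mesh(c(1, 1, 1), h = 0.02)
  pr <- tissue_problem(mesh)
  st <- tissue_state(pr)
  for (tau in c(0.05, 0.025, 0.0125)) {
    out <- step_odes(pr, st$states, istim = 0, tau = tau)
    delta <- max(abs(out$states - st$states))
    expect_lt(delta, 0.1 * tau / 0.0125)
  }
  # after relaxing toward the quiescent equilibrium, ten further steps are
  # near-stationary and agree exactly with the space-clamped stepping
  eq <- run_single_cell(n_beats = 1, bcl = 5000, stim_amplitude = 0,
                        record_dt = 1000)$final_state
  seq_states <- matrix(eq, ncol = 1)
  s <- seq_states
  for (k in 1:10) {
    out <- step_odes(pr, s, 0)
    s <- out$states
    s[1, 1] <- s[1, 1] + 0.05 * (-out$iion[1])  # space-clamped V update
  }
  expect_lt(max(abs(s - seq_states)), 1e-4)
  oracle0d <- run_single_cell(n_beats = 1, bcl = 0.5, stim_amplitude = 0,
                              record_dt = 0.5, state0 = eq)$final_state
  expect_identical(s[, 1], unname(oracle0d))
})

test_that("a single-node cable reproduces the space-clamped cell bit for bit", {
  cab <- build_cable(2, 0.02)  # build constraint, then restrict to one node
  one <- structure(list(n_nodes = 1L, n_elems = 0L, h = 0.02, sigma = 2,
                        x = 0, length = 0, type = "cable"),
                   class = "lqt8_cable")
  states <- matrix(tp06_initial_state(), ncol = 1)
  res <- cable_advance(one, states, mutation_setting(0.11), iks_factor = 1.3,
                       t_end = 400, stim_onsets = 0, stim_amplitude = 52,
                       stim_nodes = 1, probes = 1)
  cell <- run_single_cell(cell_phenotype("ENDO", "HET1"),
                          mutation_setting(0.11), bcl = 400, n_beats = 1,
                          stim_amplitude = 52)
  expect_identical(res$final_states[, 1], unname(cell$final_state))
  expect_identical(res$traces[, 1], unname(cell$states[, "V"]))
})

test_that("elliptic stage: constant v gives zero extracellular potential", {
  mesh <- build_slab_mesh(c(3, 3, 2), h = 0.03)
  pr <- tissue_problem(mesh, config = solver_config(model = "bidomain"))
  ue <- solve_elliptic(pr, rep(-84.7, mesh$n_nodes))
  expect_lt(max(abs(ue)), 1e-9)
})

test_that("elliptic stage satisfies the equal-anisotropy closed form", {
  # De = lambda * Di with lambda = 1.5
  sig <- conductivity_set(sigma_l_i = 2, sigma_l_e = 3,
                          sigma_t_i = 0.4, sigma_t_e = 0.6)
  mesh <- build_slab_mesh(c(4, 3, 2), h = 0.025)
  pr <- tissue_problem(mesh, sigma = sig,
                       config = solver_config(model = "bidomain"))
  set.seed(11)
  v <- rnorm(mesh$n_nodes, sd = 20)
  ue <- solve_elliptic(pr, v)
  lam <- 1.5
  expected <- -v / (1 + lam)
  expected <- expected - sum(pr$Mlump * expected) / sum(pr$Mlump)
  expect_lt(max(abs(ue - expected)), 1e-6)
  # residual honours the configured tolerance
  rhs <- -as.numeric(pr$Ki_s %*% v)
  resid <- rhs - as.numeric(pr$Kie_s %*% ue)
  resid <- resid - mean(resid)
  expect_lt(sqrt(sum(resid^2)),
            1.01e-8 * sqrt(sum(rhs^2)) + 1e-11)
})

test_that("parabolic stage is identity for steady uniform fields", {
  mesh <- build_slab_mesh(c(3, 2, 2), h = 0.03)
  pr <- tissue_problem(mesh)
  v <- rep(-60, mesh$n_nodes)
  vn <- solve_parabolic(pr, v, iion = rep(0, mesh$n_nodes))
  expect_equal(vn, v, tolerance = 1e-9)
})

test_that("gauge invariance: shifting ue by a constant leaves v unchanged", {
  mesh <- build_slab_mesh(c(3, 3, 2), h = 0.03)
  pr <- tissue_problem(mesh, config = solver_config(model = "bidomain"))
  set.seed(3)
  v <- rnorm(mesh$n_nodes, -80, 5)
  ue <- rnorm(mesh$n_nodes, 0, 2)
  iion <- rnorm(mesh$n_nodes)
  v1 <- solve_parabolic(pr, v, iion, ue = ue)
  v2 <- solve_parabolic(pr, v, iion, ue = ue + 17.3)
  expect_equal(v1, v2, tolerance = 1e-8)
})

test_that("elliptic right-hand side is compatible (sums to zero) during a run", {
  mesh <- build_slab_mesh(c(4, 2, 2), h = 0.03)
  pr <- tissue_problem(mesh, config = solver_config(model = "bidomain"))
  st <- tissue_state(pr)
  res <- advance(pr, st, 5,
                 stimuli = list(list(nodes = 1:4, onset = 0, duration = 1,
                                     amplitude = 350)))
  rhs <- -as.numeric(pr$Ki_s %*% res$state$v)
  expect_lt(abs(sum(rhs)), 1e-10 * max(1, max(abs(rhs))))
})

test_that("quiescent tissue stays at rest and both engines agree", {
  mesh <- build_slab_mesh(c(3, 2, 2), h = 0.03)
  pr <- tissue_problem(mesh)
  st <- tissue_state(pr)
  res <- advance(pr, st, 100, probes = 1L)
  expect_lt(max(abs(res$state$v - st$v[1])), 0.5)
  prb <- tissue_problem(mesh, config = solver_config(model = "bidomain"))
  stim <- list(list(nodes = 1:4, onset = 0, duration = 1, amplitude = 350))
  ra <- advance(prb, tissue_state(prb), 3, stimuli = stim, engine = "r")
  ca <- advance(prb, tissue_state(prb), 3, stimuli = stim, engine = "cpp")
  expect_equal(ra$state$v, unname(ca$state$v), tolerance = 1e-9)
  expect_equal(ra$state$ue, unname(ca$state$ue), tolerance = 1e-9)
})

test_that("equal-anisotropy bidomain matches monodomain within 0.5 mV", {
  sig <- conductivity_set(sigma_l_i = 2, sigma_l_e = 4,
                          sigma_t_i = 0.5, sigma_t_e = 1)
  mesh <- build_slab_mesh(c(8, 4, 3), h = 0.04)
  fs <- assemble_fem(mesh, sig)
  prb <- tissue_problem(mesh, sigma = sig, fem = fs,
                        config = solver_config(model = "bidomain"))
  prm <- tissue_problem(mesh, sigma = sig, fem = fs,
                        config = solver_config(model = "monodomain"))
  stim <- list(list(nodes = stimulus_footprint(mesh, "endocardial"),
                    onset = 0, duration = 1, amplitude = 350))
  rb <- advance(prb, tissue_state(prb), 25, stimuli = stim)
  rm_ <- advance(prm, tissue_state(prm), 25, stimuli = stim)
  expect_lt(max(abs(rb$state$v - rm_$state$v)), 0.5)
})

test_that("halving the time step changes the cable APD by less than 1 ms", {
  cab <- build_cable(50, 0.02)
  a1 <- run_cable_pacing(cab, mutation_setting(0), 1.3, bcl = 500,
                         n_beats = 2, tau = 0.05)$markers$apd
  a2 <- run_cable_pacing(cab, mutation_setting(0), 1.3, bcl = 500,
                         n_beats = 2, tau = 0.025)$markers$apd
  expect_lt(abs(a1 - a2), 1)
})

test_that("a planar wave propagates along the cable with finite velocity", {
  cab <- build_cable(100, 0.02)
  states <- matrix(rep(tp06_initial_state(), cab$n_nodes), nrow = 21)
  res <- cable_advance(cab, states, mutation_setting(0), 1.3, t_end = 60,
                       probes = c(26L, 76L))
  t1 <- activation_time(res$time, res$traces[, 1])
  t2 <- activation_time(res$time, res$traces[, 2])
  cv <- 50 * cab$h / (t2 - t1)  # cm/ms
  expect_gt(cv, 0.03); expect_lt(cv, 0.12)
})
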