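test_that("reentry classification follows the event-log definitions", {
  window <- 4000
  # single outward wave then quiescence
  direct <- data.frame(node = 1:50, time = seq(1, 120, length.out = 50))
  expect_equal(classify_reentry(direct, window), "none")
  # re-activations that die early
  early <- rbind(direct, data.frame(node = 1:20,
                                    time = seq(400, 1200, length.out = 20)))
  expect_equal(classify_reentry(early, window), "nonsustained")
  # re-activations persisting to the window end
  late <- rbind(direct, data.frame(node = rep(1:10, 12),
                                   time = seq(400, 3900, length.out = 120)))
  expect_equal(classify_reentry(late, window), "sustained")
})

test_that("pacing with zero stimuli returns the input state", {
  cab <- build_cable(20, 0.02)
  sim <- pvs_sim(cab, mutation_setting(0), iks_factor = 1.3)
  st0 <- sim$initial_state()
  out <- run_pacing(sim, pvs_plan(n_s1 = 0), state = st0)
  expect_identical(out$state, st0)
})

test_that("two paced beats produce two full action potentials at a distal site", {
  cab <- build_cable(50, 0.02)
  states <- matrix(rep(tp06_initial_state(), cab$n_nodes), nrow = 21)
  res <- cable_advance(cab, states, mutation_setting(0), 1.3, t_end = 1000,
                       stim_onsets = c(0, 500), probes = 45L)
  upstrokes <- res$events[res$events$node == 45, ]
  expect_equal(nrow(upstrokes), 2)
  # upstroke count agrees with the space-clamped reference
  cell <- run_single_cell(cell_phenotype("ENDO", "HET1"), mutation_setting(0),
                          bcl = 500, n_beats = 2)
  v <- cell$states[, "V"]
  cross <- sum(diff(v > -20) == 1)
  expect_equal(nrow(upstrokes), cross)
})

test_that("attempted couplings form the arithmetic decrement sequence", {
  cab <- build_cable(40, 0.02)
  sim <- pvs_sim(cab, mutation_setting(0), iks_factor = 1.3)
  plan <- pvs_plan(n_s1 = 2, bcl_s1 = 500, attempt_window = 450,
                   observation = 450, max_level = 2)
  paced <- run_pacing(sim, plan)
  out <- pvs_search(sim, paced, plan)
  s2 <- out$attempts[out$attempts$level == "S2", ]
  expect_equal(s2$coupling,
               seq(380, by = -10, length.out = nrow(s2)))
  # every attempted coupling appears exactly once
  expect_false(any(duplicated(s2$coupling)))
  # search ends by losing capture in a homogeneous medium, without reentry
  expect_false(s2$captured[nrow(s2)])
  expect_true(all(s2$captured[-nrow(s2)]))
  expect_equal(out$classification, "none")
})

test_that("checkpointed attempts are reproducible", {
  cab <- build_cable(40, 0.02)
  sim <- pvs_sim(cab, mutation_setting(0), iks_factor = 1.3)
  plan <- pvs_plan(n_s1 = 2, bcl_s1 = 500, attempt_window = 400,
                   observation = 400, max_level = 2)
  paced <- run_pacing(sim, plan)
  out1 <- pvs_search(sim, paced, plan)
  out2 <- pvs_search(sim, paced, plan)
  expect_identical(out1$attempts, out2$attempts)
  expect_identical(out1$classification, out2$classification)
})

test_that("stimulus footprints select nodes on the requested surface", {
  mesh <- build_ellipsoid_mesh(ellipsoid_spec(n_phi = 48, n_theta = 24,
                                              n_r = 6))
  fp_endo <- stimulus_footprint(mesh, "endocardial")
  expect_true(all(mesh$r[fp_endo] <= 0.06 / 1.2 + 1e-9))
  fp_epi <- stimulus_footprint(mesh, "epicardial")
  expect_true(all(mesh$r[fp_epi] >= 1 - 0.06 / 1.2 - 1e-9))
  expect_true(any(mesh$r[fp_epi] == 1))
  # central location: equidistant from apex and base in theta
  th <- atan2(mesh$coords[fp_epi, 3],
              sqrt(mesh$coords[fp_epi, 1]^2 + mesh$coords[fp_epi, 2]^2) *
                5 / 2.7)
  expect_lt(abs(mean(th) - mean(c(-3 * pi / 8, pi / 8))), 0.2)
})

test_that("intramural conduction block is detected when the mid-wall is refractory", {
  cab <- build_cable(60, 0.02)
  sim <- pvs_sim(cab, mutation_setting(0), iks_factor = 1.3)
  plan <- pvs_plan(attempt_window = 300, block_window = 150)
  # control: a wave launched into resting tissue conducts end to end
  st <- sim$initial_state()
  att <- sim$advance(st, 300, 0)
  ctl <- classify_attempt(att$events, sim, plan)
  expect_true(ctl$captured)
  expect_false(ctl$block)
  expect_equal(ctl$reentry, "none")
  # engineered refractory mid-wall: the middle third is set to a late
  # phase-3 state (repolarized to about -65 mV, sodium inactivation gates
  # not yet recovered), which is refractory without acting as a wave source
  ap <- run_single_cell(cell_phenotype("ENDO", "HOM"), mutation_setting(0),
                        bcl = 400, n_beats = 1)
  i_ref <- which(ap$states[, "V"] < -65 & ap$time > 50)[1]
  refractory <- ap$states[i_ref, ]
  st2 <- sim$initial_state()
  st2$states[, 21:41] <- refractory
  att2 <- sim$advance(st2, 300, 0)
  blk <- classify_attempt(att2$events, sim, plan)
  expect_true(blk$captured)
  expect_true(blk$block)
  # the wavefront terminated intramurally within the block window
  early <- att2$events[att2$events$time <= 150, ]
  expect_lt(max(early$node), 42)
})
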