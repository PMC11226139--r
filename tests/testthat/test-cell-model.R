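test_that("steady-state activation and inactivation curves behave as defined", {
  wt <- gate_params_wt()
  ts <- gate_params_ts()
  expect_equal(d_inf(-4, wt), 0.5)
  expect_equal(d_inf(-8, ts), 0.5)
  expect_equal(f_inf(-20, wt), 0.5)
  expect_equal(f_inf(0, ts), 0.5)
  # hand-evaluated sigmoids
  expect_equal(d_inf(30, wt), 1 / (1 + exp((-4 - 30) / 7.5)))
  expect_gt(d_inf(30, wt), 0.98); expect_lt(d_inf(30, wt), 1)
  expect_gt(f_inf(-80, wt), 0.999); expect_lt(f_inf(-80, wt), 1)
  # monotonicity
  v <- seq(-90, 60, by = 1)
  expect_true(all(diff(d_inf(v, wt)) > 0))
  expect_true(all(diff(f_inf(v, ts)) < 0))
  # optional non-inactivating floor
  fl <- gate_params_ts(ts_floor = 0.2)
  expect_equal(f_inf(1e3, fl), 0.2, tolerance = 1e-12)
})

test_that("ICaL mixture degenerates and averages correctly", {
  state <- tp06_initial_state()
  state[["V"]] <- 0; state[["d_wt"]] <- 0.6; state[["f_wt"]] <- 0.5
  state[["d_ts"]] <- 0.3; state[["f_ts"]] <- 0.8; state[["CaSS"]] <- 2e-4
  phen <- cell_phenotype()
  # rho = 0: mixture equals the pure WT component
  m0 <- i_cal_mixed(state, mutation_setting(0), phen)
  expect_identical(m0$ICaL, m0$ICaL_wt)
  # TS gates and parameters equal to WT: rho = 1 equals WT current
  st2 <- state
  st2[["d_ts"]] <- st2[["d_wt"]]; st2[["f_ts"]] <- st2[["f_wt"]]
  m1 <- i_cal_mixed(st2, mutation_setting(1, ts_params = gate_params_wt()),
                    phen)
  expect_equal(m1$ICaL, m1$ICaL_wt)
  # rho = 0.5: arithmetic mean of the two variant currents
  mh <- i_cal_mixed(state, mutation_setting(0.5), phen)
  expect_equal(mh$ICaL, (mh$ICaL_wt + mh$ICaL_ts) / 2)
})

test_that("right-hand side is near equilibrium at the published resting state", {
  d <- tp06_rhs(tp06_initial_state(), cell_phenotype(),
                mutation_setting(0), i_app = 0)
  expect_lt(abs(d[["V"]]), 0.05)
  expect_error(tp06_rhs(c(tp06_initial_state()[-1], NaN)), "non-finite")
})

test_that("IKs scales exactly linearly with the layer factor", {
  state <- tp06_initial_state()
  state[["V"]] <- 10; state[["Xs"]] <- 0.4
  p1 <- cell_phenotype(); p1$iks_factor <- 0.65
  p2 <- cell_phenotype(); p2$iks_factor <- 1.3
  c1 <- tp06_currents(state, p1); c2 <- tp06_currents(state, p2)
  expect_equal(c2[["IKs"]], 2 * c1[["IKs"]], tolerance = 1e-14)
  other <- setdiff(names(c1), c("IKs", "Iion"))
  expect_equal(c1[other], c2[other])
})

test_that("activation gates relax upward from zero at depolarized potentials", {
  state <- tp06_initial_state()
  state[["V"]] <- 20
  gates <- c("m", "h", "j", "Xr1", "Xr2", "Xs", "r", "s",
             "d_wt", "f_wt", "d_ts", "f_ts", "f2", "fCass")
  state[gates] <- 0
  d <- tp06_rhs(state, cell_phenotype(), mutation_setting(0.5))
  act <- c("m", "Xr1", "Xs", "r", "d_wt", "d_ts")
  expect_true(all(d[act] >= 0))
})

test_that("at rho = 0 the mutant branch is exactly inert", {
  # rho = 0 with stock TP06 WT gates is the unmodified TP06 model; the
  # trajectory must be bit-identical regardless of how the (zero-weight)
  # mutant channels are parameterised
  stock <- gate_params_tp06()
  m_a <- mutation_setting(0, wt_params = stock,
                          ts_params = gate_params_ts())
  m_b <- mutation_setting(0, wt_params = stock,
                          ts_params = gate_params_ts(ts_floor = 0.4))
  tr_a <- run_single_cell(mutation = m_a, n_beats = 2, bcl = 400)
  tr_b <- run_single_cell(mutation = m_b, n_beats = 2, bcl = 400)
  keep <- setdiff(colnames(tr_a$states), c("d_ts", "f_ts"))
  expect_identical(tr_a$states[, keep], tr_b$states[, keep])
})

test_that("paced cell runner measures a quasi-steady action potential", {
  phen <- cell_phenotype("ENDO", "HET1")
  tr <- run_single_cell(phen, mutation_setting(0), bcl = 1000, n_beats = 8)
  expect_true(tr$captured)
  # 0D convenience band: within 10% of the cable reference value 266 ms
  expect_lt(abs(tr$markers$apd - 266) / 266, 0.10)
  tr0 <- run_single_cell(phen, n_beats = 0)
  expect_equal(nrow(tr0$states), 1L)
  expect_equal(unname(tr0$final_state), unname(tp06_initial_state()))
})

test_that("gates stay within [0, 1] along a paced trajectory", {
  tr <- run_single_cell(cell_phenotype("MID", "HET1"),
                        mutation_setting(0.5), bcl = 500, n_beats = 3)
  gates <- c("m", "h", "j", "Xr1", "Xr2", "Xs", "r", "s",
             "d_wt", "f_wt", "d_ts", "f_ts", "f2", "fCass", "Rbar")
  g <- tr$states[, gates]
  expect_true(all(g >= 0 & g <= 1))
  conc <- tr$states[, c("Ki", "Nai", "Cai", "CaSS", "CaSR")]
  expect_true(all(conc > 0))
})

test_that("APD increases monotonically with heterozygosis in every phenotype", {
  combos <- expand.grid(layer = c("ENDO", "MID", "EPI"),
                        het = c("HET1", "HET2"), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    apds <- vapply(c(0, 0.11, 0.5), function(rho) {
      phen <- cell_phenotype(combos$layer[i], combos$het[i])
      run_single_cell(phen, mutation_setting(rho), bcl = 1000,
                      n_beats = 4)$markers$apd
    }, numeric(1))
    expect_true(all(diff(apds) > 0),
                info = paste(combos$layer[i], combos$het[i]))
  }
})

test_that("steady AP agrees with an independent adaptive-step integration", {
  # condition with the package integrator, then integrate one beat with
  # lsoda on an independently transcribed right-hand side
  tr <- run_single_cell(cell_phenotype("ENDO", "HOM"), mutation_setting(0),
                        bcl = 1000, n_beats = 6)
  y0 <- tr$final_state
  sol <- lsoda_tp06_beat(y0, t_end = 600, dt = 1, rho = 0, iksf = 1.3,
                         va_wt = -4, vina_wt = -20)
  fine <- run_single_cell(cell_phenotype("ENDO", "HOM"), mutation_setting(0),
                          bcl = 1000, n_beats = 1, tau = 0.01,
                          state0 = y0)
  v_pkg <- approx(fine$time, fine$states[, "V"], xout = sol[, "time"])$y
  expect_lt(max(abs(v_pkg - sol[, "V"])), 2)
})
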