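test_that("activation marker finds the centre of a symmetric upstroke", {
  tt <- seq(0, 100, by = 0.5)
  v <- -85 + 60 * (1 + tanh((tt - 40) / 3))
  expect_equal(activation_time(tt, v), 40, tolerance = 0.5)
  # flat trace: missing marker
  expect_true(is.na(activation_time(tt, rep(-85, length(tt)))))
})

test_that("repolarization marker recovers analytic steepest-fall times", {
  tr <- make_ap_trace(ap_template(t_up = 10, t_rep = 310), sampling = 0.5)
  expect_equal(repolarization_time(tr$time, tr$v), 310, tolerance = 0.5)
  mk <- trace_markers(tr$time, tr$v)
  expect_equal(mk$apd, 300, tolerance = 1)
  expect_false(mk$ead)
  # monotone-decaying exponential: steepest slope at segment start
  tt <- seq(0, 50, by = 1)
  vexp <- -85 + 60 * exp(-tt / 10)
  expect_equal(repolarization_time(tt, vexp, complete_level = -70), tt[2])
})

test_that("EAD-bearing traces put the marker on terminal repolarization", {
  tmpl <- ap_template(t_up = 10, t_rep = 420, ead_time = 250, ead_amp = 25,
                      ead_width = 12)
  tr <- make_ap_trace(tmpl, sampling = 0.5)
  # two local maxima above the hump threshold
  pk <- which(diff(sign(diff(tr$v))) < 0) + 1
  expect_gte(sum(tr$v[pk] > -40), 2)
  mk <- trace_markers(tr$time, tr$v)
  expect_true(mk$ead)
  # marker lands after the hump, on the terminal fall, not between humps
  expect_gt(mk$repo, 250)
  expect_equal(mk$repo, 420, tolerance = 2)
})

test_that("incomplete repolarization yields a missing marker", {
  tt <- seq(0, 300, by = 1)
  v <- -85 + 100 / (1 + exp(-(tt - 10) * 2))  # rises, never repolarizes
  expect_true(is.na(repolarization_time(tt, v)))
})

test_that("markers on a TP06 action potential match a dense-derivative search", {
  tr <- run_single_cell(cell_phenotype("ENDO", "HET1"), mutation_setting(0),
                        bcl = 600, n_beats = 1, record_dt = 0.05)
  tt <- tr$time; v <- tr$states[, "V"]
  dense_acti <- tt[which.max(diff(v) / diff(tt))]
  expect_lt(abs(activation_time(tt, v) - dense_acti), 1)
  # halving the sampling interval moves markers by at most one coarse sample
  coarse <- seq(1, length(tt), by = 20)   # 1 ms sampling
  coarser <- seq(1, length(tt), by = 40)  # 2 ms sampling
  m1 <- trace_markers(tt[coarse], v[coarse])
  m2 <- trace_markers(tt[coarser], v[coarser])
  expect_lte(abs(m1$acti - m2$acti), 2)
  expect_lte(abs(m1$repo - m2$repo), 2)
})

test_that("dispersion summary equals exhaustive brute force with noise", {
  mf <- make_marker_field(12, 7, 7, acti_range = 80, trans_range = 35,
                          profile = "midwall", noise_sd = 4, seed = 99)
  ds <- dispersion_summary(mf$markers)
  bf <- dispersion_brute_force(mf$markers)
  for (f in names(bf)) expect_equal(ds[[f]], bf[[f]], tolerance = 1e-12)
  # stored truths from the generator agree too
  for (f in names(mf$truth)) expect_equal(ds[[f]], mf$truth[[f]],
                                          tolerance = 1e-12)
})

test_that("marker consistency: apd equals repo - acti at every site", {
  mf <- make_marker_field(6, 4, 5, noise_sd = 2, seed = 5)
  expect_equal(mf$markers$apd, mf$markers$repo - mf$markers$acti)
  ds <- dispersion_summary(mf$markers)
  expect_lte(ds$dRT_trans, ds$dRT_tot)
  expect_lte(ds$dAPD_trans, ds$dAPD_tot)
})

test_that("identical markers everywhere give zero dispersion", {
  mk <- expand.grid(needle = 1:10, site = 1:7)
  mk$acti <- 12; mk$repo <- 300; mk$apd <- 288
  ds <- dispersion_summary(mk)
  expect_equal(ds$dAT_tot, 0); expect_equal(ds$dRT_tot, 0)
  expect_equal(ds$dRT_trans, 0); expect_equal(ds$dAPD_tot, 0)
  expect_equal(ds$dAPD_trans, 0)
})

test_that("missing markers are excluded with a reported count", {
  mf <- make_marker_field(4, 3, 5, seed = 2)
  mk <- mf$markers
  mk$repo[c(3, 10)] <- NA; mk$apd[c(3, 10)] <- NA
  ds <- dispersion_summary(mk)
  expect_equal(ds$n_missing, 2)
  bf <- dispersion_brute_force(mk[stats::complete.cases(mk), ])
  expect_equal(ds$dRT_tot, bf$dRT_tot)
  mk$acti[] <- NA; mk$repo[] <- NA; mk$apd[] <- NA
  expect_error(dispersion_summary(mk), "all markers missing")
})

test_that("section dispersion is a plain range with empty-section error", {
  expect_equal(section_dispersion(rep(7, 5)), 0)
  set.seed(31)
  x <- runif(200, 100, 400)
  expect_equal(section_dispersion(x), max(x) - min(x))
  expect_error(section_dispersion(numeric(0)), "empty section")
})

test_that("needle array covers the default layout with ordered depths", {
  mesh <- build_ellipsoid_mesh(ellipsoid_spec(n_phi = 64, n_theta = 32,
                                              n_r = 6))
  arr <- needle_array(mesh, n_phi = 16, n_theta = 9, n_sites = 7)
  expect_equal(nrow(arr), 16 * 9 * 7)
  expect_equal(length(unique(arr$needle)), 16 * 9)
  # per-needle sites strictly ordered epi to endo
  for (k in unique(arr$needle)[1:10]) {
    rs <- arr$r[arr$needle == k]
    expect_true(all(diff(rs) < 0))
    expect_equal(rs[1], 1); expect_equal(rs[7], 0)
  }
  expect_true(all(arr$node >= 1 & arr$node <= mesh$n_nodes))
})

test_that("marker tables round-trip through delimited text", {
  mf <- make_marker_field(3, 2, 4, noise_sd = 1, seed = 8)
  path <- tempfile(fileext = ".tsv")
  write_marker_table(mf$markers, path)
  back <- read_marker_table(path)
  expect_equal(back$acti, mf$markers$acti, tolerance = 1e-9)
  expect_equal(dispersion_summary(back)$dAPD_tot,
               dispersion_summary(mf$markers)$dAPD_tot, tolerance = 1e-9)
})
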