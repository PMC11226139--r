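test_that("trace templates emit their construction truths", {
  tr <- make_ap_trace(ap_template(t_up = 10, t_rep = 310), sampling = 1)
  expect_equal(tr$truth$apd, 300)
  expect_false(tr$truth$ead)
  tr2 <- make_ap_trace(ap_template(t_rep = 400, ead_time = 250,
                                   ead_amp = 20), sampling = 1)
  expect_true(tr2$truth$ead)
  # fine sampling: marker recovery within one sample of truth
  fine <- make_ap_trace(ap_template(), sampling = 0.05)
  mk <- trace_markers(fine$time, fine$v)
  expect_lte(abs(mk$acti - fine$truth$acti), 0.05)
  expect_lte(abs(mk$repo - fine$truth$repo), 0.05)
})

test_that("zero gradients and zero noise give all-zero dispersion truths", {
  mf <- make_marker_field(5, 4, 7, acti_range = 0, trans_range = 0,
                          noise_sd = 0, seed = 1)
  expect_true(all(unlist(mf$truth[c("dAT_tot", "dRT_tot", "dRT_trans",
                                    "dAPD_tot", "dAPD_trans")]) == 0))
})

test_that("a pure linear transmural gradient gives the exact per-needle range", {
  g <- 6  # ms per unit depth fraction span
  mf <- make_marker_field(4, 3, 7, acti_range = 50, trans_range = g,
                          profile = "linear", noise_sd = 0, seed = 1)
  expect_equal(mf$truth$dRT_trans, g, tolerance = 1e-12)
  expect_equal(mf$truth$dRT_trans_sd, 0, tolerance = 1e-12)
  expect_equal(mf$truth$dAPD_trans, g, tolerance = 1e-12)
})

test_that("fields are reproducible by seed and differ across seeds", {
  a <- make_marker_field(6, 5, 7, noise_sd = 5, seed = 123)
  b <- make_marker_field(6, 5, 7, noise_sd = 5, seed = 123)
  c <- make_marker_field(6, 5, 7, noise_sd = 5, seed = 124)
  expect_identical(a$markers, b$markers)
  expect_false(isTRUE(all.equal(a$markers$repo, c$markers$repo)))
})

test_that("midwall and endo profiles place the range where intended", {
  mid <- make_marker_field(2, 2, 7, acti_range = 0, trans_range = 30,
                           profile = "midwall", noise_sd = 0, seed = 1)
  m <- mid$markers[mid$markers$needle == 1, ]
  expect_equal(which.max(m$repo), 4)  # mid-depth site of 7
  en <- make_marker_field(2, 2, 7, acti_range = 0, trans_range = 30,
                          profile = "endo", noise_sd = 0, seed = 1)
  e <- en$markers[en$markers$needle == 1, ]
  expect_equal(which.max(e$repo), 7)  # deepest (endocardial) site
})
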