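test_that("peak detection separates sustained, damped and flat traces", {
  s <- synthetic_signal("sinusoid", period = 20, amplitude = 1, t_end = 300)
  det <- detect_oscillations(s$time, s$x, transient_cut = 60)
  expect_true(det$sustained)
  expect_equal(diff(det$peak_times), rep(20, length(det$peak_times) - 1),
               tolerance = 0.02)

  d <- synthetic_signal("damped", period = 20, amplitude = 1, decay = 0.5,
                        t_end = 300)
  expect_false(detect_oscillations(d$time, d$x, transient_cut = 60)$sustained)

  k <- synthetic_signal("constant", baseline = 0.4, t_end = 300)
  detk <- detect_oscillations(k$time, k$x, transient_cut = 60)
  expect_false(detk$sustained)
  expect_length(detk$peak_times, 0)
})

test_that("sustained classification is invariant to amplitude scaling", {
  s <- synthetic_signal("sinusoid", period = 15, amplitude = 1,
                        baseline = 1, t_end = 240)
  d <- synthetic_signal("damped", period = 15, amplitude = 1, baseline = 1,
                        decay = 0.5, t_end = 240)
  for (scale in c(1e-3, 1, 1e3)) {
    expect_true(detect_oscillations(s$time, s$x * scale,
                                    transient_cut = 45)$sustained)
    expect_false(detect_oscillations(d$time, d$x * scale,
                                     transient_cut = 45)$sustained)
  }
})

test_that("frequency estimator is exact on periodic signals", {
  expect_equal(frequency_of(seq(0, 150, by = 15)), 4)
  expect_equal(frequency_of(seq(0, 200, by = 20)), 3)
  # across periods 5..60 s, sampled at >= 5x the frequency
  for (period in c(5, 12, 20, 37, 60)) {
    dt <- period / 8
    s <- synthetic_signal("sinusoid", period = period, t_end = 12 * period,
                          dt = dt)
    det <- detect_oscillations(s$time, s$x, transient_cut = 2 * period)
    expect_true(det$sustained)
    expect_equal(frequency_of(det$peak_times), 60 / period,
                 tolerance = 0.02)
  }
  expect_warning(f <- frequency_of(3.2), "fewer than 2")
  expect_true(is.na(f))
})

test_that("relative normalization maps basal to 0 and the extreme to 1", {
  x <- c(1, 1.5, 3, 2, 0.8)
  n <- normalize_relative(x, basal = 1)
  expect_equal(n[1], 0)
  expect_equal(max(n), 1)
  # emptying store: extreme below basal still maps to 1
  er <- c(400, 300, 150, 220, 390)
  ne <- normalize_relative(er, basal = 400)
  expect_equal(ne[1], 0)
  expect_equal(ne[3], 1)
  expect_true(all(diff(order(ne)) != 0))
  # affine invariance under positive scaling of deviations around basal
  expect_equal(normalize_relative(1 + 5 * (x - 1), basal = 1), n)
  expect_error(normalize_relative(rep(2, 10), basal = 2), "extreme")
})

test_that("the shipped alternative parameter sets reproduce their
           labelled feeder modes", {
  cases <- list(
    c("params_mode_er_feeding_synthetic.yaml", "ER_feeding", 0.7),
    c("params_mode_mt_feeding_synthetic.yaml", "Mt_feeding", 0.2),
    c("params_mode_er_and_mt_feeding_synthetic.yaml",
      "ER_and_Mt_feeding", 0.2))
  for (cs in cases) {
    p <- load_parameters(system.file("extdata", cs[1],
                                     package = "microca"))
    tr <- run_protocol(p, ca_protocol(ip3_post = as.numeric(cs[3]),
                                      t_end = 400), dt = 0.25)
    expect_identical(classify_feeder_mode(tr), cs[2], label = cs[1])
  }
})

test_that("antiphase synthetic pair yields opposite phase slopes", {
  s <- synthetic_signal("antiphase", period = 20, amplitude = 1,
                        baseline = 2, t_end = 100)
  sx <- sign(diff(s$x))
  sy <- sign(diff(s$y))
  nz <- sx != 0 & sy != 0
  expect_true(all(sx[nz] == -sy[nz]))
})
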