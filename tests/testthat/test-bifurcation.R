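# Scans here use a short horizon and coarse grids; the quantitative
# window/threshold claims are covered in test-acceptance.R.

test_that("a sweep over an inert parameter returns one full-range window", {
  p <- default_parameters()
  proto <- ca_protocol(ip3_post = 0.7, t_end = 250)
  # sodium in the microdomain far above k_na is saturating and inert here
  sc <- scan_1d(p, "na_ud", c(400, 500, 600), proto, refine = FALSE,
                dt = 0.25)
  expect_true(all(sc$sustained) || !any(sc$sustained))
  w <- scan_windows(sc)
  if (all(sc$sustained)) {
    expect_equal(nrow(w), 1)
    expect_equal(c(w$lower, w$upper), c(400, 600))
  }
})

test_that("a 1 x N heatmap reproduces the 1-D scan", {
  p <- default_parameters()
  proto <- ca_protocol(ip3_post = 0.5, t_end = 250)
  grid <- c(0.3, 0.7, 1.1)
  sc <- scan_1d(p, "ip3", grid, proto, refine = FALSE, dt = 0.25)
  hm <- scan_2d(p, "ip3", grid, "na_ud", c(9.9, 10.1), proto, dt = 0.25)
  freq1 <- ifelse(sc$sustained, sc$frequency, 0)
  expect_equal(unname(hm$frequency[, 1]), unname(freq1), tolerance = 1e-8)
  expect_equal(unname(hm$frequency[, 2]), unname(freq1), tolerance = 0.05)
})

test_that("refined boundaries bracket a sustained/non-sustained flip", {
  p <- default_parameters()
  proto <- ca_protocol(ip3_post = NA, t_end = 300)
  grid <- seq(0.05, 0.95, by = 0.3)
  sc <- scan_1d(p, "ip3", grid, proto, refine = TRUE, refine_tol = 0.02,
                dt = 0.25)
  b <- attr(sc, "boundaries")
  if (length(b)) {
    tol <- attr(sc, "refine_tol")
    for (bd in b) {
      lo <- .point_sustained(p, proto, bd - tol, dt = 0.25)
      hi <- .point_sustained(p, proto, bd + tol, dt = 0.25)
      expect_false(isTRUE(all.equal(lo, hi)))
    }
  } else {
    succeed("no flip on this coarse grid")
  }
})

.point_sustained <- function(p, proto, ip3, dt) {
  proto$ip3_post <- ip3
  tr <- run_protocol(p, proto, dt = dt)
  oscillation_metrics(tr, classify = FALSE)$sustained
}

test_that("scans are deterministic given fixed solver settings", {
  p <- default_parameters()
  proto <- ca_protocol(ip3_post = 0.6, t_end = 250)
  s1 <- scan_1d(p, "ip3", c(0.4, 0.6, 0.8), proto, refine = FALSE, dt = 0.25)
  s2 <- scan_1d(p, "ip3", c(0.4, 0.6, 0.8), proto, refine = FALSE, dt = 0.25)
  expect_identical(s1$frequency, s2$frequency)
  expect_identical(s1$env_max, s2$env_max)
})

test_that("vmcu_sweep validates its grid and recovers the control point", {
  p <- default_parameters()
  expect_error(vmcu_sweep(p, 0.7, scalings = c(0.5, 1)), "include 0")
  sc <- vmcu_sweep(p, 0.7, scalings = c(0, 0.5, 1),
                   protocol = ca_protocol(ip3_post = 0.7, t_end = 250),
                   dt = 0.25)
  ctrl <- run_protocol(p, ca_protocol(ip3_post = 0.7, t_end = 250),
                       dt = 0.25)
  met <- oscillation_metrics(ctrl, classify = FALSE)
  i1 <- which(sc$value == 1)
  expect_equal(sc$sustained[i1], met$sustained)
  if (met$sustained)
    expect_equal(sc$frequency[i1], met$frequency, tolerance = 1e-6)
})

test_that("distance sweeps respect the 10 nm floor via validation", {
  p <- default_parameters()
  proto <- ca_protocol(ip3_post = 0.2, t_end = 150)
  sc <- scan_1d(p, "d_er_mt", c(0.005, 0.02, 0.05), proto, refine = FALSE,
                dt = 0.5)
  expect_true(sc$failed[1])     # below the floor -> recorded, not fatal
  expect_false(any(sc$failed[-1]))
})
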