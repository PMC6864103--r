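# A cheap protocol reused across tests; the control set's behaviour at
# this stimulus is exercised in depth in test-acceptance.R.
quick_proto <- function(...) ca_protocol(ip3_post = 0.7, t_end = 200, ...)

test_that("compiled and R right-hand sides integrate identically", {
  p <- ca_parameters(ip3 = 0.7)
  y0 <- initial_state_guess()
  times <- seq(0, 20, by = 0.5)
  fast <- deSolve::ode(unname(y0), times, func = "ca_derivs",
                       parms = microca:::.pack_parms(p),
                       dllname = "microca", initfunc = "ca_initmod",
                       nout = 11L, method = "lsoda",
                       rtol = 1e-10, atol = 1e-12)
  slow <- deSolve::ode(unname(y0), times,
                       func = function(t, y, parms) {
                         names(y) <- microca:::.state_names
                         list(unname(model_rhs(y, p)))
                       }, parms = NULL, method = "lsoda",
                       rtol = 1e-10, atol = 1e-12)
  expect_equal(unclass(fast)[, 2:7], unclass(slow)[, 2:7],
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("rest state has near-zero derivatives from any initial guess", {
  p <- default_parameters()
  r1 <- find_rest_state(p)
  expect_lt(max(abs(model_rhs(r1, ca_parameters(ip3 = 0, base = p)))), 1e-8)
  # different guesses with the same total calcium land on the same rest;
  # redistribute calcium between compartments, keeping the total
  tot <- total_cell_ca(initial_state_guess(), p)
  g2 <- initial_state_guess(ca_cyt = 0.4, ca_mt = 0.3, ca_ud = 4)
  over <- (total_cell_ca(g2, p) - tot) * 1e6 / p$vol_er  # uM excess, free scale
  # move the excess out of the ER numerically
  f <- function(ce) {
    g <- g2; g[["ca_er"]] <- ce
    total_cell_ca(g, p) - tot
  }
  ce_adj <- uniroot(f, c(1, 2000))$root
  g2[["ca_er"]] <- ce_adj
  r2 <- find_rest_state(p, y0 = g2)
  expect_equal(unname(r1), unname(r2), tolerance = 1e-5)
})

test_that("no stimulus means a flat trajectory at rest", {
  p <- default_parameters()
  tr <- run_protocol(p, ca_protocol(ip3_post = 0, t_end = 120), dt = 0.5)
  expect_lt(diff(range(tr$ca_eff)), 1e-6 * max(tr$ca_eff))
  expect_lt(diff(range(tr$state[, "ca_er"])), 1e-6 * max(tr$state[, "ca_er"]))
})

test_that("total calcium is conserved along a stimulated trajectory", {
  p <- default_parameters()
  tr <- run_protocol(p, ca_protocol(ip3_post = 0.7, t_end = 600), dt = 0.5)
  tot <- rowSums(tr$content)
  expect_lt(diff(range(tot)) / mean(tot), 1e-4)
})

test_that("time grid is uniform and calcium stays non-negative", {
  p <- default_parameters()
  tr <- run_protocol(p, quick_proto(), dt = 0.25)
  expect_equal(unique(round(diff(tr$time), 10)), 0.25)
  expect_true(all(tr$state[, 1:4] >= 0))
  expect_true(all(tr$state[, c("h", "h_ud")] >= 0 &
                    tr$state[, c("h", "h_ud")] <= 1))
})

test_that("MCU knockout zeroes both uniporter fluxes along the run", {
  p <- default_parameters()
  tr <- run_protocol(p, quick_proto(overrides = list(v_mcu0 = 0)), dt = 0.5)
  expect_true(all(tr$fluxes[, "j_mcu"] == 0))
  expect_true(all(tr$fluxes[, "j_mcu_ud"] == 0))
})

test_that("microdomain inactivation freezes the compartment and matches a
           three-compartment reduction", {
  p <- ca_parameters(c_ip3r = 0, c_serca = 0, c_mcu = 0, c_mncx = 0)
  tr <- run_protocol(p, quick_proto(inactivate_ud = TRUE), dt = 0.5)
  expect_equal(diff(range(tr$state[, "ca_ud"])), 0)
  expect_true(all(tr$fluxes[, c("j_ip3r_ud", "j_serca_ud", "j_mcu_ud",
                                "j_mncx_ud", "j_leak_er_ud",
                                "j_leak_ud_cyt")] == 0))
  # hand-built 3-compartment model: same equations with the microdomain
  # terms struck out, integrated independently
  rest <- tr$state[1, ]
  times <- seq(50, 200, by = 0.5)
  q <- ca_parameters(ip3 = 0.7, base = p)
  ode3 <- deSolve::ode(
    y = unname(rest[c("ca_cyt", "ca_er", "ca_mt", "h")]),
    times = times,
    func = function(t, y, parms) {
      th <- function(ca, bp, k) bp * k / (ca + k)^2
      s <- (q$ip3 / (q$ip3 + q$d1)) * (y[1] / (y[1] + q$d5)) * y[4]
      po <- s^4 + 4 * s^3 * (1 - s)
      j_ip3r <- q$v_ip3r * po * (y[2] - y[1])
      j_serca <- q$v_serca * y[1]^2 / (q$k_serca^2 + y[1]^2)
      x <- q$b_mcu * q$faraday * (q$psi - q$psi0) * 1e-3 /
        (q$gas_const * q$temperature)
      j_mcu <- q$v_mcu0 * x * exp(x) * sinh(x) *
        y[1]^2 / (q$k_mcu^2 + y[1]^2)
      j_mncx <- q$v_mncx * q$na_cyt^3 / (q$k_na^3 + q$na_cyt^3) *
        y[3] / (q$k_mncx + y[3])
      j_leak <- q$k_leak_er_cyt * (y[2] - y[1])
      alpha <- q$a2 * q$d2 * (q$ip3 + q$d1) / (q$ip3 + q$d3)
      list(c(
        (j_ip3r + j_mncx + j_leak - j_serca - j_mcu) /
          (1 + th(y[1], q$bp_cyt, q$k_buf_cyt)),
        (q$vol_cyt / q$vol_er) * (j_serca - j_ip3r - j_leak) /
          (1 + th(y[2], q$bp_er, q$k_buf_er)),
        (q$vol_cyt / q$vol_mt) * (j_mcu - j_mncx) /
          (1 + th(y[3], q$bp_mt, q$k_buf_mt)),
        alpha * (1 - y[4]) - q$a2 * y[1] * y[4]))
    }, parms = NULL, method = "lsoda", rtol = 1e-8, atol = 1e-10)
  sel <- tr$time >= 50
  expect_equal(tr$state[sel, "ca_cyt"], ode3[, 2], tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(tr$state[sel, "ca_er"], ode3[, 3], tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(tr$state[sel, "ca_mt"], ode3[, 4], tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("clamping a constant flux reproduces the control trajectory", {
  # in a non-oscillating regime the post-transient IP3R flux is constant,
  # so clamping it to that constant must not change the attractor
  p <- default_parameters()
  ctrl <- run_protocol(p, ca_protocol(ip3_post = 0, t_end = 150), dt = 0.5)
  val <- ctrl$fluxes[nrow(ctrl$fluxes), "j_ip3r"]
  clamped <- run_protocol(
    p, ca_protocol(ip3_post = 0, t_end = 150,
                   clamp = clamp_spec("ip3r_cyt", max(val, 0))), dt = 0.5)
  expect_equal(clamped$state[, "ca_cyt"], ctrl$state[, "ca_cyt"],
               tolerance = 1e-5)
})

test_that("auto clamping requires an oscillating control run", {
  p <- default_parameters()
  pr <- ca_protocol(ip3_post = 0, t_end = 150,
                    clamp = clamp_spec("ip3r_ud", "auto"))
  expect_error(run_clamped(p, pr), "sustained")
})

test_that("trajectory CSV + JSON sidecar round-trips the protocol", {
  p <- default_parameters()
  tr <- run_protocol(p, quick_proto(), dt = 1)
  csv <- file.path(tempdir(), "traj.csv")
  write_trajectory(tr, csv)
  df <- utils::read.csv(csv)
  expect_equal(nrow(df), length(tr$time))
  side <- jsonlite::read_json(sub("csv$", "json", csv))
  expect_equal(side$protocol$ip3_post, 0.7)
  expect_equal(side$parameter_hash, hash_parameters(tr$params))
})

test_that("protocol validation rejects bad steps and unknown overrides", {
  expect_error(ca_protocol(0.7, t_step = 300, t_end = 200), "t_step")
  expect_error(ca_protocol(0.7, overrides = list(bogus = 1)), "unknown")
})
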