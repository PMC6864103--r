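test_that("microdomain volume is the 20% surface slab, linear in each input", {
  expect_equal(microdomain_volume(3.7, 150, 0), 0)
  # 1-um-diameter sphere: SA = pi um^2; 200 mitochondria at 20 nm
  expect_equal(microdomain_volume(pi, 200, 0.02), 0.2 * pi * 200 * 0.02,
               tolerance = 1e-12)
  expect_equal(microdomain_volume(pi, 200, 0.04),
               2 * microdomain_volume(pi, 200, 0.02))
  expect_equal(microdomain_volume(2 * pi, 200, 0.02),
               2 * microdomain_volume(pi, 200, 0.02))
  expect_error(microdomain_volume(-1, 200, 0.02), ">= 0")
})

test_that("buffering factor obeys its closed-form special cases", {
  expect_equal(buffering_factor(0.3, 0, 5), 0)
  expect_equal(buffering_factor(5, 120, 5), 120 / (4 * 5))
  expect_equal(buffering_factor(0, 120, 5), 120 / 5)
  ca <- seq(0, 50, by = 0.5)
  expect_true(all(diff(buffering_factor(ca, 120, 5)) < 0))
  expect_error(buffering_factor(1, 100, 0), "> 0")
})

test_that("IP3R open probability spans [0,1] with the 3-of-4 subunit law", {
  p <- default_parameters()
  expect_equal(ip3r_open_probability(0.5, 0.3, 0, p$d1, p$d5), 0)
  # saturated subunits: s -> 1
  expect_equal(ip3r_open_probability(1e12, 1e12, 1, p$d1, p$d5), 1,
               tolerance = 1e-6)
  # s = 0.5 exactly at ip3 = d1, saturating calcium, h = 1 gives
  # 0.5^4 + 4 * 0.5^3 * 0.5 = 0.3125
  expect_equal(ip3r_open_probability(p$d1, 1e12 * p$d5, 1, p$d1, p$d5),
               0.3125, tolerance = 1e-6)
  grid <- expand.grid(ip3 = c(0, 0.1, 1, 10), ca = c(0, 0.05, 1, 50),
                      h = c(0, 0.4, 1))
  po <- with(grid, ip3r_open_probability(ip3, ca, h, p$d1, p$d5))
  expect_true(all(po >= 0 & po <= 1))
})

test_that("h gate rates give the documented fixed points", {
  p <- default_parameters()
  g <- h_gate_rates(0.5, 0, p$a2, p$d1, p$d2, p$d3)
  expect_equal(g$beta, 0)
  expect_equal(g$alpha / (g$alpha + g$beta), 1)
  # beta = alpha at ca = alpha / a2 -> h_inf = 1/2
  ca_half <- g$alpha / p$a2
  g2 <- h_gate_rates(0.5, ca_half, p$a2, p$d1, p$d2, p$d3)
  expect_equal(g2$alpha / (g2$alpha + g2$beta), 0.5)
  g0 <- h_gate_rates(0, 1, p$a2, p$d1, p$d2, p$d3)
  expect_equal(g0$alpha, p$a2 * p$d2 * p$d1 / p$d3)
})

test_that("SERCA flux has Hill-2 half-activation and connectivity split", {
  expect_equal(serca_flux(0, 40, 0.2, 0.3), 0)
  expect_equal(serca_flux(0.2, 40, 0.2, 0.3), 0.7 * 40 / 2)
  expect_equal(serca_flux(5, 40, 0.2, 1, facing_ud = FALSE), 0)
  expect_equal(serca_flux(0.2, 40, 0.2, 0.3, facing_ud = TRUE), 0.3 * 40 / 2)
  ca <- seq(0, 10, by = 0.1)
  expect_true(all(diff(serca_flux(ca, 40, 0.2, 0)) > 0))
})

test_that("MCU flux vanishes at zero driving force and halves at k", {
  p <- default_parameters()
  expect_equal(mcu_flux(3, p$v_mcu0, p$k_mcu, 0.5, psi = p$psi0,
                        psi0 = p$psi0, b = p$b_mcu), 0)
  v_eff <- p$v_mcu0 * mcu_driving_force(p$psi, p$psi0, p$b_mcu)
  expect_equal(mcu_flux(p$k_mcu, p$v_mcu0, p$k_mcu, 0, p$psi, p$psi0,
                        p$b_mcu),
               v_eff / 2, tolerance = 1e-12)
  expect_equal(mcu_flux(7, p$v_mcu0, p$k_mcu, 0, p$psi, p$psi0, p$b_mcu,
                        facing_ud = TRUE), 0)
})

test_that("mNCX flux combines Hill-3 sodium and Michaelis calcium factors", {
  expect_equal(mncx_flux(0, 10, 2, 9.4, 0.3, 0), 0)
  expect_equal(mncx_flux(0.3, 9.4, 2, 9.4, 0.3, 0), 2 / 4)
  expect_equal(mncx_flux(1e9, 1e9, 2, 9.4, 0.3, 0), 2, tolerance = 1e-6)
})

test_that("leak flux is linear and antisymmetric in the gradient", {
  expect_equal(leak_flux(2.5, 2.5, 0.04), 0)
  expect_equal(leak_flux(400, 0.1, 0.01), 3.999)
  expect_equal(leak_flux(0.1, 400, 0.01), -leak_flux(400, 0.1, 0.01))
})

test_that("gradient fluxes vanish without gradients; connectivity gates pools", {
  p <- default_parameters()
  s <- c(ca_cyt = 0.5, ca_er = 0.5, ca_mt = 1, ca_ud = 0.5, h = 0.7,
         h_ud = 0.7)
  j <- compute_fluxes(s, ca_parameters(ip3 = 0.5, base = p))
  expect_equal(unname(j[c("j_ip3r", "j_ip3r_ud", "j_leak_er_cyt",
                          "j_leak_er_ud", "j_leak_ud_cyt")]),
               rep(0, 5))
  p1 <- ca_parameters(ip3 = 0.5, c_ip3r = 1, base = p)
  s2 <- c(ca_cyt = 0.2, ca_er = 300, ca_mt = 1, ca_ud = 5, h = 0.7,
          h_ud = 0.7)
  expect_equal(unname(compute_fluxes(s2, p1)[["j_ip3r"]]), 0)
  pc0 <- ca_parameters(ip3 = 0.5, c_ip3r = 0, c_serca = 0, c_mcu = 0,
                       c_mncx = 0, base = p)
  jud <- compute_fluxes(s2, pc0)[c("j_ip3r_ud", "j_serca_ud", "j_mcu_ud",
                                   "j_mncx_ud")]
  expect_equal(unname(jud), rep(0, 4))
})

test_that("fluxes and rhs match an independent literal transcription", {
  set.seed(42)
  for (i in 1:1000) {
    p <- random_params()
    s <- random_state()
    expect_equal(compute_fluxes(s, p), oracle_fluxes(s, p),
                 tolerance = 1e-12)
    expect_equal(unname(model_rhs(s, p)), unname(oracle_rhs(s, p)),
                 tolerance = 1e-12)
  }
})

test_that("total buffered calcium is a conserved quantity of the rhs", {
  # d/dt total = sum_i vol_i (1 + theta_i) dca_i/dt, which the flux
  # bookkeeping makes identically zero for the closed cell
  set.seed(7)
  for (i in 1:200) {
    p <- random_params()
    s <- random_state()
    d <- model_rhs(s, p)
    th <- c(buffering_factor(s[["ca_cyt"]], p$bp_cyt, p$k_buf_cyt),
            buffering_factor(s[["ca_er"]], p$bp_er, p$k_buf_er),
            buffering_factor(s[["ca_mt"]], p$bp_mt, p$k_buf_mt),
            buffering_factor(s[["ca_ud"]], p$bp_ud, p$k_buf_ud))
    vols <- c(p$vol_cyt, p$vol_er, p$vol_mt, p$vol_ud)
    dtotal <- sum(vols * (1 + th) * d[1:4])
    scale <- sum(abs(vols * (1 + th) * d[1:4]))
    expect_lt(abs(dtotal), 1e-10 * max(scale, 1))
  }
})

test_that("effective calcium is the volume-weighted average", {
  expect_equal(effective_ca(0.7, 0.7, 500, 2), 0.7)
  expect_equal(effective_ca(1, 3, 5, 5), 2)
  expect_equal(effective_ca(1, 50, 700, 0), 1)
  expect_error(effective_ca(1, 2, 0, 0), "not both zero")
})

test_that("total content covers free-only, saturation and monotonicity", {
  expect_equal(total_content(2, 0, 5, 100), 100 * 2 * 1e-6)
  expect_equal(total_content(1e9, 50, 5, 100),
               100 * (1e9 + 50) * 1e-6, tolerance = 1e-6)
  ca <- seq(0, 100, by = 1)
  expect_true(all(diff(total_content(ca, 50, 5, 100)) > 0))
})
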