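# Independent literal transcription of the model equations, written as
# one expression per flux/derivative.  Used to cross-check the package's
# structured implementation (R and compiled paths) term by term; kept
# deliberately free of any package helper.

oracle_fluxes <- function(s, p) {
  po <- function(ca, h) {
    sa <- (p$ip3 / (p$ip3 + p$d1)) * (ca / (ca + p$d5)) * h
    sa^4 + 4 * sa^3 * (1 - sa)
  }
  x <- p$b_mcu * p$faraday * (p$psi - p$psi0) * 1e-3 /
    (p$gas_const * p$temperature)
  dphi <- x * exp(x) * sinh(x)
  c(
    j_ip3r = (1 - p$c_ip3r) * (p$v_ip3r * po(s[["ca_cyt"]], s[["h"]])) *
      (s[["ca_er"]] - s[["ca_cyt"]]),
    j_ip3r_ud = p$c_ip3r * (p$v_ip3r * po(s[["ca_ud"]], s[["h_ud"]])) *
      (s[["ca_er"]] - s[["ca_ud"]]),
    j_serca = (1 - p$c_serca) * p$v_serca *
      (s[["ca_cyt"]]^2 / (p$k_serca^2 + s[["ca_cyt"]]^2)),
    j_serca_ud = p$c_serca * p$v_serca *
      (s[["ca_ud"]]^2 / (p$k_serca^2 + s[["ca_ud"]]^2)),
    j_mcu = (1 - p$c_mcu) * (p$v_mcu0 * dphi) *
      (s[["ca_cyt"]]^2 / (p$k_mcu^2 + s[["ca_cyt"]]^2)),
    j_mcu_ud = p$c_mcu * (p$v_mcu0 * dphi) *
      (s[["ca_ud"]]^2 / (p$k_mcu^2 + s[["ca_ud"]]^2)),
    j_mncx = (1 - p$c_mncx) * p$v_mncx *
      (p$na_cyt^3 / (p$k_na^3 + p$na_cyt^3)) *
      (s[["ca_mt"]] / (p$k_mncx + s[["ca_mt"]])),
    j_mncx_ud = p$c_mncx * p$v_mncx *
      (p$na_ud^3 / (p$k_na^3 + p$na_ud^3)) *
      (s[["ca_mt"]] / (p$k_mncx + s[["ca_mt"]])),
    j_leak_er_cyt = p$k_leak_er_cyt * (s[["ca_er"]] - s[["ca_cyt"]]),
    j_leak_er_ud = p$k_leak_er_ud * (s[["ca_er"]] - s[["ca_ud"]]),
    j_leak_ud_cyt = p$k_leak_ud_cyt * (s[["ca_ud"]] - s[["ca_cyt"]]))
}

oracle_rhs <- function(s, p) {
  j <- oracle_fluxes(s, p)
  th <- function(ca, bp, k) bp * k / (ca + k)^2
  alpha <- p$a2 * p$d2 * (p$ip3 + p$d1) / (p$ip3 + p$d3)
  c(
    (j[["j_ip3r"]] + j[["j_mncx"]] + j[["j_leak_ud_cyt"]] +
       j[["j_leak_er_cyt"]] - j[["j_serca"]] - j[["j_mcu"]]) /
      (1 + th(s[["ca_cyt"]], p$bp_cyt, p$k_buf_cyt)),
    (p$vol_cyt / p$vol_er) *
      (j[["j_serca"]] + j[["j_serca_ud"]] - j[["j_ip3r"]] -
         j[["j_ip3r_ud"]] - j[["j_leak_er_ud"]] - j[["j_leak_er_cyt"]]) /
      (1 + th(s[["ca_er"]], p$bp_er, p$k_buf_er)),
    (p$vol_cyt / p$vol_mt) *
      (j[["j_mcu"]] + j[["j_mcu_ud"]] - j[["j_mncx"]] - j[["j_mncx_ud"]]) /
      (1 + th(s[["ca_mt"]], p$bp_mt, p$k_buf_mt)),
    (p$vol_cyt / p$vol_ud) *
      (j[["j_ip3r_ud"]] + j[["j_mncx_ud"]] + j[["j_leak_er_ud"]] -
         j[["j_serca_ud"]] - j[["j_mcu_ud"]] - j[["j_leak_ud_cyt"]]) /
      (1 + th(s[["ca_ud"]], p$bp_ud, p$k_buf_ud)),
    alpha * (1 - s[["h"]]) - p$a2 * s[["ca_cyt"]] * s[["h"]],
    alpha * (1 - s[["h_ud"]]) - p$a2 * s[["ca_ud"]] * s[["h_ud"]])
}

# Random valid state for property tests.
random_state <- function() {
  c(ca_cyt = runif(1, 0.01, 5), ca_er = runif(1, 10, 800),
    ca_mt = runif(1, 0.01, 10), ca_ud = runif(1, 0.01, 100),
    h = runif(1), h_ud = runif(1))
}

# Random parameter jitter around the control set (keeps validity).
random_params <- function(base = default_parameters()) {
  jit <- function(x) x * exp(runif(1, -0.3, 0.3))
  ov <- list(ip3 = runif(1, 0, 3))
  for (nm in c("v_ip3r", "v_serca", "v_mcu0", "v_mncx",
               "k_leak_er_cyt", "k_leak_er_ud", "k_leak_ud_cyt"))
    ov[[nm]] <- jit(base[[nm]])
  for (nm in c("c_ip3r", "c_serca", "c_mcu", "c_mncx"))
    ov[[nm]] <- runif(1)
  do.call(ca_parameters, c(ov, list(base = base)))
}
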