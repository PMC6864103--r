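#' Fast-buffer factor
#'
#' Rapid-equilibrium calcium buffering contributes the factor
#' `theta = bp * k / (ca + k)^2`; every net flux in a compartment is
#' divided by `1 + theta`, so heavily buffered compartments respond
#' slowly in free calcium.
#'
#' @param ca free calcium concentration (uM).
#' @param bp buffer protein concentration (uM).
#' @param k buffer dissociation constant (uM), strictly positive.
#' @return the dimensionless buffering factor, >= 0 and decreasing in `ca`.
#' @export
buffering_factor <- function(ca, bp, k) {
  if (any(k <= 0)) stop("'k' must be > 0")
  if (any(ca < 0) || any(bp < 0)) stop("'ca' and 'bp' must be >= 0")
  bp * k / (ca + k)^2
}

#' IP3 receptor open probability
#'
#' A receptor opens when at least three of its four identical subunits
#' are active: `P_o = s^4 + 4 s^3 (1 - s)`, with subunit activity
#' `s = ip3/(ip3 + d1) * ca/(ca + d5) * h`.  The same law applies to the
#' cytosol-facing pool (with cytosolic calcium and gate) and to the
#' microdomain-facing pool (with microdomain calcium and gate).
#'
#' @param ip3 IP3 concentration (uM).
#' @param ca_local calcium at the receptor mouth (uM).
#' @param h_local slow inactivation gate in `[0, 1]`.
#' @param d1 IP3 binding constant (uM).
#' @param d5 calcium activation constant (uM).
#' @return open probability in `[0, 1]`.
#' @export
ip3r_open_probability <- function(ip3, ca_local, h_local, d1, d5) {
  if (any(ip3 < 0) || any(ca_local < 0)) stop("concentrations must be >= 0")
  if (any(h_local < 0) || any(h_local > 1)) stop("'h_local' must be in [0, 1]")
  s <- (ip3 / (ip3 + d1)) * (ca_local / (ca_local + d5)) * h_local
  s^4 + 4 * s^3 * (1 - s)
}

#' Opening/closing rates of the slow IP3R inactivation gate
#'
#' The gate obeys `dh/dt = alpha (1 - h) - beta h` with
#' `alpha = a2 d2 (ip3 + d1)/(ip3 + d3)` (recovery, set by IP3 only) and
#' `beta = a2 ca_local` (calcium-dependent inactivation).  The microdomain
#' gate uses the same `alpha` with the microdomain calcium in `beta`.
#'
#' @param ip3 IP3 concentration (uM).
#' @param ca_local local calcium concentration (uM).
#' @param a2 inactivation rate constant (1/(uM s)).
#' @param d1,d2,d3 IP3R binding constants (uM).
#' @return list with components `alpha` and `beta` (1/s).
#' @export
h_gate_rates <- function(ip3, ca_local, a2, d1, d2, d3) {
  if (any(c(ip3, ca_local, a2, d1, d2, d3) < 0)) stop("inputs must be >= 0")
  list(alpha = a2 * d2 * (ip3 + d1) / (ip3 + d3),
       beta  = a2 * ca_local)
}

#' SERCA pump flux
#'
#' Hill-2 uptake from the facing compartment into the ER.  The pump
#' population is split by the connectivity coefficient: the cytosol-facing
#' fraction `(1 - c)` senses cytosolic calcium, the microdomain-facing
#' fraction `c` senses microdomain calcium.
#'
#' @param ca_source calcium in the facing compartment (uM).
#' @param v maximal pump flux (uM/s, cytosol-referenced).
#' @param k half-activation constant (uM).
#' @param c connectivity coefficient in `[0, 1]`.
#' @param facing_ud `TRUE` for the microdomain-facing pool.
#' @return pump flux (uM/s).
#' @export
serca_flux <- function(ca_source, v, k, c, facing_ud = FALSE) {
  if (any(k <= 0)) stop("'k' must be > 0")
  if (any(c < 0) || any(c > 1)) stop("'c' must be in [0, 1]")
  scale <- if (facing_ud) c else 1 - c
  scale * v * ca_source^2 / (k^2 + ca_source^2)
}

#' MCU voltage driving force
#'
#' The uniporter's maximal flux is `v_mcu0 * dPhi(psi)` where, with
#' `x = b F (psi - psi0) / (R T)`, the driving force is
#' `dPhi = x e^x sinh(x)`.  The inner-membrane voltage is held constant
#' in this model, so `dPhi` is a constant scalar on `v_mcu0`; the
#' expression is kept behind this one function so an alternative
#' formulation can be swapped in without touching any flux law.
#'
#' @param psi inner mitochondrial membrane voltage (mV).
#' @param psi0 offset fitting parameter (mV).
#' @param b dimensionless fitting parameter.
#' @param f Faraday constant (C/mol).
#' @param r gas constant (J/(mol K)).
#' @param t temperature (K).
#' @return dimensionless driving force.
#' @export
mcu_driving_force <- function(psi, psi0, b, f = 96485, r = 8.314, t = 310) {
  x <- b * f * (psi - psi0) * 1e-3 / (r * t)
  x * exp(x) * sinh(x)
}

#' MCU uptake flux
#'
#' Hill-2 calcium uptake into the mitochondria, driven by the constant
#' membrane-voltage factor of [mcu_driving_force()].  The channel
#' population splits between the cytosol-facing fraction `(1 - c)` and
#' the microdomain-facing fraction `c`.
#'
#' @param ca_source calcium in the facing compartment (uM).
#' @param v_mcu0 maximal flux scale (uM/s).
#' @param k half-activation constant (uM).
#' @param c connectivity coefficient in `[0, 1]`.
#' @param psi,psi0,b,f,r,t voltage-factor parameters, see
#'   [mcu_driving_force()].
#' @param facing_ud `TRUE` for the microdomain-facing pool.
#' @return uptake flux (uM/s).
#' @export
mcu_flux <- function(ca_source, v_mcu0, k, c, psi, psi0, b,
                     f = 96485, r = 8.314, t = 310, facing_ud = FALSE) {
  if (any(k <= 0)) stop("'k' must be > 0")
  if (any(c < 0) || any(c > 1)) stop("'c' must be in [0, 1]")
  scale <- if (facing_ud) c else 1 - c
  scale * v_mcu0 * mcu_driving_force(psi, psi0, b, f, r, t) *
    ca_source^2 / (k^2 + ca_source^2)
}

#' Mitochondrial Na/Ca exchanger flux
#'
#' Extrudes mitochondrial calcium in exchange for three sodium ions:
#' Hill-3 in the local sodium, Michaelis-Menten in mitochondrial calcium.
#' The cytosol-facing fraction `(1 - c)` uses cytosolic sodium, the
#' microdomain-facing fraction `c` uses microdomain sodium.
#'
#' @param ca_mt mitochondrial calcium (uM).
#' @param na_local sodium in the receiving compartment (mM).
#' @param v maximal exchanger flux (uM/s).
#' @param k_na sodium activation constant (mM).
#' @param k_ca calcium activation constant (uM).
#' @param c connectivity coefficient in `[0, 1]`.
#' @param facing_ud `TRUE` for the microdomain-facing pool.
#' @return efflux (uM/s).
#' @export
mncx_flux <- function(ca_mt, na_local, v, k_na, k_ca, c, facing_ud = FALSE) {
  if (any(k_na <= 0) || any(k_ca <= 0)) stop("'k_na' and 'k_ca' must be > 0")
  if (any(c < 0) || any(c > 1)) stop("'c' must be in [0, 1]")
  scale <- if (facing_ud) c else 1 - c
  scale * v * na_local^3 / (k_na^3 + na_local^3) * ca_mt / (k_ca + ca_mt)
}

#' Passive leak flux
#'
#' Linear in the concentration gradient, `k (ca_from - ca_to)`;
#' antisymmetric under swapping the two compartments.
#'
#' @param ca_from,ca_to calcium in the source and destination (uM).
#' @param k leak rate constant (1/s).
#' @return leak flux (uM/s), positive when flowing from `ca_from`.
#' @export
leak_flux <- function(ca_from, ca_to, k) {
  if (any(k < 0)) stop("'k' must be >= 0")
  k * (ca_from - ca_to)
}

#' All eleven model fluxes at a given state
#'
#' Evaluates every channel, pump, exchanger and leak flux of the model
#' (all referenced to the cytosolic volume): the two IP3R pools (each
#' gradient-driven with the open probability of the pool's facing
#' compartment), the two SERCA pools, the two MCU pools, the two mNCX
#' pools, and the three leaks (ER to cytosol, ER to microdomain,
#' microdomain to cytosol).
#'
#' @param state named numeric vector or list with `ca_cyt`, `ca_er`,
#'   `ca_mt`, `ca_ud`, `h`, `h_ud`.
#' @param params a `ca_params` object.
#' @return named numeric vector of the eleven fluxes (uM/s).
#' @export
compute_fluxes <- function(state, params) {
  s <- .as_state(state)
  p <- params
  po_cyt <- ip3r_open_probability(p$ip3, s[["ca_cyt"]], s[["h"]], p$d1, p$d5)
  po_ud  <- ip3r_open_probability(p$ip3, s[["ca_ud"]], s[["h_ud"]], p$d1, p$d5)
  c(j_ip3r = (1 - p$c_ip3r) * p$v_ip3r * po_cyt * (s[["ca_er"]] - s[["ca_cyt"]]),
    j_ip3r_ud = p$c_ip3r * p$v_ip3r * po_ud * (s[["ca_er"]] - s[["ca_ud"]]),
    j_serca = serca_flux(s[["ca_cyt"]], p$v_serca, p$k_serca, p$c_serca, FALSE),
    j_serca_ud = serca_flux(s[["ca_ud"]], p$v_serca, p$k_serca, p$c_serca, TRUE),
    j_mcu = mcu_flux(s[["ca_cyt"]], p$v_mcu0, p$k_mcu, p$c_mcu,
                     p$psi, p$psi0, p$b_mcu, p$faraday, p$gas_const,
                     p$temperature, FALSE),
    j_mcu_ud = mcu_flux(s[["ca_ud"]], p$v_mcu0, p$k_mcu, p$c_mcu,
                        p$psi, p$psi0, p$b_mcu, p$faraday, p$gas_const,
                        p$temperature, TRUE),
    j_mncx = mncx_flux(s[["ca_mt"]], p$na_cyt, p$v_mncx, p$k_na, p$k_mncx,
                       p$c_mncx, FALSE),
    j_mncx_ud = mncx_flux(s[["ca_mt"]], p$na_ud, p$v_mncx, p$k_na, p$k_mncx,
                          p$c_mncx, TRUE),
    j_leak_er_cyt = leak_flux(s[["ca_er"]], s[["ca_cyt"]], p$k_leak_er_cyt),
    j_leak_er_ud = leak_flux(s[["ca_er"]], s[["ca_ud"]], p$k_leak_er_ud),
    j_leak_ud_cyt = leak_flux(s[["ca_ud"]], s[["ca_cyt"]], p$k_leak_ud_cyt))
}

#' Time derivative of the six-variable model state
#'
#' Assembles the compartment balances from [compute_fluxes()]: each
#' compartment's net flux is scaled by `vol_cyt / vol_i` and divided by
#' `1 + theta_i` (fast buffering), and the two IP3R inactivation gates
#' relax with the rates of [h_gate_rates()] driven by their local calcium.
#' This reference implementation mirrors the compiled right-hand side
#' used by the integrator.
#'
#' @inheritParams compute_fluxes
#' @param inactivate_ud zero every microdomain flux and freeze its state.
#' @param inactivate_mt zero every mitochondrial flux and freeze its state.
#' @param clamp_ip3r_cyt,clamp_ip3r_ud optional constants replacing the
#'   corresponding IP3R pool flux (uM/s).
#' @return named numeric vector of the six state derivatives.
#' @export
model_rhs <- function(state, params, inactivate_ud = FALSE,
                      inactivate_mt = FALSE,
                      clamp_ip3r_cyt = NULL, clamp_ip3r_ud = NULL) {
  s <- .as_state(state)
  p <- params
  j <- compute_fluxes(s, p)
  if (!is.null(clamp_ip3r_cyt)) j[["j_ip3r"]] <- clamp_ip3r_cyt
  if (!is.null(clamp_ip3r_ud)) j[["j_ip3r_ud"]] <- clamp_ip3r_ud
  if (inactivate_ud)
    j[c("j_ip3r_ud", "j_serca_ud", "j_mcu_ud", "j_mncx_ud",
        "j_leak_er_ud", "j_leak_ud_cyt")] <- 0
  if (inactivate_mt)
    j[c("j_mcu", "j_mcu_ud", "j_mncx", "j_mncx_ud")] <- 0
  th_cyt <- buffering_factor(s[["ca_cyt"]], p$bp_cyt, p$k_buf_cyt)
  th_er  <- buffering_factor(s[["ca_er"]], p$bp_er, p$k_buf_er)
  th_mt  <- buffering_factor(s[["ca_mt"]], p$bp_mt, p$k_buf_mt)
  th_ud  <- buffering_factor(s[["ca_ud"]], p$bp_ud, p$k_buf_ud)
  d_cyt <- (j[["j_ip3r"]] + j[["j_mncx"]] + j[["j_leak_ud_cyt"]] +
            j[["j_leak_er_cyt"]] - j[["j_serca"]] - j[["j_mcu"]]) / (1 + th_cyt)
  d_er <- (p$vol_cyt / p$vol_er) *
    (j[["j_serca"]] + j[["j_serca_ud"]] - j[["j_ip3r"]] - j[["j_ip3r_ud"]] -
     j[["j_leak_er_ud"]] - j[["j_leak_er_cyt"]]) / (1 + th_er)
  d_mt <- (p$vol_cyt / p$vol_mt) *
    (j[["j_mcu"]] + j[["j_mcu_ud"]] - j[["j_mncx"]] - j[["j_mncx_ud"]]) /
    (1 + th_mt)
  d_ud <- (p$vol_cyt / p$vol_ud) *
    (j[["j_ip3r_ud"]] + j[["j_mncx_ud"]] + j[["j_leak_er_ud"]] -
     j[["j_serca_ud"]] - j[["j_mcu_ud"]] - j[["j_leak_ud_cyt"]]) / (1 + th_ud)
  g <- h_gate_rates(p$ip3, s[["ca_cyt"]], p$a2, p$d1, p$d2, p$d3)
  d_h <- g$alpha * (1 - s[["h"]]) - g$beta * s[["h"]]
  gu <- h_gate_rates(p$ip3, s[["ca_ud"]], p$a2, p$d1, p$d2, p$d3)
  d_hu <- gu$alpha * (1 - s[["h_ud"]]) - gu$beta * s[["h_ud"]]
  if (inactivate_ud) { d_ud <- 0; d_hu <- 0 }
  if (inactivate_mt) d_mt <- 0
  c(ca_cyt = d_cyt, ca_er = d_er, ca_mt = d_mt, ca_ud = d_ud,
    h = d_h, h_ud = d_hu)
}

#' Effective cytosolic calcium
#'
#' The microdomain is physically part of the cytosol, so the observable
#' plotted throughout is the volume-weighted average of the two free
#' concentrations.
#'
#' @param ca_cyt,ca_ud free calcium in cytosol and microdomain (uM).
#' @param vol_cyt,vol_ud the two volumes (um^3), not both zero.
#' @return effective concentration (uM), bounded by the two inputs.
#' @export
effective_ca <- function(ca_cyt, ca_ud, vol_cyt, vol_ud) {
  if (any(vol_cyt < 0) || any(vol_ud < 0) || any(vol_cyt + vol_ud <= 0))
    stop("volumes must be >= 0 and not both zero")
  (vol_cyt * ca_cyt + vol_ud * ca_ud) / (vol_cyt + vol_ud)
}

#' Total calcium content of a compartment
#'
#' Free plus buffer-bound calcium under the rapid-buffer model, converted
#' to femtomoles: `vol * (ca + bp * ca / (ca + k)) * 1e-6` for
#' concentrations in uM and volumes in um^3.
#'
#' @param ca free calcium (uM).
#' @param bp buffer protein concentration (uM).
#' @param k buffer dissociation constant (uM).
#' @param vol compartment volume (um^3).
#' @return total content (femtomoles).
#' @export
total_content <- function(ca, bp, k, vol) {
  if (any(k <= 0)) stop("'k' must be > 0")
  if (any(ca < 0) || any(bp < 0) || any(vol < 0)) stop("inputs must be >= 0")
  vol * (ca + bp * ca / (ca + k)) * 1e-6
}

#' Total cell calcium (free plus buffered, all compartments)
#'
#' The conserved quantity of the closed cell: the sum of
#' [total_content()] over cytosol, ER, mitochondria and microdomain.
#'
#' @param state model state (see [compute_fluxes()]).
#' @param params a `ca_params` object.
#' @return total cell calcium (femtomoles).
#' @export
total_cell_ca <- function(state, params) {
  s <- .as_state(state)
  p <- params
  total_content(s[["ca_cyt"]], p$bp_cyt, p$k_buf_cyt, p$vol_cyt) +
    total_content(s[["ca_er"]], p$bp_er, p$k_buf_er, p$vol_er) +
    total_content(s[["ca_mt"]], p$bp_mt, p$k_buf_mt, p$vol_mt) +
    total_content(s[["ca_ud"]], p$bp_ud, p$k_buf_ud, p$vol_ud)
}

.as_state <- function(state) {
  s <- unlist(state)
  if (is.null(names(s)) && length(s) == 6) names(s) <- .state_names
  miss <- setdiff(.state_names, names(s))
  if (length(miss)) stop("state is missing: ", paste(miss, collapse = ", "))
  s[.state_names]
}
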