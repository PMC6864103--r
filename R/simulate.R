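# Packing order must match src/ca_rhs.c.
.pack_parms <- function(p, inactivate_ud = FALSE, inactivate_mt = FALSE,
                        clamp_cyt = NULL, clamp_ud = NULL) {
  v <- vapply(.param_names, function(nm) as.numeric(p[[nm]]), numeric(1))
  c(v, vol_ud = p$vol_ud,
    inact_ud = as.numeric(inactivate_ud), inact_mt = as.numeric(inactivate_mt),
    clamp_c_on = as.numeric(!is.null(clamp_cyt)),
    clamp_c_v = if (is.null(clamp_cyt)) 0 else clamp_cyt,
    clamp_u_on = as.numeric(!is.null(clamp_ud)),
    clamp_u_v = if (is.null(clamp_ud)) 0 else clamp_ud)
}

.flux_names <- c("j_ip3r", "j_ip3r_ud", "j_serca", "j_serca_ud",
                 "j_mcu", "j_mcu_ud", "j_mncx", "j_mncx_ud",
                 "j_leak_er_cyt", "j_leak_er_ud", "j_leak_ud_cyt")

.integrate <- function(y0, times, p, rtol, atol, inactivate_ud = FALSE,
                       inactivate_mt = FALSE, clamp_cyt = NULL,
                       clamp_ud = NULL) {
  out <- deSolve::ode(
    y = unname(y0[.state_names]), times = times, func = "ca_derivs",
    parms = .pack_parms(p, inactivate_ud, inactivate_mt, clamp_cyt, clamp_ud),
    dllname = "microca", initfunc = "ca_initmod",
    nout = 11L, outnames = .flux_names,
    method = "lsoda", rtol = rtol, atol = atol, maxsteps = 50000L)
  if (attr(out, "istate")[1] < 0)
    stop("integration failed at t = ", max(out[, 1]),
         " (istate ", attr(out, "istate")[1], "); see diagnostics(out)")
  colnames(out)[2:7] <- .state_names
  # lsoda may undershoot zero by ~atol; clip the dust, flag real excursions
  st <- out[, 2:7]
  if (any(st < -1e-6))
    stop("state went negative beyond solver tolerance (min ",
         format(min(st)), "); tighten rtol/atol")
  st[st < 0] <- 0
  out[, 2:7] <- st
  out
}

#' Default initial state guess for rest-state relaxation
#'
#' A physiologically plausible starting point (cytosolic calcium near
#' 0.1 uM, a loaded ER, gates at their no-calcium fixed point) from which
#' the closed cell is relaxed to rest.  The rest state itself depends on
#' the total calcium this guess implies, since the cell is closed.
#'
#' @param ca_cyt,ca_er,ca_mt,ca_ud starting free calcium levels (uM).
#' @return named state vector.
#' @export
initial_state_guess <- function(ca_cyt = 0.1, ca_er = 400, ca_mt = 0.1,
                                ca_ud = 0.1) {
  c(ca_cyt = ca_cyt, ca_er = ca_er, ca_mt = ca_mt, ca_ud = ca_ud,
    h = 0.9, h_ud = 0.9)
}

#' Find the pre-stimulus resting state
#'
#' Relaxes the model for `t_relax` seconds at the basal IP3 level, then
#' polishes the end point with damped Newton iterations on the full
#' right-hand side (using a pseudo-inverse, since the closed cell has a
#' conserved total-calcium direction along which the Jacobian is
#' singular).
#'
#' @param params a `ca_params` object.
#' @param ip3_basal basal IP3 level (uM); 0 by default, giving a
#'   quiescent cell.
#' @param y0 initial guess; defaults to [initial_state_guess()].
#' @param t_relax relaxation horizon (s).
#' @param tol convergence tolerance on `max(abs(rhs))` (uM/s).
#' @param inactivate_ud,inactivate_mt compartment inactivation flags
#'   (frozen compartments keep their `y0` values).
#' @return named state vector at rest, with attribute `"residual"`.
#' @export
find_rest_state <- function(params, ip3_basal = 0, y0 = initial_state_guess(),
                            t_relax = 2000, tol = 1e-8,
                            inactivate_ud = FALSE, inactivate_mt = FALSE) {
  p <- ca_parameters(ip3 = ip3_basal, base = params)
  out <- .integrate(y0, c(0, t_relax), p, rtol = 1e-10, atol = 1e-12,
                    inactivate_ud = inactivate_ud,
                    inactivate_mt = inactivate_mt)
  y <- pmax(out[nrow(out), .state_names], 0)
  free <- !(c(FALSE, FALSE, inactivate_mt, inactivate_ud,
              FALSE, inactivate_ud))
  f <- function(s) model_rhs(s, p, inactivate_ud, inactivate_mt)
  for (it in 1:50) {
    r <- f(y)
    if (max(abs(r)) < tol) break
    J <- matrix(0, 6, 6)
    for (j in which(free)) {
      dy <- max(1e-7, abs(y[j]) * 1e-7)
      yp <- y; yp[j] <- yp[j] + dy
      J[, j] <- (f(yp) - r) / dy
    }
    sv <- svd(J[free, free, drop = FALSE])
    keep <- sv$d > max(sv$d) * 1e-10
    step <- sv$v[, keep, drop = FALSE] %*%
      ((t(sv$u[, keep, drop = FALSE]) %*% r[free]) / sv$d[keep])
    lambda <- 1
    repeat {
      ytry <- y
      ytry[free] <- pmax(y[free] - lambda * step, 0)
      if (max(abs(f(ytry))) < max(abs(r)) || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    y <- ytry
  }
  r <- f(y)
  if (max(abs(r)) > tol)
    stop(sprintf(paste0("rest state did not converge: max |rhs| = %.3g uM/s ",
                        "after %g s relaxation + Newton polish"),
                 max(abs(r)), t_relax))
  attr(y, "residual") <- max(abs(r))
  y
}

#' Define a stimulation protocol
#'
#' A protocol holds everything one run needs besides the parameter set:
#' the IP3 step (basal level, stimulated level, onset time), the horizon,
#' named parameter overrides (e.g. `v_mcu0 = 0` for an MCU knockout),
#' compartment inactivation flags, and an optional IP3R flux clamp.
#'
#' @param ip3_post stimulated IP3 level (uM), applied at `t_step`.
#' @param ip3_pre basal IP3 level before the step (uM).
#' @param t_step stimulus onset (s), `0 <= t_step < t_end`.
#' @param t_end end of the run (s).
#' @param overrides named list of parameter replacements.
#' @param inactivate_ud,inactivate_mt zero all fluxes entering/leaving
#'   the compartment and freeze its state.
#' @param clamp optional clamp specification from [clamp_spec()].
#' @return an object of class `ca_protocol`.
#' @export
ca_protocol <- function(ip3_post, ip3_pre = 0, t_step = 50, t_end = 600,
                        overrides = list(), inactivate_ud = FALSE,
                        inactivate_mt = FALSE, clamp = NULL) {
  if (!(t_step >= 0 && t_step < t_end))
    stop("need 0 <= t_step < t_end")
  if (length(overrides)) {
    bad <- setdiff(names(overrides), c(.param_names, "vol_ud"))
    if (length(bad))
      stop("overrides name unknown parameter(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(clamp) && !inherits(clamp, "ca_clamp"))
    stop("'clamp' must come from clamp_spec()")
  structure(list(ip3_pre = ip3_pre, ip3_post = ip3_post, t_step = t_step,
                 t_end = t_end, overrides = overrides,
                 inactivate_ud = inactivate_ud, inactivate_mt = inactivate_mt,
                 clamp = clamp),
            class = "ca_protocol")
}

#' Specify an IP3R flux clamp
#'
#' Replaces one IP3R pool's flux by a constant from the stimulus onset
#' onwards, abolishing its periodic opening while maintaining the same
#' average ER efflux.  With `value = "auto"` the constant is the
#' time-average of that flux over the last complete oscillation cycle of
#' a control run (see [run_clamped()]).
#'
#' @param target `"ip3r_cyt"` or `"ip3r_ud"`.
#' @param value non-negative clamp level (uM/s), or `"auto"`.
#' @return an object of class `ca_clamp`.
#' @export
clamp_spec <- function(target = c("ip3r_cyt", "ip3r_ud"), value = "auto") {
  target <- match.arg(target)
  if (!identical(value, "auto")) {
    if (!is.numeric(value) || length(value) != 1 || value < 0)
      stop("explicit clamp value must be a single number >= 0")
  }
  structure(list(target = target, value = value), class = "ca_clamp")
}

#' Run a stimulation protocol
#'
#' Starts from the rest state for the basal IP3 level, integrates to the
#' stimulus onset, switches IP3 to the stimulated level and integrates to
#' the horizon with a stiff solver, reporting on a uniform grid.  The
#' returned trajectory carries the six state variables, the effective
#' cytosolic calcium, the full flux breakdown and the per-compartment
#' total calcium content at every sample.
#'
#' @param params a `ca_params` object.
#' @param protocol a `ca_protocol` object.
#' @param dt reporting interval (s).
#' @param rtol,atol solver tolerances.
#' @param rest optional precomputed rest state (skips equilibration).
#' @return an object of class `ca_traj`.
#' @export
run_protocol <- function(params, protocol, dt = 0.1, rtol = 1e-8,
                         atol = 1e-10, rest = NULL) {
  stopifnot(inherits(protocol, "ca_protocol"))
  p <- do.call(ca_parameters, c(protocol$overrides, list(base = params)))
  clamp_cyt <- clamp_ud <- NULL
  if (!is.null(protocol$clamp)) {
    if (identical(protocol$clamp$value, "auto"))
      stop("clamp value 'auto' requires run_clamped()")
    if (protocol$clamp$target == "ip3r_cyt") clamp_cyt <- protocol$clamp$value
    else clamp_ud <- protocol$clamp$value
  }
  pre <- ca_parameters(ip3 = protocol$ip3_pre, base = p)
  if (is.null(rest))
    rest <- find_rest_state(pre, ip3_basal = protocol$ip3_pre,
                            inactivate_ud = protocol$inactivate_ud,
                            inactivate_mt = protocol$inactivate_mt)
  t1 <- seq(0, protocol$t_step, by = dt)
  t2 <- seq(protocol$t_step, protocol$t_end, by = dt)
  args <- list(rtol = rtol, atol = atol,
               inactivate_ud = protocol$inactivate_ud,
               inactivate_mt = protocol$inactivate_mt)
  out1 <- if (length(t1) > 1)
    do.call(.integrate, c(list(rest, t1, pre), args)) else NULL
  y_step <- if (is.null(out1)) rest else out1[nrow(out1), .state_names]
  post <- ca_parameters(ip3 = protocol$ip3_post, base = p)
  out2 <- do.call(.integrate, c(list(y_step, t2, post), args,
                                list(clamp_cyt = clamp_cyt,
                                     clamp_ud = clamp_ud)))
  m <- if (is.null(out1)) out2 else rbind(out1[-nrow(out1), ], out2)
  state <- m[, .state_names, drop = FALSE]
  fluxes <- m[, .flux_names, drop = FALSE]
  content <- cbind(
    cyt = total_content(state[, "ca_cyt"], p$bp_cyt, p$k_buf_cyt, p$vol_cyt),
    er = total_content(state[, "ca_er"], p$bp_er, p$k_buf_er, p$vol_er),
    mt = total_content(state[, "ca_mt"], p$bp_mt, p$k_buf_mt, p$vol_mt),
    ud = total_content(state[, "ca_ud"], p$bp_ud, p$k_buf_ud, p$vol_ud))
  structure(list(time = m[, 1], state = state, fluxes = fluxes,
                 ca_eff = effective_ca(state[, "ca_cyt"], state[, "ca_ud"],
                                       p$vol_cyt, p$vol_ud),
                 content = content, params = p, protocol = protocol,
                 solver = list(dt = dt, rtol = rtol, atol = atol)),
            class = "ca_traj")
}

#' Run a protocol with an IP3R pool clamped to its cycle average
#'
#' Two-pass clamping: pass one runs the unclamped control protocol and
#' averages the target IP3R flux over the last complete peak-to-peak
#' oscillation cycle within the final quarter of the run; pass two
#' re-integrates with that flux replaced by the constant from the
#' stimulus onset.  With an explicit clamp value the first pass is
#' skipped.
#'
#' @inheritParams run_protocol
#' @return a `ca_traj` with attributes `"clamp_value"` and (for auto
#'   clamps) `"control"` holding the pass-one trajectory.
#' @export
run_clamped <- function(params, protocol, dt = 0.1, rtol = 1e-8,
                        atol = 1e-10) {
  stopifnot(inherits(protocol, "ca_protocol"))
  if (is.null(protocol$clamp)) stop("protocol has no clamp specification")
  value <- protocol$clamp$value
  control <- NULL
  if (identical(value, "auto")) {
    ctrl_proto <- protocol
    ctrl_proto$clamp <- NULL
    control <- run_protocol(params, ctrl_proto, dt = dt, rtol = rtol,
                            atol = atol)
    det <- detect_oscillations(control$time, control$ca_eff,
                               transient_cut = cycle_window_start(control))
    if (!det$sustained || length(det$peak_times) < 2)
      stop("auto clamp needs a sustained oscillatory control run")
    pk <- det$peak_times
    t0 <- pk[length(pk) - 1]; t1 <- pk[length(pk)]
    fx <- if (protocol$clamp$target == "ip3r_cyt") "j_ip3r" else "j_ip3r_ud"
    sel <- control$time >= t0 & control$time <= t1
    value <- mean(control$fluxes[sel, fx])
  }
  proto2 <- protocol
  proto2$clamp <- clamp_spec(protocol$clamp$target, value)
  traj <- run_protocol(params, proto2, dt = dt, rtol = rtol, atol = atol)
  attr(traj, "clamp_value") <- value
  attr(traj, "control") <- control
  traj
}

# Start of the "late" window (final 25%) used for cycle selection.
cycle_window_start <- function(traj) {
  t <- traj$time
  t[length(t)] - 0.25 * (t[length(t)] - traj$protocol$t_step)
}

#' @export
print.ca_traj <- function(x, ...) {
  pr <- x$protocol
  cat(sprintf("Calcium trajectory: %d samples over %g s (dt %g s)\n",
              length(x$time), max(x$time), x$solver$dt))
  cat(sprintf("  IP3 step %g -> %g uM at t = %g s\n",
              pr$ip3_pre, pr$ip3_post, pr$t_step))
  if (pr$inactivate_ud) cat("  microdomain inactivated\n")
  if (pr$inactivate_mt) cat("  mitochondria inactivated\n")
  if (!is.null(pr$clamp))
    cat(sprintf("  clamp: %s\n", pr$clamp$target))
  rng <- range(x$ca_eff)
  cat(sprintf("  effective [Ca]: %.3g .. %.3g uM\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
as.data.frame.ca_traj <- function(x, ...) {
  data.frame(time = x$time, x$state, ca_eff = x$ca_eff, x$fluxes,
             content_cyt = x$content[, "cyt"], content_er = x$content[, "er"],
             content_mt = x$content[, "mt"], content_ud = x$content[, "ud"])
}

#' @export
plot.ca_traj <- function(x, which = c("ca_eff", "state", "content"), ...) {
  which <- match.arg(which)
  if (which == "ca_eff") {
    plot(x$time, x$ca_eff, type = "l", xlab = "time (s)",
         ylab = "effective [Ca] (uM)", ...)
    abline(v = x$protocol$t_step, lty = 3)
  } else if (which == "state") {
    op <- par(mfrow = c(2, 2), mar = c(4, 4, 1, 1))
    on.exit(par(op))
    for (nm in c("ca_cyt", "ca_er", "ca_mt", "ca_ud"))
      plot(x$time, x$state[, nm], type = "l", xlab = "time (s)",
           ylab = paste0(nm, " (uM)"))
  } else {
    matplot(x$time, x$content, type = "l", lty = 1, xlab = "time (s)",
            ylab = "total Ca content (fmol)", ...)
    legend("topright", legend = colnames(x$content), col = 1:4, lty = 1,
           bty = "n")
  }
  invisible(x)
}

#' Write a trajectory as CSV plus a JSON sidecar
#'
#' The CSV holds one row per sample with labelled columns (state, fluxes,
#' effective calcium, contents); the sidecar records the protocol, a hash
#' of the parameter set and the solver settings, enough to reproduce the
#' run.
#'
#' @param traj a `ca_traj`.
#' @param path output CSV path; the sidecar is written next to it with
#'   extension `.json`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  side <- sub("\\.csv$", ".json", path)
  if (identical(side, path)) side <- paste0(path, ".json")
  pr <- traj$protocol
  manifest <- list(
    protocol = list(ip3_pre = pr$ip3_pre, ip3_post = pr$ip3_post,
                    t_step = pr$t_step, t_end = pr$t_end,
                    overrides = pr$overrides,
                    inactivate_ud = pr$inactivate_ud,
                    inactivate_mt = pr$inactivate_mt,
                    clamp = if (!is.null(pr$clamp)) unclass(pr$clamp)),
    parameter_hash = hash_parameters(traj$params),
    solver = traj$solver,
    package_version = as.character(utils::packageVersion("microca")))
  jsonlite::write_json(manifest, side, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Stable digest of a parameter set
#'
#' @param p a `ca_params` object.
#' @return md5 digest string of the canonical parameter serialization.
#' @export
hash_parameters <- function(p) {
  txt <- paste(sprintf("%s=%.17g", c(.param_names, "vol_ud"),
                       vapply(c(.param_names, "vol_ud"),
                              function(nm) as.numeric(p[[nm]]), numeric(1))),
               collapse = ";")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}
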