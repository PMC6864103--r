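# Apply one swept value to (params, protocol).  "ip3" sweeps the
# stimulated level; "d_er_mt" re-derives the microdomain volume; any
# other name is an ordinary parameter replacement.
.apply_sweep <- function(params, protocol, name, value) {
  if (name == "ip3") {
    protocol$ip3_post <- value
  } else {
    ov <- protocol$overrides
    ov[[name]] <- value
    protocol$overrides <- ov
  }
  list(params = params, protocol = protocol)
}

.point_metrics <- function(params, protocol, dt, rtol, atol,
                           envelope_frac = 0.4) {
  traj <- run_protocol(params, protocol, dt = dt, rtol = rtol, atol = atol)
  met <- oscillation_metrics(traj, classify = FALSE)
  tail_sel <- traj$time >= traj$time[length(traj$time)] -
    envelope_frac * (traj$protocol$t_end - traj$protocol$t_step)
  list(sustained = met$sustained, frequency = met$frequency,
       amplitude = met$peak_amplitude[["cyt"]],
       env_max = max(traj$ca_eff[tail_sel]),
       env_min = min(traj$ca_eff[tail_sel]))
}

#' One-dimensional bifurcation scan
#'
#' Runs the protocol at every grid value of one swept quantity (the
#' stimulated IP3 level or any model parameter), records oscillation
#' metrics and the post-transient envelope of the effective cytosolic
#' calcium, and refines every boundary where the sustained flag flips by
#' bisection.  Boundaries delimit the Hopf windows of the model; the
#' scan is the brute-force counterpart of a continuation diagram.
#'
#' @param params a `ca_params` object.
#' @param name swept quantity: `"ip3"` or a parameter name (sweeping
#'   `"d_er_mt"` re-derives the microdomain volume at every point).
#' @param grid strictly increasing numeric grid with at least 3 points.
#' @param protocol protocol template (its `ip3_post` is overridden when
#'   sweeping IP3).
#' @param refine_tol bisection tolerance on the swept value; `NULL`
#'   defaults to 1/50 of the grid span. Set `refine = FALSE` to skip.
#' @param refine whether to bisect the window boundaries.
#' @param dt,rtol,atol solver settings per point.
#' @return an object of class `ca_scan`: a data.frame of per-point
#'   metrics (`value`, `sustained`, `frequency`, `amplitude`, `env_max`,
#'   `env_min`, `failed`) with the refined `boundaries` as an attribute.
#' @export
scan_1d <- function(params, name, grid, protocol, refine = TRUE,
                    refine_tol = NULL, dt = 0.1, rtol = 1e-8, atol = 1e-10) {
  if (length(grid) < 3 || is.unsorted(grid, strictly = TRUE))
    stop("'grid' must be strictly increasing with >= 3 points")
  rows <- lapply(grid, function(v) {
    sw <- .apply_sweep(params, protocol, name, v)
    res <- tryCatch(.point_metrics(sw$params, sw$protocol, dt, rtol, atol),
                    error = function(e)
                      list(sustained = NA, frequency = NA_real_,
                           amplitude = NA_real_, env_max = NA_real_,
                           env_min = NA_real_, error = conditionMessage(e)))
    data.frame(value = v, sustained = isTRUE(res$sustained),
               frequency = res$frequency %||% NA_real_,
               amplitude = res$amplitude, env_max = res$env_max,
               env_min = res$env_min,
               failed = !is.null(res$error))
  })
  df <- do.call(rbind, rows)
  bounds <- NULL
  if (refine) {
    if (is.null(refine_tol)) refine_tol <- diff(range(grid)) / 50
    flips <- which(diff(df$sustained) != 0 & !df$failed[-nrow(df)] &
                     !df$failed[-1])
    bounds <- vapply(flips, function(i) {
      lo <- grid[i]; hi <- grid[i + 1]
      lo_s <- df$sustained[i]
      while (hi - lo > refine_tol) {
        mid <- (lo + hi) / 2
        sw <- .apply_sweep(params, protocol, name, mid)
        s <- tryCatch(.point_metrics(sw$params, sw$protocol, dt, rtol,
                                     atol)$sustained,
                      error = function(e) NA)
        if (is.na(s)) break
        if (s == lo_s) lo <- mid else hi <- mid
      }
      (lo + hi) / 2
    }, numeric(1))
  }
  structure(df, class = c("ca_scan", "data.frame"),
            name = name, boundaries = bounds, refine_tol = refine_tol)
}

#' Oscillation windows of a 1-D scan
#'
#' @param scan a `ca_scan` from [scan_1d()].
#' @return data.frame with one row per contiguous sustained window
#'   (`lower`, `upper`), using refined boundaries where available.
#' @export
scan_windows <- function(scan) {
  s <- scan$sustained
  v <- scan$value
  b <- attr(scan, "boundaries")
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- list()
  bi <- 1
  lower_of <- function(i) {
    if (i == 1) return(v[1])
    b[sum(which(diff(s) != 0) < i)]
  }
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    i0 <- starts[k]; i1 <- ends[k]
    lo <- if (i0 == 1) v[1] else {
      idx <- which(diff(s) != 0)
      pos <- match(i0 - 1, idx)
      if (!is.null(b) && !is.na(pos) && pos <= length(b)) b[pos] else v[i0 - 1]
    }
    hi <- if (i1 == length(v)) v[length(v)] else {
      idx <- which(diff(s) != 0)
      pos <- match(i1, idx)
      if (!is.null(b) && !is.na(pos) && pos <= length(b)) b[pos] else v[i1 + 1]
    }
    out[[length(out) + 1]] <- data.frame(lower = lo, upper = hi)
  }
  if (!length(out))
    return(data.frame(lower = numeric(0), upper = numeric(0)))
  do.call(rbind, out)
}

#' @export
print.ca_scan <- function(x, ...) {
  cat(sprintf("1-D scan over '%s' (%d points, %d sustained)\n",
              attr(x, "name"), nrow(x), sum(x$sustained)))
  w <- scan_windows(x)
  if (nrow(w))
    for (i in seq_len(nrow(w)))
      cat(sprintf("  window %d: [%.4g, %.4g]\n", i, w$lower[i], w$upper[i]))
  invisible(x)
}

#' Two-dimensional frequency heatmap
#'
#' Runs the protocol on the tensor grid of two swept quantities and
#' returns the oscillation-frequency matrix (0 where not sustained, NA
#' where the solve failed).  Sweeping `d_er_mt` re-derives the
#' microdomain volume at every point and respects the 10 nm floor.
#'
#' @param params a `ca_params` object.
#' @param name_x,grid_x,name_y,grid_y the two swept quantities and grids
#'   (see [scan_1d()]); a 1-row or 1-column scan reproduces [scan_1d()]
#'   on the other axis.
#' @param protocol protocol template.
#' @param dt,rtol,atol solver settings per point.
#' @return an object of class `ca_heatmap`: list with `x`, `y`,
#'   `frequency` (matrix `length(grid_x)` x `length(grid_y)`),
#'   `sustained`, and per-point amplitude matrices.
#' @export
scan_2d <- function(params, name_x, grid_x, name_y, grid_y, protocol,
                    dt = 0.1, rtol = 1e-8, atol = 1e-10) {
  if (is.unsorted(grid_x, strictly = TRUE) ||
      is.unsorted(grid_y, strictly = TRUE))
    stop("grids must be strictly increasing")
  freq <- sus <- amp <- matrix(NA_real_, length(grid_x), length(grid_y))
  for (j in seq_along(grid_y)) {
    swy <- .apply_sweep(params, protocol, name_y, grid_y[j])
    for (i in seq_along(grid_x)) {
      sw <- .apply_sweep(swy$params, swy$protocol, name_x, grid_x[i])
      res <- tryCatch(.point_metrics(sw$params, sw$protocol, dt, rtol, atol),
                      error = function(e) NULL)
      if (is.null(res)) next
      sus[i, j] <- as.numeric(res$sustained)
      freq[i, j] <- if (res$sustained) res$frequency else 0
      amp[i, j] <- res$amplitude
    }
  }
  structure(list(x = grid_x, y = grid_y, frequency = freq,
                 sustained = sus, amplitude = amp,
                 name_x = name_x, name_y = name_y),
            class = "ca_heatmap")
}

#' @export
print.ca_heatmap <- function(x, ...) {
  cat(sprintf("Frequency heatmap %s x %s (%d x %d points)\n",
              x$name_x, x$name_y, length(x$x), length(x$y)))
  cat(sprintf("  sustained at %d / %d points; freq range %.3g .. %.3g /min\n",
              sum(x$sustained == 1, na.rm = TRUE), length(x$sustained),
              min(x$frequency[x$sustained == 1], na.rm = TRUE),
              max(x$frequency[x$sustained == 1], na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.ca_heatmap <- function(x, ...) {
  image(x$x, x$y, x$frequency, xlab = x$name_x, ylab = x$name_y,
        col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Frequency response to MCU activity, including the knockout endpoint
#'
#' Scales the uniporter flux `v_mcu0` by each grid factor (the grid must
#' include 0, the knockout, and 1, the control) and reports the
#' oscillation frequency at the given IP3 level, flagging the scalings
#' where oscillations are lost.
#'
#' @param params a `ca_params` object.
#' @param ip3 stimulated IP3 level (uM).
#' @param scalings multiplicative grid on `v_mcu0`, containing 0 and 1.
#' @param protocol optional protocol template; by default a standard
#'   step protocol at `ip3`.
#' @param dt,rtol,atol solver settings.
#' @return a `ca_scan` data.frame over the scaling grid, with the
#'   absolute `v_mcu0` values in column `v_mcu0`.
#' @export
vmcu_sweep <- function(params, ip3, scalings = c(0, 0.25, 0.5, 0.75, 1,
                                                 1.5, 2),
                       protocol = NULL, dt = 0.1, rtol = 1e-8, atol = 1e-10) {
  if (!any(scalings == 0) || !any(scalings == 1))
    stop("'scalings' must include 0 (knockout) and 1 (control)")
  if (is.null(protocol)) protocol <- ca_protocol(ip3_post = ip3)
  sc <- scan_1d(params, "v_mcu0", sort(scalings) * params$v_mcu0,
                protocol, refine = FALSE, dt = dt, rtol = rtol, atol = atol)
  sc$v_mcu0 <- sc$value
  sc$value <- sc$v_mcu0 / params$v_mcu0
  attr(sc, "name") <- "v_mcu0 scaling"
  sc
}
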