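#' Detect sustained oscillations in a trace
#'
#' Peaks are local maxima passing a prominence floor (by default 2
#' percent of the post-transient range).  A trace is called sustained
#' when at least four post-transient peaks remain and the amplitudes of
#' consecutive late peaks (measured from the post-transient minimum)
#' vary by less than `amp_tol`; damped transients and flat traces fail
#' one of the two conditions.
#'
#' @param time sample times (s), strictly increasing.
#' @param x trace values.
#' @param transient_cut discard samples before this time (s).
#' @param prominence_frac prominence floor as a fraction of the
#'   post-transient range.
#' @param amp_tol maximal relative variation between consecutive late
#'   peak amplitudes.
#' @param min_peaks minimum number of post-transient peaks.
#' @param min_range_frac the post-transient excursion must exceed this
#'   fraction of the full trace's range to count as sustained; this
#'   separates a residual numerical ripple riding on a decayed transient
#'   from a genuine limit cycle, while keeping the classification
#'   invariant under amplitude scaling of the whole trace.
#' @return list with `sustained` (flag), `peak_times` (s) and
#'   `peak_values`.
#' @export
detect_oscillations <- function(time, x, transient_cut = 0,
                                prominence_frac = 0.02, amp_tol = 0.05,
                                min_peaks = 4, min_range_frac = 0.02) {
  if (length(time) != length(x)) stop("'time' and 'x' lengths differ")
  if (transient_cut >= time[length(time)])
    stop("trace ends before 'transient_cut'")
  sel <- time >= transient_cut
  if (sum(sel) < 10) stop("too few samples after 'transient_cut'")
  ts <- time[sel]; xs <- x[sel]
  rng <- diff(range(xs))
  full_rng <- diff(range(x))
  if (rng <= .Machine$double.eps * max(1, abs(xs[1])) ||
      rng < min_range_frac * full_rng)
    return(list(sustained = FALSE, peak_times = numeric(0),
                peak_values = numeric(0)))
  idx <- .local_maxima(xs)
  if (length(idx)) {
    prom <- .prominence(xs, idx)
    idx <- idx[prom >= prominence_frac * rng]
  }
  if (length(idx) < min_peaks)
    return(list(sustained = FALSE, peak_times = ts[idx],
                peak_values = xs[idx]))
  floorv <- min(xs)
  late <- utils::tail(xs[idx] - floorv, min_peaks)
  dif <- abs(diff(late)) / pmax(abs(late[-length(late)]),
                                .Machine$double.eps)
  list(sustained = all(dif < amp_tol), peak_times = ts[idx],
       peak_values = xs[idx])
}

.local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

# Prominence of each candidate peak: height above the higher of the two
# valley floors separating it from taller terrain (or the trace edge).
.prominence <- function(x, idx) {
  vapply(idx, function(i) {
    h <- x[i]
    left <- x[seq_len(i - 1)]
    hi <- which(left > h)
    lmin <- min(left[seq.int(from = if (length(hi)) max(hi) else 1,
                             to = i - 1)])
    right <- x[seq.int(i + 1, length(x))]
    hi <- which(right > h)
    rmin <- min(right[seq.int(1, if (length(hi)) min(hi) else length(right))])
    h - max(lmin, rmin)
  }, numeric(1))
}

#' Oscillation frequency from peak times
#'
#' @param peak_times peak times in seconds (at least two).
#' @return frequency in oscillations per minute: `60 / mean inter-peak
#'   interval`; `NA` with a warning when fewer than two peaks are given.
#' @export
frequency_of <- function(peak_times) {
  if (length(peak_times) < 2) {
    warning("fewer than 2 peaks; frequency undefined")
    return(NA_real_)
  }
  60 / mean(diff(peak_times))
}

#' Normalize a trace to its basal-to-extreme range
#'
#' Affine map sending the pre-stimulus basal level to 0 and the
#' post-stimulus extreme (the sample farthest from basal, which is a
#' minimum for an emptying store such as the ER) to 1.  Used to compare
#' the timing of compartments whose calcium levels differ by orders of
#' magnitude.
#'
#' @param x trace values.
#' @param basal pre-stimulus basal level.
#' @return normalized series; 0 at basal, 1 at the extreme.
#' @export
normalize_relative <- function(x, basal) {
  dev <- x - basal
  ext <- dev[which.max(abs(dev))]
  if (abs(ext) <= .Machine$double.eps * max(1, abs(basal)))
    stop("trace extreme equals the basal level; nothing to normalize")
  dev / ext
}

#' Refilling/emptying phases and peak order within one cycle
#'
#' Segments each compartment's raw calcium trace over one complete
#' post-transient cycle by the sign of its slope: a positive raw slope
#' means the net calcium flux into that compartment is inward
#' ("refilling"), a negative slope outward ("emptying"), so the phase
#' signs agree with the compartment's net flux balance.  Peak order is
#' reported on the basal-referenced normalized traces
#' ([normalize_relative()]), where a store's "peak" is its extreme
#' deviation from basal -- for an emptying store such as the ER that is
#' the raw minimum.
#'
#' @param traj a `ca_traj` from [run_protocol()].
#' @param cycle numeric length-2 window `(t0, t1)` delimiting one cycle;
#'   `NULL` picks the last complete peak-to-peak cycle of the effective
#'   calcium trace in the final quarter of the run.
#' @param compartments which compartments to analyse.
#' @return list with `cycle`, `peak_order` (compartment labels sorted by
#'   peak time), `phases` (per compartment, a data.frame of refilling /
#'   emptying intervals) and `normalized` (the normalized cycle traces).
#' @export
classify_phases <- function(traj, cycle = NULL,
                            compartments = c("cyt", "er", "mt", "ud")) {
  stopifnot(inherits(traj, "ca_traj"))
  if (is.null(cycle)) {
    det <- detect_oscillations(traj$time, traj$ca_eff,
                               transient_cut = cycle_window_start(traj))
    if (length(det$peak_times) < 2)
      stop("no complete post-transient cycle found")
    n <- length(det$peak_times)
    cycle <- c(det$peak_times[n - 1], det$peak_times[n])
  }
  sel <- traj$time >= cycle[1] & traj$time <= cycle[2]
  if (sum(sel) < 5) stop("cycle window contains too few samples")
  basal <- .basal_levels(traj)
  cols <- c(cyt = "ca_cyt", er = "ca_er", mt = "ca_mt", ud = "ca_ud")
  tt <- traj$time[sel]
  raw <- lapply(compartments, function(cp) {
    if (cp == "cyt") traj$ca_eff[sel] else traj$state[sel, cols[cp]]
  })
  names(raw) <- compartments
  norm <- lapply(compartments, function(cp)
    normalize_relative(raw[[cp]], basal[cp]))
  names(norm) <- compartments
  peak_t <- vapply(norm, function(v) tt[which.max(v)], numeric(1))
  phases <- lapply(raw, function(v) {
    sl <- sign(diff(v))
    brk <- c(1, which(diff(sl) != 0) + 1, length(sl) + 1)
    data.frame(start = tt[brk[-length(brk)]],
               end = tt[brk[-1]],
               phase = ifelse(sl[brk[-length(brk)]] >= 0,
                              "refilling", "emptying"))
  })
  list(cycle = cycle,
       peak_order = names(sort(peak_t)),
       peak_times = sort(peak_t),
       phases = phases,
       raw = c(list(time = tt), raw),
       normalized = c(list(time = tt), norm))
}

.basal_levels <- function(traj) {
  pre <- traj$time < traj$protocol$t_step
  if (!any(pre)) pre <- seq_len(min(5, length(traj$time)))
  c(cyt = mean(traj$ca_eff[pre]),
    er = mean(traj$state[pre, "ca_er"]),
    mt = mean(traj$state[pre, "ca_mt"]),
    ud = mean(traj$state[pre, "ca_ud"]))
}

#' Which stores feed the cytosol between spikes
#'
#' During the interspike interval (the part of the cycle where the
#' normalized effective-cytosol trace sits below the burst threshold),
#' a store counts as a feeder when its raw calcium falls (negative
#' slope, i.e. the store is emptying) while the cytosol refills
#' (positive slope), with a mean slope magnitude above `slope_frac` of
#' the store's own cycle range per period to exclude numerically flat
#' stores.
#'
#' @param traj a `ca_traj` with sustained oscillations.
#' @param burst_threshold normalized level separating burst from
#'   interspike interval.
#' @param slope_frac minimal mean slope magnitude (fraction of
#'   range/period) to count as feeding.
#' @return one of `"ER_feeding"`, `"Mt_feeding"`, `"ER_and_Mt_feeding"`,
#'   `"none"`.
#' @export
classify_feeder_mode <- function(traj, burst_threshold = 0.5,
                                 slope_frac = 0.01) {
  ph <- classify_phases(traj)
  tt <- ph$normalized$time
  cyt <- ph$normalized$cyt
  period <- diff(ph$cycle)
  inter <- cyt < burst_threshold
  if (sum(inter) < 5) return("none")
  refill <- inter & c(diff(cyt) > 0, FALSE)
  if (sum(refill) < 3) return("none")
  # a store feeds when its raw calcium falls while the cytosol rises;
  # the slope floor is 1% of the store's own cycle range per period
  feeders <- character(0)
  for (st in c("er", "mt")) {
    v <- ph$raw[[st]]
    rng <- diff(range(v))
    if (rng <= 0) next
    slope <- mean(diff(v[refill]) / diff(tt[refill]), na.rm = TRUE)
    if (is.finite(slope) && slope < -slope_frac * rng / period)
      feeders <- c(feeders, st)
  }
  if (setequal(feeders, c("er", "mt"))) "ER_and_Mt_feeding"
  else if (identical(feeders, "er")) "ER_feeding"
  else if (identical(feeders, "mt")) "Mt_feeding"
  else "none"
}

#' Identify the oscillation-driving compartment by clamping
#'
#' Runs the protocol twice with the cytosol-facing and the
#' microdomain-facing IP3R flux clamped to its cycle average.  The
#' driving compartment is the one whose clamping abolishes the
#' oscillations; when both or neither do, the result is `"ambiguous"`.
#'
#' @param params a `ca_params` object.
#' @param protocol a `ca_protocol`; its control run must oscillate.
#' @param ... passed to [run_clamped()].
#' @return `"cyt"`, `"ud"`, or `"ambiguous"`.
#' @export
identify_driving_compartment <- function(params, protocol, ...) {
  lost <- vapply(c("ip3r_cyt", "ip3r_ud"), function(tg) {
    pr <- protocol
    pr$clamp <- clamp_spec(tg, "auto")
    tr <- run_clamped(params, pr, ...)
    det <- detect_oscillations(tr$time, tr$ca_eff,
                               transient_cut = cycle_window_start(tr))
    !det$sustained
  }, logical(1))
  if (lost[["ip3r_cyt"]] && !lost[["ip3r_ud"]]) "cyt"
  else if (lost[["ip3r_ud"]] && !lost[["ip3r_cyt"]]) "ud"
  else "ambiguous"
}

#' Full oscillation metrics of a trajectory
#'
#' Computes the sustained flag, frequency, period, per-compartment peak
#' amplitudes (post-stimulus maximum minus pre-stimulus basal), the
#' interspike interval and burst duration of the effective-cytosol
#' trace (burst = normalized trace above `burst_threshold` within a
#' cycle), the within-cycle peak order and the feeder mode.
#'
#' @param traj a `ca_traj`.
#' @param transient_cut discard samples before this time (s); default is
#'   the final-quarter window used for cycle selection.
#' @param burst_threshold normalized level defining the burst.
#' @param classify whether to run the (more expensive) phase/feeder
#'   classification for sustained trajectories.
#' @return an object of class `ca_metrics` (a list).
#' @export
oscillation_metrics <- function(traj, transient_cut = NULL,
                                burst_threshold = 0.5, classify = TRUE) {
  stopifnot(inherits(traj, "ca_traj"))
  if (is.null(transient_cut)) transient_cut <- cycle_window_start(traj)
  det <- detect_oscillations(traj$time, traj$ca_eff,
                             transient_cut = transient_cut)
  basal <- .basal_levels(traj)
  post <- traj$time >= traj$protocol$t_step
  amp <- c(cyt = max(traj$ca_eff[post]) - basal[["cyt"]],
           er = max(traj$state[post, "ca_er"]) - basal[["er"]],
           mt = max(traj$state[post, "ca_mt"]) - basal[["mt"]],
           ud = max(traj$state[post, "ca_ud"]) - basal[["ud"]])
  out <- list(sustained = det$sustained,
              frequency = if (det$sustained) frequency_of(det$peak_times)
                          else 0,
              period = if (det$sustained) 60 / frequency_of(det$peak_times)
                       else NA_real_,
              peak_amplitude = amp,
              interspike_interval = NA_real_, burst_duration = NA_real_,
              peak_order = NULL, feeder_mode = "none",
              peak_times = det$peak_times)
  if (det$sustained && classify) {
    ph <- classify_phases(traj)
    sel <- ph$normalized$time
    cyt <- ph$normalized$cyt
    dtm <- diff(ph$normalized$time)
    burst <- sum(dtm[cyt[-length(cyt)] >= burst_threshold])
    out$burst_duration <- burst
    out$interspike_interval <- out$period - burst
    out$peak_order <- ph$peak_order
    out$feeder_mode <- classify_feeder_mode(traj,
                                            burst_threshold = burst_threshold)
  }
  class(out) <- "ca_metrics"
  out
}

#' @export
print.ca_metrics <- function(x, ...) {
  if (x$sustained) {
    cat(sprintf("Sustained oscillations: %.2f /min (period %.1f s)\n",
                x$frequency, x$period))
    cat(sprintf("  burst %.1f s + interspike %.1f s\n",
                x$burst_duration, x$interspike_interval))
    if (!is.null(x$peak_order))
      cat("  peak order:", paste(x$peak_order, collapse = " -> "), "\n")
    cat("  feeder mode:", x$feeder_mode, "\n")
  } else {
    cat("No sustained oscillations\n")
  }
  cat(sprintf("  peak amplitudes (uM): cyt %.3g, ER %.3g, Mt %.3g, ud %.3g\n",
              x$peak_amplitude[["cyt"]], x$peak_amplitude[["er"]],
              x$peak_amplitude[["mt"]], x$peak_amplitude[["ud"]]))
  invisible(x)
}
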