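#' Latin hypercube sample of the parameter space
#'
#' Stratified uniform sampling: each parameter's marginal places exactly
#' one draw in each of `n` equal-probability strata, then strata are
#' permuted independently per parameter.  Deterministic under a fixed
#' seed.
#'
#' @param bounds data.frame with columns `parameter`, `lower`, `upper`,
#'   `variable` (see [parameter_bounds()]); only variable rows are
#'   sampled.
#' @param n number of parameter sets (>= 2).
#' @param seed integer seed.
#' @return numeric matrix `n` x `n_variable` with parameter names as
#'   column names.
#' @export
lhs_sample <- function(bounds, n, seed) {
  b <- bounds[bounds$variable, , drop = FALSE]
  if (!nrow(b)) stop("no variable parameters in 'bounds'")
  if (any(!is.finite(b$lower)) || any(!is.finite(b$upper)) ||
      any(b$lower >= b$upper))
    stop("variable bounds must satisfy lower < upper")
  if (n < 2) stop("'n' must be >= 2")
  set.seed(as.integer(seed))
  u <- lhs::randomLHS(n, nrow(b))
  m <- sweep(sweep(u, 2, b$upper - b$lower, "*"), 2, b$lower, "+")
  colnames(m) <- b$parameter
  m
}

#' Simulate an ensemble of sampled parameter sets
#'
#' Runs the protocol once per row of the sample matrix and extracts
#' oscillation metrics.  Solver failures are recorded as non-oscillating
#' with a failure flag (and are excluded from PRCC by [prcc()]'s
#' complete-case handling).  Results do not depend on execution order.
#'
#' @param params control `ca_params`; sampled columns replace its values
#'   row by row.
#' @param samples matrix from [lhs_sample()].
#' @param protocol a `ca_protocol` template.
#' @param dt,rtol,atol solver settings per run (the ensemble default is
#'   coarser than single-run analysis: many thousand solves).
#' @param progress print a dot every 200 runs.
#' @return data.frame with one row per set: `sustained`, `failed`,
#'   `frequency` (per min) and peak amplitudes per compartment.
#' @export
run_ensemble <- function(params, samples, protocol, dt = 0.25,
                         rtol = 1e-6, atol = 1e-8, progress = FALSE) {
  rows <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    ov <- as.list(samples[i, ])
    res <- tryCatch({
      p <- do.call(ca_parameters, c(ov, list(base = params)))
      traj <- run_protocol(p, protocol, dt = dt, rtol = rtol, atol = atol)
      met <- oscillation_metrics(traj, classify = FALSE)
      data.frame(sustained = met$sustained, failed = FALSE,
                 frequency = met$frequency,
                 amp_cyt = met$peak_amplitude[["cyt"]],
                 amp_er = met$peak_amplitude[["er"]],
                 amp_mt = met$peak_amplitude[["mt"]],
                 amp_ud = met$peak_amplitude[["ud"]])
    }, error = function(e)
      data.frame(sustained = FALSE, failed = TRUE, frequency = NA_real_,
                 amp_cyt = NA_real_, amp_er = NA_real_, amp_mt = NA_real_,
                 amp_ud = NA_real_))
    rows[[i]] <- res
    if (progress && i %% 200 == 0) cat(".")
  }
  if (progress) cat("\n")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Partial rank correlation coefficients with significance
#'
#' Rank-transforms every column (average ranks on ties), then, for each
#' parameter, removes the linear effect of all other parameters from
#' both the parameter ranks and the metric ranks and correlates the
#' residuals.  Significance uses the two-sided t statistic on the
#' partial correlation with `n - 2 - (k - 1)` degrees of freedom, at the
#' given level, without multiplicity correction.
#'
#' @param samples numeric matrix of parameter values (columns named).
#' @param metric numeric vector of the model output, one per row;
#'   rows with non-finite metric values are dropped.
#' @param level confidence level for the significance flag.
#' @return data.frame with columns `parameter`, `prcc`, `p_value`,
#'   `significant`.
#' @export
prcc <- function(samples, metric, level = 0.95) {
  keep <- is.finite(metric) & stats::complete.cases(samples)
  X <- samples[keep, , drop = FALSE]
  y <- metric[keep]
  n <- nrow(X); k <- ncol(X)
  if (n < k + 2)
    stop("need at least ncol(samples) + 2 complete observations")
  Xr <- apply(X, 2, rank)
  qrX <- qr(cbind(1, Xr))
  if (qrX$rank < k + 1) {
    piv <- qrX$pivot[seq_len(qrX$rank)]
    drop_cols <- setdiff(seq_len(k + 1), piv) - 1L
    stop("rank-deficient design; collinear column(s): ",
         paste(colnames(Xr)[drop_cols], collapse = ", "))
  }
  yr <- rank(y)
  out <- lapply(seq_len(k), function(j) {
    Z <- cbind(1, Xr[, -j, drop = FALSE])
    rx <- stats::lm.fit(Z, Xr[, j])$residuals
    ry <- stats::lm.fit(Z, yr)$residuals
    r <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
    df <- n - 2 - (k - 1)
    tt <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df)
    data.frame(parameter = colnames(Xr)[j], prcc = r, p_value = p,
               significant = p < (1 - level))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Histograms of ensemble oscillation metrics
#'
#' Bins each metric over the oscillating (sustained, non-failed) sets
#' and reports the mode (midpoint of the fullest bin) and the central
#' mass (fraction of sets within the mode bin and its neighbours).
#'
#' @param metrics data.frame from [run_ensemble()].
#' @param columns metric columns to bin.
#' @param breaks passed to [hist()].
#' @return named list per metric: `breaks`, `counts`, `mode`,
#'   `central_mass`, `n`.
#' @export
metric_histograms <- function(metrics,
                              columns = c("frequency", "amp_cyt", "amp_er",
                                          "amp_mt", "amp_ud"),
                              breaks = 30) {
  osc <- metrics$sustained & !metrics$failed
  if (!any(osc)) stop("no oscillating sets")
  out <- lapply(columns, function(cn) {
    v <- metrics[[cn]][osc]
    v <- v[is.finite(v)]
    if (length(unique(v)) == 1) {
      return(list(breaks = c(v[1] - 0.5, v[1] + 0.5), counts = length(v),
                  mode = v[1], central_mass = 1, n = length(v)))
    }
    h <- graphics::hist(v, breaks = breaks, plot = FALSE)
    i <- which.max(h$counts)
    nb <- seq(max(1, i - 1), min(length(h$counts), i + 1))
    list(breaks = h$breaks, counts = h$counts, mode = h$mids[i],
         central_mass = sum(h$counts[nb]) / length(v), n = length(v))
  })
  names(out) <- columns
  out
}

#' Full global sensitivity analysis
#'
#' Latin hypercube sampling of all variable parameters within their
#' bounds, ensemble simulation, PRCC of each metric against every
#' parameter, and metric histograms.
#'
#' @param params control `ca_params` (its attached or default +/-40
#'   percent bounds are used, see [parameter_bounds()]).
#' @param protocol a `ca_protocol` template.
#' @param n ensemble size.
#' @param seed integer seed for the sampling.
#' @param metrics_for metric columns to correlate.
#' @param ... passed to [run_ensemble()].
#' @return an object of class `ca_sensitivity`: list with `samples`,
#'   `metrics`, `prcc` (long data.frame over parameter x metric),
#'   `histograms`, `oscillating_fraction`, `failed_fraction`, `seed`.
#' @export
sensitivity_analysis <- function(params, protocol, n = 5000, seed = 1,
                                 metrics_for = c("frequency", "amp_cyt",
                                                 "amp_ud"),
                                 ...) {
  bounds <- parameter_bounds(params)
  samples <- lhs_sample(bounds, n, seed)
  met <- run_ensemble(params, samples, protocol, ...)
  osc <- met$sustained & !met$failed
  tabs <- lapply(metrics_for, function(cn) {
    y <- ifelse(osc, met[[cn]], NA_real_)
    tb <- prcc(samples, y)
    tb$metric <- cn
    tb
  })
  structure(list(samples = samples, metrics = met,
                 prcc = do.call(rbind, tabs),
                 histograms = metric_histograms(met),
                 oscillating_fraction = mean(osc),
                 failed_fraction = mean(met$failed),
                 seed = seed, bounds = bounds),
            class = "ca_sensitivity")
}

#' @export
print.ca_sensitivity <- function(x, ...) {
  cat(sprintf("Global sensitivity analysis: %d sets, %.1f%% oscillating",
              nrow(x$metrics), 100 * x$oscillating_fraction))
  if (x$failed_fraction > 0)
    cat(sprintf(" (%.2f%% failed solves)", 100 * x$failed_fraction))
  cat("\n")
  sig <- x$prcc[x$prcc$significant & abs(x$prcc$prcc) > 0.05, ]
  sig <- sig[order(sig$metric, -abs(sig$prcc)), ]
  for (m in unique(sig$metric)) {
    s <- sig[sig$metric == m, ]
    cat(sprintf("  %s: %s\n", m,
                paste(sprintf("%s %+0.2f", s$parameter, s$prcc),
                      collapse = ", ")))
  }
  invisible(x)
}
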