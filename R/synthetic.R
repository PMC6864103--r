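#' Analytic test signals for the oscillation-analysis layer
#'
#' Exact synthetic traces used to validate peak detection, frequency
#' estimation and phase classification: a pure sinusoid, an
#' exponentially damped sinusoid, a constant, or an antiphase pair of
#' sinusoids.
#'
#' @param kind one of `"sinusoid"`, `"damped"`, `"constant"`,
#'   `"antiphase"`.
#' @param period oscillation period (s).
#' @param amplitude peak amplitude around the baseline.
#' @param baseline additive offset.
#' @param decay for `"damped"`: fraction of amplitude retained per cycle
#'   (e.g. 0.5 halves the amplitude every period).
#' @param t_end,dt sampling horizon and interval (s).
#' @param t_start first sample time.
#' @return data.frame with `time` and `x` (plus `y` for the antiphase
#'   pair).
#' @export
synthetic_signal <- function(kind = c("sinusoid", "damped", "constant",
                                      "antiphase"),
                             period = 20, amplitude = 1, baseline = 0,
                             decay = 0.5, t_end = 300, dt = 0.1,
                             t_start = 0) {
  kind <- match.arg(kind)
  t <- seq(t_start, t_end, by = dt)
  w <- 2 * pi / period
  out <- switch(kind,
    sinusoid = data.frame(time = t, x = baseline + amplitude * sin(w * t)),
    damped = data.frame(time = t,
                        x = baseline + amplitude *
                          exp(log(decay) * t / period) * sin(w * t)),
    constant = data.frame(time = t, x = rep(baseline, length(t))),
    antiphase = data.frame(time = t,
                           x = baseline + amplitude * sin(w * t),
                           y = baseline - amplitude * sin(w * t)))
  out
}
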