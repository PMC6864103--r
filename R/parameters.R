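#' @useDynLib microca, .registration = TRUE
NULL

# Canonical parameter names, in the order the compiled right-hand side
# expects them.  `vol_ud` is carried alongside but usually derived from
# (sa_mito, n_mito, d_er_mt); see ca_parameters().
.param_names <- c(
  "vol_cyt", "vol_er", "vol_mt",
  "sa_mito", "n_mito", "d_er_mt",
  "bp_cyt", "bp_er", "bp_mt", "bp_ud",
  "k_buf_cyt", "k_buf_er", "k_buf_mt", "k_buf_ud",
  "v_ip3r", "d1", "d2", "d3", "d5", "a2",
  "v_serca", "k_serca",
  "v_mcu0", "k_mcu", "b_mcu", "psi0", "psi",
  "faraday", "gas_const", "temperature",
  "v_mncx", "k_na", "k_mncx", "na_cyt", "na_ud",
  "k_leak_er_cyt", "k_leak_er_ud", "k_leak_ud_cyt",
  "c_ip3r", "c_serca", "c_mcu", "c_mncx",
  "ip3"
)

.state_names <- c("ca_cyt", "ca_er", "ca_mt", "ca_ud", "h", "h_ud")

# Minimum ER-mitochondria distance (um); contact sites cannot be narrower
# than the IP3R head itself (10 nm).
.d_er_mt_floor <- 0.01

#' Construct a validated model parameter set
#'
#' Builds the full parameter list of the four-compartment closed-cell
#' calcium model: compartment volumes and geometry, fast-buffer constants,
#' IP3 receptor gating constants, SERCA / MCU / mNCX kinetics, leak rate
#' constants, and the channel connectivity coefficients that split each
#' channel population between the bulk cytosol and the ER-mitochondria
#' microdomain.
#'
#' Units: concentrations in micromolar (sodium in millimolar), time in
#' seconds, lengths in micrometres, volumes in cubic micrometres, membrane
#' voltage in millivolts.  All fluxes produced from these parameters are
#' referenced to the cytosolic volume.
#'
#' The microdomain volume is the slab of cytosol trapped between the ER
#' and the mitochondrial surface: 20 percent of the surface area of each
#' of `n_mito` spherical mitochondria, times the ER-mitochondria distance
#' `d_er_mt` (see [microdomain_volume()]).  Passing `vol_ud` explicitly
#' pins the volume instead; a pinned set rejects later edits of
#' `d_er_mt`.
#'
#' @param ... named parameter values overriding the base set (see
#'   [default_parameters()] for the control values).
#' @param base a parameter set to start from; defaults to the packaged
#'   control set.
#' @param vol_ud optional explicit microdomain volume (um^3).  When `NULL`
#'   (default) the volume is derived from the geometry.
#' @return an object of class `ca_params`: a named list of numeric scalars
#'   plus the derived `vol_ud`.
#' @seealso [default_parameters()], [load_parameters()], [microdomain_volume()]
#' @export
#' @examples
#' p <- ca_parameters(ip3 = 0.7)
#' p$vol_ud
ca_parameters <- function(..., base = default_parameters(), vol_ud = NULL) {
  over <- list(...)
  if (length(over) && is.null(names(over)))
    stop("parameter overrides must be named")
  bad <- setdiff(names(over), c(.param_names, "vol_ud"))
  if (length(bad))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p <- unclass(base)
  if ("vol_ud" %in% names(over)) {
    vol_ud <- over$vol_ud
    over$vol_ud <- NULL
  }
  if (!is.null(vol_ud) && "d_er_mt" %in% names(over) &&
      isTRUE(attr(base, "vol_ud_pinned")))
    stop("cannot edit 'd_er_mt' while 'vol_ud' is pinned")
  for (nm in names(over)) p[[nm]] <- as.numeric(over[[nm]])
  if (is.null(vol_ud)) {
    if (isTRUE(attr(base, "vol_ud_pinned"))) {
      if ("d_er_mt" %in% names(over))
        stop("cannot edit 'd_er_mt' while 'vol_ud' is pinned; rebuild with ",
             "an explicit 'vol_ud' or a derived set")
      vol_ud <- p$vol_ud
      pinned <- TRUE
    } else {
      vol_ud <- microdomain_volume(p$sa_mito, p$n_mito, p$d_er_mt)
      pinned <- FALSE
    }
  } else {
    pinned <- TRUE
  }
  p$vol_ud <- as.numeric(vol_ud)
  obj <- structure(p, class = "ca_params", vol_ud_pinned = pinned)
  validate_parameters(obj)
  obj
}

#' Validate a parameter set
#'
#' Checks positivity of volumes, rate constants and buffer constants, the
#' `[0, 1]` range of connectivity coefficients, and the 10 nm floor on the
#' ER-mitochondria distance.
#'
#' @param p a `ca_params` object or named list covering all parameters.
#' @return `p`, invisibly; errors list every violated constraint.
#' @export
validate_parameters <- function(p) {
  miss <- setdiff(.param_names, names(p))
  if (length(miss))
    stop("missing parameter(s): ", paste(miss, collapse = ", "))
  errs <- character()
  nonneg <- c("vol_cyt", "vol_er", "vol_mt", "sa_mito", "n_mito",
              "bp_cyt", "bp_er", "bp_mt", "bp_ud",
              "v_ip3r", "d1", "d2", "d3", "d5", "a2",
              "v_serca", "v_mcu0", "v_mncx",
              "k_leak_er_cyt", "k_leak_er_ud", "k_leak_ud_cyt", "ip3")
  pos <- c("k_buf_cyt", "k_buf_er", "k_buf_mt", "k_buf_ud",
           "k_serca", "k_mcu", "k_na", "k_mncx",
           "faraday", "gas_const", "temperature")
  for (nm in nonneg)
    if (!is.finite(p[[nm]]) || p[[nm]] < 0)
      errs <- c(errs, paste0("'", nm, "' must be finite and >= 0"))
  for (nm in pos)
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
      errs <- c(errs, paste0("'", nm, "' must be finite and > 0"))
  for (nm in c("c_ip3r", "c_serca", "c_mcu", "c_mncx"))
    if (!is.finite(p[[nm]]) || p[[nm]] < 0 || p[[nm]] > 1)
      errs <- c(errs, paste0("'", nm, "' must lie in [0, 1]"))
  if (!is.finite(p$d_er_mt) || p$d_er_mt < .d_er_mt_floor)
    errs <- c(errs, sprintf("'d_er_mt' must be >= %.3f um", .d_er_mt_floor))
  if (!is.null(p$vol_ud) && (!is.finite(p$vol_ud) || p$vol_ud <= 0))
    errs <- c(errs, "'vol_ud' must be finite and > 0")
  if (length(errs))
    stop("invalid parameters:\n  ", paste(errs, collapse = "\n  "))
  invisible(p)
}

#' Microdomain volume from mitochondrial geometry
#'
#' The ER-mitochondria microdomain is modelled as the cytosolic slab
#' covering 20 percent of each mitochondrion's surface at distance `d`
#' from the ER membrane, summed over all mitochondria:
#' `0.2 * sa * n * d`.
#'
#' @param sa surface area of a single mitochondrion (um^2).
#' @param n number of mitochondria (dimensionless).
#' @param d ER-mitochondria distance (um).
#' @return microdomain volume (um^3); linear in every argument.
#' @export
#' @examples
#' microdomain_volume(pi, 200, 0.02)  # 1-um-diameter spheres, 20 nm gap
microdomain_volume <- function(sa, n, d) {
  if (any(sa < 0) || any(n < 0) || any(d < 0))
    stop("'sa', 'n' and 'd' must all be >= 0")
  0.2 * sa * n * d
}

#' The packaged control parameter set
#'
#' Loads the control parameter fixture shipped with the package.  The set
#' is synthetic: it was calibrated against the published behaviour of the
#' four-compartment microdomain model (oscillation windows, frequencies,
#' clamping and knockout dichotomies) rather than transcribed from a
#' source table; see the fixture's provenance note and the methods
#' vignette.
#'
#' @return a `ca_params` object.
#' @export
default_parameters <- function() {
  path <- system.file("extdata", "params_control_synthetic.yaml",
                      package = "microca")
  if (path == "") stop("control parameter fixture not found")
  load_parameters(path)
}

#' Read a parameter fixture file
#'
#' Parameter fixtures are YAML files with a `parameters:` block (value and
#' unit per field), an optional `bounds:` block (per-parameter lower/upper
#' sampling bounds and a `variable` flag for sensitivity analysis), and a
#' `provenance:` note.  The file is schema-validated on load.
#'
#' @param path path to a YAML fixture.
#' @return a `ca_params` object; sampling bounds, when present, are
#'   attached as attribute `"bounds"` (see [parameter_bounds()]).
#' @export
load_parameters <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$parameters)) stop("fixture has no 'parameters' block")
  vals <- lapply(doc$parameters, function(f) {
    if (is.list(f)) f$value else f
  })
  miss <- setdiff(.param_names, names(vals))
  if (length(miss))
    stop("fixture is missing parameter(s): ", paste(miss, collapse = ", "))
  extra <- setdiff(names(vals), c(.param_names, "vol_ud"))
  if (length(extra))
    stop("fixture has unknown field(s): ", paste(extra, collapse = ", "))
  bad <- names(vals)[!vapply(vals, function(v)
    is.numeric(v) && length(v) == 1 && is.finite(v), logical(1))]
  if (length(bad))
    stop("non-numeric or non-scalar value(s) for: ", paste(bad, collapse = ", "))
  p <- vals[.param_names]
  pinned <- "vol_ud" %in% names(vals)
  if (pinned) {
    p$vol_ud <- vals$vol_ud
  } else {
    p$vol_ud <- microdomain_volume(p$sa_mito, p$n_mito, p$d_er_mt)
  }
  obj <- structure(p, class = "ca_params",
                   vol_ud_pinned = pinned,
                   name = doc$name %||% basename(path),
                   provenance = doc$provenance)
  validate_parameters(obj)
  if (!is.null(doc$bounds)) {
    b <- .parse_bounds(doc$bounds, obj)
    attr(obj, "bounds") <- b
  }
  obj
}

.parse_bounds <- function(blk, p) {
  rows <- lapply(names(blk), function(nm) {
    if (!nm %in% .param_names)
      stop("bounds name unknown parameter: ", nm)
    f <- blk[[nm]]
    lo <- f$lower %||% NA_real_
    hi <- f$upper %||% NA_real_
    va <- isTRUE(f$variable)
    if (va && !(is.finite(lo) && is.finite(hi) && lo < hi))
      stop("variable parameter '", nm, "' needs finite lower < upper bounds")
    if (va && !(lo <= p[[nm]] && p[[nm]] <= hi))
      stop("bounds for '", nm, "' do not bracket the control value")
    data.frame(parameter = nm, lower = lo, upper = hi, variable = va,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a parameter fixture file
#'
#' @param p a `ca_params` object.
#' @param path output YAML path.
#' @param name fixture name recorded in the file.
#' @param provenance free-text provenance note.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(p, path, name = attr(p, "name"),
                             provenance = attr(p, "provenance")) {
  validate_parameters(p)
  fields <- lapply(.param_names, function(nm) list(value = p[[nm]]))
  names(fields) <- .param_names
  doc <- list(name = name %||% "unnamed",
              provenance = provenance %||% "written by microca::write_parameters",
              parameters = fields)
  if (isTRUE(attr(p, "vol_ud_pinned")))
    doc$parameters$vol_ud <- list(value = p$vol_ud)
  b <- attr(p, "bounds")
  if (!is.null(b)) {
    blk <- lapply(seq_len(nrow(b)), function(i)
      list(lower = b$lower[i], upper = b$upper[i], variable = b$variable[i]))
    names(blk) <- b$parameter
    doc$bounds <- blk
  }
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Sampling bounds for sensitivity analysis
#'
#' Returns the per-parameter lower/upper bounds used by [lhs_sample()].
#' Bounds stored in the fixture take precedence; otherwise symmetric
#' `fraction` bounds around the control value are built for every
#' parameter flagged variable by default (kinetic constants, volumes,
#' buffer levels, connectivities, sodium levels and the ER-mitochondria
#' distance; physical constants and the fixed membrane voltage are
#' excluded).
#'
#' @param p a `ca_params` object.
#' @param fraction half-width of the default bounds, as a fraction of the
#'   control value (default 0.4, i.e. +/-40 percent).
#' @return data.frame with columns `parameter`, `lower`, `upper`,
#'   `variable`.
#' @export
parameter_bounds <- function(p, fraction = 0.4) {
  b <- attr(p, "bounds")
  if (!is.null(b)) return(b)
  fixed <- c("faraday", "gas_const", "temperature", "psi", "sa_mito",
             "n_mito", "ip3")
  rows <- lapply(.param_names, function(nm) {
    va <- !(nm %in% fixed) && p[[nm]] != 0
    lo <- if (va) p[[nm]] * (1 - fraction) else NA_real_
    hi <- if (va) p[[nm]] * (1 + fraction) else NA_real_
    if (va && nm == "d_er_mt") lo <- max(lo, .d_er_mt_floor)
    if (va && nm %in% c("c_ip3r", "c_serca", "c_mcu", "c_mncx"))
      hi <- min(hi, 1)
    data.frame(parameter = nm, lower = lo, upper = hi, variable = va,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.ca_params <- function(x, ...) {
  nm <- attr(x, "name")
  cat("Four-compartment calcium model parameters",
      if (!is.null(nm)) paste0(" ('", nm, "')"), "\n", sep = "")
  cat(sprintf("  volumes (um^3): cyt %.4g, ER %.4g, Mt %.4g, ud %.4g%s\n",
              x$vol_cyt, x$vol_er, x$vol_mt, x$vol_ud,
              if (isTRUE(attr(x, "vol_ud_pinned"))) " (pinned)"
              else sprintf(" (D = %.3g um)", x$d_er_mt)))
  cat(sprintf("  connectivity: IP3R %.2f, SERCA %.2f, MCU %.2f, mNCX %.2f\n",
              x$c_ip3r, x$c_serca, x$c_mcu, x$c_mncx))
  cat(sprintf("  [IP3] = %.3g uM\n", x$ip3))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
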