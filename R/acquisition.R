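#' Acquisition configuration for a time-gated camera
#'
#' Describes the gating scheme of a time-gated intensified camera: number of
#' gates, gate width, delay step between successive gate openings, the delay of
#' the first gate, and the excitation laser period. The default values are the
#' standard HSF acquisition: 101 gates of 300 ps width stepped by 80 ps (an
#' 8 ns span) under a 12.5 ns (80 MHz) laser.
#'
#' Times are picoseconds internally; `laser_period_ns` is accepted in
#' nanoseconds at the interface and converted.
#'
#' @param n_gates integer, number of gates (>= 1).
#' @param gate_width_ps gate integration window, ps (> 0).
#' @param gate_step_ps delay increment between gates, ps (> 0).
#' @param t0_ps delay of the first gate opening, ps.
#' @param laser_period_ns excitation repetition period, ns.
#' @param mcp_voltage free metadata (intensifier gain setting).
#' @param binning integer hardware binning factor.
#' @return An object of class `acq_config`.
#' @examples
#' cfg <- acq_config()
#' range(make_time_axis(cfg))  # 0 .. 8000 ps
#' @export
acq_config <- function(n_gates = 101L, gate_width_ps = 300, gate_step_ps = 80,
                       t0_ps = 0, laser_period_ns = 12.5,
                       mcp_voltage = NA, binning = 1L) {
  n_gates <- as.integer(n_gates)
  if (is.na(n_gates) || n_gates < 1L)
    stop("invalid acquisition config: n_gates must be >= 1", call. = FALSE)
  if (!is.finite(gate_width_ps) || gate_width_ps <= 0)
    stop("invalid acquisition config: gate_width_ps must be > 0", call. = FALSE)
  if (!is.finite(gate_step_ps) || gate_step_ps <= 0)
    stop("invalid acquisition config: gate_step_ps must be > 0", call. = FALSE)
  span <- (n_gates - 1) * gate_step_ps
  if (span + gate_width_ps > laser_period_ns * 1000 + 1e-9)
    stop("invalid acquisition config: gate span + width (", span + gate_width_ps,
         " ps) exceeds the laser period (", laser_period_ns * 1000, " ps)",
         call. = FALSE)
  structure(list(n_gates = n_gates, gate_width_ps = gate_width_ps,
                 gate_step_ps = gate_step_ps, t0_ps = t0_ps,
                 laser_period_ns = laser_period_ns,
                 mcp_voltage = mcp_voltage, binning = as.integer(binning)),
            class = "acq_config")
}

#' Gate-opening time axis
#'
#' @param config an [acq_config()].
#' @return Numeric vector of gate opening times (ps), strictly increasing with
#'   spacing `gate_step_ps`; the span of the default configuration is 8 ns.
#' @export
make_time_axis <- function(config) {
  stopifnot(inherits(config, "acq_config"))
  config$t0_ps + (seq_len(config$n_gates) - 1) * config$gate_step_ps
}

#' @export
print.acq_config <- function(x, ...) {
  span <- (x$n_gates - 1) * x$gate_step_ps
  cat(sprintf("<acq_config> %d gates, width %g ps, step %g ps, t0 %g ps (span %g ns), laser period %g ns\n",
              x$n_gates, x$gate_width_ps, x$gate_step_ps, x$t0_ps,
              span / 1000, x$laser_period_ns))
  invisible(x)
}

# stable hash of a config-like list (provenance / reproducibility logging)
config_hash <- function(x) {
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  # cheap polynomial rolling hash over the serialized text: stable, no deps
  bytes <- utf8ToInt(json)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}
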