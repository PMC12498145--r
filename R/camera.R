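#' Gated-intensifier camera model
#'
#' Forward model of a time-gated ICCD: gate shape, conversion gain from
#' detected Monte Carlo weight to camera counts, noise model and saturation.
#' `gain = "auto"` asks [generate_hsf_dataset()] to scale the brightest
#' noiseless planar decay to `target_peak` counts (the control-matched noise
#' regime of the phantom experiments).
#'
#' @param config an [acq_config()].
#' @param gate_shape `"boxcar"` (default) or `"trapezoid"`.
#' @param gain counts per detected weight per ps of gate (> 0), or `"auto"`.
#' @param noise `"none"`, `"poisson"`, or `"poisson+gaussian"`.
#' @param read_sigma Gaussian read-noise SD in counts (used by
#'   `"poisson+gaussian"`).
#' @param saturation full-well clip level in counts.
#' @param target_peak peak-count target for `gain = "auto"`.
#' @param trapezoid_rise_ps rise/fall time of the trapezoid gate.
#' @return Object of class `camera_model`.
#' @export
camera_model <- function(config = acq_config(), gate_shape = c("boxcar", "trapezoid"),
                         gain = 1, noise = c("none", "poisson", "poisson+gaussian"),
                         read_sigma = 0, saturation = Inf,
                         target_peak = 1100, trapezoid_rise_ps = 50) {
  gate_shape <- match.arg(gate_shape)
  noise <- match.arg(noise)
  stopifnot(inherits(config, "acq_config"))
  if (!identical(gain, "auto") && (!is.numeric(gain) || gain <= 0))
    stop("gain must be > 0 or \"auto\"", call. = FALSE)
  if (read_sigma < 0) stop("read_sigma must be >= 0", call. = FALSE)
  structure(list(config = config, gate_shape = gate_shape, gain = gain,
                 noise = noise, read_sigma = read_sigma,
                 saturation = saturation, target_peak = target_peak,
                 trapezoid_rise_ps = trapezoid_rise_ps),
            class = "camera_model")
}

# gate integration weights: n_gates x n_fine matrix; entry (g, j) = fraction of
# fine bin j covered by gate g (boxcar) or trapezoid-weighted coverage
gate_matrix <- function(camera, t0_fine, dt_fine, n_fine) {
  cfg <- camera$config
  ta <- make_time_axis(cfg)
  W <- cfg$gate_width_ps
  fine_lo <- t0_fine + (seq_len(n_fine) - 1) * dt_fine
  fine_hi <- fine_lo + dt_fine
  t_end <- t0_fine + n_fine * dt_fine
  truncated <- which(ta + W > t_end + 1e-9 | ta < t0_fine - 1e-9)
  if (length(truncated))
    stop("gate window exceeds the simulated time range for gate(s): ",
         paste(truncated, collapse = ", "), call. = FALSE)
  G <- matrix(0, cfg$n_gates, n_fine)
  for (g in seq_len(cfg$n_gates)) {
    lo <- ta[g]; hi <- ta[g] + W
    ov <- pmax(0, pmin(fine_hi, hi) - pmax(fine_lo, lo)) / dt_fine
    if (camera$gate_shape == "trapezoid" && camera$trapezoid_rise_ps > 0) {
      r <- camera$trapezoid_rise_ps
      mid <- (pmax(fine_lo, lo) + pmin(fine_hi, hi)) / 2
      ramp <- pmin(1, pmax(0, (mid - lo) / r)) * pmin(1, pmax(0, (hi - mid) / r))
      ov <- ov * ramp
    }
    G[g, ] <- ov
  }
  G
}

# lower-triangular Toeplitz matrix realizing discrete linear convolution with
# a kernel on the fine axis: (K %*% f)_j = sum_m k[j - m + 1] f[m]
conv_matrix <- function(kernel, n_fine) {
  lag <- row(diag(n_fine)) - col(diag(n_fine)) + 1
  K <- matrix(0, n_fine, n_fine)
  ok <- lag >= 1 & lag <= length(kernel)
  K[ok] <- kernel[lag[ok]]
  K
}

#' Integrate a fine-time surface stack into camera gates
#'
#' Gate `g` integrates the signal over `[t_g, t_g + gate_width]` (boxcar by
#' default; gates may overlap, as in the standard 300 ps / 80 ps
#' configuration), scaled by the camera gain. When an `irf` is supplied it is
#' convolved on the fine time axis *before* gating, matching the physical
#' ordering (emission kinetics convolved with the instrument response, then
#' gated). The operation is linear in the input signal.
#'
#' @param ts a `time_stack` from [reweight_by_pattern()] (fine bins must not
#'   be coarser than the gate step).
#' @param camera a [camera_model()] (numeric `gain` required here).
#' @param irf optional IRF on the fine axis: numeric vector (normalized
#'   internally) no longer than the stack's time dimension.
#' @param provenance provenance list stored in the output stack.
#' @return A [gated_stack()].
#' @export
apply_gating <- function(ts, camera, irf = NULL, provenance = list()) {
  stopifnot(inherits(ts, "time_stack"), inherits(camera, "camera_model"))
  cfg <- camera$config
  if (ts$time_bin_ps > cfg$gate_step_ps)
    stop("fine time bin (", ts$time_bin_ps,
         " ps) must be <= the gate step (", cfg$gate_step_ps, " ps)",
         call. = FALSE)
  gain <- camera$gain
  if (identical(gain, "auto"))
    stop("auto gain must be resolved before gating (see generate_hsf_dataset)",
         call. = FALSE)
  d <- dim(ts$data)
  G <- gate_matrix(camera, ts$t0_ps, ts$time_bin_ps, d[1])
  if (!is.null(irf)) {
    # fold the IRF convolution (fine axis, before gating) into the gate
    # weights: gate(conv(irf, f)) == (G %*% K) %*% f exactly
    k <- if (inherits(irf, "irf")) irf$samples else as.numeric(irf)
    k <- k / sum(k)
    G <- G %*% conv_matrix(k, d[1])
  }
  m <- matrix(ts$data, nrow = d[1])
  gated <- (G %*% m) * gain * ts$time_bin_ps
  gated_stack(array(gated, c(cfg$n_gates, d[2], d[3])), cfg,
              ts$pixel_pitch_mm, provenance = provenance)
}

#' Apply camera noise to a gated stack
#'
#' Poisson shot noise per pixel per gate (mean-preserving in expectation),
#' optional additive Gaussian read noise, clipped at zero and at the
#' saturation level.
#'
#' @param stack a [gated_stack()].
#' @param camera a [camera_model()] (its `noise` field selects the model).
#' @param seed optional integer for `set.seed()`.
#' @return A [gated_stack()] with noisy counts.
#' @export
add_noise <- function(stack, camera, seed = NULL) {
  stopifnot(inherits(stack, "gated_stack"), inherits(camera, "camera_model"))
  if (!is.null(seed)) set.seed(seed)
  x <- stack$data
  if (camera$noise %in% c("poisson", "poisson+gaussian"))
    x[] <- rpois(length(x), lambda = as.vector(x))
  if (camera$noise == "poisson+gaussian" && camera$read_sigma > 0)
    x[] <- x + rnorm(length(x), 0, camera$read_sigma)
  x[x < 0] <- 0
  if (is.finite(camera$saturation)) x[x > camera$saturation] <- camera$saturation
  prov <- stack$provenance
  prov$noise <- camera$noise
  if (!is.null(seed)) prov$noise_seed <- seed
  gated_stack(x, stack$config, stack$pixel_pitch_mm, provenance = prov)
}
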