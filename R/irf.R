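#' Instrument response function
#'
#' An IRF sampled on the gate time axis, either global (a vector) or per pixel
#' (a `T x H x W` array). `validate_irf()` checks non-negativity, rejects
#' all-zero responses, and normalizes to unit sum (pixel-wise for the
#' per-pixel variant), which is the form the decay model [model_decay()]
#' expects.
#'
#' @param irf numeric vector or `T x H x W` array of IRF samples.
#' @param config optional [acq_config()]; if given, the IRF length must equal
#'   `config$n_gates`.
#' @return Object of class `irf`: list with `samples` (normalized),
#'   `normalized = TRUE` and `per_pixel` flag.
#' @export
validate_irf <- function(irf, config = NULL) {
  if (inherits(irf, "irf")) irf <- irf$samples
  x <- as.array(irf)
  per_pixel <- length(dim(x)) == 3
  if (anyNA(x) || any(!is.finite(x)) || any(x < 0))
    stop("IRF samples must be finite and non-negative", call. = FALSE)
  nt <- if (per_pixel) dim(x)[1] else length(x)
  if (!is.null(config)) {
    stopifnot(inherits(config, "acq_config"))
    if (nt != config$n_gates)
      stop("IRF has ", nt, " samples but the config declares ",
           config$n_gates, " gates", call. = FALSE)
  }
  if (per_pixel) {
    sums <- apply(x, c(2, 3), sum)
    if (any(sums <= 0))
      stop("degenerate IRF: all-zero response in ", sum(sums <= 0), " pixel(s)",
           call. = FALSE)
    x <- sweep(x, c(2, 3), sums, "/")
  } else {
    x <- as.numeric(x)
    s <- sum(x)
    if (s <= 0) stop("degenerate IRF: all samples are zero", call. = FALSE)
    x <- x / s
  }
  structure(list(samples = x, normalized = TRUE, per_pixel = per_pixel),
            class = "irf")
}

#' Synthesize a Gaussian IRF on a time axis
#'
#' Stand-in for a measured white-paper IRF: a Gaussian of given FWHM centered
#' at `center_ps`, sampled on `time_axis` and normalized to unit sum. A FWHM of
#' 0 gives a single-bin impulse (convolution with it is the identity).
#' A warning is issued when the center lies outside the axis (truncated IRF).
#'
#' @param fwhm_ps full width at half maximum, ps (>= 0).
#' @param center_ps center of the Gaussian, ps.
#' @param time_axis sample times, ps (e.g. [make_time_axis()] output).
#' @return An [validate_irf()]-normalized `irf` object.
#' @export
synth_irf <- function(fwhm_ps, center_ps, time_axis) {
  if (!is.finite(fwhm_ps) || fwhm_ps < 0)
    stop("fwhm_ps must be >= 0", call. = FALSE)
  if (center_ps < min(time_axis) || center_ps > max(time_axis))
    warning("IRF center (", center_ps, " ps) lies outside the time axis: truncated IRF")
  if (fwhm_ps == 0) {
    s <- numeric(length(time_axis))
    s[which.min(abs(time_axis - center_ps))] <- 1
  } else {
    sigma <- fwhm_ps / (2 * sqrt(2 * log(2)))
    s <- exp(-0.5 * ((time_axis - center_ps) / sigma)^2)
  }
  validate_irf(s)
}

#' @export
print.irf <- function(x, ...) {
  if (x$per_pixel) {
    d <- dim(x$samples)
    cat(sprintf("<irf> per-pixel, %d samples x %d x %d px (normalized)\n",
                d[1], d[2], d[3]))
  } else {
    cat(sprintf("<irf> global, %d samples (normalized), peak at sample %d\n",
                length(x$samples), which.max(x$samples)))
  }
  invisible(x)
}
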