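#' IRF-convolved multi-exponential decay model
#'
#' The forward fluorescence decay model: a mono- or bi-exponential
#' `sum_i A_i exp(-t / tau_i)` convolved (discrete linear convolution, no
#' periodic wrap) with the normalized instrument response on the gate time
#' axis, plus an optional constant baseline. Times on the axis are ps,
#' lifetimes ns; the decay is evaluated relative to the first axis sample.
#'
#' @param irf an [validate_irf()] object or numeric vector on `time_axis`
#'   (normalized internally).
#' @param A amplitudes, `>= 0` (length 1 or 2).
#' @param tau_ns lifetimes in ns, `> 0` (same length as `A`).
#' @param time_axis gate times, ps.
#' @param baseline constant offset in counts.
#' @return Numeric vector `Gamma(t)` on the axis, non-negative.
#' @export
model_decay <- function(irf, A, tau_ns, time_axis, baseline = 0) {
  if (any(tau_ns <= 0)) stop("lifetimes must be > 0", call. = FALSE)
  if (any(A < 0)) stop("amplitudes must be >= 0", call. = FALSE)
  k <- if (inherits(irf, "irf")) irf$samples else as.numeric(irf)
  if (length(dim(k)) == 3) stop("per-pixel IRF: use fit_stack()", call. = FALSE)
  k <- k / sum(k)
  n <- length(time_axis)
  stopifnot(length(k) == n)
  t_rel <- time_axis - time_axis[1]
  dec <- rowSums(vapply(seq_along(A), function(i)
    A[i] * exp(-t_rel / (tau_ns[i] * 1000)), numeric(n)))
  out <- convolve(dec, rev(k), type = "open")[seq_len(n)] + baseline
  pmax(out, 0)
}

# decay basis for variable-projection fitting: one IRF-convolved unit
# exponential per lifetime; shift_ps delays the IRF by linear interpolation
# on the gate axis (the standard NLSF nuisance parameter absorbing transit
# delay between the measured IRF and the recorded decay)
decay_basis <- function(kern, tau_ns, t_rel, shift_ps = 0) {
  n <- length(t_rel)
  if (shift_ps != 0) {
    kern <- stats::approx(t_rel, kern, xout = t_rel - shift_ps,
                          yleft = 0, yright = 0)$y
    s <- sum(kern)
    if (s > 0) kern <- kern / s else kern[1] <- 1
  }
  vapply(tau_ns, function(tau)
    convolve(exp(-t_rel / (tau * 1000)), rev(kern), type = "open")[seq_len(n)],
    numeric(n))
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot` of a model against data.
#'
#' @param data,model numeric vectors of equal length; `var(data)` must be
#'   positive.
#' @return Scalar R^2 (<= 1).
#' @export
r_squared <- function(data, model) {
  stopifnot(length(data) == length(model))
  ss_tot <- sum((data - mean(data))^2)
  if (ss_tot <= 0) stop("undefined R^2: data has zero variance", call. = FALSE)
  1 - sum((data - model)^2) / ss_tot
}

#' FRET (quenched-donor) fraction from bi-exponential amplitudes
#'
#' Fraction of the short-lifetime (quenched donor) population, corrected for
#' incomplete decay within one laser period `T`:
#' \deqn{f_1 = \frac{A_1 (1 - e^{-T/\tau_1})}{\sum_i A_i (1 - e^{-T/\tau_i})}.}
#' As `T / max(tau)` grows the bracket factors approach 1 and
#' `f_1 -> A_1 / (A_1 + A_2)`.
#'
#' @param A amplitudes `c(A1, A2)` (component 1 = shorter lifetime).
#' @param tau_ns lifetimes `c(tau1, tau2)`, ns.
#' @param laser_period_ns repetition period `T`, ns (> 0).
#' @return Scalar `f1` in `[0, 1]`.
#' @export
fret_fraction <- function(A, tau_ns, laser_period_ns = 12.5) {
  stopifnot(length(A) == 2, length(tau_ns) == 2)
  if (laser_period_ns <= 0) stop("laser period must be > 0", call. = FALSE)
  if (all(A == 0))
    stop("undefined FRET fraction: both amplitudes are zero", call. = FALSE)
  br <- 1 - exp(-laser_period_ns / tau_ns)
  (A[1] * br[1]) / sum(A * br)
}

#' Amplitude-weighted mean lifetime
#'
#' `tau_a = f1 * tau1 + (1 - f1) * tau2`, the parameter used to quantify
#' energy-transfer efficiency; always lies between the component lifetimes.
#'
#' @param f1 quenched-donor fraction in `[0, 1]`.
#' @param tau1,tau2 component lifetimes, ns.
#' @return Scalar `tau_a`, ns.
#' @export
tau_amp <- function(f1, tau1, tau2) {
  stopifnot(f1 >= 0, f1 <= 1)
  f1 * tau1 + (1 - f1) * tau2
}

#' Non-linear least-squares decay fit
#'
#' Fits the IRF-convolved mono- (`k = 1`) or bi-exponential (`k = 2`) model to
#' a measured decay by variable projection: amplitudes are solved by
#' (weighted) linear least squares at each candidate lifetime set, and the
#' lifetimes are optimized by bounded quasi-Newton search in log-tau space.
#' Weights default to Poisson (Neyman) weights `1 / max(data, 1)`;
#' `weights = "none"` gives ordinary least squares. Initialization: tau from
#' the log-linear slope of the decay tail (last 40% of samples past the
#' peak); for `k = 2` the two components start at `0.5` and `1.5` times that
#' estimate. On output the ordering convention `tau1 <= tau2` is enforced
#' (component 1 = quenched donor).
#'
#' Pixels with fewer than 10 samples above the noise floor are not fitted and
#' return a masked result (`masked = TRUE`), not an error.
#'
#' @param decay measured counts on `time_axis`.
#' @param irf IRF on the same axis ([validate_irf()] or vector).
#' @param k number of exponential components (1 or 2).
#' @param time_axis gate times, ps.
#' @param laser_period_ns laser period for the `f1` correction factors.
#' @param tau_bounds_ns lifetime search bounds, ns.
#' @param weights `"poisson"` or `"none"`.
#' @param baseline fit a constant baseline (default `FALSE`).
#' @param fit_shift also fit an IRF time-shift (default `TRUE`): the nuisance
#'   parameter standard in lifetime NLSF that absorbs the delay between the
#'   measured instrument response and the recorded decay (in turbid samples,
#'   the diffuse photon transit time). Bounds `shift_bounds_ps`.
#' @param shift_bounds_ps search range of the IRF shift, ps.
#' @param init optional numeric vector of starting lifetimes (ns).
#' @return Object of class `fit_result`: `A`, `tau_ns` (sorted), `baseline`,
#'   `f1`, `tau_a_ns`, `r_squared`, `residual_norm`, `fitted`,
#'   `convergence` (list: iterations, status), `masked`.
#' @export
fit_nlsf <- function(decay, irf, k = 1, time_axis,
                     laser_period_ns = 12.5,
                     tau_bounds_ns = c(0.1, 5), weights = c("poisson", "none"),
                     baseline = FALSE, fit_shift = TRUE,
                     shift_bounds_ps = c(-500, 2000), init = NULL) {
  weights <- match.arg(weights)
  stopifnot(k %in% c(1, 2), length(decay) == length(time_axis))
  if (sum(decay > 0) < 10 || max(decay) <= 0)
    return(structure(list(masked = TRUE, A = NULL, tau_ns = NULL,
                          f1 = NA_real_, tau_a_ns = NA_real_,
                          r_squared = NA_real_, residual_norm = NA_real_,
                          fitted = NULL,
                          convergence = list(iterations = 0L, status = "masked")),
                     class = "fit_result"))
  kern <- if (inherits(irf, "irf")) irf$samples else as.numeric(irf)
  kern <- kern / sum(kern)
  t_rel <- time_axis - time_axis[1]
  w <- if (weights == "poisson") 1 / pmax(decay, 1) else rep(1, length(decay))

  # tail log-slope initialization
  if (is.null(init)) {
    ipk <- which.max(decay)
    tail_idx <- seq(max(ipk, floor(length(decay) * 0.6)), length(decay))
    pos <- tail_idx[decay[tail_idx] > 0]
    tau0 <- if (length(pos) >= 3) {
      sl <- coef(lm(log(decay[pos]) ~ t_rel[pos]))[2]
      if (is.finite(sl) && sl < 0) -1 / sl / 1000 else 1
    } else 1
    tau0 <- min(max(tau0, tau_bounds_ns[1] * 1.2), tau_bounds_ns[2] / 1.2)
    init <- if (k == 1) tau0 else c(0.5, 1.5) * tau0
    init <- pmin(pmax(init, tau_bounds_ns[1] * 1.01), tau_bounds_ns[2] * 0.99)
  }

  solve_amps <- function(B) {
    # weighted least squares with non-negative amplitudes (active set by
    # column dropping; k <= 2 so this terminates immediately)
    cols <- seq_len(ncol(B))
    if (baseline) B <- cbind(B, 1)
    repeat {
      bw <- B * sqrt(w)
      a <- tryCatch(qr.coef(qr(bw), decay * sqrt(w)),
                    error = function(e) rep(0, ncol(B)))
      a[is.na(a)] <- 0
      neg <- which(a[cols] < 0)
      if (!length(neg) || length(cols) == 1) {
        a[cols][a[cols] < 0] <- 0
        return(a)
      }
      drop_col <- cols[which.min(a[cols])]
      B[, drop_col] <- 0
      cols <- setdiff(cols, drop_col)
    }
  }
  obj <- function(par) {
    shift <- if (fit_shift) par[k + 1] * 1000 else 0
    B <- decay_basis(kern, exp(par[seq_len(k)]), t_rel, shift)
    a <- solve_amps(B)
    fit <- as.vector(cbind(B, if (baseline) 1) %*% a)
    sum(w * (decay - fit)^2)
  }
  # initialize the shift at the data-vs-IRF peak lag
  shift0 <- 0
  if (fit_shift) {
    lag <- (which.max(decay) - which.max(kern)) * (t_rel[2] - t_rel[1])
    shift0 <- min(max(lag - 300, shift_bounds_ps[1]), shift_bounds_ps[2]) / 1000
  }
  par0 <- c(log(init), if (fit_shift) shift0)
  opt <- optim(par0, obj, method = "L-BFGS-B",
               lower = c(rep(log(tau_bounds_ns[1]), k),
                         if (fit_shift) shift_bounds_ps[1] / 1000),
               upper = c(rep(log(tau_bounds_ns[2]), k),
                         if (fit_shift) shift_bounds_ps[2] / 1000),
               control = list(maxit = 200))
  tau <- exp(opt$par[seq_len(k)])
  shift_ps <- if (fit_shift) opt$par[k + 1] * 1000 else 0
  B <- decay_basis(kern, tau, t_rel, shift_ps)
  a_full <- solve_amps(B)
  A <- a_full[seq_len(k)]
  b0 <- if (baseline) a_full[k + 1] else 0
  fit <- as.vector(cbind(B, if (baseline) 1) %*% a_full)
  ord <- order(tau)
  tau <- tau[ord]; A <- A[ord]
  f1 <- if (k == 2) {
    if (all(A == 0)) NA_real_ else fret_fraction(A, tau, laser_period_ns)
  } else NA_real_
  tau_a <- if (k == 2 && !is.na(f1)) tau_amp(f1, tau[1], tau[2]) else tau[1]
  structure(list(masked = FALSE, A = A, tau_ns = tau, baseline = b0,
                 shift_ps = shift_ps,
                 f1 = f1, tau_a_ns = tau_a,
                 r_squared = r_squared(decay, fit),
                 residual_norm = sqrt(sum((decay - fit)^2)),
                 fitted = fit,
                 convergence = list(iterations = opt$counts[["function"]],
                                    status = if (opt$convergence == 0)
                                      "converged" else "not-converged")),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  if (isTRUE(x$masked)) { cat("<fit_result> masked pixel\n"); return(invisible(x)) }
  cat(sprintf("<fit_result> tau = %s ns, A = %s, f1 = %s, tau_a = %.4g ns, R^2 = %.5f (%s)\n",
              paste(signif(x$tau_ns, 4), collapse = "/"),
              paste(signif(x$A, 4), collapse = "/"),
              if (is.na(x$f1)) "NA" else signif(x$f1, 4),
              x$tau_a_ns, x$r_squared, x$convergence$status))
  invisible(x)
}
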