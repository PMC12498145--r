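#' Per-pixel lifetime fitting of a gated stack
#'
#' Runs [fit_nlsf()] on every pixel whose peak gate count passes the intensity
#' mask (`peak >= max(min_counts, peak_frac * image peak)`), and summarizes
#' each labeled ROI (mean, SD, pixel count for tau, f1, tau_a, intensity).
#' The result is deterministic given the stack and settings, independent of
#' pixel evaluation order.
#'
#' @param stack a [gated_stack()].
#' @param irf global IRF on the gate axis, or a per-pixel `irf`.
#' @param k components per pixel (1 or 2).
#' @param roi_labels optional integer ROI label matrix (H x W, 0 =
#'   background); when given, per-ROI statistics are returned.
#' @param min_counts absolute peak-count threshold of the mask.
#' @param peak_frac relative threshold (fraction of the image peak).
#' @param ... further arguments to [fit_nlsf()].
#' @return Object of class `fit_map`: list with parameter images `tau`
#'   (`tau1` and `tau2` for k = 2), `f1`, `tau_a`, `r_squared`, `intensity`,
#'   the logical `mask`, `n_fitted`, and `roi` (data.frame of ROI statistics
#'   or NULL).
#' @export
fit_stack <- function(stack, irf, k = 1, roi_labels = NULL,
                      min_counts = 50, peak_frac = 0.02, ...) {
  stopifnot(inherits(stack, "gated_stack"))
  d <- dim(stack$data)
  ta <- make_time_axis(stack$config)
  peak <- apply(stack$data, c(2, 3), max)
  thr <- max(min_counts, peak_frac * max(peak))
  mask <- peak >= thr
  if (!any(mask))
    stop("empty pixel mask: no pixel peak reaches the threshold (", thr,
         " counts)", call. = FALSE)
  per_pixel_irf <- inherits(irf, "irf") && irf$per_pixel
  namat <- function() matrix(NA_real_, d[2], d[3])
  tau1 <- namat(); tau2 <- namat(); f1 <- namat(); tau_a <- namat()
  r2 <- namat()
  idx <- which(mask, arr.ind = TRUE)
  for (p in seq_len(nrow(idx))) {
    i <- idx[p, 1]; j <- idx[p, 2]
    kirf <- if (per_pixel_irf) irf$samples[, i, j] else irf
    fr <- fit_nlsf(stack$data[, i, j], kirf, k = k, time_axis = ta,
                   laser_period_ns = stack$config$laser_period_ns, ...)
    if (isTRUE(fr$masked)) next
    tau1[i, j] <- fr$tau_ns[1]
    if (k == 2) { tau2[i, j] <- fr$tau_ns[2]; f1[i, j] <- fr$f1 }
    tau_a[i, j] <- fr$tau_a_ns
    r2[i, j] <- fr$r_squared
  }
  roi <- NULL
  if (!is.null(roi_labels)) {
    roi_labels <- as.matrix(roi_labels)
    stopifnot(identical(dim(roi_labels), d[2:3]))
    roi <- roi_stats(list(tau = tau1, tau2 = if (k == 2) tau2 else NULL,
                          f1 = if (k == 2) f1 else NULL, tau_a = tau_a,
                          r_squared = r2, intensity = peak),
                     roi_labels)
  }
  structure(list(tau = tau1, tau2 = if (k == 2) tau2 else NULL,
                 f1 = if (k == 2) f1 else NULL, tau_a = tau_a,
                 r_squared = r2, intensity = peak, mask = mask,
                 n_fitted = sum(!is.na(tau1)), roi = roi, k = k),
            class = "fit_map")
}

#' ROI summary statistics of quantity images
#'
#' Mean, standard deviation and pixel count of each quantity image over each
#' positive ROI label, skipping unfitted (NA) pixels.
#'
#' @param quantities named list of H x W numeric matrices (NULL entries are
#'   dropped).
#' @param roi_labels integer label matrix (0 = background).
#' @return data.frame with columns `roi`, `quantity`, `mean`, `sd`, `n`.
#' @export
roi_stats <- function(quantities, roi_labels) {
  quantities <- Filter(Negate(is.null), quantities)
  labs <- sort(unique(roi_labels[roi_labels > 0]))
  out <- list()
  for (lb in labs) {
    sel <- roi_labels == lb
    for (qn in names(quantities)) {
      v <- quantities[[qn]][sel]
      v <- v[!is.na(v)]
      out[[length(out) + 1]] <- data.frame(
        roi = lb, quantity = qn,
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) > 1) sd(v) else 0,
        n = length(v))
    }
  }
  do.call(rbind, out)
}

#' @export
print.fit_map <- function(x, ...) {
  cat(sprintf("<fit_map> k = %d, %d pixel(s) fitted (mask %d), mean tau %.4g ns, mean R^2 %.5f\n",
              x$k, x$n_fitted, sum(x$mask),
              mean(x$tau, na.rm = TRUE), mean(x$r_squared, na.rm = TRUE)))
  invisible(x)
}
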