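#' Generate an 8-bit sinusoidal illumination pattern
#'
#' A 1-D sinusoid along the image columns (x axis), extruded along rows:
#' `round((2^bit_depth - 1)/2 * (1 + cos(2*pi*fx*x + phase)))` with
#' `x = (col - 0.5) * pixel_pitch_mm` (origin at the image corner). This is the
#' digital pattern a DMD projector would display; gray levels are integers in
#' `[0, 2^bit_depth - 1]`. `fx = 0` yields a uniform image at the maximum gray
#' level. Patterns above the Nyquist limit of the pixel grid (fewer than ~4
#' pixels per period by default) are rejected as undersampled.
#'
#' @param fx spatial frequency along x, mm^-1 (>= 0).
#' @param phase phase offset, radians (the three-phase scheme uses 0, 2pi/3,
#'   4pi/3).
#' @param shape `c(H, W)` image size in pixels.
#' @param pixel_pitch_mm projector/detector pixel pitch, mm.
#' @param bit_depth quantization depth (8 for a DMD gray-scale pattern).
#' @param min_pixels_per_period sampling adequacy limit.
#' @return Object of class `illum_pattern`: list with `image` (H x W integer
#'   gray levels), `fx`, `phase`, `bit_depth`, `pixel_pitch_mm`.
#' @export
generate_sinusoid <- function(fx, phase, shape, pixel_pitch_mm, bit_depth = 8,
                              min_pixels_per_period = 4) {
  if (!is.finite(fx) || fx < 0) stop("fx must be >= 0", call. = FALSE)
  if (pixel_pitch_mm <= 0) stop("pixel_pitch_mm must be > 0", call. = FALSE)
  if (fx > 0 && 1 / (fx * pixel_pitch_mm) < min_pixels_per_period)
    stop("undersampled pattern: fx = ", fx, " mm^-1 gives ",
         round(1 / (fx * pixel_pitch_mm), 2),
         " pixels per period (need >= ", min_pixels_per_period, ")",
         call. = FALSE)
  H <- shape[1]; W <- shape[2]
  amax <- 2^bit_depth - 1
  x <- (seq_len(W) - 0.5) * pixel_pitch_mm
  row <- round(amax / 2 * (1 + cos(2 * pi * fx * x + phase)))
  image <- matrix(rep(row, each = H), nrow = H)
  structure(list(image = image, fx = fx, phase = phase, bit_depth = bit_depth,
                 pixel_pitch_mm = pixel_pitch_mm),
            class = "illum_pattern")
}

#' Three-phase pattern triplet
#'
#' The three patterns at phases `phase0 + {0, 2pi/3, 4pi/3}` used by the
#' three-phase demodulation scheme.
#'
#' @inheritParams generate_sinusoid
#' @param phase0 global phase offset of the first pattern.
#' @return List of three `illum_pattern` objects.
#' @export
pattern_triplet <- function(fx, shape, pixel_pitch_mm, bit_depth = 8,
                            phase0 = 0) {
  lapply(phase0 + c(0, 2, 4) * pi / 3, function(p)
    generate_sinusoid(fx, p, shape, pixel_pitch_mm, bit_depth))
}

#' Source modulation depth of a projected pattern triplet
#'
#' Applies the three-phase demodulation identity to the pattern images
#' themselves: `M_S = mean(I_P_AC) / mean(I_P_DC)` over the analysis region.
#' For an ideal full-swing sinusoid this is 1 (up to 8-bit quantization); a
#' uniform (zero-frequency) triplet has no modulation and is an error.
#'
#' @param patterns list of three `illum_pattern` objects (or three numeric
#'   matrices) sharing `fx` and differing by the 2pi/3 offsets.
#' @param roi_mask optional logical matrix selecting the analysis region.
#' @return Scalar `M_S` in (0, 1].
#' @export
source_modulation <- function(patterns, roi_mask = NULL) {
  imgs <- lapply(patterns, function(p)
    if (inherits(p, "illum_pattern")) p$image else as.matrix(p))
  stopifnot(length(imgs) == 3)
  dm <- demodulate_triplet(imgs[[1]], imgs[[2]], imgs[[3]], clamp = FALSE)
  if (is.null(roi_mask)) roi_mask <- matrix(TRUE, nrow(imgs[[1]]), ncol(imgs[[1]]))
  ac <- mean(dm$I_AC[roi_mask]); dc <- mean(dm$I_DC[roi_mask])
  if (ac <= 0)
    stop("zero-modulation source: the pattern triplet has no AC component",
         call. = FALSE)
  ac / dc
}

#' Lateral resolution of structured illumination at frequency fx
#'
#' The smallest resolvable lateral feature equals half the projected pattern
#' period, `1 / (2 * fx)`; at the practical frequency limit of 0.6 mm^-1 this
#' is ~0.83 mm.
#'
#' @param fx spatial frequency, mm^-1 (> 0).
#' @return Half-period, mm.
#' @export
lateral_resolution <- function(fx) {
  if (any(fx <= 0)) stop("fx must be > 0", call. = FALSE)
  1 / (2 * fx)
}

#' @export
print.illum_pattern <- function(x, ...) {
  cat(sprintf("<illum_pattern> fx = %g mm^-1, phase = %.4g rad, %dx%d px @ %g mm, %d-bit\n",
              x$fx, x$phase, nrow(x$image), ncol(x$image), x$pixel_pitch_mm,
              x$bit_depth))
  invisible(x)
}
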