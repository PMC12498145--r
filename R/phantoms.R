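#' Synthetic phantom specification
#'
#' Parameterizes the phantom geometries used throughout: a tube tilted through
#' the depth axis (`tilted_tube`), the 8-tube depth ladder (`depth_ladder`), a
#' single tube at a prescribed depth for MTF calibration sweeps
#' (`single_tube`), scattering-free dye wells (`well_plate`), and a thin
#' surface emitter over a deep inclusion (`two_layer`) — the minimal geometry
#' for surface-removal tests.
#'
#' Depths are measured from the illuminated surface to the *top* of the
#' inclusion. Defaults follow the standard agar/intralipid capillary phantoms:
#' bulk `mu_a = 0.002 mm^-1`, `mu_s' = 1 mm^-1` (`0.02 mm^-1` absorption for
#' the depth ladder), dye `mu_a = 0.04 mm^-1`, `mu_s' = 0.09 mm^-1`, 1 mm
#' capillaries, ladder tube 1 at 0.4 mm with 1 mm depth increments, AF700-like
#' fluorophore (lifetime 0.9 ns).
#'
#' @param kind one of `"tilted_tube"`, `"depth_ladder"`, `"single_tube"`,
#'   `"well_plate"`, `"two_layer"`.
#' @param ... overrides of the kind-specific defaults (see Details in the
#'   package vignette).
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(kind = c("depth_ladder", "tilted_tube", "single_tube",
                                  "well_plate", "two_layer"), ...) {
  kind <- match.arg(kind)
  base <- list(field_mm = c(24, 24), thickness_mm = 10, voxel_size_mm = 0.1,
               bulk = optical_properties(0.002, 1),
               dye = optical_properties(0.04, 0.09),
               fluor = list(yield = 1, lifetime_ns = 0.9),
               tube_diameter_mm = 1)
  extra <- switch(kind,
    depth_ladder = list(n_tubes = 8L, first_depth_mm = 0.4, depth_step_mm = 1,
                        tube_spacing_mm = 2.5, tube_length_mm = 20,
                        bulk = optical_properties(0.02, 1)),
    single_tube = list(depth_mm = 0.5, tube_length_mm = 20),
    tilted_tube = list(depth_start_mm = 0, depth_end_mm = 4,
                       tube_length_mm = 20),
    well_plate = list(well_diameter_mm = 6, well_depth_mm = 2,
                      bulk = optical_properties(1e-4, 0, g = 0, n = 1.33),
                      dye = optical_properties(0.04, 0, g = 0, n = 1.33),
                      thickness_mm = 5),
    two_layer = list(surface_thickness_mm = 0.2, surface_yield = 2,
                     surface_lifetime_ns = 0.5, surface_mu_a = 0.01,
                     depth_mm = 1.5, tube_length_mm = 20))
  spec <- modifyList(modifyList(base, extra), list(...))
  spec$kind <- kind
  class(spec) <- "phantom_spec"
  spec
}

#' Build a voxelized volume from a phantom specification
#'
#' Rasterizes the inclusions into a [voxel_volume()] by center-in-voxel
#' membership; fluorophore yield/lifetime maps are set inside inclusions only.
#' FRET mixtures (a `fluor` given as a list of `(yield, lifetime_ns,
#' amplitude)` components) are realized by assigning components to inclusion
#' voxels in proportion to their amplitudes — at the macroscopic pixel scale
#' each camera pixel averages many voxels, which reproduces the
#' multi-exponential mixture decay.
#'
#' @param spec a [phantom_spec()].
#' @return A [voxel_volume()].
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$voxel_size_mm
  nx <- round(spec$field_mm[1] / h)
  ny <- round(spec$field_mm[2] / h)
  nz <- round(spec$thickness_mm / h)
  cx <- (seq_len(nx) - 0.5) * h
  cy <- (seq_len(ny) - 0.5) * h
  cz <- (seq_len(nz) - 0.5) * h
  labels <- array(1L, c(nx, ny, nz))
  yield <- array(0, c(nx, ny, nz))
  tau <- array(0, c(nx, ny, nz))
  r <- spec$tube_diameter_mm / 2

  check_inside <- function(depth_top, what) {
    if (depth_top < 0 || depth_top + 2 * r > spec$thickness_mm)
      stop("inclusion (", what, ") lies outside the volume", call. = FALSE)
  }
  # mark a y-axis tube: center x position xc, axis depth zc (tube center)
  mark_tube_y <- function(xc, zc, length_mm) {
    if (r <= 0) return(invisible())
    y_ok <- abs(cy - spec$field_mm[2] / 2) <= length_mm / 2
    dx2 <- outer((cx - xc)^2, (cz - zc)^2, "+")  # nx x nz
    inside <- dx2 <= r^2
    for (k in seq_len(nz)) {
      ii <- which(inside[, k])
      if (length(ii)) {
        labels[ii, y_ok, k] <<- 2L
      }
    }
  }
  # tube along x whose center depth varies linearly with x
  mark_tube_tilted <- function(z_of_x, length_mm) {
    if (r <= 0) return(invisible())
    x_ok <- which(abs(cx - spec$field_mm[1] / 2) <= length_mm / 2)
    yc <- spec$field_mm[2] / 2
    for (i in x_ok) {
      zc <- z_of_x(cx[i])
      d2 <- outer((cy - yc)^2, (cz - zc)^2, "+")
      sel <- which(d2 <= r^2, arr.ind = TRUE)
      if (nrow(sel)) labels[cbind(i, sel)] <<- 2L
    }
  }

  if (spec$kind == "depth_ladder") {
    x0 <- spec$field_mm[1] / 2 -
      (spec$n_tubes - 1) / 2 * spec$tube_spacing_mm
    for (j in seq_len(spec$n_tubes)) {
      depth <- spec$first_depth_mm + (j - 1) * spec$depth_step_mm
      check_inside(depth, paste0("tube ", j))
      mark_tube_y(x0 + (j - 1) * spec$tube_spacing_mm, depth + r,
                  spec$tube_length_mm)
    }
  } else if (spec$kind == "single_tube") {
    check_inside(spec$depth_mm, "tube")
    mark_tube_y(spec$field_mm[1] / 2, spec$depth_mm + r, spec$tube_length_mm)
  } else if (spec$kind == "tilted_tube") {
    check_inside(min(spec$depth_start_mm, spec$depth_end_mm), "tube (shallow end)")
    check_inside(max(spec$depth_start_mm, spec$depth_end_mm), "tube (deep end)")
    xa <- spec$field_mm[1] / 2 - spec$tube_length_mm / 2
    slope <- (spec$depth_end_mm - spec$depth_start_mm) / spec$tube_length_mm
    mark_tube_tilted(function(x) spec$depth_start_mm + r +
                                 slope * pmin(pmax(x - xa, 0), spec$tube_length_mm),
                     spec$tube_length_mm)
  } else if (spec$kind == "well_plate") {
    if (spec$well_depth_mm > spec$thickness_mm)
      stop("inclusion (well) lies outside the volume", call. = FALSE)
    rw <- spec$well_diameter_mm / 2
    d2 <- outer((cx - spec$field_mm[1] / 2)^2, (cy - spec$field_mm[2] / 2)^2, "+")
    inside <- d2 <= rw^2
    kz <- which(cz <= spec$well_depth_mm)
    for (k in kz) labels[, , k][inside] <- 2L
  } else if (spec$kind == "two_layer") {
    check_inside(spec$depth_mm, "deep tube")
    mark_tube_y(spec$field_mm[1] / 2, spec$depth_mm + r, spec$tube_length_mm)
    # skin-like surface emitter: bulk scattering, its own absorption, bright
    # short-lifetime fluorescence (the surface-dominated regime the
    # subtraction targets)
    ks <- which(cz <= spec$surface_thickness_mm)
    for (k in ks) {
      sl <- labels[, , k]
      sl[sl == 1L] <- 3L
      labels[, , k] <- sl
    }
    yield[, , ks][labels[, , ks] == 3L] <- spec$surface_yield
    tau[, , ks][labels[, , ks] == 3L] <- spec$surface_lifetime_ns
  }

  # fluorophore maps inside label-2 inclusions
  incl <- labels == 2L
  fl <- spec$fluor
  if (!is.null(fl$yield)) {            # single component
    yield[incl] <- fl$yield
    tau[incl] <- fl$lifetime_ns
  } else {                             # mixture components
    amps <- vapply(fl, function(c) c$amplitude, numeric(1))
    idx <- which(incl)
    if (length(idx)) {
      # deterministic even interleaving of components in proportion to their
      # amplitudes (reproducible, seed-free): each component ci claims voxels
      # at evenly spaced quantile positions
      n <- length(idx)
      ni <- diff(round(cumsum(c(0, amps)) / sum(amps) * n))
      keys <- unlist(lapply(ni, function(m) if (m > 0) (seq_len(m) - 0.5) / m else numeric(0)))
      comps <- rep(seq_along(fl), times = ni)
      comp <- comps[order(keys)]  # interleaved component sequence, array order
      for (ci in seq_along(fl)) {
        sel <- idx[comp == ci]
        yield[sel] <- fl[[ci]]$yield
        tau[sel] <- fl[[ci]]$lifetime_ns
      }
    }
  }
  props <- list(spec$bulk, spec$dye)
  if (spec$kind == "two_layer")
    props <- c(props, list(optical_properties(spec$surface_mu_a,
                                              spec$bulk$mu_s_prime,
                                              g = spec$bulk$g,
                                              n = spec$bulk$n)))
  voxel_volume(labels, props, h,
               fluor_yield = yield, fluor_lifetime_ns = tau)
}

#' Per-tube analysis masks for tube phantoms
#'
#' Returns an integer ROI label image (H x W on the camera grid) marking the
#' surface projection of each tube (1-based tube index), restricted to a
#' central band along the tube axis to avoid end effects.
#'
#' @param spec a [phantom_spec()] of kind `depth_ladder`, `single_tube` or
#'   `two_layer`.
#' @param pixel_pitch_mm camera pixel pitch.
#' @param band_mm length of the central band along the tube axis.
#' @return Integer matrix (H rows = y, W cols = x); 0 = background.
#' @export
tube_roi_labels <- function(spec, pixel_pitch_mm, band_mm = 10) {
  stopifnot(inherits(spec, "phantom_spec"))
  W <- round(spec$field_mm[1] / pixel_pitch_mm)
  H <- round(spec$field_mm[2] / pixel_pitch_mm)
  px <- (seq_len(W) - 0.5) * pixel_pitch_mm
  py <- (seq_len(H) - 0.5) * pixel_pitch_mm
  lab <- matrix(0L, H, W)
  r <- spec$tube_diameter_mm / 2
  y_ok <- abs(py - spec$field_mm[2] / 2) <= band_mm / 2
  centers <- switch(spec$kind,
    depth_ladder = spec$field_mm[1] / 2 -
      (spec$n_tubes - 1) / 2 * spec$tube_spacing_mm +
      (seq_len(spec$n_tubes) - 1) * spec$tube_spacing_mm,
    single_tube = spec$field_mm[1] / 2,
    two_layer = spec$field_mm[1] / 2,
    stop("no tube ROI for phantom kind ", spec$kind, call. = FALSE))
  for (j in seq_along(centers)) {
    x_ok <- abs(px - centers[j]) <= r
    lab[y_ok, x_ok] <- j
  }
  lab
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> kind = %s, field %g x %g mm, %g mm thick, voxel %g mm\n",
              x$kind, x$field_mm[1], x$field_mm[2], x$thickness_mm,
              x$voxel_size_mm))
  invisible(x)
}
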