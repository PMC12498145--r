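#' Sample scattering deflection cosines (Henyey-Greenstein)
#'
#' Draws deflection cosines from the Henyey-Greenstein phase function with
#' anisotropy `g` (the first moment of the distribution equals `g`). Uses R's
#' RNG, so `set.seed()` controls reproducibility.
#'
#' @param n number of draws.
#' @param g anisotropy, |g| < 1.
#' @return Numeric vector of cosines in `[-1, 1]`.
#' @export
sample_scattering_cosine <- function(n, g) {
  if (abs(g) >= 1) stop("|g| must be < 1", call. = FALSE)
  .cpp_hg_sample(as.integer(n), g)
}

# default survival-weighting / roulette parameters
.mc_defaults <- list(w_min = 1e-4, p_survive = 0.1, n_out = 1.0)

#' Excitation-step Monte Carlo transport
#'
#' Propagates excitation photons through a [voxel_volume()] and tallies the
#' absorbed energy. The photon clock advances by `pathlength * n / c`
#' (`c = 0.299792 mm/ps`); the top surface applies Fresnel
#' reflection/refraction for the refractive-index mismatch (including the
#' specular entry loss); side and bottom faces absorb. Inside fluorescent
#' voxels every absorption event is recorded with its exact position, time,
#' deposited weight and the photon's launch x-position — the tag that lets
#' [reweight_by_pattern()] synthesize any pattern frequency and phase from a
#' single uniform-illumination run.
#'
#' Energy bookkeeping is exact per run:
#' `launched = specular + absorbed + escaped + roulette_net` to ~1e-9 relative.
#'
#' @param volume a [voxel_volume()].
#' @param n_photons number of photons to launch (>= 1).
#' @param source launch sampler: `list(type = "planar")` (uniform collimated
#'   over the full field, the default), `list(type = "pencil", x, y)`, or
#'   `list(type = "pattern", pattern = illum_pattern)` for direct
#'   pattern-modulated launching (used to cross-check reweighting).
#' @param seed optional integer passed to `set.seed()`.
#' @param record_reflectance record the table of photons escaping the top
#'   surface (diffuse reflectance).
#' @param record_all_exits also tabulate bottom/side exits (face codes 1/2).
#' @return Object of class `mc_excitation`: list with
#'   `absorbed` (nx,ny,nz time-integrated grid), `events` (absorption-event
#'   matrix in fluorescent voxels), `reflectance` (exit table or NULL),
#'   `totals` (energy bookkeeping), `volume`, `n_photons`, `source`, `seed`.
#' @export
propagate_excitation <- function(volume, n_photons,
                                 source = list(type = "planar"),
                                 seed = NULL,
                                 record_reflectance = FALSE,
                                 record_all_exits = FALSE) {
  stopifnot(inherits(volume, "voxel_volume"))
  n_photons <- as.integer(n_photons)
  if (n_photons < 1) stop("n_photons must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  d <- dim(volume$tissue_label)
  h <- volume$voxel_size_mm
  pm <- props_matrix(volume$properties)
  n_in <- volume$properties[[1]]$n
  stype <- switch(source$type, planar = 0L, pencil = 1L, pattern = 2L,
                  stop("unknown source type: ", source$type, call. = FALSE))
  spos <- c(0, 0)
  launch_x <- numeric(0)
  if (stype == 1L) spos <- c(source$x, source$y)
  if (stype == 2L) {
    pat <- source$pattern
    stopifnot(inherits(pat, "illum_pattern"))
    # sample launch x positions proportional to the pattern profile
    prof <- pat$image[1, ]
    if (sum(prof) <= 0) stop("all-zero launch pattern", call. = FALSE)
    col <- sample.int(length(prof), n_photons, replace = TRUE, prob = prof)
    launch_x <- (col - runif(n_photons)) * pat$pixel_pitch_mm
  }
  res <- .cpp_mc_excitation(as.vector(volume$tissue_label), d, h, pm,
                            as.vector(volume$fluor_yield),
                            n_in, .mc_defaults$n_out,
                            n_photons, stype, spos, launch_x,
                            .mc_defaults$w_min, .mc_defaults$p_survive,
                            TRUE, record_reflectance || record_all_exits,
                            record_all_exits, -1)
  tot <- res$totals
  # for pattern-modulated launches each photon represents mean(pattern)/amax
  # source energy so that reweighted and direct runs share a normalization
  src_scale <- 1
  if (stype == 2L) {
    amax <- 2^source$pattern$bit_depth - 1
    src_scale <- mean(source$pattern$image) / amax
  }
  structure(list(absorbed = res$absorbed * src_scale,
                 events = sweep_events(res$events, src_scale),
                 reflectance = if (record_reflectance || record_all_exits)
                   scale_exits(res$detected, src_scale) else NULL,
                 totals = tot, source_scale = src_scale,
                 volume = volume, n_photons = n_photons, source = source,
                 seed = seed),
            class = "mc_excitation")
}

sweep_events <- function(ev, s) {
  if (s != 1 && nrow(ev)) ev[, "weight"] <- ev[, "weight"] * s
  ev
}
scale_exits <- function(det, s) {
  if (s != 1 && nrow(det)) det[, "weight"] <- det[, "weight"] * s
  det
}

#' Form fluorescence emission sources from absorbed excitation
#'
#' Converts the absorption events recorded inside fluorescent voxels into an
#' emission source table: each event's deposited weight is multiplied by the
#' local relative quantum yield, and the local fluorescence lifetime is
#' attached. The emission time kernel (excitation arrival convolved with
#' `(1/tau) exp(-t/tau)`) is realized stochastically at launch time by adding
#' an exponential delay, so the total emitted energy
#' `sum(absorbed * yield)` is independent of `tau` by construction.
#'
#' @param excitation result of [propagate_excitation()].
#' @param volume the same [voxel_volume()] (defaults to the one stored in
#'   `excitation`).
#' @return Object of class `emission_sources`: list with `events`
#'   (x, y, z, t_ps, weight, launch_x, tau_ns), `total_energy`, `volume`.
#' @export
form_emission_sources <- function(excitation, volume = excitation$volume) {
  stopifnot(inherits(excitation, "mc_excitation"),
            inherits(volume, "voxel_volume"))
  if (any(volume$fluor_yield > 0 & volume$fluor_lifetime_ns <= 0))
    stop("fluor_yield > 0 where fluor_lifetime <= 0", call. = FALSE)
  ev <- excitation$events
  if (nrow(ev) == 0) {
    events <- cbind(ev[, c("x", "y", "z", "t_ps", "weight", "launch_x"),
                       drop = FALSE],
                    tau_ns = numeric(0))
    return(structure(list(events = events, total_energy = 0, volume = volume),
                     class = "emission_sources"))
  }
  vox <- as.integer(ev[, "voxel"])
  yield <- as.vector(volume$fluor_yield)[vox]
  tau <- as.vector(volume$fluor_lifetime_ns)[vox]
  keep <- yield > 0
  events <- cbind(ev[keep, c("x", "y", "z", "t_ps", "weight", "launch_x"),
                     drop = FALSE],
                  tau_ns = tau[keep])
  events[, "weight"] <- events[, "weight"] * yield[keep]
  structure(list(events = events, total_energy = sum(events[, "weight"]),
                 volume = volume),
            class = "emission_sources")
}

#' Sample emission start times from a source table
#'
#' Draws `n` emission events (index sampled proportional to source energy) and
#' returns launch rows with start time = excitation arrival time + an
#' exponential lifetime delay. Exposed for tests of the emission time kernel;
#' [propagate_emission()] calls it internally.
#'
#' @param sources an [form_emission_sources()] result.
#' @param n number of emission photons.
#' @param equal_weight if `TRUE` (default) each sampled photon carries
#'   `total_energy / n`; otherwise the raw event weights are kept.
#' @return Matrix with columns x, y, z, t_ps, weight, launch_x.
#' @export
sample_emission_launches <- function(sources, n, equal_weight = TRUE) {
  stopifnot(inherits(sources, "emission_sources"))
  ev <- sources$events
  if (nrow(ev) == 0 || sources$total_energy <= 0)
    stop("empty emission source distribution", call. = FALSE)
  # weighted sampling with replacement via inverse-CDF binary search
  # (sample.int(prob =) is O(rows x draws) and infeasible at MC scale)
  cw <- cumsum(ev[, "weight"])
  idx <- findInterval(runif(n) * cw[length(cw)], cw) + 1L
  idx[idx > nrow(ev)] <- nrow(ev)
  delay_ps <- rexp(n, rate = 1) * ev[idx, "tau_ns"] * 1000
  out <- cbind(x = ev[idx, "x"], y = ev[idx, "y"], z = ev[idx, "z"],
               t_ps = ev[idx, "t_ps"] + delay_ps,
               weight = if (equal_weight) rep(sources$total_energy / n, n)
                        else ev[idx, "weight"],
               launch_x = ev[idx, "launch_x"])
  out
}

#' Emission-step Monte Carlo transport
#'
#' Second step of the two-step fluorescence workflow: launches fluorescence
#' photons isotropically from the emission source distribution (position and
#' start time sampled by [sample_emission_launches()]) and propagates them
#' through the volume under the emission-wavelength optical properties,
#' recording the photons that escape the top surface (exit position, exit
#' time, statistical weight, inherited launch-x tag).
#'
#' @param volume a [voxel_volume()].
#' @param sources an [form_emission_sources()] result (or a launch matrix).
#' @param n_photons number of emission photons to launch.
#' @param seed optional integer for `set.seed()`.
#' @param t_max_ps drop photons whose clock exceeds this (0 = no limit).
#' @return Object of class `surface_record`: list with `detected` (matrix
#'   x, y, t_ps, weight, launch_x, face == 0), `totals`, `field_mm`
#'   (lateral extents), `n_photons`, `seed`.
#' @export
propagate_emission <- function(volume, sources, n_photons, seed = NULL,
                               t_max_ps = 0) {
  stopifnot(inherits(volume, "voxel_volume"))
  if (!is.null(seed)) set.seed(seed)
  launches <- if (is.matrix(sources)) sources
              else sample_emission_launches(sources, as.integer(n_photons))
  d <- dim(volume$tissue_label)
  h <- volume$voxel_size_mm
  pm <- props_matrix(volume$properties_em)
  n_in <- volume$properties_em[[1]]$n
  res <- .cpp_mc_emission(as.vector(volume$tissue_label), d, h, pm,
                          n_in, .mc_defaults$n_out, launches,
                          .mc_defaults$w_min, .mc_defaults$p_survive,
                          TRUE, FALSE, if (t_max_ps > 0) t_max_ps else -1)
  structure(list(detected = res$detected, totals = res$totals,
                 absorbed = res$absorbed,
                 field_mm = c(d[1] * h, d[2] * h),
                 n_photons = nrow(launches), seed = seed),
            class = "surface_record")
}

#' @export
print.surface_record <- function(x, ...) {
  cat(sprintf("<surface_record> %d detected photons over %g x %g mm (launched weight %.4g, detected %.4g)\n",
              nrow(x$detected), x$field_mm[1], x$field_mm[2],
              x$totals[["launched"]], sum(x$detected[, "weight"])))
  invisible(x)
}

#' Synthesize a surface image stack for an illumination pattern
#'
#' Uses the linearity of photon transport: a single uniform-illumination run
#' tags every detected fluorescence photon with the x-position at which its
#' excitation ancestor was launched, so weighting each photon by the pattern
#' transmission at that x reproduces, in expectation, a direct simulation
#' under pattern-modulated launching. Returns a time-resolved surface stack
#' histogrammed on the camera grid.
#'
#' @param record a [propagate_emission()] `surface_record` whose photons carry
#'   launch-x tags.
#' @param pattern an `illum_pattern` ([generate_sinusoid()]) — or `NULL` for
#'   unit weights (uniform illumination).
#' @param pixel_pitch_mm camera pixel pitch; defaults to the pattern's.
#' @param time_bin_ps width of the fine time bins (default 10 ps).
#' @param t_range_ps time range `c(t0, t1)`; default `c(0, 12500)` (one laser
#'   period). Use `NULL` for a time-integrated (single-bin) image.
#' @return Object of class `time_stack`: list with `data` (nt x H x W array),
#'   `t0_ps`, `time_bin_ps`, `pixel_pitch_mm`.
#' @export
reweight_by_pattern <- function(record, pattern = NULL,
                                pixel_pitch_mm = NULL,
                                time_bin_ps = 10, t_range_ps = c(0, 12500)) {
  stopifnot(inherits(record, "surface_record"))
  det <- record$detected
  if (!("launch_x" %in% colnames(det)))
    stop("surface record lacks launch-x tags", call. = FALSE)
  w <- det[, "weight"]
  if (!is.null(pattern)) {
    stopifnot(inherits(pattern, "illum_pattern"))
    amax <- 2^pattern$bit_depth - 1
    prof <- pattern$image[1, ]
    col <- pmin(pmax(ceiling(det[, "launch_x"] / pattern$pixel_pitch_mm), 1L),
                length(prof))
    w <- w * prof[col] / amax
    if (is.null(pixel_pitch_mm)) pixel_pitch_mm <- pattern$pixel_pitch_mm
  }
  if (is.null(pixel_pitch_mm))
    stop("pixel_pitch_mm required when no pattern is given", call. = FALSE)
  nx_img <- round(record$field_mm[1] / pixel_pitch_mm)
  ny_img <- round(record$field_mm[2] / pixel_pitch_mm)
  if (is.null(t_range_ps)) {
    t0 <- 0; dt <- 1; nt <- 1L
  } else {
    t0 <- t_range_ps[1]; dt <- time_bin_ps
    nt <- as.integer(ceiling((t_range_ps[2] - t_range_ps[1]) / dt))
  }
  data <- .cpp_bin_stack(det[, "x"], det[, "y"], det[, "t_ps"], w,
                         pixel_pitch_mm, nx_img, ny_img, t0, dt, nt)
  structure(list(data = data, t0_ps = t0, time_bin_ps = dt,
                 pixel_pitch_mm = pixel_pitch_mm),
            class = "time_stack")
}

#' Two-step fluorescence simulation for a pattern set
#'
#' Convenience driver for the full forward model: one excitation run under
#' uniform illumination, emission-source formation, one emission run, then
#' pattern synthesis by reweighting for every requested `(fx, phase)` pattern.
#' With `camera` supplied the result is IRF-convolved, gate-integrated and
#' returned as [gated_stack()]s; otherwise raw time-resolved stacks.
#'
#' @param volume a [voxel_volume()].
#' @param patterns list of `illum_pattern`s (e.g. from [pattern_triplet()]).
#' @param n_photons excitation photon budget.
#' @param n_emission emission photon budget (default `2 * n_photons`).
#' @param camera optional [camera_model()]; when given, output stacks are
#'   camera-ready (`gated_stack`s).
#' @param irf optional [validate_irf()] IRF on the fine time axis used before
#'   gating (see [apply_gating()]).
#' @param seed integer seed (controls both MC steps).
#' @param time_bin_ps fine histogram bin.
#' @return List with `stacks` (one per pattern), `excitation`, `sources`,
#'   `record`, `totals`.
#' @export
simulate_two_step <- function(volume, patterns, n_photons,
                              n_emission = 2 * n_photons,
                              camera = NULL, irf = NULL, seed = 1,
                              time_bin_ps = 10) {
  exc <- propagate_excitation(volume, n_photons, seed = seed)
  src <- form_emission_sources(exc)
  if (src$total_energy <= 0) {
    # non-fluorescent volume: zero stacks
    stacks <- lapply(patterns, function(p) NULL)
    return(list(stacks = stacks, excitation = exc, sources = src,
                record = NULL, totals = exc$totals))
  }
  rec <- propagate_emission(volume, src, n_emission, seed = seed + 1L)
  stacks <- lapply(patterns, function(p) {
    ts <- reweight_by_pattern(rec, p, time_bin_ps = time_bin_ps)
    if (!is.null(camera)) apply_gating(ts, camera, irf = irf) else ts
  })
  list(stacks = stacks, excitation = exc, sources = src, record = rec,
       totals = exc$totals)
}
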