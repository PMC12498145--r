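#' Reference acceptance experiments
#'
#' Canonical desk-scale reproductions of the phantom claims, shared by the
#' test suite and `scripts/acceptance.R`. Budgets are reduced relative to the
#' GPU-scale originals and are part of the stated experiment, not tuning
#' knobs.
#'
#' `acceptance_mtf_point()` simulates the single-capillary calibration phantom
#' (bulk `mu_a = 0.002`, `mu_s' = 1`, `g = 0.9`, `n = 1.37`; 1 mm dye-filled
#' tube) at one depth and returns the demodulated MTF at the requested
#' frequencies.
#'
#' @param depth_mm tube-top depth below the surface.
#' @param fx spatial frequencies to synthesize, mm^-1.
#' @param n_photons,n_emission MC budgets.
#' @param seed integer seed.
#' @return [mtf_depth_sweep()] result (one row).
#' @export
acceptance_mtf_point <- function(depth_mm, fx, n_photons, n_emission, seed) {
  mtf_depth_sweep(fx_grid = fx, depth_grid = depth_mm,
                  spec_fun = function(d)
                    phantom_spec("single_tube", depth_mm = d,
                                 thickness_mm = 6),
                  n_photons = n_photons, n_emission = n_emission,
                  seed = seed, n_blocks = 8)
}

#' @rdname acceptance_mtf_point
#'
#' @description
#' `acceptance_ladder_fits()` simulates the three shallowest tubes of the
#' depth-ladder phantom (tube tops at 0.4 / 1.4 / 2.4 mm, ladder bulk
#' `mu_a = 0.02`, `mu_s' = 1`) with the AF700-like 0.9 ns fluorophore, 101
#' gates (300 ps width / 80 ps step) at fx in \{0, 0.6\} mm^-1, Poisson noise
#' with the brightest planar pixel scaled to ~1100 counts, then demodulates
#' gate-wise and fits: per-pixel mono-exponential NLSF of `I_sub` at
#' fx = 0.6 (tube means and their grand mean), and ROI-averaged decays of
#' `I_DC`/`I_sub` at both frequencies (minimum R^2 over tubes, components and
#' frequencies).
#'
#' @return `acceptance_ladder_fits()`: list with `tube_means_ns`,
#'   `grand_mean_ns`, `r2_table`, `min_r2`, `n_pixels`, `dataset`.
#' @export
acceptance_ladder_fits <- function(n_photons = 6e5, n_emission = 2.4e6,
                                   seed = 1) {
  spec <- phantom_spec("depth_ladder", n_tubes = 3L, thickness_mm = 6)
  cam <- camera_model(gain = "auto", noise = "poisson", target_peak = 1100)
  ds <- generate_hsf_dataset(spec, c(0, 0.6), camera = cam,
                             n_photons = n_photons, n_emission = n_emission,
                             pixel_pitch_mm = 0.375, seed = seed)
  ta <- make_time_axis(ds$camera$config)
  roi <- ds$roi_labels
  # shot-noise-debiased AC (the stacks are Poisson counts); see the vignette
  demod <- lapply(ds$triplets, demodulate_gated, shot_debias = TRUE)
  # per-pixel I_sub fits at fx = 0.6 (unweighted; see methods vignette)
  fm <- fit_stack(demod[[2]]$I_sub, ds$irf_gated, k = 1, roi_labels = roi,
                  weights = "none")
  tab <- fm$roi
  tube_means <- tab$mean[tab$quantity == "tau"]
  n_pix <- sum(tab$n[tab$quantity == "tau"])
  # ROI-averaged decay fits for the R^2 criterion
  rows <- list()
  for (fi in 1:2) for (comp in c("I_DC", "I_sub")) for (lb in 1:3) {
    sel <- roi == lb
    dec <- apply(demod[[fi]][[comp]]$data, 1, function(img) mean(img[sel]))
    fr <- fit_nlsf(dec, ds$irf_gated, k = 1, time_axis = ta,
                   weights = "none")
    rows[[length(rows) + 1]] <- data.frame(
      fx = ds$fx_list[fi], component = comp, tube = lb,
      tau_ns = fr$tau_ns[1], r_squared = fr$r_squared)
  }
  r2_table <- do.call(rbind, rows)
  list(tube_means_ns = tube_means, grand_mean_ns = mean(tube_means),
       r2_table = r2_table, min_r2 = min(r2_table$r_squared),
       n_pixels = n_pix, dataset = ds)
}
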