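test_that("Henyey-Greenstein sampling has the right first moment", {
  set.seed(1)
  for (g in c(0, 0.5, 0.9)) {
    x <- sample_scattering_cosine(2e5, g)
    expect_true(all(x >= -1 & x <= 1))
    expect_lt(abs(mean(x) - g), 0.01)
  }
  # strongly forward-peaked limit: mass concentrates near 1
  x99 <- sample_scattering_cosine(1e5, 0.999)
  expect_gt(mean(x99 > 0.9), 0.99)
  expect_error(sample_scattering_cosine(10, 1), "< 1")
})

test_that("ballistic transit and photon clock", {
  # transparent medium, n = 1: pencil photons cross 3 mm in 10.0 ps
  vol <- make_homog_volume(0, 0, n = 1, dims = c(10L, 10L, 30L))
  exc <- propagate_excitation(vol, 50, source = list(type = "pencil",
                                                     x = 0.5, y = 0.5),
                              seed = 3, record_all_exits = TRUE)
  bt <- exc$reflectance[exc$reflectance[, "face"] == 1, "t_ps"]
  expect_equal(unique(round(bt, 2)), round(3 / 0.299792, 2))
  # with n = 1.37 the clock runs slower by n
  vol37 <- make_homog_volume(0, 0, n = 1.37, dims = c(10L, 10L, 30L))
  exc37 <- propagate_excitation(vol37, 50, source = list(type = "pencil",
                                                         x = 0.5, y = 0.5),
                                seed = 3, record_all_exits = TRUE)
  bt37 <- exc37$reflectance[exc37$reflectance[, "face"] == 1, "t_ps"]
  expect_equal(mean(bt37) / mean(bt), 1.37, tolerance = 1e-6)
})

test_that("Beer-Lambert oracle in absorbing-only media", {
  # transmitted fraction exp(-mua * d) within 3 MC standard errors
  for (mua in c(0.01, 0.1, 1)) {
    n_ph <- 4e4
    vol <- make_homog_volume(mua, 0, n = 1, dims = c(20L, 20L, 100L))
    exc <- propagate_excitation(vol, n_ph,
                                source = list(type = "pencil", x = 1, y = 1),
                                seed = 11)
    p <- exp(-mua * 10)
    frac <- exc$totals[["escaped_bottom"]] / exc$totals[["launched"]]
    se <- sqrt(p * (1 - p) / n_ph)
    expect_lt(abs(frac - p), 3 * se + 1e-9)
  }
})

test_that("energy conservation bookkeeping is exact", {
  vol <- make_block_volume()
  exc <- propagate_excitation(vol, 2e4, seed = 21)
  tot <- exc$totals
  resid <- tot[["launched"]] -
    (tot[["specular"]] + tot[["absorbed"]] + tot[["escaped_top"]] +
     tot[["escaped_bottom"]] + tot[["escaped_side"]] + tot[["roulette_net"]])
  expect_lt(abs(resid) / tot[["launched"]], 1e-9)
  # same contract on the emission step
  src <- form_emission_sources(exc)
  rec <- propagate_emission(vol, src, 2e4, seed = 22)
  tot2 <- rec$totals
  resid2 <- tot2[["launched"]] -
    (tot2[["absorbed"]] + tot2[["escaped_top"]] + tot2[["escaped_bottom"]] +
     tot2[["escaped_side"]] + tot2[["roulette_net"]])
  expect_lt(abs(resid2) / tot2[["launched"]], 1e-9)
})

test_that("isotropic point source in transparent medium: 1/(d^2+r^2) obliquity", {
  # exit-radius CDF for upward photons: F(r) = 1 - d / sqrt(d^2 + r^2)
  d <- 2
  lab <- array(1L, c(120L, 120L, 40L))
  vol <- voxel_volume(lab, list(optical_properties(0, 0, g = 0, n = 1)), 0.25)
  n_ph <- 2e4
  src <- cbind(x = rep(15, n_ph), y = 15, z = d, t_ps = 0,
               weight = 1 / n_ph, launch_x = 15)
  set.seed(31)
  rec <- propagate_emission(vol, src, 0)
  det <- rec$detected
  r <- sqrt((det[, "x"] - 15)^2 + (det[, "y"] - 15)^2)
  n_up <- nrow(det)
  for (rho in c(1, 2, 4)) {
    Fhat <- mean(r <= rho)
    # renormalize for the finite 15 mm half-width aperture
    Fmax <- 1 - d / sqrt(d^2 + 14^2)
    Ftheo <- (1 - d / sqrt(d^2 + rho^2))
    se <- sqrt(Ftheo * (1 - Ftheo) / n_up) / Fmax
    expect_lt(abs(Fhat - Ftheo / Fmax), 3 * se + 0.01)
  }
  # exit time equals start time + ballistic transit
  t5 <- src; t5[, "t_ps"] <- 5000
  set.seed(32)
  rec5 <- propagate_emission(vol, t5, 0)
  expect_gte(min(rec5$detected[, "t_ps"]), 5000 + d / 0.299792 - 1e-6)
})

test_that("emission sources conserve energy and realize the lifetime kernel", {
  vol <- make_block_volume(tau_ns = 1)
  exc <- propagate_excitation(vol, 2e4, seed = 41)
  src <- form_emission_sources(exc)
  # total emitted energy = sum(absorbed * yield), independent of tau
  vox_yield <- as.vector(vol$fluor_yield)
  expect_equal(src$total_energy,
               sum(exc$absorbed * array(vox_yield, dim(exc$absorbed))),
               tolerance = 1e-9)
  vol2 <- vol; vol2$fluor_lifetime_ns[vol2$fluor_yield > 0] <- 2
  src2 <- form_emission_sources(exc, vol2)
  expect_equal(src$total_energy, src2$total_energy, tolerance = 1e-12)
  # impulse excitation: emission delays are Exp(tau)
  src_imp <- src
  src_imp$events[, "t_ps"] <- 0
  set.seed(42)
  la <- sample_emission_launches(src_imp, 5e4)
  delays <- la[, "t_ps"]
  expect_equal(mean(delays), 1000, tolerance = 0.03)
  # doubling tau doubles the mean delay, leaves total weight unchanged
  src_imp2 <- src_imp; src_imp2$events[, "tau_ns"] <- 2
  set.seed(42)
  la2 <- sample_emission_launches(src_imp2, 5e4)
  expect_equal(mean(la2[, "t_ps"]), 2000, tolerance = 0.03)
  expect_equal(sum(la2[, "weight"]), sum(la[, "weight"]), tolerance = 1e-12)
  # yield where lifetime <= 0 is rejected
  vol3 <- vol; vol3$fluor_lifetime_ns[] <- 0
  expect_error(form_emission_sources(exc, vol3), "fluor_lifetime")
  # non-fluorescent volume gives an empty source distribution
  volnf <- make_homog_volume(0.01, 1, g = 0.9, n = 1.37,
                             dims = c(10L, 10L, 10L))
  excnf <- propagate_excitation(volnf, 1e3, seed = 43)
  expect_equal(form_emission_sources(excnf)$total_energy, 0)
})

test_that("pattern reweighting: trivial weights and dual-method agreement", {
  vol <- cached("block_mid", {
    v <- make_block_volume(depth_mm = 0.6, dims = c(60L, 60L, 20L), voxel = 0.2)
    exc <- propagate_excitation(v, 1e5, seed = 51)
    src <- form_emission_sources(exc)
    rec <- propagate_emission(v, src, 2e5, seed = 52)
    list(vol = v, rec = rec, src = src)
  })
  rec <- vol$rec
  pitch <- 0.375
  # uniform pattern: identical to the unweighted histogram up to the
  # 255/255 transmission factor
  pat0 <- generate_sinusoid(0, 0, c(32, 32), pitch)
  img_u <- reweight_by_pattern(rec, NULL, pixel_pitch_mm = pitch,
                               t_range_ps = NULL)
  img_0 <- reweight_by_pattern(rec, pat0, t_range_ps = NULL)
  expect_equal(img_0$data, img_u$data, tolerance = 1e-12)
  # all-zero pattern: zero stack
  patz <- pat0; patz$image[] <- 0L
  expect_equal(max(reweight_by_pattern(rec, patz, t_range_ps = NULL)$data), 0)
  # reweighted uniform run vs direct pattern-modulated launching agree on
  # demodulated ROI means within 3 MC standard errors
  fx <- 0.3
  trip <- pattern_triplet(fx, c(32, 32), pitch)
  roi <- matrix(FALSE, 32, 32); roi[10:22, 10:22] <- TRUE
  imgs_rw <- lapply(trip, function(p)
    drop(reweight_by_pattern(rec, p, t_range_ps = NULL)$data))
  d_rw <- demodulate_triplet(imgs_rw[[1]], imgs_rw[[2]], imgs_rw[[3]])
  direct <- lapply(trip, function(p) {
    exc <- propagate_excitation(vol$vol, 1e5,
                                source = list(type = "pattern", pattern = p),
                                seed = 53 + round(p$phase * 10))
    srcd <- form_emission_sources(exc)
    recd <- propagate_emission(vol$vol, srcd, 2e5, seed = 54 + round(p$phase * 10))
    drop(reweight_by_pattern(recd, NULL, pixel_pitch_mm = pitch,
                             t_range_ps = NULL)$data)
  })
  d_dir <- demodulate_triplet(direct[[1]], direct[[2]], direct[[3]])
  m_rw <- mean(d_rw$I_DC[roi]); m_dir <- mean(d_dir$I_DC[roi])
  expect_lt(abs(m_rw - m_dir) / m_rw, 0.05)
  ac_rw <- mean(d_rw$I_AC[roi]) / m_rw
  ac_dir <- mean(d_dir$I_AC[roi]) / m_dir
  expect_lt(abs(ac_rw - ac_dir), 3 * 0.02 + 0.02)
  # missing launch tags
  rec_bad <- rec
  colnames(rec_bad$detected)[5] <- "nope"
  expect_error(reweight_by_pattern(rec_bad, pat0), "launch-x")
})

test_that("runs are deterministic under a fixed seed", {
  vol <- make_block_volume(dims = c(20L, 20L, 15L), voxel = 0.2)
  e1 <- propagate_excitation(vol, 5e3, seed = 61)
  e2 <- propagate_excitation(vol, 5e3, seed = 61)
  expect_identical(e1$absorbed, e2$absorbed)
  expect_identical(e1$events, e2$events)
  e3 <- propagate_excitation(vol, 5e3, seed = 62)
  expect_false(identical(e1$absorbed, e3$absorbed))
})

test_that("fluence decay approaches the diffusion slope", {
  # isotropic source deep in a large homogeneous volume: beyond a few
  # transport mean free paths the fluence falls as exp(-mu_eff r)/r with
  # mu_eff = sqrt(3 mua (mua + mus')). The domain must be much larger than
  # 1/mu_eff (~13 mm) or boundary absorption steepens the tail.
  dims <- c(60L, 60L, 60L)
  vol <- voxel_volume(array(1L, dims),
                      list(optical_properties(0.002, 1, g = 0.9, n = 1)), 1)
  n_ph <- 6e4
  src <- cbind(x = rep(30, n_ph), y = 30, z = 30, t_ps = 0, weight = 1,
               launch_x = 30)
  set.seed(71)
  rec <- propagate_emission(vol, src, 0)
  idx <- which(rec$absorbed > -1, arr.ind = TRUE)
  r <- sqrt(((idx[, 1] - 0.5) - 30)^2 + ((idx[, 2] - 0.5) - 30)^2 +
            ((idx[, 3] - 0.5) - 30)^2)
  rb <- cut(r, seq(0, 28, 1))
  phi <- tapply(as.vector(rec$absorbed), rb, sum) / tapply(r, rb, length)
  rmid <- seq(0.5, 27.5, 1)
  sel <- rmid > 4 & rmid < 14 & !is.na(phi) & phi > 0
  slope <- -coef(lm(log(phi[sel] * rmid[sel]) ~ rmid[sel]))[2]
  mu_eff <- sqrt(3 * 0.002 * 1.002)
  expect_lt(abs(slope - mu_eff) / mu_eff, 0.15)
})

test_that("two-step driver: non-fluorescent volume yields zero stacks", {
  vol <- make_homog_volume(0.01, 1, g = 0.9, n = 1.37, dims = c(10L, 10L, 10L))
  pats <- pattern_triplet(0.3, c(4, 4), 0.25)
  out <- simulate_two_step(vol, pats, n_photons = 500, seed = 81)
  expect_true(all(vapply(out$stacks, is.null, logical(1))))
  expect_equal(out$sources$total_energy, 0)
})
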