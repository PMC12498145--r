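test_that("phantom builders place inclusions with the right optics", {
  # tilted tube carries the dye optical properties
  spec <- phantom_spec("tilted_tube", field_mm = c(12, 12), thickness_mm = 6,
                       voxel_size_mm = 0.2, tube_length_mm = 8,
                       depth_start_mm = 0.2, depth_end_mm = 3)
  vol <- build_phantom(spec)
  expect_gt(sum(vol$tissue_label == 2L), 0)
  expect_equal(vol$properties[[2]]$mu_a, 0.04)
  expect_equal(vol$properties[[2]]$mu_s_prime, 0.09)
  expect_equal(vol$properties[[1]]$mu_a, 0.002)
  expect_equal(vol$properties[[1]]$mu_s_prime, 1)
  # fluorophore maps confined to the inclusion
  expect_true(all(vol$fluor_yield[vol$tissue_label == 1L] == 0))
  expect_true(all(vol$fluor_yield[vol$tissue_label == 2L] > 0))
  # depth increases from side A to side B along x
  occ <- which(vol$tissue_label == 2L, arr.ind = TRUE)
  zmean <- tapply(occ[, 3], occ[, 1], mean)
  expect_gt(cor(as.numeric(names(zmean)), zmean), 0.99)
})

test_that("depth ladder geometry: 8 tubes at 0.4 + (i-1) mm", {
  spec <- phantom_spec("depth_ladder", voxel_size_mm = 0.2)
  expect_equal(spec$bulk$mu_a, 0.02)  # ladder bulk absorption
  vol <- build_phantom(spec)
  occ <- which(vol$tissue_label == 2L, arr.ind = TRUE)
  xs <- occ[, 1] * 0.2
  grp <- cut(xs, 8)
  ztop <- tapply((occ[, 3] - 1) * 0.2, grp, min)
  expect_equal(as.vector(ztop), 0.4 + (0:7) * 1.0, tolerance = 0.15)
  # zero-diameter tube: pure bulk
  vol0 <- build_phantom(phantom_spec("depth_ladder", tube_diameter_mm = 0,
                                     voxel_size_mm = 0.2))
  expect_true(all(vol0$tissue_label == 1L))
  # inclusion outside the volume
  expect_error(build_phantom(phantom_spec("single_tube", depth_mm = 9.8)),
               "outside the volume")
})

test_that("apply_gating integrates boxcar windows with gain", {
  cam <- camera_model(acq_config(n_gates = 10, gate_width_ps = 300,
                                 gate_step_ps = 80),
                      gain = 2)
  nt <- 200
  ts <- structure(list(data = array(1, c(nt, 2, 2)), t0_ps = 0,
                       time_bin_ps = 10, pixel_pitch_mm = 0.1),
                  class = "time_stack")
  g <- apply_gating(ts, cam)
  # constant unit signal: every gate reads S * W * gain = 1 * 300 * 2
  expect_equal(as.vector(g$data), rep(600, 40), tolerance = 1e-12)
  # doubling the gate width doubles the read in the exact analytic ratio
  dec <- exp(-(seq_len(nt) - 0.5) * 10 / 900)
  ts2 <- ts; ts2$data <- array(rep(dec, 4), c(nt, 2, 2))
  gW <- apply_gating(ts2, camera_model(acq_config(n_gates = 5,
                                                  gate_width_ps = 300), gain = 1))
  g2W <- apply_gating(ts2, camera_model(acq_config(n_gates = 5,
                                                   gate_width_ps = 600), gain = 1))
  ratio_theo <- (1 - exp(-600 / 900)) / (1 - exp(-300 / 900))
  expect_equal(g2W$data[1, 1, 1] / gW$data[1, 1, 1], ratio_theo,
               tolerance = 0.01)
  # linearity
  ts3 <- ts2; ts3$data <- 3 * ts2$data
  expect_equal(apply_gating(ts3, cam, irf = synth_irf(100, 200, seq(5, 1995, 10)))$data,
               3 * apply_gating(ts2, cam, irf = synth_irf(100, 200, seq(5, 1995, 10)))$data,
               tolerance = 1e-9)
  # truncated gates are an error listing the gate indices
  cam_long <- camera_model(acq_config(n_gates = 101), gain = 1)
  expect_error(apply_gating(ts, cam_long), "gate window exceeds")
})

test_that("paper gating config covers an 8 ns record", {
  cam <- camera_model(acq_config(), gain = 1)
  nt <- 1000  # 10 ns at 10 ps
  ts <- structure(list(data = array(1, c(nt, 1, 1)), t0_ps = 0,
                       time_bin_ps = 10, pixel_pitch_mm = 0.1),
                  class = "time_stack")
  g <- apply_gating(ts, cam)
  expect_equal(dim(g$data)[1], 101)
  expect_equal(make_time_axis(g$config)[101], 8000)
})

test_that("camera noise model preserves means and Poisson variance", {
  cfg <- acq_config(n_gates = 4)
  cam <- camera_model(cfg, gain = 1, noise = "poisson")
  zero <- gated_stack(array(0, c(4, 3, 3)), cfg, 0.1)
  expect_equal(add_noise(zero, cam, seed = 1)$data, zero$data)
  base <- gated_stack(array(100, c(4, 4, 4)), cfg, 0.1)
  set.seed(2)
  reps <- replicate(1000, mean(add_noise(base, cam)$data))
  expect_lt(abs(mean(reps) - 100), 1)
  # per-element variance ~ mean within 10%
  set.seed(3)
  vals <- replicate(1000, add_noise(base, cam)$data[1, 1, 1])
  expect_lt(abs(var(vals) - 100) / 100, 0.10)
  # saturation clip
  cams <- camera_model(cfg, gain = 1, noise = "poisson", saturation = 100)
  expect_lte(max(add_noise(base, cams, seed = 4)$data), 100)
})

test_that("generate_hsf_dataset counts, determinism, and ground truth", {
  spec <- phantom_spec("single_tube", depth_mm = 0.4, field_mm = c(9, 9),
                       thickness_mm = 4, voxel_size_mm = 0.3,
                       tube_length_mm = 6)
  cam <- camera_model(gain = "auto", noise = "poisson", target_peak = 300)
  ds <- generate_hsf_dataset(spec, c(0, 0.6), camera = cam, n_photons = 2e4,
                             n_emission = 4e4, pixel_pitch_mm = 0.375,
                             seed = 9, time_bin_ps = 20)
  # two triplets of three stacks each
  expect_length(ds$triplets, 2)
  expect_true(all(vapply(ds$triplets, length, 1L) == 3))
  # auto gain scales the brightest noiseless planar pixel to the target
  dc0 <- ds$truth$noiseless[[1]]$I_DC$data
  expect_equal(max(dc0), 300, tolerance = 1e-6)
  # ground truth sidecar carries the oracle
  expect_equal(ds$truth$lifetimes_ns, 0.9)
  expect_equal(ds$truth$depths_mm, 0.4)
  # reproducibility: dataset hash is a function of (spec, config, seed)
  ds2 <- generate_hsf_dataset(spec, c(0, 0.6), camera = cam, n_photons = 2e4,
                              n_emission = 4e4, pixel_pitch_mm = 0.375,
                              seed = 9, time_bin_ps = 20)
  expect_identical(ds$triplets[[2]][[1]]$data, ds2$triplets[[2]][[1]]$data)
  # fx = 0 triplet members are identical up to noise: their noiseless AC is 0
  expect_lt(max(ds$truth$noiseless[[1]]$I_AC$data), 1e-9)
})
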