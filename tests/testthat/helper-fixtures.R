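# shared fixtures: all generated in code, no files

# small gated stack with a reproducible ramp pattern
make_test_stack <- function(n_gates = 101L, H = 8L, W = 8L, seed = 42) {
  set.seed(seed)
  cfg <- acq_config(n_gates = n_gates)
  data <- array(runif(n_gates * H * W, 0, 100), c(n_gates, H, W))
  gated_stack(data, cfg, pixel_pitch_mm = 0.1875,
              provenance = list(fx_per_mm = 0.6, phase_index = 1L, seed = seed))
}

# homogeneous voxel volume
make_homog_volume <- function(mu_a, mu_s_prime, g = 0, n = 1,
                              dims = c(20L, 20L, 50L), voxel = 0.1) {
  voxel_volume(array(1L, dims),
               list(optical_properties(mu_a, mu_s_prime, g = g, n = n)), voxel)
}

# analytic noiseless sinusoid triplet a + b*cos(theta + phi_i)
analytic_triplet <- function(a, b, theta = 0) {
  phases <- c(0, 2, 4) * pi / 3
  lapply(phases, function(p) a + b * cos(theta + p))
}

# a tiny fluorescent block volume: cube inclusion at given top depth
make_block_volume <- function(depth_mm = 0.5, tau_ns = 0.9,
                              dims = c(40L, 40L, 30L), voxel = 0.2,
                              bulk = optical_properties(0.002, 1)) {
  lab <- array(1L, dims)
  yield <- array(0, dims)
  tau <- array(0, dims)
  cz <- (seq_len(dims[3]) - 0.5) * voxel
  kz <- which(cz > depth_mm & cz <= depth_mm + 1)
  ctr <- (dims[1:2] / 2)
  ix <- seq(ctr[1] - 4, ctr[1] + 5)
  lab[ix, ix, kz] <- 2L
  yield[ix, ix, kz] <- 1
  tau[ix, ix, kz] <- tau_ns
  voxel_volume(lab, list(bulk, optical_properties(0.04, 0.09)), voxel,
               fluor_yield = yield, fluor_lifetime_ns = tau)
}

# cached heavy simulations shared across test files (computed at most once
# per test run)
.sim_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- force(expr)
  .sim_cache[[key]]
}
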