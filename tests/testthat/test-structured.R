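test_that("generate_sinusoid produces valid 8-bit patterns", {
  # zero frequency: uniform image at full gray level
  p0 <- generate_sinusoid(0, 0, c(4, 4), 0.1875)
  expect_true(all(p0$image == 255))
  # gray levels are integers within the bit depth
  p <- generate_sinusoid(0.6, 0, c(8, 128), 0.1875)
  expect_true(all(p$image >= 0 & p$image <= 255))
  expect_true(all(p$image == round(p$image)))
  # period of the 0.6 mm^-1 pattern is 1/0.6 mm: the profile repeats after
  # 1.667 mm and correlates maximally there
  prof <- p$image[1, ]
  x <- (seq_along(prof) - 0.5) * 0.1875
  ref <- 127.5 * (1 + cos(2 * pi * 0.6 * x))
  expect_lt(max(abs(prof - ref)), 0.5 + 1e-9)  # quantization only
  # spatial mean over whole periods near half swing
  nper <- floor(max(x) * 0.6) / 0.6
  sel <- x <= nper
  expect_lt(abs(mean(prof[sel]) - 127.5), 1)
  # undersampling guard
  expect_error(generate_sinusoid(2, 0, c(4, 32), 1), "undersampled")
})

test_that("phase-shifted patterns are translations (identical histograms)", {
  # 48 px per period: the 2pi/3 offset is an integer (16 px) translation and
  # the 96 px image holds a whole number of periods
  pitch <- 1 / 0.6 / 48
  trip <- pattern_triplet(0.6, c(2, 96), pitch)
  h <- lapply(trip, function(p) tabulate(p$image[1, ] + 1, 256))
  expect_identical(h[[1]], h[[2]])
  expect_identical(h[[2]], h[[3]])
})

test_that("three-phase demodulation is exact on analytic sinusoids", {
  # unmodulated input
  d <- demodulate_triplet(5, 5, 5)
  expect_equal(unname(c(d$I_DC, d$I_AC, d$I_sub)), c(5, 0, 5))
  # hand-derived case at theta = 0: a = 10, b = 4
  d2 <- demodulate_triplet(14, 8, 8)
  expect_equal(unname(c(d2$I_DC, d2$I_AC, d2$I_sub)), c(10, 4, 6))
  # property: exactness and phase invariance over random a, b, theta
  set.seed(7)
  for (i in 1:50) {
    a <- runif(1, 1, 100); b <- runif(1, 0, a); th <- runif(1, 0, 2 * pi)
    tr <- analytic_triplet(a, b, th)
    d3 <- demodulate_triplet(tr[[1]], tr[[2]], tr[[3]])
    expect_lt(abs(d3$I_DC - a), 1e-10)
    expect_lt(abs(d3$I_AC - b), 1e-10)
    expect_lt(abs(d3$I_sub - (a - b)), 1e-10)
  }
})

test_that("demodulation validates inputs and reports conservation", {
  expect_error(demodulate_triplet(matrix(1, 2, 2), matrix(1, 2, 3),
                                  matrix(1, 2, 2)), "identical shapes")
  expect_error(demodulate_triplet(-1, 1, 1), "non-negative")
  # conservation pre-clamp: I_AC + I_sub == I_DC exactly
  set.seed(8)
  I <- lapply(1:3, function(i) matrix(runif(64, 0, 10), 8))
  d <- demodulate_triplet(I[[1]], I[[2]], I[[3]], clamp = FALSE)
  expect_equal(d$I_AC + d$I_sub, d$I_DC, tolerance = 1e-12)
  # clamping counts negative subsurface pixels
  dcl <- demodulate_triplet(I[[1]], I[[2]], I[[3]], clamp = TRUE)
  expect_true(all(dcl$I_sub >= 0))
  expect_equal(dcl$clamp_count, sum(d$I_sub < 0))
})

test_that("shot-noise debiasing removes the AC rectification floor", {
  # Poisson-noised unmodulated triplet: the plain magnitude floors at
  # ~1.15 sqrt(counts); the debiased estimator is unbiased near zero
  set.seed(12)
  mu <- 400
  I <- lapply(1:3, function(i) matrix(rpois(4e4, mu), 200))
  plain <- demodulate_triplet(I[[1]], I[[2]], I[[3]])
  deb <- demodulate_triplet(I[[1]], I[[2]], I[[3]], shot_debias = TRUE)
  # E[AC] at zero modulation ~ sqrt(2/9 * E[sum d^2]) * Jensen factor ~ sigma
  expect_gt(mean(plain$I_AC), 0.95 * sqrt(mu))
  expect_lt(mean(deb$I_AC), 0.5 * 1.155 * sqrt(mu))
  # with real modulation well above the floor both estimators agree
  set.seed(13)
  b <- 200
  Im <- analytic_triplet(mu, b)
  In <- lapply(Im, function(x) matrix(rpois(4e4, x), 200))
  p2 <- demodulate_triplet(In[[1]], In[[2]], In[[3]])
  d2 <- demodulate_triplet(In[[1]], In[[2]], In[[3]], shot_debias = TRUE)
  expect_equal(mean(d2$I_AC), b, tolerance = 0.01)
  expect_lt(abs(mean(p2$I_AC) - mean(d2$I_AC)) / b, 0.02)
})

test_that("gate-wise demodulation decomposes a two-layer decay", {
  cfg <- acq_config()
  ax <- make_time_axis(cfg)
  irf <- synth_irf(300, 500, ax)
  S <- model_decay(irf, A = 800, tau_ns = 0.5, time_axis = ax)   # surface
  D <- model_decay(irf, A = 500, tau_ns = 1.2, time_axis = ax)   # deep
  m_s <- 1; m_d <- 0.05  # modulation carried by each layer
  mk <- function(ph) {
    dec <- S * (1 + m_s * cos(ph)) + D * (1 + m_d * cos(ph))
    gated_stack(array(rep(dec, 4), c(cfg$n_gates, 2, 2)), cfg, 0.1875)
  }
  trip <- lapply(c(0, 2, 4) * pi / 3, mk)
  dm <- demodulate_gated(trip)
  # I_sub isolates the deep decay (surface fully modulated): NLSF on I_sub
  # recovers tau_d within 5%, while I_DC lies between tau_s and tau_d
  dec_sub <- dm$I_sub$data[, 1, 1]
  dec_dc <- dm$I_DC$data[, 1, 1]
  f_sub <- fit_nlsf(dec_sub, irf, k = 1, time_axis = ax, fit_shift = FALSE)
  f_dc <- fit_nlsf(dec_dc, irf, k = 1, time_axis = ax, fit_shift = FALSE)
  expect_lt(abs(f_sub$tau_ns - 1.2) / 1.2, 0.05)
  expect_gt(f_dc$tau_ns, 0.5)
  expect_lt(f_dc$tau_ns, 1.2)
  # trivial gated properties
  same <- lapply(1:3, function(i) trip[[1]])
  dm2 <- demodulate_gated(same)
  expect_equal(max(abs(dm2$I_AC$data)), 0)
  expect_equal(dm2$I_sub$data, dm2$I_DC$data)
  # config mismatch
  trip_bad <- trip
  trip_bad[[2]] <- gated_stack(trip[[2]]$data[1:50, , , drop = FALSE],
                               acq_config(n_gates = 50), 0.1875)
  expect_error(demodulate_gated(trip_bad), "configs differ")
})

test_that("gate-sum commutation holds for gate-independent modulation", {
  cfg <- acq_config(n_gates = 20)
  ax <- make_time_axis(cfg)
  base <- exp(-ax / 900)
  trip <- lapply(c(0, 2, 4) * pi / 3, function(ph)
    gated_stack(array(base %o% c(1 + 0.4 * cos(ph)), c(20, 1, 1)), cfg, 0.1))
  dm_gated <- demodulate_gated(trip)
  summed <- demodulate_triplet(sum(trip[[1]]$data), sum(trip[[2]]$data),
                               sum(trip[[3]]$data))
  expect_equal(sum(dm_gated$I_AC$data), summed$I_AC, tolerance = 1e-10)
  expect_equal(sum(dm_gated$I_DC$data), summed$I_DC, tolerance = 1e-12)
})

test_that("source modulation and MTF arithmetic", {
  # ideal continuous sinusoid: M_S = 1
  tr <- analytic_triplet(127.5, 127.5)
  expect_equal(source_modulation(lapply(tr, function(v) matrix(v, 2, 2))), 1,
               tolerance = 1e-12)
  # half swing: M_S = 0.5
  tr2 <- analytic_triplet(100, 50)
  expect_equal(source_modulation(lapply(tr2, function(v) matrix(v, 2, 2))), 0.5,
               tolerance = 1e-12)
  # digital 8-bit triplet is within a quantization step of 1
  trip <- pattern_triplet(0.6, c(4, 128), 0.1875)
  expect_equal(source_modulation(trip), 1, tolerance = 0.01)
  # uniform triplet: zero-modulation error
  u <- replicate(3, generate_sinusoid(0, 0, c(4, 8), 0.1875), simplify = FALSE)
  expect_error(source_modulation(u), "zero-modulation")
  # MTF quotient arithmetic
  roi <- matrix(TRUE, 2, 2)
  expect_equal(compute_mtf(matrix(0.5, 2, 2), matrix(1, 2, 2), 0.5, roi), 1)
  expect_equal(compute_mtf(matrix(0.005, 2, 2), matrix(1, 2, 2), 0.5, roi), 0.01)
  expect_error(compute_mtf(matrix(1, 2, 2), matrix(1, 2, 2), 0, roi), "M_S")
  expect_error(compute_mtf(matrix(1, 2, 2), matrix(1, 2, 2), 1,
                           matrix(FALSE, 2, 2)), "empty ROI")
  expect_warning(v <- compute_mtf(matrix(2, 2, 2), matrix(1, 2, 2), 1, roi),
                 "clipped")
  # zero-frequency limit: sample modulation equals source modulation -> 1
  d <- demodulate_triplet(matrix(160, 3, 3), matrix(40, 3, 3), matrix(40, 3, 3))
  expect_equal(compute_mtf(d$I_AC, d$I_DC, d$I_AC[1] / d$I_DC[1],
                           roi = matrix(TRUE, 3, 3)), 1)
})

test_that("lateral resolution is the half period", {
  expect_equal(lateral_resolution(0.6), 1 / 1.2)
  expect_equal(lateral_resolution(c(0.2, 0.5)), c(2.5, 1))
  expect_error(lateral_resolution(0), "fx")
})
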