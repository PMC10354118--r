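test_that("aperture pixel counts match the pi/4 D^2 bookkeeping", {
  expect_equal(offaxis_config(aperture_diameter = 245)$A_aperture, 47144)
  expect_equal(offaxis_config(aperture_diameter = 201)$A_aperture, 31731)
})

test_that("the noise budget reproduces the published operating points", {
  s <- sensor_2M()
  v <- infer_visibility(0.9, 3.6e5, s, 245)
  expect_equal(v, 0.7716, tolerance = 1e-4)
  cfg <- offaxis_config(aperture_diameter = 245, visibility = v)
  # the inversion round-trips exactly
  expect_equal(predict_phase_noise(3.6e5, s, cfg), 0.9, tolerance = 1e-12)
  # shot-noise-limited prediction at full capacity: ~0.4 mrad
  s0 <- sensor_model(2e6, 11, gain = 1.73, read_noise = 0, dims = c(1440, 1440))
  expect_equal(predict_phase_noise(1e6, s0, cfg), 0.391, tolerance = 1e-3)
})

test_that("shot-limited noise scales as 1/sqrt(N); inversion rejects sub-shot inputs", {
  s0 <- sensor_model(1e6, 12, read_noise = 0, dims = c(256, 256))
  cfg <- offaxis_config(aperture_diameter = 64, visibility = 0.9)
  expect_equal(predict_phase_noise(4e4, s0, cfg),
               predict_phase_noise(1e4, s0, cfg) / 2, tolerance = 1e-12)
  # a claimed noise below the v = 1 shot limit implies v > 1
  shot_limit <- predict_phase_noise(1e4, s0,
                                    offaxis_config(aperture_diameter = 64,
                                                   visibility = 1))
  expect_error(infer_visibility(shot_limit * 0.5, 1e4, s0, 64), "v = ")
  expect_error(offaxis_config(aperture_diameter = 64, visibility = 0), "visibility")
})

test_that("digital counts convert to electrons via full well, bits and gain", {
  s <- sensor_2M()
  expect_equal(electrons_from_counts(0, s), 0)
  half <- (2^11 - 1) / 2
  expect_equal(electrons_from_counts(half, s), half * 2e6 / ((2^11 - 1) * 1.73))
  expect_error(electrons_from_counts(-1, s), "non-negative")
  expect_warning(electrons_from_counts(2^11 - 1, s), "saturated")
})

test_that("hologram synthesis has the configured mean, contrast and variance", {
  s <- sensor_model(1e7, 16, read_noise = 0, dims = c(64, 64))
  ph <- matrix(0, 64, 64)
  cfg0 <- offaxis_config(carrier = c(0.25, 0.25), aperture_diameter = 20,
                         visibility = 1e-9)
  h0 <- synthesize_hologram(ph, cfg0, 1e4, s, shot_noise = FALSE)
  expect_lt(max(abs(h0 - 1e4)), 1e-3) # flat at v ~ 0
  cfg <- offaxis_config(carrier = c(0.25, 0.25), aperture_diameter = 20,
                        visibility = 0.73)
  h <- synthesize_hologram(ph, cfg, 1e4, s, shot_noise = FALSE)
  # fringe contrast from the spectral amplitude ratio: 2|F(k)|/|F(0)| = v
  F <- fft(h)
  v_est <- 2 * Mod(F[17, 17]) / Mod(F[1, 1])
  expect_equal(v_est, 0.73, tolerance = 1e-6)
  # Poisson + Gaussian noise: per-pixel variance ~ mean + sigma^2
  s572 <- sensor_model(1e7, 16, read_noise = 572, dims = c(64, 64))
  set.seed(99)
  reps <- vapply(1:40, function(i) {
    hh <- synthesize_hologram(ph, cfg0, 2e5, s572)
    c(mean(hh), var(as.vector(hh)))
  }, numeric(2))
  expect_equal(mean(reps[2, ]), 2e5 + 572^2, tolerance = 0.03)
})

test_that("phase reconstruction round-trips noiseless holograms", {
  n <- 128
  s <- sensor_model(1e7, 16, read_noise = 0, dims = c(n, n))
  cfg <- offaxis_config(carrier = c(0.25, 0.25), aperture_diameter = 40,
                        visibility = 0.8, frame_dims = c(n, n))
  # zero phase -> constant reconstruction
  h0 <- synthesize_hologram(matrix(0, n, n), cfg, 1e5, s, shot_noise = FALSE)
  p0 <- reconstruct_phase(h0, cfg)
  expect_lt(sd(p0), 1e-6)
  # Gaussian bump 0.5 rad, sigma 10 px: RMS error < 1e-3 rad
  xs <- seq_len(n) - n / 2 - 0.5
  bump <- 0.5 * exp(-outer(xs^2, xs^2, `+`) / (2 * 10^2))
  h <- synthesize_hologram(bump, cfg, 1e5, s, shot_noise = FALSE)
  p <- reconstruct_phase(h, cfg)
  expect_lt(sqrt(mean((p - bump)^2)), 1e-3)
  # a carrier inside the aperture is not separable
  expect_error(offaxis_config(carrier = c(0.02, 0), aperture_diameter = 40,
                              visibility = 0.8, frame_dims = c(n, n)),
               "separable")
})

test_that("temporal noise measurement returns sqrt(2) x frame noise", {
  set.seed(42)
  sig <- 0.01
  stack <- array(rnorm(64 * 64 * 51, sd = sig), c(64, 64, 51))
  est <- measure_temporal_noise(stack, roi = c(1, 1, 64, 64))
  expect_equal(est, sqrt(2) * sig * 1000, tolerance = 0.03)
  expect_equal(measure_temporal_noise(array(1, c(16, 16, 5))), 0)
  expect_error(measure_temporal_noise(stack, roi = c(60, 60, 20, 20)),
               "outside")
  expect_error(measure_temporal_noise(stack[, , 1:2, drop = FALSE]), "3 frames")
})

test_that("Monte-Carlo synth/reconstruct noise agrees with the closed form", {
  n <- 128
  sensor <- sensor_model(2e6, 16, read_noise = 0, dims = c(n, n))
  cfg <- offaxis_config(carrier = c(0.25, 0.25), aperture_diameter = 40,
                        visibility = 0.8, frame_dims = c(n, n))
  stack <- make_hologram_stack(matrix(0, n, n), cfg, 1e5, sensor,
                               n_frames = 24, seed = 5)
  rec <- array(0, c(n, n, 24))
  for (f in 1:24) rec[, , f] <- reconstruct_phase(stack[, , f], cfg)
  meas <- measure_temporal_noise(rec)
  pred <- predict_phase_noise(1e5, sensor, cfg)
  expect_equal(meas, pred, tolerance = 0.1)
})

test_that("hologram stacks are seed-reproducible with independent frames", {
  s <- sensor_model(1e6, 16, read_noise = 0, dims = c(32, 32))
  cfg <- offaxis_config(carrier = c(0.25, 0.25), aperture_diameter = 10,
                        visibility = 0.8)
  a <- make_hologram_stack(matrix(0, 32, 32), cfg, 1e4, s, n_frames = 6, seed = 3)
  b <- make_hologram_stack(matrix(0, 32, 32), cfg, 1e4, s, n_frames = 6, seed = 3)
  expect_identical(a, b)
  # adjacent-frame fluctuations (deterministic fringe removed) are uncorrelated
  det <- synthesize_hologram(matrix(0, 32, 32), cfg, 1e4, s, shot_noise = FALSE)
  d <- apply(a, 3, function(f) as.vector(f - det))
  cors <- vapply(1:5, function(i) cor(d[, i], d[, i + 1]), numeric(1))
  expect_lt(max(abs(cors)), 0.05)
})
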