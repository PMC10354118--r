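test_that("phase-to-height conversion evaluates the closed form and clips", {
  expect_equal(height_from_phase(matrix(0, 4, 4), lowpass_sigma = 0),
               matrix(0, 4, 4))
  h <- height_from_phase(matrix(0.3819, 4, 4), lowpass_sigma = 0)
  expect_equal(h[1, 1], 1.0, tolerance = 2e-3)
  # extreme phase clips at the channel depth
  h20 <- height_from_phase(matrix(100, 4, 4), lowpass_sigma = 0)
  expect_true(all(h20 == 20))
  expect_warning(height_from_phase(matrix(c(-1, 1, 1, 1), 2, 2),
                                   lowpass_sigma = 0), "negative")
})

test_that("A(h) has exact endpoints, matches numeric integration, decreases", {
  expect_equal(contribution_ratio(0), 1)
  expect_equal(contribution_ratio(20), 0)
  # oracle: A = S_water / (S_water + S_cell) with the Lambert-Beer integrals
  oracle <- function(h, Dz = 6.73, L = 20) {
    s_cell <- integrate(function(z) exp(-z / Dz), 0, h, rel.tol = 1e-13)$value
    s_wat <- integrate(function(z) exp(-z / Dz), h, L, rel.tol = 1e-13)$value
    s_wat / (s_wat + s_cell)
  }
  for (h in c(3, 6.73, 15)) {
    expect_equal(contribution_ratio(h), oracle(h), tolerance = 1e-10)
  }
  expect_equal(contribution_ratio(6.73), 0.33376, tolerance = 1e-4)
  hs <- seq(0, 20, 0.5)
  expect_true(all(diff(contribution_ratio(hs)) < 0))
  expect_error(contribution_ratio(25), "\\[0, L\\]")
})

test_that("exchange model at t = t0 equals 1 for all A; thicker pixels decay slower", {
  model <- function(t, A, tau, t0 = 99, tau_ext = 82) {
    A * exp(-(t - t0) / tau_ext) + (1 - A) * exp(-(t - t0) / tau)
  }
  for (A in c(0, 0.3, 1)) expect_equal(model(99, A, 420), 1)
  # effective 1/e time increases with height for tau > tau_ext
  t <- seq(100, 3000, 5)
  t1e <- vapply(c(2, 6, 12, 18), function(h) {
    decay_time(t, model(t, contribution_ratio(h), 420))
  }, numeric(1))
  expect_true(all(diff(t1e) > 0))
})

test_that("extracellular fit recovers t0 and tau_ext", {
  ph <- make_phantom_cell(size = 48, seed = 4)
  gen <- make_exchange_series(ph, tau = 420, noise = 0, seed = 1)
  # corner region is cell-free (h = 0)
  expect_true(all(ph$height[1:8, 1:8] == 0))
  fit <- fit_extracellular(gen$series, roi = c(1, 1, 8, 8))
  expect_equal(fit$t0, 99, tolerance = 0.02)
  expect_equal(fit$tau_ext, 82, tolerance = 0.005)
  # 2% noise: recovery within 5%
  gen_n <- make_exchange_series(ph, tau = 420, noise = 0.02, seed = 8)
  fit_n <- fit_extracellular(gen_n$series, roi = c(1, 1, 8, 8))
  expect_equal(fit_n$tau_ext, 82, tolerance = 0.05)
  # constant series cannot be fitted
  flat <- exchange_series(seq(-100, 500, 20),
                          array(1, c(4, 4, 31)))
  expect_error(fit_extracellular(flat, roi = c(1, 1, 2, 2)), "decay")
})

test_that("decay-map fitting round-trips a noiseless generator", {
  ph <- make_phantom_cell(size = 32, seed = 5)
  gen <- make_exchange_series(ph, tau = 420, noise = 0, seed = 1,
                              t_range = c(-100, 1500))
  fit <- fit_decay_map(gen$series, gen$truth$height)
  inside <- !is.na(fit$tau) & gen$truth$A < 0.9
  expect_gt(sum(inside), 20)
  expect_lt(max(abs(fit$tau[inside] - 420) / 420), 1e-3)
  # A ~ 1 pixels are flagged unidentifiable
  expect_true(all(is.na(fit$tau[gen$truth$height == 0])))
  expect_gt(fit$n_flagged, 0)
  expect_error(fit_decay_map(gen$series, gen$truth$height, fit_start = 1e5),
               "insufficient")
})

test_that("surface and volume integrals match closed-form solids", {
  # flat slab: 100 px of 0.44 um at h = 1 um
  h <- matrix(0, 12, 12)
  h[2:11, 2:11] <- 1
  mask <- h > 0.5
  sv <- surface_and_volume(h, mask = mask)
  expect_equal(sv$V, 100 * 0.44^2, tolerance = 1e-12)
  # the rim gradient contributes extra area; interior pixels alone are flat
  interior <- matrix(FALSE, 12, 12); interior[3:10, 3:10] <- TRUE
  sv_int <- surface_and_volume(h, mask = interior)
  expect_equal(sv_int$S, 64 * 0.44^2, tolerance = 1e-12)
  # hemisphere: S = 2 pi R^2, V = 2/3 pi R^3
  R <- 20; px <- 0.05
  n <- 803
  xs <- (seq_len(n) - (n + 1) / 2) * px
  r2 <- outer(xs^2, xs^2, `+`)
  hemi <- sqrt(pmax(R^2 - r2, 0))
  sv_h <- surface_and_volume(hemi, dx = px, dy = px, mask = hemi > 0)
  expect_equal(sv_h$V, 2 / 3 * pi * R^3, tolerance = 0.03)
  expect_equal(sv_h$S, 2 * pi * R^2, tolerance = 0.03)
  # h = 0 everywhere: V = 0, S = masked area
  expect_error(surface_and_volume(matrix(0, 4, 4)), "empty")
  sv0 <- surface_and_volume(matrix(0, 4, 4), mask = matrix(TRUE, 4, 4))
  expect_equal(sv0$V, 0)
  expect_equal(sv0$S, 16 * 0.44^2)
})

test_that("permeability evaluates Eq-of-motion closed form in cm/s", {
  expect_equal(permeability(420, 1404, 3779), 6.4e-4, tolerance = 0.005)
  expect_equal(permeability(1000, 1, 1), 1e-4)
  # hemisphere S/V = (2 pi R^2)/(2/3 pi R^3) = 3/R
  R <- 10
  expect_equal(permeability(1000, 2 * pi * R^2, 2 / 3 * pi * R^3),
               R / 3 / 1000 * 0.1)
  expect_error(permeability(0, 1, 1), "> 0")
})

test_that("the joint pipeline recovers a known permeability at 2% frame noise", {
  ph <- make_phantom_cell(size = 48, seed = 6)
  gen <- make_exchange_series(ph, tau = 420, noise = 0.02, seed = 3,
                              t_range = c(-100, 1500))
  res <- fit_water_exchange(gen$series, ph$phase, lowpass_sigma = 2)
  sv_true <- surface_and_volume(ph$height, mask = ph$height > 0.5)
  pd_true <- permeability(420, sv_true$S, sv_true$V)
  expect_equal(res$P_d, pd_true, tolerance = 0.1)
})
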