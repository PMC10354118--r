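make_mix <- function(n_pix = 300, noise = 0, seed = 1) {
  set.seed(seed)
  S <- make_component_spectra()
  C <- matrix(runif(n_pix * 3), n_pix, 3)
  D <- C %*% S
  if (noise > 0) D <- D + rnorm(length(D), 0, noise)
  list(D = D, C = C, S = S)
}

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

test_that("a one-component stack is recovered up to scale", {
  set.seed(3)
  S <- make_component_spectra()[1, , drop = FALSE]
  C <- matrix(runif(200), 200, 1)
  fit <- mcr_als(C %*% S, init_spectra = S * 0.5 + 0.01)
  expect_gt(cosine(fit$S[1, ], S[1, ]), 0.9999)
})

test_that("three well-separated components are recovered from a noiseless mix", {
  mix <- make_mix()
  # identifiability of the default spectra
  combs <- utils::combn(3, 2)
  for (j in seq_len(ncol(combs))) {
    expect_lt(cosine(mix$S[combs[1, j], ], mix$S[combs[2, j], ]), 0.8)
  }
  init <- mix$S * matrix(runif(length(mix$S), 0.7, 1.3), nrow(mix$S))
  fit <- mcr_als(mix$D, init)
  for (i in 1:3) expect_gt(cosine(fit$S[i, ], mix$S[i, ]), 0.999)
  # concentrations match after per-component rescaling
  for (i in 1:3) {
    sc <- sum(fit$C[, i] * mix$C[, i]) / sum(fit$C[, i]^2)
    expect_lt(max(abs(fit$C[, i] * sc - mix$C[, i])) / max(mix$C[, i]), 0.01)
  }
})

test_that("the ALS residual is non-increasing and the fit object reports it", {
  mix <- make_mix(noise = 0.02, seed = 9)
  init <- mix$S * matrix(runif(length(mix$S), 0.5, 1.5), 3)
  fit <- mcr_als(mix$D, init, max_iter = 50)
  expect_true(all(diff(fit$residuals) <= 1e-9 * fit$residuals[1]))
})

test_that("degenerate initializations are rejected", {
  mix <- make_mix()
  expect_error(mcr_als(mix$D, rbind(mix$S[1, ], mix$S[1, ], mix$S[1, ])),
               "rank")
  expect_error(mcr_als(mix$D, -mix$S), "non-negative")
  expect_error(mcr_als(mix$D[, 1:2], mix$S[, 1:2]), "components")
})

test_that("component contributions conserve the raw phase change exactly", {
  mix <- make_mix()
  init <- mix$S * matrix(runif(length(mix$S), 0.8, 1.2), 3)
  fit <- mcr_als(mix$D, init)
  R <- component_contribution(fit, mix$D)
  total <- R[, , 1] + R[, , 2] + R[, , 3]
  expect_lt(max(abs(total - mix$D)), 1e-10)
})

test_that("two-component contributions match ground-truth shares when pure pixels exist", {
  # pure pixels (water-only background, lipid-droplet cores) pin the
  # factorization; without them ALS carries a rotational ambiguity
  set.seed(1)
  S <- make_component_spectra()[c(1, 3), ]
  C <- matrix(runif(300 * 2), 300, 2)
  C[1:20, 2] <- 0
  C[21:40, 1] <- 0
  D <- C %*% S
  set.seed(2)
  init <- S * matrix(runif(length(S), 0.8, 1.2), 2)
  fit <- mcr_als(D, init)
  expect_true(fit$converged)
  R <- component_contribution(fit, D)
  R_true <- outer(C[, 1], S[1, ])
  expect_lt(max(abs(R[, , 1] - R_true)) / max(D), 0.01)
})

test_that("a single-component model attributes the full signal to it", {
  S <- make_component_spectra()[2, , drop = FALSE]
  C <- matrix(runif(100) + 0.1, 100, 1)
  D <- C %*% S
  fit <- mcr_als(D, S)
  R <- component_contribution(fit, D)
  expect_equal(R[, , 1], D, tolerance = 1e-10)
})

test_that("stack normalization removes pulse-energy variation and the beam", {
  ph <- make_phantom_cell(size = 32, seed = 2)
  sp <- make_component_spectra()
  E <- seq(8, 12, length.out = 40)
  gen <- make_hyperspectral(ph, sp, beam_fwhm = 60, pulse_energy = E, seed = 4)
  norm <- normalize_stack(gen$stack, gen$water_stack)
  # doubling E(k) at one k halves that frame (before beam correction)
  E2 <- E; E2[5] <- 2 * E[5]
  st2 <- gen$stack
  st2$frames[, , 5] <- 2 * st2$frames[, , 5]
  st2$pulse_energy <- E2
  norm2 <- normalize_stack(st2, gen$water_stack)
  expect_equal(norm2$frames, norm$frames, tolerance = 1e-12)
  # round trip: flat-response phantom region matches truth modulo the beam
  expect_error(normalize_stack(gen$stack,
                               hyperspectral_stack(gen$water_stack$wavenumbers + 5,
                                                   gen$water_stack$frames)),
               "axes")
})

test_that("initial spectra come from rois with the stated background handling", {
  ph <- make_phantom_cell(size = 48, seed = 1)
  sp <- make_component_spectra()
  gen <- make_hyperspectral(ph, sp, beam_fwhm = Inf, noise = 0, seed = 2)
  # find a pure-lipid pixel block
  idx <- which(ph$masks$droplets, arr.ind = TRUE)
  px <- idx[1, ]
  rois <- list(lipid = c(px[1], px[2], 1, 1), extracellular = c(1, 1, 2, 2))
  init <- pick_initial_spectra(gen$stack, rois, gen$water_stack)
  # droplet pixel after background subtraction: lipid + protein + water-deficit
  # mixture; must correlate far better with lipid than water
  expect_gt(cosine(init["lipid", ], sp["lipid", ]) -
              cosine(init["lipid", ], sp["water", ]), 0.1)
  # extracellular roi without subtraction is pure water spectrum
  expect_gt(cosine(init["extracellular", ], sp["water", ]), 0.9999)
  expect_error(pick_initial_spectra(gen$stack, list(lipid = c(100, 1, 1, 1))),
               "outside")
})
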