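# Oracle values computed from the closed-form Green's function of a
# uniformly heated sphere (impulse response integrated over the pulse,
# projected along the line of sight on a fine grid):
#   constant power 100 ns, R = 0.25 um, water  -> e^-2 ratio 1.3112
#   10-ns pulse + 100-ns free diffusion        -> ratio 1.6843, centre 0.4804
EXACT_RATIO_100NS <- 1.3112
EXACT_RATIO_DELAY100 <- 1.6843
EXACT_FRAC_DELAY100 <- 0.4804

test_that("free diffusion of a Gaussian field matches the Green's-function widths", {
  med <- water_medium()
  g <- radial_grid(0.02, 4)
  s0 <- 0.25 # 12.5 grid steps
  t <- 0.1
  init <- exp(-g$r^2 / (2 * s0^2))
  pr <- heating_profile("impulse", sphere_radius = s0)
  sol <- solve_thermal_radial(pr, med, g, t_free = t, snapshot_times = t,
                              initial_field = init)
  s2 <- s0^2 + 2 * med$thermal_diffusivity * t
  expected <- (s0^2 / s2)^(3 / 2) * exp(-g$r^2 / (2 * s2))
  expect_lt(max(abs(sol$fields[1, ] - expected)) / max(expected), 0.01)
  # fitted variance from the second moment
  sig2_num <- sum(sol$fields[1, ] * g$r^4) / sum(sol$fields[1, ] * g$r^2) / 3
  expect_equal(sig2_num, s2, tolerance = 0.01)
})

test_that("zero deposition gives an identically zero field", {
  pr <- heating_profile("constant_power", pulse_duration = 0.05,
                        sphere_radius = 0.25, deposition_rate = 0)
  sol <- solve_thermal_radial(pr, water_medium(), radial_grid(0.0125, 3),
                              t_heat = 0.05)
  expect_true(all(sol$fields == 0))
})

test_that("energy is conserved under adiabatic boundaries and books deposited energy", {
  med <- water_medium()
  g <- radial_grid(0.0125, 5)
  # free diffusion: conservation to well under 0.1%
  pr <- heating_profile("impulse", sphere_radius = 0.25)
  sol <- solve_thermal_radial(pr, med, g, t_free = 0.3,
                              snapshot_times = c(0.05, 0.15, 0.3),
                              boundary = "adiabatic")
  E <- apply(sol$fields, 1, function(f) thermal_energy(sol$r, f, med))
  expect_lt(diff(range(E)) / mean(E), 1e-3)
  # constant-power deposit: energy at pulse end equals q rho c_p V t to 0.5%
  pr2 <- heating_profile("constant_power", pulse_duration = 0.01,
                         sphere_radius = 0.25)
  sol2 <- solve_thermal_radial(pr2, med, g, t_heat = 0.01,
                               boundary = "adiabatic")
  E2 <- thermal_energy(sol2$r, sol2$fields[1, ], med)
  E_dep <- med$vol_heat * 1 * 4 / 3 * pi * 0.25^3 * 0.01
  expect_equal(E2, E_dep, tolerance = 5e-3)
})

test_that("negative times and snapshots beyond the run are rejected", {
  pr <- heating_profile("constant_power", pulse_duration = 0.01,
                        sphere_radius = 0.25)
  expect_error(solve_thermal_radial(pr, water_medium(), t_heat = -1),
               "negative")
  expect_error(solve_thermal_radial(pr, water_medium(), t_heat = 0.01,
                                    snapshot_times = 5),
               "snapshot_times")
})

test_that("Abel projection reproduces closed-form profiles", {
  r <- seq(0, 4, 0.005)
  # zero field projects to zero
  expect_true(all(abel_project(r, rep(0, length(r))) == 0))
  # uniform sphere projects to the chord length 2 sqrt(R^2 - x^2)
  R <- 0.5
  P <- abel_project(r, as.numeric(r <= R))
  inside <- r < R - 0.02
  expect_lt(max(abs(P[inside] - 2 * sqrt(R^2 - r[inside]^2))), 0.02)
  expect_equal(e2_radius(r, P) / R, sqrt(1 - exp(-4)), tolerance = 5e-3)
  # radial Gaussian keeps its lateral sigma, amplitude sqrt(2 pi) sigma
  sig <- 0.4
  Pg <- abel_project(r, exp(-r^2 / (2 * sig^2)))
  expect_equal(Pg[1], sqrt(2 * pi) * sig, tolerance = 1e-3)
  expect_equal(Pg / Pg[1], exp(-r^2 / (2 * sig^2)), tolerance = 1e-3)
  # non-finite fields are rejected
  expect_error(abel_project(r, c(NaN, rep(0, length(r) - 1))), "finite")
})

test_that("e2_radius is exact on a Gaussian and rejects non-decaying profiles", {
  r <- seq(0, 10, 0.01)
  a <- 1.3
  expect_equal(e2_radius(r, exp(-(r / a)^2)), a * sqrt(2), tolerance = 1e-4)
  expect_error(e2_radius(r, r), "maximum at r = 0")
  expect_error(e2_radius(seq(0, 0.5, 0.01), exp(-(seq(0, 0.5, 0.01) / 2)^2)),
               "enlarge the domain")
})

test_that("resolution degradation matches the exact-diffusion oracle", {
  ratio <- resolution_degradation(0.25, 0.1)
  expect_equal(ratio, EXACT_RATIO_100NS, tolerance = 0.01)
  # vanishing duration: projection geometry only
  ratio0 <- resolution_degradation(0.25, 1e-4)
  expect_equal(ratio0, sqrt(1 - exp(-4)), tolerance = 0.01)
})

test_that("probe-delay metrics are monotone and match the exact oracle", {
  pm <- probe_delay_metrics(0.25, c(0.02, 0.05, 0.1))
  expect_true(all(diff(pm$radius_ratio) > 0))
  expect_true(all(diff(pm$phase_fraction) < 0))
  expect_equal(pm$phase_fraction[1], 1)
  last <- nrow(pm)
  expect_equal(pm$radius_ratio[last], EXACT_RATIO_DELAY100, tolerance = 0.01)
  expect_equal(pm$phase_fraction[last], EXACT_FRAC_DELAY100, tolerance = 0.01)
  expect_error(probe_delay_metrics(0.25, -0.1), "negative")
})

test_that("saturation curve is normalized at 10 ns and monotone; onset scales as R^2", {
  sc <- saturation_curve(0.25, c(0.01, 0.03, 0.1, 0.3))
  expect_equal(sc$phase[sc$duration == 0.01], 1)
  expect_true(all(diff(sc$phase) > 0))
  expect_error(saturation_curve(0.25, numeric(0)), "non-empty")
  t1 <- saturation_onset(0.25)
  t2 <- saturation_onset(0.5)
  expect_equal(t2 / t1, 4, tolerance = 0.2)
})

test_that("constant-energy heating: centre phase non-increasing in duration", {
  centre <- vapply(c(0.01, 0.05, 0.2, 1), function(d) {
    pr <- heating_profile("constant_energy", pulse_duration = d,
                          sphere_radius = 0.25)
    sol <- solve_thermal_radial(pr, water_medium(), radial_grid(0.0125, 6),
                                t_heat = d)
    ph <- project_phase(sol)
    ph$delta_theta[nrow(ph$delta_theta), 1]
  }, numeric(1))
  expect_true(all(diff(centre) <= 0))
})

test_that("CW spread is the steady-state temperature e^-2 radius, ~4.9 sphere radii", {
  ratio <- cw_resolution_limit(0.25)
  # infinite-medium closed form: T(0) = q R^2 / (2 nu), tail q R^3/(3 nu r)
  # => r*/R = 1/(3 e^-2 / 2) = e^2 * 2/3 / ... = 4.93 (finite bath slightly less)
  expect_gt(ratio, 4.5)
  expect_lt(ratio, 5.0)
})

test_that("decay_time interpolates crossings and rejects flat curves", {
  t <- seq(0, 400, 0.5)
  expect_equal(decay_time(t, exp(-t / 50)), 50, tolerance = 1e-3)
  expect_equal(decay_time(t, exp(-t / 50), level = 0.03), -50 * log(0.03),
               tolerance = 1e-3)
  expect_error(decay_time(t, rep(1, length(t))), "does not cross")
})

test_that("temperature-rise inversion reproduces the droplet and nucleolus scales", {
  expect_equal(estimate_temperature_rise(40, 3), 8.06, tolerance = 1e-2)
  expect_equal(estimate_temperature_rise(14, 5), 1.69, tolerance = 1e-2)
  expect_equal(estimate_temperature_rise(0, 3), 0)
  expect_error(estimate_temperature_rise(40, 0), "diameter")
})
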