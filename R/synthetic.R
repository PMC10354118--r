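#' Synthetic phantom cell
#'
#' Generates a smooth dome-shaped cell on a flat background with disjoint
#' organelle masks — an elliptical nucleus containing a nucleolus, and
#' extranuclear lipid droplets — plus per-component concentration maps
#' (lipid, protein, water) and the MIR-OFF quantitative phase image
#' \eqn{\phi = 2\pi \Delta n h / \lambda}. All randomness (droplet
#' placement) derives from `seed`; the default 256 x 256 field at
#' 0.44 um/pixel matches a 110-um illumination field.
#'
#' @param size image edge, pixels.
#' @param pixel_size um per pixel.
#' @param height_max dome height, um (must not exceed the 20-um channel).
#' @param n_droplets number of lipid droplets.
#' @param delta_n refractive-index difference for the phase image.
#' @param lambda probe wavelength, um.
#' @param seed integer seed.
#' @return An object of class `phantom_cell`: list with `height` (um),
#'   `masks` (nucleus, nucleolus, droplets, cell), `conc`
#'   (rows x cols x 3, lipid/protein/water), `phase` (radians),
#'   `pixel_size`.
#' @export
make_phantom_cell <- function(size = 256, pixel_size = 0.44,
                              height_max = 8, n_droplets = 6,
                              delta_n = 0.0323, lambda = 0.532,
                              seed = 1) {
  set.seed(as.integer(seed %% 2147483647))
  stopifnot(height_max <= 20)
  n <- size
  fov <- n * pixel_size
  xs <- (seq_len(n) - 0.5) * pixel_size - fov / 2
  X <- outer(rep(1, n), xs)
  Y <- outer(xs, rep(1, n))
  # dome: rounded super-Gaussian, ~60% of the field across
  a <- 0.28 * fov
  h <- height_max * exp(-((X / a)^2 + (Y / (0.8 * a))^2)^2)
  h[h < 1e-3] <- 0

  nucleus <- ((X + 0.05 * fov) / (0.35 * a))^2 + (Y / (0.3 * a))^2 <= 1
  nucleolus <- ((X + 0.05 * fov) / (0.08 * a))^2 + (Y / (0.08 * a))^2 <= 1
  cell <- h > 0.5
  droplets <- matrix(FALSE, n, n)
  placed <- 0
  guard <- 0
  while (placed < n_droplets && guard < 1000) {
    guard <- guard + 1
    cx <- runif(1, -0.8, 0.8) * a
    cy <- runif(1, -0.7, 0.7) * a
    rad <- runif(1, 1.0, 1.8) # um
    cand <- (X - cx)^2 + (Y - cy)^2 <= rad^2
    # droplets are extranuclear and inside the cell
    if (any(cand & nucleus) || !all(cand[cand] & cell[cand])) next
    if (!all(cell[cand])) next
    droplets <- droplets | cand
    placed <- placed + 1
  }

  conc <- array(0, c(n, n, 3), dimnames = list(NULL, NULL,
                                               c("lipid", "protein", "water")))
  conc[, , "lipid"][droplets] <- 1
  conc[, , "protein"] <- 0.25 * cell + 0.45 * nucleus + 0.8 * nucleolus
  # water path shrinks where the cell displaces the channel
  conc[, , "water"] <- (20 - 0.6 * h) / 20

  phase <- 2 * pi * delta_n * h / lambda
  structure(
    list(height = h, masks = list(nucleus = nucleus, nucleolus = nucleolus,
                                  droplets = droplets, cell = cell),
         conc = conc, phase = phase, pixel_size = pixel_size,
         delta_n = delta_n, lambda = lambda, seed = seed),
    class = "phantom_cell"
  )
}

#' @export
print.phantom_cell <- function(x, ...) {
  cat(sprintf(
    "<phantom_cell> %d x %d px at %g um/px, peak height %.3g um, %d droplet px\n",
    nrow(x$height), ncol(x$height), x$pixel_size, max(x$height),
    sum(x$masks$droplets)
  ))
  invisible(x)
}

#' Synthetic component spectra in the CH/OH stretching region
#'
#' Three non-negative reference spectra on a wavenumber axis: a lipid-like
#' component with the symmetric/asymmetric CH2 stretches (2854 and
#' 2925 cm^-1), a protein-like component dominated by the CH3 stretch
#' (2945 cm^-1), and a water-like OH component peaking near 3400 cm^-1 —
#' monotonically rising across a 2800-3250 cm^-1 window. Peak widths are
#' kept at or above the ~10 cm^-1 source linewidth.
#'
#' @param wavenumbers cm^-1 axis.
#' @param fwhm peak full width at half maximum, cm^-1 (>= 10).
#' @return matrix (3 x wavenumbers) with rows `lipid`, `protein`, `water`.
#' @export
make_component_spectra <- function(wavenumbers = seq(2800, 3250, length.out = 40),
                                   fwhm = 22) {
  stopifnot(fwhm >= 10)
  sig <- fwhm / (2 * sqrt(2 * log(2)))
  g <- function(mu, s = sig) exp(-(wavenumbers - mu)^2 / (2 * s^2))
  lipid <- 0.75 * g(2854) + 1.0 * g(2925)
  protein <- 0.35 * g(2874) + 1.0 * g(2945) + 0.25 * g(2880)
  water <- g(3400, 160)
  out <- rbind(lipid = lipid, protein = protein, water = water)
  pmax(out, 0)
}

#' Synthetic hyperspectral MIP stack
#'
#' Forward model of the spectro-imaging measurement: the phase-change
#' stack is \eqn{H(x,k) = B(x)\sum_i C_i(x) S_i(k)} with a lateral
#' Gaussian excitation-beam envelope B and optional i.i.d. Gaussian
#' noise. The matching water-only stack (the background a real
#' measurement would record without cells) and the exact C, S ground
#' truth are returned with the data.
#'
#' @param phantom a [make_phantom_cell()] phantom supplying the
#'   concentration maps.
#' @param spectra component spectra from [make_component_spectra()].
#' @param wavenumbers cm^-1 axis (must match `spectra`).
#' @param beam_fwhm excitation-beam FWHM, um (Inf for a flat beam).
#' @param amplitude scale of the water-component phase change, mrad.
#' @param noise i.i.d. Gaussian noise sigma, mrad.
#' @param pulse_energy optional per-wavenumber pulse energies to imprint
#'   (the stack is multiplied by `E(k)/E(k_1)`).
#' @param seed integer seed.
#' @return list with `stack`, `water_stack` (both
#'   [hyperspectral_stack()]), and `truth = list(C, S, beam)`.
#' @export
make_hyperspectral <- function(phantom, spectra,
                               wavenumbers = seq(2800, 3250, length.out = 40),
                               beam_fwhm = 85, amplitude = 30,
                               noise = 0, pulse_energy = NULL, seed = 1) {
  stopifnot(ncol(spectra) == length(wavenumbers))
  set.seed(as.integer((seed + 11) %% 2147483647))
  n <- nrow(phantom$height)
  npx <- n * n
  C <- matrix(phantom$conc, npx, dim(phantom$conc)[3])
  C <- C * amplitude
  beam <- if (is.infinite(beam_fwhm)) {
    matrix(1, n, n)
  } else {
    fov <- n * phantom$pixel_size
    xs <- (seq_len(n) - 0.5) * phantom$pixel_size - fov / 2
    sig <- beam_fwhm / (2 * sqrt(2 * log(2)))
    outer(exp(-xs^2 / (2 * sig^2)), exp(-xs^2 / (2 * sig^2)))
  }
  H <- (C %*% spectra) * as.vector(beam)
  Cw <- matrix(0, npx, nrow(spectra))
  Cw[, nrow(spectra)] <- amplitude # water only, full channel
  Hw <- (Cw %*% spectra) * as.vector(beam)
  escale <- if (is.null(pulse_energy)) rep(1, length(wavenumbers)) else {
    pulse_energy / pulse_energy[1]
  }
  H <- sweep(H, 2, escale, `*`)
  Hw <- sweep(Hw, 2, escale, `*`)
  if (noise > 0) {
    H <- H + rnorm(length(H), 0, noise)
    Hw <- Hw + rnorm(length(Hw), 0, noise)
  }
  list(
    stack = hyperspectral_stack(wavenumbers,
                                array(H, c(n, n, length(wavenumbers))),
                                pulse_energy),
    water_stack = hyperspectral_stack(wavenumbers,
                                      array(Hw, c(n, n, length(wavenumbers))),
                                      pulse_energy),
    truth = list(C = C, S = spectra, beam = beam)
  )
}

#' Synthetic H2O/D2O exchange series
#'
#' Generates per-pixel MIP traces from the two-compartment exchange
#' model: a pre-exchange plateau, then
#' \eqn{I(t) = A(h) e^{-(t-t_0)/\tau_{ext}} + (1-A(h)) e^{-(t-t_0)/\tau}}
#' with the contribution ratio A(h) from the phantom's height map under
#' Lambert-Beer attenuation. Extracellular pixels (h = 0, A = 1) decay
#' with `tau_ext` exactly. Gaussian noise is added as a fraction of the
#' pre-exchange amplitude.
#'
#' @param phantom a [make_phantom_cell()] phantom.
#' @param tau intracellular decay time, ms: a scalar or a matrix matching
#'   the phantom.
#' @param t0 exchange time origin, ms.
#' @param tau_ext extracellular decay time, ms.
#' @param fps frame rate, frames/s.
#' @param t_range `c(first, last)` frame times, ms.
#' @param noise Gaussian noise sigma as a fraction of the plateau.
#' @param D_z,L Lambert-Beer depth and channel depth, um.
#' @param seed integer seed.
#' @return list with `series` (an [exchange_series()]) and
#'   `truth = list(tau, A, height)`.
#' @export
make_exchange_series <- function(phantom, tau = 420, t0 = 99, tau_ext = 82,
                                 fps = 50, t_range = c(-100, 2000),
                                 noise = 0, D_z = 6.73, L = 20, seed = 1) {
  set.seed(as.integer((seed + 23) %% 2147483647))
  h <- phantom$height
  n <- nrow(h)
  if (is.matrix(tau)) stopifnot(identical(dim(tau), dim(h))) else {
    tau <- matrix(tau, n, n)
  }
  A <- matrix(contribution_ratio(h, D_z, L), n, n)
  times <- seq(t_range[1], t_range[2], by = 1000 / fps)
  nt <- length(times)
  frames <- array(0, c(n, n, nt))
  for (k in seq_len(nt)) {
    t <- times[k]
    I <- if (t <= t0) matrix(1, n, n) else {
      A * exp(-(t - t0) / tau_ext) + (1 - A) * exp(-(t - t0) / tau)
    }
    if (noise > 0) I <- I + rnorm(n * n, 0, noise)
    frames[, , k] <- I
  }
  list(series = exchange_series(times, frames),
       truth = list(tau = tau, A = A, height = h))
}

#' Synthetic off-axis hologram stack
#'
#' Repeated noisy holograms of a fixed object phase, for Monte-Carlo
#' validation of the phase-noise budget. Frame f uses the substream seed
#' `seed * 1000 + f`, so frames are independent and the stack is
#' reproducible.
#'
#' @param phase object phase, radians (matrix).
#' @param config an [offaxis_config()].
#' @param N_electron mean electrons per pixel.
#' @param sensor a [sensor_model()].
#' @param n_frames number of frames.
#' @param seed integer stack seed.
#' @param ... passed to [synthesize_hologram()].
#' @return 3D array (rows x cols x frames) of electron counts.
#' @export
make_hologram_stack <- function(phase, config, N_electron, sensor,
                                n_frames, seed = 1, ...) {
  out <- array(0, c(dim(phase), n_frames))
  for (f in seq_len(n_frames)) {
    out[, , f] <- synthesize_hologram(phase, config, N_electron, sensor,
                                      seed = (seed * 1000 + f) %% 2147483647,
                                      ...)
  }
  out
}
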