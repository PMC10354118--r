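#' Image-sensor model
#'
#' Parameters of the camera used for hologram acquisition: full-well
#' capacity, ADC bit depth, gain, temporal read noise and frame geometry.
#' `A_sensor` (the pixel count entering the phase-noise model) is the
#' product of the frame dimensions.
#'
#' @param full_well full-well capacity, electrons/pixel.
#' @param bit_depth ADC bits.
#' @param gain dimensionless sensor gain entering the count-to-electron
#'   conversion.
#' @param read_noise temporal sensor noise, electrons RMS.
#' @param dims frame dimensions in pixels, length-2 integer.
#' @param label sensor name.
#' @return An object of class `sensor_model`.
#' @seealso [sensor_2M()], [sensor_10k()] for the two stock cameras.
#' @export
sensor_model <- function(full_well, bit_depth, gain = 1, read_noise = 0,
                         dims = c(1024L, 1024L), label = "sensor") {
  stopifnot(full_well > 0, bit_depth >= 1, read_noise >= 0, length(dims) == 2L)
  structure(
    list(full_well = full_well, bit_depth = as.integer(bit_depth),
         gain = gain, read_noise = read_noise,
         dims = as.integer(dims), A_sensor = prod(as.integer(dims)),
         label = label),
    class = "sensor_model"
  )
}

#' High full-well-capacity camera (2 Me- per pixel)
#'
#' 2M-electron full well, 11-bit, gain 1.73, 1440 x 1440 frame,
#' 572 e- read noise.
#' @return A `sensor_model`.
#' @export
sensor_2M <- function() {
  sensor_model(2e6, 11, gain = 1.73, read_noise = 572,
               dims = c(1440L, 1440L), label = "2M-e")
}

#' Conventional CMOS camera (10 ke- per pixel)
#'
#' 10k-electron full well, 16-bit, gain 1, 1023 x 1023 frame.
#' @param read_noise electrons RMS (not part of the published operating
#'   point; defaults to 0, the shot-noise-limited regime).
#' @return A `sensor_model`.
#' @export
sensor_10k <- function(read_noise = 0) {
  sensor_model(1e4, 16, gain = 1, read_noise = read_noise,
               dims = c(1023L, 1023L), label = "10k-e")
}

#' @export
print.sensor_model <- function(x, ...) {
  cat(sprintf(
    "<sensor_model> %s: %g e- full well, %d bit, gain %g, read noise %g e-, %d x %d px\n",
    x$label, x$full_well, x$bit_depth, x$gain, x$read_noise, x$dims[1], x$dims[2]
  ))
  invisible(x)
}

#' Off-axis holography configuration
#'
#' Carrier frequency of the tilted reference wave, diameter of the
#' circular sideband crop in the spatial-frequency plane, and fringe
#' visibility. The aperture pixel count is `A_aperture = round(pi/4 D^2)`
#' (245 px -> 47,144; 201 px -> 31,731). The carrier must lie outside the
#' aperture radius so the sideband is separable from the DC term.
#'
#' @param carrier carrier frequency, cycles/pixel, length-2 (row, col).
#' @param aperture_diameter sideband crop diameter, pixels.
#' @param visibility fringe visibility v in (0, 1].
#' @param frame_dims dims of the frames this configuration will be applied
#'   to (used only for the separability check; `NULL` skips it).
#' @return An object of class `offaxis_config`.
#' @export
offaxis_config <- function(carrier = c(0.25, 0.25), aperture_diameter,
                           visibility = 1, frame_dims = NULL) {
  stopifnot(length(carrier) == 2L, aperture_diameter > 0)
  if (visibility <= 0 || visibility > 1) stop("visibility must be in (0, 1]")
  if (!is.null(frame_dims)) {
    k_px <- sqrt(sum((carrier * frame_dims)^2))
    if (k_px <= aperture_diameter / 2) {
      stop("carrier lies inside the aperture radius; sideband not separable")
    }
  }
  structure(
    list(carrier = carrier, aperture_diameter = aperture_diameter,
         A_aperture = round(pi / 4 * aperture_diameter^2),
         visibility = visibility),
    class = "offaxis_config"
  )
}

#' Shot- and sensor-noise phase precision of off-axis holography
#'
#' Temporal phase noise of the reconstructed phase difference between
#' adjacent frames,
#' \deqn{\sigma_{phase} = 2\sqrt{\frac{[N_e + \sigma_{sensor}^2]\,A_{aperture}}
#'   {v^2 N_e^2 A_{sensor}}}}
#' in mrad. With `read_noise = 0` this is the optical shot-noise limit,
#' scaling as \eqn{1/\sqrt{N_e}}. The prefactor 2 accounts for the frame
#' difference (\eqn{\sqrt 2}) and the quadrature noise split
#' (\eqn{\sqrt 2}).
#'
#' @param N_electron mean electrons per pixel contributing to the
#'   reconstruction (vectorized).
#' @param sensor a [sensor_model()].
#' @param config an [offaxis_config()] carrying visibility and aperture.
#' @return phase noise, mrad.
#' @examples
#' s <- sensor_2M()
#' cfg <- offaxis_config(aperture_diameter = 245, visibility = 0.77)
#' predict_phase_noise(3.6e5, s, cfg) # ~0.9 mrad
#' @export
predict_phase_noise <- function(N_electron, sensor, config) {
  if (any(N_electron <= 0)) stop("N_electron must be > 0")
  v <- config$visibility
  if (v <= 0) stop("visibility must be > 0")
  sig2 <- sensor$read_noise^2
  1000 * 2 * sqrt((N_electron + sig2) * config$A_aperture /
                    (v^2 * N_electron^2 * sensor$A_sensor))
}

#' Infer fringe visibility from a measured phase noise
#'
#' Closed-form inversion of the phase-noise model for the visibility:
#' \deqn{v = \frac{2}{\sigma_{phase}}
#'   \sqrt{\frac{(N_e + \sigma_{sensor}^2) A_{aperture}}{N_e^2 A_{sensor}}}}
#' The inversion is rejected when the stated noise is below the v = 1
#' (shot-limited) bound, which would imply v > 1.
#'
#' @param sigma_phase measured temporal phase noise, mrad.
#' @param N_electron electrons per pixel at the operating point.
#' @param sensor a [sensor_model()].
#' @param aperture_diameter sideband crop diameter, pixels.
#' @return visibility in (0, 1].
#' @examples
#' infer_visibility(0.9, 3.6e5, sensor_2M(), 245) # ~0.77
#' @export
infer_visibility <- function(sigma_phase, N_electron, sensor, aperture_diameter) {
  stopifnot(sigma_phase > 0, N_electron > 0)
  A_ap <- round(pi / 4 * aperture_diameter^2)
  v <- 2 / (sigma_phase / 1000) *
    sqrt((N_electron + sensor$read_noise^2) * A_ap /
           (N_electron^2 * sensor$A_sensor))
  if (v > 1) {
    stop(sprintf(
      "inconsistent inputs: stated noise %.3g mrad is below the v = 1 limit (implied v = %.3g)",
      sigma_phase, v
    ))
  }
  v
}

#' Convert sensor digital output to electrons
#'
#' \eqn{N_e = \mathrm{DN} \times \mathrm{full\_well} /
#' ((2^{bits} - 1)\,\mathrm{gain})}: the full well referred to the ADC
#' full scale, divided by the sensor gain.
#'
#' @param value digital number(s), in `[0, 2^bits - 1]`.
#' @param sensor a [sensor_model()].
#' @return electrons per pixel.
#' @export
electrons_from_counts <- function(value, sensor) {
  if (any(value < 0)) stop("digital values must be non-negative")
  max_code <- 2^sensor$bit_depth - 1
  if (any(value >= max_code)) {
    warning("saturated digital value(s) at or above full scale")
  }
  value * sensor$full_well / (max_code * sensor$gain)
}

#' Synthesize an off-axis hologram
#'
#' Forward model
#' \eqn{I(x) = N_e [1 + v\cos(2\pi k\cdot x + \phi(x))]}
#' with optional Poisson shot noise, Gaussian read noise and ADC
#' quantization (round-half-even via [round()]; clipping at full well is
#' logged with a warning, not fatal). Output is in electrons.
#'
#' @param phase object phase \eqn{\phi(x)}, radians, as a matrix.
#' @param config an [offaxis_config()].
#' @param N_electron mean electrons per pixel.
#' @param sensor a [sensor_model()]; its `read_noise` is applied.
#' @param seed optional integer seed for reproducible noise.
#' @param shot_noise apply Poisson shot noise.
#' @param quantize apply gain/bit-depth quantization.
#' @return matrix of electron counts, same shape as `phase`.
#' @export
synthesize_hologram <- function(phase, config, N_electron, sensor,
                                seed = NULL, shot_noise = TRUE,
                                quantize = FALSE) {
  stopifnot(is.matrix(phase))
  if (!is.null(seed)) set.seed(as.integer(seed %% 2147483647))
  nr <- nrow(phase)
  nc <- ncol(phase)
  ky <- config$carrier[1]
  kx <- config$carrier[2]
  carg <- 2 * pi * (outer(seq_len(nr) - 1, rep(1, nc)) * ky +
                      outer(rep(1, nr), seq_len(nc) - 1) * kx) + phase
  I <- N_electron * (1 + config$visibility * cos(carg))
  if (N_electron * (1 + config$visibility) > sensor$full_well) {
    warning("fringe peaks exceed the sensor full well; clipping")
  }
  if (shot_noise) I <- matrix(rpois(length(I), pmax(I, 0)), nr, nc)
  if (sensor$read_noise > 0) I <- I + rnorm(length(I), 0, sensor$read_noise)
  I <- pmin(I, sensor$full_well)
  if (quantize) {
    conv <- sensor$full_well / ((2^sensor$bit_depth - 1) * sensor$gain)
    I <- round(I / conv) * conv
  }
  matrix(I, nr, nc)
}

#' Reconstruct the phase from an off-axis hologram
#'
#' Fourier sideband method: 2D FFT, circular crop of diameter
#' `aperture_diameter` centred on the carrier, shift of the carrier to
#' zero frequency, inverse FFT and complex argument. The result is the
#' principal-value phase in (-pi, pi]; no spatial unwrapping is applied.
#'
#' @param hologram intensity/count matrix.
#' @param config an [offaxis_config()]; its carrier must land within half
#'   a frequency bin of an integer grid position.
#' @return phase matrix, radians.
#' @export
reconstruct_phase <- function(hologram, config) {
  stopifnot(is.matrix(hologram))
  nr <- nrow(hologram)
  nc <- ncol(hologram)
  kbin <- config$carrier * c(nr, nc)
  if (any(abs(kbin - round(kbin)) > 0.5)) {
    stop("carrier frequency does not fall on the discrete frequency grid")
  }
  kbin <- round(kbin)
  F <- fft(hologram)
  # frequency coordinates relative to the carrier, with wrap-around
  fy <- ((seq_len(nr) - 1 - kbin[1] + nr / 2) %% nr) - nr / 2
  fx <- ((seq_len(nc) - 1 - kbin[2] + nc / 2) %% nc) - nc / 2
  mask <- outer(fy^2, fx^2, `+`) <= (config$aperture_diameter / 2)^2
  # recentre the carrier at (0, 0) and apply the circular crop
  Fs <- F[((seq_len(nr) - 1 + kbin[1]) %% nr) + 1,
          ((seq_len(nc) - 1 + kbin[2]) %% nc) + 1]
  my <- ((seq_len(nr) - 1 + nr / 2) %% nr) - nr / 2
  mx <- ((seq_len(nc) - 1 + nc / 2) %% nc) - nc / 2
  mask0 <- outer(my^2, mx^2, `+`) <= (config$aperture_diameter / 2)^2
  field <- fft(Fs * mask0, inverse = TRUE) / length(Fs)
  Arg(field)
}

#' Temporal phase noise of a reconstructed phase stack
#'
#' Differences between adjacent frames are formed, the temporal standard
#' deviation of the differences is computed per pixel, and the mean over a
#' region of interest (default 80 x 80 pixels) is returned. For i.i.d.
#' frames of noise s this estimates \eqn{\sqrt 2 s} — the frame-difference
#' noise that the closed-form budget predicts.
#'
#' @param stack 3D array (rows x cols x frames) of phase, radians;
#'   at least 3 frames.
#' @param roi `c(row0, col0, height, width)` region of interest, 1-based
#'   origin; default a centred 80 x 80 box.
#' @return temporal phase noise, mrad.
#' @export
measure_temporal_noise <- function(stack, roi = NULL) {
  stopifnot(length(dim(stack)) == 3)
  d <- dim(stack)
  if (d[3] < 3) stop("at least 3 frames are required")
  if (is.null(roi)) {
    h <- min(80L, d[1])
    w <- min(80L, d[2])
    roi <- c((d[1] - h) %/% 2 + 1L, (d[2] - w) %/% 2 + 1L, h, w)
  }
  r0 <- roi[1]; c0 <- roi[2]; h <- roi[3]; w <- roi[4]
  if (r0 < 1 || c0 < 1 || r0 + h - 1 > d[1] || c0 + w - 1 > d[2]) {
    stop("roi outside the image")
  }
  diffs <- stack[, , -1, drop = FALSE] - stack[, , -d[3], drop = FALSE]
  px_sd <- apply(diffs, c(1, 2), sd)
  mean(px_sd[r0:(r0 + h - 1), c0:(c0 + w - 1)]) * 1000
}
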