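#' Photothermal (MIP) image from an ON/OFF phase frame pair
#'
#' The MIP phase-change image is the pixelwise difference between the
#' phase images captured with the MIR excitation on and off. Frames are
#' assumed registered (common-path geometry).
#'
#' @param on_phase,off_phase phase matrices of identical shape (any
#'   consistent unit; mrad throughout the pipeline).
#' @return matrix, `on_phase - off_phase`.
#' @export
mip_image <- function(on_phase, off_phase) {
  if (!identical(dim(on_phase), dim(off_phase))) stop("frame shapes differ")
  on_phase - off_phase
}

#' Subtract the water-only MIP background
#'
#' The MIP image of water without cells (same excitation) is subtracted to
#' reveal intracellular structure against the bulk-water photothermal
#' background. Noise inflates by sqrt(2) because two independent noisy
#' images are differenced.
#'
#' @param mip MIP image of the sample.
#' @param water_mip MIP image of water without cells, same geometry.
#' @return matrix.
#' @export
subtract_water_background <- function(mip, water_mip) {
  if (!identical(dim(mip), dim(water_mip))) stop("frame shapes differ")
  mip - water_mip
}

#' Correct the MIR beam profile
#'
#' Divides a MIP image by the peak-normalized water MIP image, flattening
#' the spatial envelope of the excitation beam. Pixels where the water
#' image falls below `epsilon` times its maximum are masked to `NA`
#' (beam skirts, where the division would amplify noise) and are excluded
#' from downstream statistics.
#'
#' @param mip MIP image.
#' @param water_mip water-only MIP image, same geometry.
#' @param epsilon mask threshold as a fraction of the water-map maximum.
#' @return matrix with `NA` at masked pixels.
#' @export
beam_profile_correct <- function(mip, water_mip, epsilon = 0.05) {
  if (!identical(dim(mip), dim(water_mip))) stop("frame shapes differ")
  wnorm <- water_mip / max(water_mip, na.rm = TRUE)
  ok <- wnorm > epsilon
  if (!any(ok)) stop("all pixels fall below the beam-profile mask threshold")
  out <- mip / wnorm
  out[!ok] <- NA_real_
  out
}

#' Signal-to-noise report for a MIP image
#'
#' The noise is the spatial standard deviation inside a 20 x 20 pixel box;
#' the signal is the MIP phase change at a stated pixel (or the image
#' maximum). SNR is their ratio.
#'
#' @param mip MIP image, mrad.
#' @param signal_pixel `c(row, col)` of the signal site, 1-based; `NULL`
#'   uses the location of the image maximum.
#' @param noise_box `c(row0, col0)` 1-based origin of the noise box.
#' @param box_size box edge, pixels (default 20).
#' @return An object of class `snr_report`: list with `signal` (mrad),
#'   `noise` (mrad), `snr`, `box` and `signal_pixel`.
#' @export
evaluate_snr <- function(mip, signal_pixel = NULL, noise_box, box_size = 20L) {
  d <- dim(mip)
  r0 <- noise_box[1]; c0 <- noise_box[2]
  if (r0 < 1 || c0 < 1 || r0 + box_size - 1 > d[1] || c0 + box_size - 1 > d[2]) {
    stop("noise box outside the image")
  }
  if (is.null(signal_pixel)) {
    signal_pixel <- which(abs(mip) == max(abs(mip), na.rm = TRUE), arr.ind = TRUE)[1, ]
  }
  signal <- mip[signal_pixel[1], signal_pixel[2]]
  noise <- sd(mip[r0:(r0 + box_size - 1), c0:(c0 + box_size - 1)], na.rm = TRUE)
  if (!is.finite(noise) || noise == 0) {
    warning("degenerate noise box (zero spatial STD); SNR reported as Inf")
    snr <- Inf
  } else {
    snr <- abs(signal) / noise
  }
  structure(
    list(signal = signal, noise = noise, snr = snr,
         box = c(noise_box, box_size, box_size),
         signal_pixel = signal_pixel),
    class = "snr_report"
  )
}

#' @export
print.snr_report <- function(x, ...) {
  cat(sprintf("<snr_report> signal %.3g mrad, noise %.3g mrad, SNR %.3g\n",
              x$signal, x$noise, x$snr))
  invisible(x)
}

#' Demodulate a chopped frame stream into ON/OFF pairs
#'
#' The mechanical chopper blocks the MIR beam on alternating sensor
#' frames, so consecutive frames pair into (ON, OFF) and the MIP image
#' rate is half the sensor frame rate. An odd trailing frame is dropped
#' with a warning.
#'
#' @param frames 3D array (rows x cols x frames) at the sensor rate.
#' @param first_frame `"on"` if the first frame is MIR-ON, `"off"` for the
#'   inverted chopper phase.
#' @return list with `on` and `off` 3D arrays (`n_pairs` frames each) and
#'   `n_pairs`.
#' @export
demodulate_stream <- function(frames, first_frame = c("on", "off")) {
  first_frame <- match.arg(first_frame)
  stopifnot(length(dim(frames)) == 3)
  nf <- dim(frames)[3]
  if (nf < 2) stop("need at least one ON/OFF pair")
  if (nf %% 2 == 1) {
    warning("odd frame count; dropping the last frame")
    nf <- nf - 1L
  }
  idx <- seq_len(nf)
  odd <- idx[idx %% 2 == 1]
  even <- idx[idx %% 2 == 0]
  if (first_frame == "on") {
    list(on = frames[, , odd, drop = FALSE],
         off = frames[, , even, drop = FALSE],
         n_pairs = nf %/% 2)
  } else {
    list(on = frames[, , even, drop = FALSE],
         off = frames[, , odd, drop = FALSE],
         n_pairs = nf %/% 2)
  }
}
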