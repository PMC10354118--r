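#' Cell height map from a quantitative phase image
#'
#' The MIR-OFF phase image is low-pass filtered (Gaussian blur) to keep
#' the global cell shape and converted to height with
#' \eqn{h = \phi \lambda / (2\pi \Delta n)}, using the literature
#' intracellular/extracellular refractive-index difference
#' \eqn{\Delta n = 0.0323}. Heights are clipped to `[0, max_height]`
#' (the capillary channel depth); substantial negative phase triggers a
#' warning before clipping.
#'
#' @param phase phase image, radians.
#' @param delta_n refractive-index difference (> 0).
#' @param lambda probe wavelength, um.
#' @param lowpass_sigma Gaussian blur sigma in um (0 disables filtering).
#' @param pixel_size um per pixel.
#' @param max_height channel depth L, um.
#' @return height map, um.
#' @examples
#' height_from_phase(matrix(0.3819, 8, 8), lowpass_sigma = 0) # ~1 um
#' @export
height_from_phase <- function(phase, delta_n = 0.0323, lambda = 0.532,
                              lowpass_sigma = 5, pixel_size = 0.44,
                              max_height = 20) {
  stopifnot(delta_n > 0)
  lp <- if (lowpass_sigma > 0) {
    gaussian_blur(phase, lowpass_sigma / pixel_size)
  } else {
    phase
  }
  h <- lp * lambda / (2 * pi * delta_n)
  if (any(h < -0.05 * max(abs(h)))) {
    warning("negative heights beyond tolerance; clipping to 0")
  }
  pmin(pmax(h, 0), max_height)
}

# Separable Gaussian blur with edge renormalization (kernel mass that
# falls outside the image is compensated, so flat regions stay flat).
gaussian_blur <- function(x, sigma_px) {
  if (sigma_px <= 0) return(x)
  rad <- max(1L, ceiling(4 * sigma_px))
  k <- exp(-((-rad:rad)^2) / (2 * sigma_px^2))
  k <- k / sum(k)
  blur1 <- function(m) {
    n <- nrow(m)
    pad <- matrix(0, rad, ncol(m))
    xp <- rbind(pad, m, pad)
    out <- matrix(0, n, ncol(m))
    for (i in seq_along(k)) {
      out <- out + k[i] * xp[(i - 1) + seq_len(n), , drop = FALSE]
    }
    out
  }
  ones <- matrix(1, nrow(x), ncol(x))
  num <- t(blur1(t(blur1(x))))
  den <- t(blur1(t(blur1(ones))))
  num / den
}

#' Extracellular contribution ratio A(h)
#'
#' Fraction of a pixel's photothermal signal that originates from the
#' extracellular water column in a channel of depth `L`, for cell height
#' `h`, under Lambert-Beer attenuation of the MIR beam with 1/e depth
#' `D_z`:
#' \deqn{A(h) = \frac{e^{-h/D_z} - e^{-L/D_z}}{1 - e^{-L/D_z}}}
#' so A(0) = 1 (no cell, all signal extracellular) and A(L) = 0 (cell
#' fills the channel). A(h) is strictly decreasing in h.
#'
#' @param h cell height, um, in `[0, L]` (vectorized).
#' @param D_z MIR 1/e attenuation depth, um (6.73 at 3014 cm^-1).
#' @param L channel (capillary) depth, um.
#' @return contribution ratio in `[0, 1]`.
#' @export
contribution_ratio <- function(h, D_z = 6.73, L = 20) {
  if (any(h < -1e-9 | h > L + 1e-9)) stop("h must lie in [0, L]")
  h <- pmin(pmax(h, 0), L)
  (exp(-h / D_z) - exp(-L / D_z)) / (1 - exp(-L / D_z))
}

#' Time series of MIP frames during an H2O/D2O exchange
#'
#' Container for a stack of MIP images with time stamps (ms). Time stamps
#' must be strictly increasing and uniformly spaced to within 1% (50-fps
#' acquisition).
#'
#' @param times frame time stamps, ms; t = 0 marks the onset of the
#'   exchange, negative times are pre-exchange.
#' @param frames 3D array (rows x cols x frames).
#' @param wavenumber excitation wavenumber, cm^-1.
#' @return An object of class `exchange_series`.
#' @export
exchange_series <- function(times, frames, wavenumber = 3014) {
  stopifnot(length(dim(frames)) == 3, dim(frames)[3] == length(times))
  dt <- diff(times)
  if (any(dt <= 0)) stop("time stamps must be strictly increasing")
  if (max(dt) / min(dt) - 1 > 0.01) stop("frame spacing not uniform within 1%")
  structure(list(times = times, frames = frames, wavenumber = wavenumber),
            class = "exchange_series")
}

#' @export
print.exchange_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<exchange_series> %d frames of %d x %d px, t = %g..%g ms at %g cm^-1\n",
    d[3], d[1], d[2], min(x$times), max(x$times), x$wavenumber
  ))
  invisible(x)
}

#' Fit the extracellular decay (time origin and decay time)
#'
#' The mean MIP trace over a cell-free region, normalized to its
#' pre-exchange plateau, is fitted with the pure extracellular model
#' (contribution ratio A = 1):
#' \eqn{I(t) = 1} for \eqn{t \le t_0}, \eqn{\exp(-(t-t_0)/\tau_{ext})}
#' after, by least squares over \eqn{(t_0, \tau_{ext})}.
#'
#' @param series an [exchange_series()].
#' @param roi `c(row0, col0, height, width)` of a cell-free region.
#' @return list with `t0` (ms), `tau_ext` (ms) and the fitted trace.
#' @export
fit_extracellular <- function(series, roi) {
  tr <- roi_trace(series, roi)
  t <- series$times
  pre <- tr[t <= 0]
  if (length(pre) == 0) pre <- tr[1]
  y <- tr / mean(pre)
  if (y[length(y)] > 0.8 * max(y)) stop("series does not decay; cannot fit")
  model <- function(p) {
    t0 <- p[1]; tau <- p[2]
    ifelse(t <= t0, 1, exp(-(t - t0) / tau))
  }
  sse <- function(p) {
    if (p[2] <= 0) return(1e12)
    sum((y - model(p))^2)
  }
  # starting values: t0 where the trace first drops below 90%, tau from
  # a log-linear fit of the tail
  t0_init <- t[which(y < 0.9)[1]]
  tail_idx <- which(y < 0.7 & y > 0.05)
  tau_init <- if (length(tail_idx) >= 2) {
    -1 / stats::coef(stats::lm(log(y[tail_idx]) ~ t[tail_idx]))[2]
  } else {
    diff(range(t)) / 3
  }
  fit <- optim(c(t0_init, unname(tau_init)), sse, method = "L-BFGS-B",
               lower = c(min(t), 1e-3), upper = c(max(t), 1e6))
  list(t0 = unname(fit$par[1]), tau_ext = unname(fit$par[2]), fitted = model(fit$par),
       trace = y, times = t)
}

roi_trace <- function(series, roi) {
  d <- dim(series$frames)
  r <- roi[1]:(roi[1] + roi[3] - 1)
  cc <- roi[2]:(roi[2] + roi[4] - 1)
  if (max(r) > d[1] || max(cc) > d[2] || roi[1] < 1 || roi[2] < 1) {
    stop("roi outside the image")
  }
  apply(series$frames[r, cc, , drop = FALSE], 3, mean)
}

#' Per-pixel intracellular decay-time map
#'
#' Each pixel's MIP trace, normalized to its pre-exchange plateau, is
#' fitted with the two-compartment exchange model
#' \deqn{I(t) = A(h)\, e^{-(t-t_0)/\tau_{ext}} + (1 - A(h))\, e^{-(t-t_0)/\tau}}
#' where the extracellular parameters \eqn{t_0, \tau_{ext}} and the
#' pixelwise contribution ratio \eqn{A(h)} are fixed, and only the
#' intracellular decay time \eqn{\tau} is free (bounded scalar least
#' squares on log tau). The fit uses frames with \eqn{t \ge} `fit_start`
#' to skip the liquid-exchange agitation artifact. Pixels with
#' \eqn{A(h) > } `A_max` carry essentially no intracellular amplitude and
#' are flagged unidentifiable (`NA`).
#'
#' @param series an [exchange_series()].
#' @param height height map, um, same spatial shape as the frames.
#' @param t0 exchange time origin, ms.
#' @param tau_ext extracellular decay time, ms.
#' @param D_z,L Lambert-Beer depth and channel depth, um.
#' @param fit_start first time (ms) included in the fit.
#' @param tau_bounds `(lower, upper)` bounds on tau, ms.
#' @param mask logical matrix of pixels to fit; default: all pixels with
#'   identifiable intracellular amplitude.
#' @param A_max contribution-ratio cutoff above which a pixel is flagged.
#' @return An object of class `exchange_fit`: list with `tau` (matrix,
#'   ms, `NA` where not fitted), `A`, `n_fitted`, `n_flagged` and the
#'   model constants.
#' @export
fit_decay_map <- function(series, height, t0 = 99, tau_ext = 82,
                          D_z = 6.73, L = 20, fit_start = 120,
                          tau_bounds = c(10, 5000), mask = NULL,
                          A_max = 0.99) {
  d <- dim(series$frames)
  stopifnot(identical(dim(height), d[1:2]))
  t <- series$times
  use_t <- t >= fit_start
  if (sum(use_t) < 3) stop("insufficient time points after fit_start")
  A <- matrix(contribution_ratio(height, D_z, L), d[1], d[2])
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  pre_idx <- which(t <= 0)
  if (length(pre_idx) == 0) pre_idx <- 1L
  tt <- t[use_t]
  ext_term <- exp(-(tt - t0) / tau_ext)
  log_b <- log(tau_bounds)

  tau <- matrix(NA_real_, d[1], d[2])
  flagged <- matrix(FALSE, d[1], d[2])
  for (j in seq_len(d[2])) {
    for (i in seq_len(d[1])) {
      if (!mask[i, j]) next
      if (A[i, j] > A_max) {
        flagged[i, j] <- TRUE
        next
      }
      y <- series$frames[i, j, ]
      y <- y / mean(y[pre_idx])
      yy <- y[use_t]
      a <- A[i, j]
      sse <- function(ltau) {
        m <- a * ext_term + (1 - a) * exp(-(tt - t0) / exp(ltau))
        sum((yy - m)^2)
      }
      opt <- optimize(sse, interval = log_b, tol = 1e-8)
      tau[i, j] <- exp(opt$minimum)
    }
  }
  structure(
    list(tau = tau, A = A, t0 = t0, tau_ext = tau_ext, D_z = D_z, L = L,
         fit_start = fit_start, n_fitted = sum(!is.na(tau)),
         n_flagged = sum(flagged), flagged = flagged),
    class = "exchange_fit"
  )
}

#' @export
print.exchange_fit <- function(x, ...) {
  cat(sprintf(
    "<exchange_fit> %d pixels fitted (%d flagged unidentifiable); mean tau %.3g ms\n",
    x$n_fitted, x$n_flagged, mean(x$tau, na.rm = TRUE)
  ))
  invisible(x)
}

#' Cell surface area and volume from a height map
#'
#' \deqn{S = \sum \sqrt{1 + (\partial h/\partial x)^2 +
#'   (\partial h/\partial y)^2}\, \Delta x \Delta y, \qquad
#'   V = \sum h\, \Delta x \Delta y}
#' with central-difference gradients (one-sided at the image edge), summed
#' over the cell mask.
#'
#' @param height height map, um.
#' @param dx,dy pixel pitch, um.
#' @param mask logical matrix of cell pixels; default `height > 0.5` um.
#' @return list with `S` (um^2) and `V` (um^3).
#' @export
surface_and_volume <- function(height, dx = 0.44, dy = 0.44, mask = NULL) {
  if (any(!is.finite(height))) stop("height map must be finite")
  if (is.null(mask)) mask <- height > 0.5
  if (!any(mask)) stop("empty cell mask")
  gx <- height
  gx[, ] <- 0
  nc <- ncol(height)
  nr <- nrow(height)
  gx[, 2:(nc - 1)] <- (height[, 3:nc] - height[, 1:(nc - 2)]) / (2 * dx)
  gx[, 1] <- (height[, 2] - height[, 1]) / dx
  gx[, nc] <- (height[, nc] - height[, nc - 1]) / dx
  gy <- height
  gy[, ] <- 0
  gy[2:(nr - 1), ] <- (height[3:nr, ] - height[1:(nr - 2), ]) / (2 * dy)
  gy[1, ] <- (height[2, ] - height[1, ]) / dy
  gy[nr, ] <- (height[nr, ] - height[nr - 1, ]) / dy
  el <- sqrt(1 + gx^2 + gy^2)
  list(S = sum(el[mask]) * dx * dy, V = sum(height[mask]) * dx * dy)
}

#' Diffusional membrane water permeability
#'
#' \deqn{P_d = \frac{1}{\tau\,(S/V)}}
#' with tau in ms and S/V in um^-1; the um/ms result is converted to cm/s
#' (1 um/ms = 0.1 cm/s).
#'
#' @param tau mean intracellular decay time, ms.
#' @param S cell surface area, um^2.
#' @param V cell volume, um^3.
#' @return permeability, cm/s.
#' @examples
#' permeability(420, 1404, 3779) # ~6.4e-4 cm/s
#' @export
permeability <- function(tau, S, V) {
  if (tau <= 0 || S <= 0 || V <= 0) stop("tau, S and V must be > 0")
  V / (tau * S) * 0.1
}

#' Full water-exchange analysis
#'
#' Runs the complete permeability pipeline on an exchange series: height
#' map from the MIR-OFF phase image, per-pixel decay-time fit, mean tau
#' over an averaging region, morphological S and V, and the permeability.
#'
#' @param series an [exchange_series()] of MIP frames.
#' @param off_phase MIR-OFF phase image, radians.
#' @param t0,tau_ext exchange model constants, ms (fit them with
#'   [fit_extracellular()] when unknown).
#' @param tau_roi `c(row0, col0, height, width)` averaging region for tau;
#'   `NULL` averages fitted pixels with intracellular amplitude
#'   `1 - A >= 1 - A_max_mean` (thin-edge pixels with a vanishing
#'   intracellular share produce noise-dominated tau estimates and would
#'   bias the mean).
#' @param A_max_mean contribution-ratio cutoff for the default averaging
#'   mask.
#' @param pixel_size um per pixel.
#' @param lowpass_sigma height-map low-pass scale, um; keep it small
#'   relative to the cell footprint or the height (and hence A and tau)
#'   will be biased.
#' @param ... passed to [fit_decay_map()].
#' @return An object of class `permeability_result`: list with `P_d`
#'   (cm/s), `S`, `V`, `tau_mean`, the `exchange_fit` and the height map.
#' @export
fit_water_exchange <- function(series, off_phase, t0 = 99, tau_ext = 82,
                               tau_roi = NULL, A_max_mean = 0.8,
                               pixel_size = 0.44, lowpass_sigma = 5, ...) {
  h <- height_from_phase(off_phase, pixel_size = pixel_size,
                         lowpass_sigma = lowpass_sigma)
  fit <- fit_decay_map(series, h, t0 = t0, tau_ext = tau_ext, ...)
  tau_vals <- if (is.null(tau_roi)) {
    fit$tau[fit$A <= A_max_mean]
  } else {
    fit$tau[tau_roi[1]:(tau_roi[1] + tau_roi[3] - 1),
            tau_roi[2]:(tau_roi[2] + tau_roi[4] - 1)]
  }
  tau_mean <- mean(tau_vals, na.rm = TRUE)
  sv <- surface_and_volume(h, dx = pixel_size, dy = pixel_size)
  structure(
    list(P_d = permeability(tau_mean, sv$S, sv$V), S = sv$S, V = sv$V,
         tau_mean = tau_mean, fit = fit, height = h,
         pixel_size = pixel_size),
    class = "permeability_result"
  )
}

#' @export
print.permeability_result <- function(x, ...) {
  cat(sprintf(
    "<permeability_result> P_d = %.3g cm/s (tau = %.3g ms, S = %.4g um^2, V = %.4g um^3)\n",
    x$P_d, x$tau_mean, x$S, x$V
  ))
  invisible(x)
}
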