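#' Hyperspectral MIP stack
#'
#' One MIP phase-change image per excitation wavenumber, with an optional
#' per-wavenumber pulse-energy record. Wavenumbers must be strictly
#' increasing and match the number of frames.
#'
#' @param wavenumbers cm^-1, strictly increasing.
#' @param frames 3D array (rows x cols x wavenumbers), mrad.
#' @param pulse_energy optional pulse energies E(k), uJ.
#' @return An object of class `hyperspectral_stack`.
#' @export
hyperspectral_stack <- function(wavenumbers, frames, pulse_energy = NULL) {
  stopifnot(length(dim(frames)) == 3, dim(frames)[3] == length(wavenumbers))
  if (any(diff(wavenumbers) <= 0)) stop("wavenumbers must be strictly increasing")
  if (!is.null(pulse_energy)) {
    stopifnot(length(pulse_energy) == length(wavenumbers))
  }
  structure(
    list(wavenumbers = wavenumbers, frames = frames,
         pulse_energy = pulse_energy),
    class = "hyperspectral_stack"
  )
}

#' @export
print.hyperspectral_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<hyperspectral_stack> %d x %d px at %d wavenumbers (%g-%g cm^-1)\n",
              d[1], d[2], d[3], min(x$wavenumbers), max(x$wavenumbers)))
  invisible(x)
}

#' Normalize a hyperspectral stack for unmixing
#'
#' Two corrections prepare the stack for multivariate curve resolution:
#' per-wavenumber beam-profile division by the peak-normalized water-only
#' frame ([beam_profile_correct()] applied per wavenumber), and
#' per-wavenumber scaling by `E(k_ref)/E(k)` to remove the source's
#' pulse-energy variation.
#'
#' @param stack a [hyperspectral_stack()] of the sample.
#' @param water_stack a [hyperspectral_stack()] of water without cells on
#'   the same wavenumber axis, or `NULL` to skip the beam correction.
#' @param k_ref index of the reference wavenumber for the energy scaling.
#' @param epsilon beam-profile mask threshold.
#' @return a normalized `hyperspectral_stack`.
#' @export
normalize_stack <- function(stack, water_stack = NULL, k_ref = 1L,
                            epsilon = 0.05) {
  out <- stack$frames
  nk <- length(stack$wavenumbers)
  if (!is.null(water_stack)) {
    if (!isTRUE(all.equal(stack$wavenumbers, water_stack$wavenumbers))) {
      stop("wavenumber axes of sample and water stacks differ")
    }
    for (k in seq_len(nk)) {
      out[, , k] <- beam_profile_correct(out[, , k], water_stack$frames[, , k],
                                         epsilon = epsilon)
    }
  }
  if (!is.null(stack$pulse_energy)) {
    scale <- stack$pulse_energy[k_ref] / stack$pulse_energy
    for (k in seq_len(nk)) out[, , k] <- out[, , k] * scale[k]
  }
  hyperspectral_stack(stack$wavenumbers, out, stack$pulse_energy)
}

#' Multivariate curve resolution by alternating non-negative least squares
#'
#' Factorizes the pixels-by-wavenumbers matrix \eqn{H \approx C S} into
#' non-negative concentration maps C (pixels x components) and component
#' spectra S (components x wavenumbers), alternating exact non-negative
#' least-squares solves of C given S and S given C until the relative
#' change of the residual norm falls below `tol`. The residual is
#' non-increasing by construction. Component identity follows the
#' initialization order (no sorting).
#'
#' @param stack a [hyperspectral_stack()] or a pixels-by-wavenumbers
#'   matrix. `NA` pixels (e.g. masked by the beam correction) are dropped
#'   from the factorization and returned as `NA` rows of C.
#' @param init_spectra components-by-wavenumbers non-negative matrix of
#'   starting spectra (e.g. from [pick_initial_spectra()]); its rank must
#'   equal the component count.
#' @param max_iter iteration cap.
#' @param tol relative residual-change stopping threshold.
#' @return An object of class `mcr_fit`: `C` (pixels x components), `S`
#'   (components x wavenumbers), `residuals` (per iteration), `iterations`,
#'   `converged`, and the stack geometry for re-folding maps.
#' @export
mcr_als <- function(stack, init_spectra, max_iter = 500, tol = 1e-8) {
  if (inherits(stack, "hyperspectral_stack")) {
    d <- dim(stack$frames)
    D <- matrix(stack$frames, d[1] * d[2], d[3])
    geom <- d[1:2]
    wavenumbers <- stack$wavenumbers
  } else {
    D <- as.matrix(stack)
    geom <- NULL
    wavenumbers <- seq_len(ncol(D))
  }
  S <- as.matrix(init_spectra)
  ncomp <- nrow(S)
  if (ncomp > ncol(D)) stop("more components than wavenumbers")
  if (any(S < 0)) stop("init_spectra must be non-negative")
  if (qr(S)$rank < ncomp) stop("rank-deficient initialization spectra")

  ok <- rowSums(is.na(D)) == 0
  Dw <- D[ok, , drop = FALSE]
  Cw <- matrix(0, nrow(Dw), ncomp)
  dnorm <- norm(Dw, "F")
  res <- numeric(0)
  prev <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Cw <- nnls_rows(Dw, S)
    S_new <- t(nnls_rows(t(Dw), t(Cw)))
    # guard against a component collapsing to zero (keeps rank)
    dead <- rowSums(S_new) == 0
    S_new[dead, ] <- S[dead, ]
    S <- S_new
    r <- norm(Dw - Cw %*% S, "F")
    res <- c(res, r)
    if (r <= 1e-12 * dnorm ||
        (is.finite(prev) && abs(prev - r) <= tol * max(prev, .Machine$double.eps))) {
      converged <- TRUE
      break
    }
    prev <- r
  }
  C <- matrix(NA_real_, nrow(D), ncomp)
  C[ok, ] <- Cw
  structure(
    list(C = C, S = S, residuals = res, iterations = length(res),
         converged = converged, geometry = geom, wavenumbers = wavenumbers),
    class = "mcr_fit"
  )
}

# Row-wise non-negative least squares: minimize ||C S - D||_F over C >= 0
# for fixed S (ncomp x nk). Rows whose unconstrained solution is already
# non-negative are kept; the rest are refined with Lawson-Hanson NNLS.
nnls_rows <- function(D, S) {
  G <- S %*% t(S)
  Cu <- D %*% t(S) %*% solve(G)
  bad <- which(apply(Cu, 1, function(x) any(x < 0)))
  if (length(bad)) {
    St <- t(S)
    for (i in bad) {
      Cu[i, ] <- pracma::lsqnonneg(St, D[i, ])$x
    }
  }
  Cu
}

#' @export
print.mcr_fit <- function(x, ...) {
  cat(sprintf(
    "<mcr_fit> %d components, %d pixels, %d iterations (%sconverged), residual %.4g\n",
    nrow(x$S), nrow(x$C), x$iterations, if (x$converged) "" else "not ",
    x$residuals[length(x$residuals)]
  ))
  invisible(x)
}

#' @export
summary.mcr_fit <- function(object, ...) {
  cat(sprintf("MCR-ALS fit: %d components over %d wavenumbers\n",
              nrow(object$S), ncol(object$S)))
  for (i in seq_len(nrow(object$S))) {
    peak <- object$wavenumbers[which.max(object$S[i, ])]
    cat(sprintf("  component %d: spectral peak at %g cm^-1, max concentration %.3g\n",
                i, peak, max(object$C[, i], na.rm = TRUE)))
  }
  invisible(object)
}

#' Per-component contribution to the raw MIP phase change
#'
#' Distributes the raw phase change at each (pixel, wavenumber) among the
#' fitted components in proportion to their modelled share:
#' \deqn{R_i(x,k) = \frac{C_i(x) S_i(k)}{\sum_j C_j(x) S_j(k)}
#'   \Delta\theta(x,k)}
#' so that \eqn{\sum_i R_i = \Delta\theta} exactly wherever the model sum
#' is nonzero. Pixels with an all-zero model are flagged `NA`.
#'
#' @param fit an [mcr_als()] fit.
#' @param raw the raw stack (a [hyperspectral_stack()] or matrix) whose
#'   phase change is being attributed.
#' @return array (pixels x wavenumbers x components), or
#'   (rows x cols x wavenumbers x components) when the fit carries image
#'   geometry.
#' @export
component_contribution <- function(fit, raw) {
  D <- if (inherits(raw, "hyperspectral_stack")) {
    d <- dim(raw$frames)
    matrix(raw$frames, d[1] * d[2], d[3])
  } else {
    as.matrix(raw)
  }
  stopifnot(nrow(D) == nrow(fit$C), ncol(D) == ncol(fit$S))
  ncomp <- nrow(fit$S)
  denom <- fit$C %*% fit$S
  out <- array(NA_real_, c(nrow(D), ncol(D), ncomp))
  nz <- denom > 0 & !is.na(denom)
  for (i in seq_len(ncomp)) {
    contrib <- outer(fit$C[, i], fit$S[i, ]) / denom * D
    contrib[!nz] <- NA_real_
    out[, , i] <- contrib
  }
  if (!is.null(fit$geometry)) {
    dim(out) <- c(fit$geometry, ncol(D), ncomp)
  }
  out
}

#' Initial spectra from reference regions
#'
#' Mean spectra over user-drawn regions: lipid-droplet and nucleolus
#' regions use the water-background-subtracted stack, the extracellular
#' region uses the raw stack (its spectrum *is* the water background).
#' Negative excursions from the subtraction are clipped to zero so the
#' result is a valid non-negative initialization.
#'
#' @param stack raw [hyperspectral_stack()].
#' @param rois named list of `c(row0, col0, height, width)` entries;
#'   regions named `"extracellular"` skip the background subtraction.
#' @param water_stack water-only [hyperspectral_stack()] for the
#'   subtraction, or `NULL` to skip it everywhere.
#' @return matrix (length(rois) x wavenumbers), rows named as `rois`.
#' @export
pick_initial_spectra <- function(stack, rois, water_stack = NULL) {
  d <- dim(stack$frames)
  nk <- d[3]
  out <- matrix(0, length(rois), nk, dimnames = list(names(rois), NULL))
  for (nm in names(rois)) {
    roi <- rois[[nm]]
    r <- roi[1]:(roi[1] + roi[3] - 1)
    cc <- roi[2]:(roi[2] + roi[4] - 1)
    if (roi[1] < 1 || roi[2] < 1 || max(r) > d[1] || max(cc) > d[2]) {
      stop(sprintf("roi '%s' outside the image", nm))
    }
    sub <- !identical(nm, "extracellular") && !is.null(water_stack)
    spec <- vapply(seq_len(nk), function(k) {
      frame <- stack$frames[, , k]
      if (sub) frame <- frame - water_stack$frames[, , k]
      mean(frame[r, cc])
    }, numeric(1))
    out[nm, ] <- pmax(spec, 0)
  }
  out
}
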