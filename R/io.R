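#' Read and write image stacks as multi-page TIFF
#'
#' Stacks are stored as multi-page TIFF with axis order (row, col, frame).
#' `"uint16"` writes integer counts (holograms) exactly. `"float32"`
#' stores values as 32-bit fixed point scaled to the stack range, which
#' preserves ~9 significant digits; the affine range is recorded in a
#' plain-text sidecar `<path>.range` (two numbers, `lo hi`) that
#' `read_stack` consumes transparently.
#'
#' @param path file path.
#' @param stack matrix or 3D array to write.
#' @param dtype `"float32"` or `"uint16"`.
#' @return `read_stack` returns a 3D array; `write_stack` returns `path`
#'   invisibly.
#' @export
write_stack <- function(path, stack, dtype = c("float32", "uint16")) {
  dtype <- match.arg(dtype)
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1))
  stopifnot(length(dim(stack)) == 3)
  if (any(!is.finite(stack))) stop("stack must be finite")
  pages <- lapply(seq_len(dim(stack)[3]), function(k) stack[, , k])
  if (dtype == "float32") {
    lo <- min(stack)
    hi <- max(stack)
    span <- if (hi > lo) hi - lo else 1
    tiff::writeTIFF(lapply(pages, function(p) (p - lo) / span), path,
                    bits.per.sample = 32L, compression = "none")
    writeLines(sprintf("%.17g %.17g", lo, hi), paste0(path, ".range"))
  } else {
    if (any(stack < 0 | stack > 65535)) stop("uint16 stack values out of range")
    tiff::writeTIFF(lapply(pages, function(p) round(p) / 65535),
                    path, bits.per.sample = 16L, compression = "none")
  }
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path, dtype = c("float32", "uint16")) {
  dtype <- match.arg(dtype)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  out <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) out[, , k] <- pages[[k]]
  if (dtype == "uint16") {
    out <- round(out * 65535)
  } else {
    side <- paste0(path, ".range")
    if (!file.exists(side)) stop("missing range sidecar for float32 stack")
    rng <- scan(side, quiet = TRUE)
    span <- if (rng[2] > rng[1]) rng[2] - rng[1] else 1
    out <- out * span + rng[1]
  }
  out
}

#' Read and write decay curves as CSV
#'
#' Two-column CSV with header `time,value`; units are documented by the
#' caller. Parsing is locale-independent (C locale decimal point).
#'
#' @param path file path.
#' @param time,value numeric vectors of equal length.
#' @return `read_curve` returns a data.frame with columns `time`, `value`.
#' @export
write_curve <- function(path, time, value) {
  stopifnot(length(time) == length(value))
  write.csv(data.frame(time = time, value = value), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  df <- read.csv(path)
  if (!all(c("time", "value") %in% names(df))) {
    stop("malformed curve file: expected columns 'time' and 'value'")
  }
  df[c("time", "value")]
}
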