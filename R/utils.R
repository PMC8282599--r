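# Internal numerical helpers shared across the imaging modules.

#' Catmull-Rom (Keys a = -1/2) cubic convolution weights
#'
#' @param s fractional offset in [0, 1) from the second stencil sample.
#' @return n x 4 weight matrix for samples at integer offsets -1, 0, 1, 2.
#' @noRd
cubic_conv_weights <- function(s) {
  w0 <- ((-0.5 * s + 1) * s - 0.5) * s
  w1 <- ((1.5 * s - 2.5) * s) * s + 1
  w2 <- ((-1.5 * s + 2) * s + 0.5) * s
  w3 <- (0.5 * s - 0.5) * s * s
  cbind(w0, w1, w2, w3)
}

#' Bicubic convolution interpolation on a uniform grid
#'
#' Separable Keys cubic convolution; exact for polynomials up to total degree 2
#' along each axis and interpolating at the grid nodes. Queries in the edge
#' cells use a clamped stencil (cubic extrapolation of the boundary cell).
#'
#' @param gx,gy strictly increasing uniform grid coordinates.
#' @param z matrix of values, `z[i, j]` at `(gx[i], gy[j])`.
#' @param xq,yq query coordinates (equal length).
#' @return numeric vector of interpolated values.
#' @noRd
interp_bicubic_grid <- function(gx, gy, z, xq, yq) {
  nx <- length(gx); ny <- length(gy)
  dx <- gx[2] - gx[1]; dy <- gy[2] - gy[1]
  ix <- floor((xq - gx[1]) / dx) + 1
  iy <- floor((yq - gy[1]) / dy) + 1
  ix <- pmin(pmax(ix, 2L), nx - 2L)
  iy <- pmin(pmax(iy, 2L), ny - 2L)
  sx <- (xq - gx[ix]) / dx
  sy <- (yq - gy[iy]) / dy
  wx <- cubic_conv_weights(sx)
  wy <- cubic_conv_weights(sy)
  out <- numeric(length(xq))
  for (j in 0:3) {
    col <- iy + (j - 1L)
    acc <- numeric(length(xq))
    for (i in 0:3) {
      idx <- (col - 1L) * nx + (ix + (i - 1L))
      acc <- acc + wx[, i + 1L] * z[idx]
    }
    out <- out + wy[, j + 1L] * acc
  }
  out
}

#' Column-wise boxcar smoothing of an image matrix
#'
#' Moving average of width `k` down each column (depth axis), with shrinking
#' windows at the ends so the output has the same size as the input.
#' @noRd
boxcar_columns <- function(x, k = 3L) {
  if (k <= 1L) return(x)
  h <- nrow(x)
  cs <- rbind(0, apply(x, 2, cumsum))
  half <- (k - 1L) %/% 2L
  lo <- pmax(seq_len(h) - half - 1L, 0L)
  hi <- pmin(seq_len(h) + (k - 1L - half), h)
  (cs[hi + 1L, , drop = FALSE] - cs[lo + 1L, , drop = FALSE]) / (hi - lo)
}

#' Topographic prominence of a peak in a 1-D profile
#' @noRd
peak_prominence <- function(v, p) {
  h <- v[p]
  left <- if (p > 1) v[seq_len(p - 1L)] else numeric(0)
  right <- if (p < length(v)) v[(p + 1L):length(v)] else numeric(0)
  base_side <- function(seg, from_peak) {
    if (!length(seg)) return(h)  # peak at the edge: no drop on this side
    if (from_peak) seg <- rev(seg)
    higher <- which(seg > h)
    if (length(higher)) min(seg[seq_len(higher[1])]) else min(seg)
  }
  minl <- base_side(left, from_peak = TRUE)
  minr <- base_side(right, from_peak = FALSE)
  h - max(minl, minr)
}

#' Sub-pixel peak refinement by a log-quadratic (Gaussian) fit
#'
#' Exact for a sampled Gaussian profile: the log of a Gaussian is a parabola,
#' so the three-point vertex estimate recovers the continuous band centre.
#' @noRd
refine_peak_subpixel <- function(v, p, eps = 1e-9) {
  if (p <= 1L || p >= length(v)) return(as.numeric(p))
  l <- log(pmax(v[(p - 1L):(p + 1L)], eps))
  denom <- l[1] - 2 * l[2] + l[3]
  if (!is.finite(denom) || denom >= -1e-12) return(as.numeric(p))
  delta <- 0.5 * (l[1] - l[3]) / denom
  p + max(min(delta, 0.75), -0.75)
}

#' Evaluate a polynomial with coefficients in increasing degree order
#' @noRd
polyval_inc <- function(beta, u) {
  out <- rep(beta[length(beta)], length(u))
  for (k in rev(seq_len(length(beta) - 1L))) out <- out * u + beta[k]
  out
}

assert_that <- function(ok, msg) if (!isTRUE(ok)) abort(msg)
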