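# Low-level pre-treatment operators. All take and return a numeric matrix
# (scans x points); shape is always preserved. The spectra_set-aware
# pipeline interface lives in pipeline.R.

as_absorbance <- function(x) {
  if (inherits(x, "spectra_set")) x$absorbance else as.matrix(x)
}

#' Detrend: remove a per-scan baseline polynomial
#'
#' Fits, for every scan independently, a least-squares polynomial of the
#' given order in the point index and subtracts it, removing tilted or
#' curved baseline variation. The residual of each row is orthogonal to the
#' polynomial basis.
#'
#' @param X Absorbance matrix (scans x points) or [spectra_set()].
#' @param order Polynomial order, `0 <= order < n_points`; default 1
#'   (linear), the common choice for NIR baseline tilt.
#' @return Matrix of the same shape.
#' @export
detrend <- function(X, order = 1) {
  X <- as_absorbance(X)
  p <- ncol(X)
  if (order < 0 || order != round(order)) stop("order must be a nonnegative integer")
  if (order >= p) stop("detrend order (", order, ") must be < n_points (", p, ")")
  B <- poly_basis(p, order)
  Q <- qr.Q(qr(B))
  X - (X %*% Q) %*% t(Q)
}

# orthonormal-ready polynomial basis incl. intercept, in centered index
poly_basis <- function(p, order) {
  idx <- seq_len(p) - (p + 1) / 2
  outer(idx, 0:order, `^`)
}

#' Standard normal variate (SNV)
#'
#' Centers and scales every scan to mean 0 and unit sample standard
#' deviation (divisor n-1), the reference-free scatter correction.
#'
#' @inheritParams detrend
#' @return Matrix of the same shape; each row has mean 0 and sd 1.
#' @export
snv <- function(X) {
  X <- as_absorbance(X)
  m <- rowMeans(X)
  s <- sqrt(rowSums((X - m)^2) / (ncol(X) - 1))
  bad <- which(s < .Machine$double.eps * 1e3)
  if (length(bad))
    stop("SNV undefined for constant scan(s): row ", paste(bad, collapse = ", "))
  (X - m) / s
}

#' Multiplicative scatter correction (MSC)
#'
#' Regresses every scan on a reference spectrum (`row ~ b + a * reference`,
#' ordinary least squares) and returns `(row - b) / a`, undoing additive
#' offset and multiplicative scatter. The "MSC-mean" variant uses the
#' column mean of the calibration set as reference, which is what
#' [fit_pipeline()] stores for a [step_msc()].
#'
#' @inheritParams detrend
#' @param reference Reference spectrum (length `n_points`); default the
#'   column mean of `X` itself.
#' @return Matrix of the same shape.
#' @export
msc <- function(X, reference = NULL) {
  X <- as_absorbance(X)
  cf <- msc_coefficients(X, reference)
  (X - cf$intercept) / cf$slope
}

#' MSC regression coefficients
#'
#' The per-scan slope and intercept of the least-squares regression of each
#' scan on the reference spectrum, as used by [msc()]. The slope estimates
#' each scan's multiplicative scatter factor.
#'
#' @inheritParams msc
#' @return List with numeric vectors `slope` and `intercept` (one per scan).
#' @export
msc_coefficients <- function(X, reference = NULL) {
  X <- as_absorbance(X)
  if (is.null(reference)) reference <- colMeans(X)
  if (length(reference) != ncol(X))
    stop("reference length ", length(reference), " != n_points ", ncol(X))
  rc <- reference - mean(reference)
  ss <- sum(rc^2)
  if (ss < .Machine$double.eps * 1e3)
    stop("MSC reference has zero variance")
  a <- as.vector(X %*% rc) / ss  # slope of row on reference
  b <- rowMeans(X) - a * mean(reference)
  bad <- which(abs(a) < 1e-12)
  if (length(bad))
    stop("MSC slope ~ 0 for scan(s): row ", paste(bad, collapse = ", "))
  list(slope = a, intercept = b)
}

#' Extended multiplicative scatter correction (EMSC)
#'
#' Least-squares fit of every scan as `a * reference + polynomial baseline`
#' (powers of the point index up to `order`); returns
#' `(row - baseline) / a`. Reduces to [msc()] at `order = 0`.
#'
#' @inheritParams msc
#' @param order Baseline polynomial order (default 2).
#' @return Matrix of the same shape.
#' @export
emsc <- function(X, reference = NULL, order = 2) {
  X <- as_absorbance(X)
  if (is.null(reference)) reference <- colMeans(X)
  if (length(reference) != ncol(X))
    stop("reference length ", length(reference), " != n_points ", ncol(X))
  if (stats::var(reference) < .Machine$double.eps * 1e3)
    stop("EMSC reference has zero variance")
  P <- poly_basis(ncol(X), order)
  D <- cbind(reference, P)
  qd <- qr(D)
  if (qd$rank < ncol(D))
    stop("EMSC design is collinear (reference lies in the polynomial span)")
  coefs <- t(qr.coef(qd, t(X)))           # n x (order + 2)
  a <- coefs[, 1]
  bad <- which(abs(a) < 1e-12)
  if (length(bad))
    stop("EMSC reference coefficient ~ 0 for scan(s): row ",
         paste(bad, collapse = ", "))
  baseline <- coefs[, -1, drop = FALSE] %*% t(P)
  (X - baseline) / a
}

#' Savitzky-Golay smoothing and derivatives
#'
#' Per scan, each point is replaced by the `deriv`-th derivative (with
#' respect to point index) of the local least-squares polynomial of order
#' `polyorder` over a centered window of `window` points. At the spectrum
#' ends, where the full window does not fit, the window shrinks to the
#' available points (no padding), so output length equals input length.
#' `deriv = 0` is a smoother that leaves polynomials of degree
#' `<= polyorder` unchanged on interior points.
#'
#' The derivative is taken in index units; on the uniform grid a derivative
#' per cm-1 is obtained by dividing by `(-spacing)^deriv` (the grid
#' descends), an optional rescaling left to the caller since classification
#' after mean centering is scale invariant.
#'
#' @inheritParams detrend
#' @param window Odd window width in points (default 15).
#' @param polyorder Local polynomial order (default 2); `< window`.
#' @param deriv Derivative order, 0, 1 or 2 (default 0); `<= polyorder`.
#' @return Matrix of the same shape.
#' @export
savgol <- function(X, window = 15, polyorder = 2, deriv = 0) {
  X <- as_absorbance(X)
  p <- ncol(X)
  if (window %% 2 != 1) stop("savgol window must be odd, got ", window)
  if (window <= polyorder)
    stop("savgol window (", window, ") must exceed polyorder (", polyorder, ")")
  if (window > p)
    stop("savgol window (", window, ") exceeds n_points (", p, ")")
  if (!deriv %in% 0:2) stop("deriv must be 0, 1 or 2")
  if (deriv > polyorder) stop("deriv (", deriv, ") must be <= polyorder")
  X %*% t(savgol_matrix(p, window, polyorder, deriv))
}

.savgol_cache <- new.env(parent = emptyenv())

# p x p linear operator applying the filter; row i gives output point i.
# Cached: the operator depends only on (p, window, polyorder, deriv).
savgol_matrix <- function(p, window, polyorder, deriv) {
  key <- paste(p, window, polyorder, deriv, sep = "_")
  hit <- .savgol_cache[[key]]
  if (!is.null(hit)) return(hit)
  M <- savgol_matrix_build(p, window, polyorder, deriv)
  .savgol_cache[[key]] <- M
  M
}

savgol_matrix_build <- function(p, window, polyorder, deriv) {
  h <- (window - 1L) / 2L
  w_at <- function(offsets) {
    A <- outer(offsets, 0:polyorder, `^`)
    # deriv-th derivative at offset 0 = factorial(deriv) * coef[deriv+1]
    factorial(deriv) * solve(crossprod(A), t(A))[deriv + 1L, ]
  }
  M <- matrix(0, p, p)
  interior <- w_at(seq(-h, h))
  for (i in seq_len(p)) {
    lo <- max(1L, i - h); hi <- min(p, i + h)
    if (hi - lo + 1L == window) {
      M[i, lo:hi] <- interior
    } else {
      # shrink-window fit at the edges
      off <- (lo:hi) - i
      if (length(off) <= polyorder) stop("window degenerates at the edge")
      M[i, lo:hi] <- w_at(off)
    }
  }
  M
}

#' Mean centering with calibration-fitted means
#'
#' `mean_center_fit()` computes column means on calibration data;
#' `mean_center_apply()` subtracts those means from any matrix on the same
#' grid. Validation and prediction data are always shifted by the
#' calibration means, never their own.
#'
#' @inheritParams detrend
#' @param X_cal Calibration absorbance matrix.
#' @param means Column-mean vector from `mean_center_fit()`.
#' @return `mean_center_fit()`: numeric vector of column means;
#'   `mean_center_apply()`: centered matrix.
#' @export
mean_center_fit <- function(X_cal) colMeans(as_absorbance(X_cal))

#' @rdname mean_center_fit
#' @export
mean_center_apply <- function(X, means) {
  X <- as_absorbance(X)
  if (length(means) != ncol(X))
    stop("means length ", length(means), " != n_points ", ncol(X))
  X - rep(means, each = nrow(X))
}
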