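#' Kennard-Stone calibration/validation split
#'
#' Deterministic max-min-distance sample selection: the first two selected
#' points are the pair at maximum Euclidean distance; every subsequent
#' selection maximizes its minimum distance to the already-selected set.
#' Selected scans form the calibration set, the remainder the validation
#' set. Ties (duplicate points) are broken by lowest index. The split is
#' conventionally run on the pre-processed spectra, i.e. the same
#' representation the classifier sees.
#'
#' @param X Feature matrix (scans x variables) or [spectra_set()].
#' @param fraction Calibration proportion in (0, 1); default 0.75. The
#'   calibration size is `round(fraction * n)`.
#' @return A `"ks_split"` object: list with `calibration` and `validation`
#'   index vectors (ascending) and `fraction`.
#' @export
kennard_stone <- function(X, fraction = 0.75) {
  X <- as_absorbance(X)
  n <- nrow(X)
  if (n < 2) stop("Kennard-Stone needs at least 2 samples")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  n_cal <- round(fraction * n)
  if (n_cal < 1 || n_cal >= n)
    stop("fraction ", fraction, " selects ", n_cal, " of ", n,
         " samples; both sets must be non-empty")
  D <- as.matrix(stats::dist(X))
  # seed pair: maximum distance, ties -> lexicographically lowest (i, j)
  mx <- max(D)
  cand <- which(D == mx, arr.ind = TRUE)
  cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  sel <- as.integer(cand[1, ])
  if (n_cal == 1L) sel <- sel[1]
  if (n_cal > 2L) {
    mind <- pmin(D[, sel[1]], D[, sel[2]])
    mind[sel] <- -Inf
    for (k in seq_len(n_cal - 2L)) {
      nxt <- which.max(mind)  # ties -> lowest index
      sel <- c(sel, nxt)
      mind <- pmin(mind, D[, nxt])
      mind[nxt] <- -Inf
    }
  }
  sel <- unname(sel)
  structure(list(calibration = sort(sel),
                 validation = setdiff(seq_len(n), sel),
                 fraction = fraction),
            class = "ks_split")
}

#' @export
print.ks_split <- function(x, ...) {
  cat(sprintf("<ks_split> %d calibration / %d validation (fraction %.2f)\n",
              length(x$calibration), length(x$validation), x$fraction))
  invisible(x)
}

#' Venetian-blinds cross-validation folds
#'
#' Assigns the scan at position `i` (0-based, in the dataset's recorded
#' ordering) to fold `floor(i / blind_width) %% n_splits`. With one sample
#' per blind every `n_splits`-th scan shares a fold; fold sizes differ by at
#' most `blind_width`.
#'
#' @param n Number of scans.
#' @param n_splits Number of folds (default 10).
#' @param blind_width Samples per blind (default 1).
#' @return A `"cv_folds"` object: list with `n_splits`, `blind_width` and
#'   `assignment` (fold label 1..n_splits per scan).
#' @export
venetian_blinds <- function(n, n_splits = 10, blind_width = 1) {
  if (n < n_splits)
    stop("n (", n, ") must be >= n_splits (", n_splits, ")")
  if (blind_width < 1) stop("blind_width must be >= 1")
  assignment <- (floor((seq_len(n) - 1L) / blind_width) %% n_splits) + 1L
  structure(list(n_splits = as.integer(n_splits),
                 blind_width = as.integer(blind_width),
                 assignment = as.integer(assignment)),
            class = "cv_folds")
}

#' @export
print.cv_folds <- function(x, ...) {
  cat(sprintf("<cv_folds> venetian blinds: %d splits, width %d, n = %d\n",
              x$n_splits, x$blind_width, length(x$assignment)))
  invisible(x)
}

#' Q-residual outlier screening
#'
#' Fits a principal-component model of rank `n_components` to the
#' (column-centered) matrix and computes each scan's Q residual, the
#' squared reconstruction error. Scans whose Q exceeds the confidence
#' threshold are flagged as outliers.
#'
#' Two threshold rules are available. `"chi2"` (default) moment-matches the
#' Q distribution with a scaled chi-square, `Q ~ g * chisq(h)` with
#' `g = var(Q) / (2 mean(Q))` and `h = 2 mean(Q)^2 / var(Q)`, and takes its
#' `confidence` quantile -- the standard approximation for squared PCA
#' residuals, robust to a few gross outliers inflating the tail.
#' `"percentile"` takes the empirical `confidence` quantile of the observed
#' Q values (by construction it flags about `(1 - confidence) * n` scans,
#' outliers present or not).
#'
#' @param X Matrix (scans x points) or [spectra_set()]; typically trimmed
#'   raw or scatter-corrected spectra.
#' @param n_components PCA rank of the in-control model (default 5);
#'   `1 <= n_components < min(n, p)`.
#' @param confidence Confidence level for the threshold (default 0.99).
#' @param threshold_method `"chi2"` or `"percentile"`.
#' @param scale Optional per-scan multiplier applied to the squared
#'   residuals before thresholding, used to express Q in a common metric
#'   when the pre-treatment rescaled each scan's noise (see
#'   [screen_outliers()]). Default 1.
#' @return An `"outlier_report"`: list with `q_residuals`, `threshold`,
#'   `flagged` (indices with `Q > threshold`), `n_components`, `confidence`
#'   and, when `X` is a [spectra_set()], the flagged scans' `metadata`.
#' @export
q_residual_outliers <- function(X, n_components = 5, confidence = 0.99,
                                threshold_method = c("chi2", "percentile"),
                                scale = NULL) {
  threshold_method <- match.arg(threshold_method)
  md <- if (inherits(X, "spectra_set")) X$metadata else NULL
  X <- as_absorbance(X)
  n <- nrow(X); p <- ncol(X)
  if (is.null(scale)) scale <- rep(1, n)
  if (length(scale) != n) stop("scale must have one value per scan")
  if (n_components < 1 || n_components >= min(n, p))
    stop("n_components must satisfy 1 <= n_components < min(n_scans, n_points)")
  Xc <- X - rep(colMeans(X), each = n)
  sv <- svd(Xc, nu = n_components, nv = n_components)
  r <- sum(sv$d > max(sv$d) * max(n, p) * .Machine$double.eps)
  if (n_components >= r)
    warning("n_components (", n_components, ") >= matrix rank (", r,
            "); all Q residuals are ~0")
  recon <- sv$u %*% (sv$d[seq_len(n_components)] * t(sv$v))
  q <- rowSums((Xc - recon)^2) * scale
  threshold <- if (threshold_method == "percentile") {
    unname(stats::quantile(q, confidence))
  } else {
    m <- mean(q); v <- stats::var(q)
    if (v <= 0 || m <= 0) max(q)  # degenerate: flag nothing
    else (v / (2 * m)) * stats::qchisq(confidence, df = 2 * m^2 / v)
  }
  flagged <- which(q > threshold)
  structure(list(q_residuals = q, threshold = threshold,
                 flagged = flagged, n_components = n_components,
                 confidence = confidence, threshold_method = threshold_method,
                 metadata = if (!is.null(md)) md[flagged, , drop = FALSE]),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf(
    "<outlier_report> %d of %d scans flagged (Q > %.4g, %s threshold at %.0f%%, %d PCs)\n",
    length(x$flagged), length(x$q_residuals), x$threshold,
    x$threshold_method, 100 * x$confidence, x$n_components))
  if (length(x$flagged)) {
    if (!is.null(x$metadata)) {
      info <- cbind(scan = x$flagged, x$metadata,
                    q_residual = signif(x$q_residuals[x$flagged], 4))
      print(info, row.names = FALSE)
    } else {
      cat("  scans:", paste(x$flagged, collapse = ", "), "\n")
    }
  }
  invisible(x)
}

#' Recommended outlier screening for raw seed spectra
#'
#' The screening procedure applied during pre-treatment of a raw (trimmed)
#' dataset: scatter-correct with MSC against the mean spectrum, detrend the
#' residual linear baseline, compute Q residuals against a
#' `n_components`-rank PCA model, and re-express each scan's Q in the raw
#' absorbance metric by multiplying with the squared MSC slope (MSC divides
#' every scan by its fitted scatter factor, so without this the residual
#' noise -- and hence Q -- of strongly scattering scans is inflated by a
#' known per-scan factor). Thresholding is the moment-matched chi-square
#' rule of [q_residual_outliers()].
#'
#' @param s A [spectra_set()] of raw (typically trimmed) spectra.
#' @param n_components PCA rank of the in-control model; default 6, the
#'   number of absorption-band amplitude directions the class structure
#'   spans.
#' @param confidence Threshold confidence level (default 0.99).
#' @return An `"outlier_report"` (with the flagged scans' metadata).
#' @seealso [q_residual_outliers()], [inject_outliers()]
#' @export
screen_outliers <- function(s, n_components = 6, confidence = 0.99) {
  stopifnot(inherits(s, "spectra_set"))
  slope <- msc_coefficients(s$absorbance)$slope
  Xp <- detrend(msc(s$absorbance), 1)
  rep <- q_residual_outliers(Xp, n_components = n_components,
                             confidence = confidence, scale = slope^2)
  rep$metadata <- s$metadata[rep$flagged, , drop = FALSE]
  rep
}
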