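#' Binary PLS-DA
#'
#' Partial least squares discriminant analysis for two (possibly pooled)
#' classes. Class membership is coded +1 (the `positive` class-1 set) and
#' -1 (everything else); the coded response is regressed on the spectra by
#' NIPALS PLS1 (X and y centered on the calibration data, X deflated per
#' component), and new scans are classified by comparing the predicted
#' response with a calibration-derived decision threshold.
#'
#' When an unfitted [preprocess_pipeline()] is supplied it is fitted on the
#' calibration spectra first and stored with the model, so `predict()` can
#' be given raw absorbance and will route it through the same fitted
#' pre-treatment.
#'
#' @param x Calibration spectra: matrix (scans x points) or
#'   [spectra_set()]. Pre-processed if `pipeline` is `NULL`, raw otherwise.
#' @param y Class labels (character or factor), at least two distinct.
#' @param n_lv Number of latent variables, `>= 1` and at most the rank of
#'   the (pre-processed, centered) calibration matrix.
#' @param pipeline Optional unfitted [preprocess_pipeline()].
#' @param positive Labels forming class 1 (coded +1). Default: the first
#'   level of `factor(y)`. All other observed labels are pooled as class 2.
#' @param threshold_method Decision threshold rule, see
#'   [decision_threshold()].
#' @return An object of class `"plsda"` with elements `n_lv`, `x_weights`,
#'   `x_loadings`, `y_loadings`, `coefficients`, `scores`, `x_center`,
#'   `y_center`, `threshold`, `class_map`, `labels` (class-1/class-2 display
#'   labels), `pipeline` and calibration predictions in `cal`.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(40 * 8), 40)
#' y <- rep(c("A", "B"), 20)
#' X[y == "A", 1] <- X[y == "A", 1] + 3
#' m <- plsda(X, y, n_lv = 2)
#' table(predict(m, X, type = "class"), y)
#' @export
plsda <- function(x, y, n_lv, pipeline = NULL, positive = NULL,
                  threshold_method = c("gaussian", "midpoint", "zero")) {
  threshold_method <- match.arg(threshold_method)
  y <- as.character(y)
  classes <- unique(y)
  if (length(classes) < 2)
    stop("y contains a single class ('", classes, "'); two are required")
  if (is.null(positive)) positive <- levels(factor(y))[1]
  if (!all(positive %in% classes))
    stop("positive label(s) not present in y: ",
         paste(setdiff(positive, classes), collapse = ", "))
  negative <- setdiff(classes, positive)
  if (!length(negative)) stop("all observed labels are in 'positive'")
  if (!is.null(pipeline)) {
    pipeline <- fit_pipeline(pipeline, x)
    X <- pipeline$cal_transformed
    pipeline$cal_transformed <- NULL
  } else X <- as_absorbance(x)
  if (nrow(X) != length(y)) stop("x and y lengths differ")

  ynum <- ifelse(y %in% positive, 1, -1)
  x_center <- colMeans(X)
  y_center <- mean(ynum)
  Xc <- X - rep(x_center, each = nrow(X))
  r <- qr(Xc)$rank
  if (n_lv < 1 || n_lv != round(n_lv)) stop("n_lv must be a positive integer")
  if (n_lv > r)
    stop("n_lv (", n_lv, ") exceeds the rank of the calibration matrix (",
         r, ")")
  dec <- nipals_pls1(Xc, ynum - y_center, n_lv)

  coefficients <- pls_coefficients(dec, n_lv)
  cal_response <- as.vector(y_center + Xc %*% coefficients)
  lab1 <- paste(positive, collapse = "+")
  lab2 <- paste(negative, collapse = "+")
  is1 <- y %in% positive
  threshold <- decision_threshold(cal_response, is1, method = threshold_method)
  m1 <- mean(cal_response[is1]); m2 <- mean(cal_response[!is1])

  model <- structure(list(
    n_lv = as.integer(n_lv),
    x_weights = dec$W, x_loadings = dec$P, y_loadings = dec$q,
    coefficients = coefficients, scores = dec$T,
    x_center = x_center, y_center = y_center,
    threshold = threshold, threshold_method = threshold_method,
    class1_high = m1 >= m2,
    class_map = list(class1 = positive, class2 = negative),
    labels = c(class1 = lab1, class2 = lab2),
    pipeline = pipeline,
    cal = list(response = cal_response, truth = ifelse(is1, lab1, lab2))),
    class = "plsda")
  model
}

# NIPALS PLS1 on centered Xc, yc. Returns weights W, x-loadings P,
# y-loadings q and scores T for `a` components.
nipals_pls1 <- function(Xc, yc, a) {
  n <- nrow(Xc); p <- ncol(Xc)
  W <- matrix(0, p, a); P <- matrix(0, p, a); Tm <- matrix(0, n, a)
  q <- numeric(a)
  Xd <- Xc; yd <- yc
  for (k in seq_len(a)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      a <- k - 1L
      break
    }
    w <- w / nw
    t_k <- as.vector(Xd %*% w)
    tt <- sum(t_k^2)
    p_k <- crossprod(Xd, t_k) / tt
    q_k <- sum(yd * t_k) / tt
    Xd <- Xd - tcrossprod(t_k, p_k)
    yd <- yd - q_k * t_k
    W[, k] <- w; P[, k] <- p_k; Tm[, k] <- t_k; q[k] <- q_k
  }
  list(W = W[, seq_len(a), drop = FALSE], P = P[, seq_len(a), drop = FALSE],
       T = Tm[, seq_len(a), drop = FALSE], q = q[seq_len(a)], n_lv = a)
}

# regression coefficients using the first `a` latent variables
pls_coefficients <- function(dec, a) {
  W <- dec$W[, seq_len(a), drop = FALSE]
  P <- dec$P[, seq_len(a), drop = FALSE]
  q <- dec$q[seq_len(a)]
  as.vector(W %*% solve(crossprod(P, W), q))
}

#' Calibration-derived decision threshold
#'
#' Places the classification cut on the predicted-response axis from the
#' calibration predictions. The default `"gaussian"` rule fits one normal
#' density per class and takes the crossing point of the two densities that
#' lies between the class means (for equal spreads this is the midpoint of
#' the means); when no crossing lies between the means, or a class has
#' fewer than two predictions or zero spread, it falls back to the midpoint
#' of the class means (with a warning in the degenerate cases).
#' `"midpoint"` always uses the midpoint of the class means; `"zero"` uses
#' the fixed midpoint 0 of the +/-1 class codes.
#'
#' @param predictions Numeric calibration predicted responses.
#' @param is_class1 Logical, `TRUE` for class-1 scans.
#' @param method `"gaussian"`, `"midpoint"` or `"zero"`.
#' @return The threshold value.
#' @export
decision_threshold <- function(predictions, is_class1,
                               method = c("gaussian", "midpoint", "zero")) {
  method <- match.arg(method)
  if (method == "zero") return(0)
  p1 <- predictions[is_class1]; p2 <- predictions[!is_class1]
  m1 <- mean(p1); m2 <- mean(p2)
  mid <- (m1 + m2) / 2
  if (method == "midpoint") return(mid)
  if (length(p1) < 2 || length(p2) < 2) {
    warning("a class has < 2 calibration predictions; using midpoint threshold")
    return(mid)
  }
  s1 <- stats::sd(p1); s2 <- stats::sd(p2)
  if (s1 < 1e-12 || s2 < 1e-12) {
    warning("a class has ~zero spread; using midpoint threshold")
    return(mid)
  }
  if (abs(s1 - s2) < 1e-9 * max(s1, s2)) return(mid)
  # equal-density points of the two normals: quadratic in x
  A <- 1 / s1^2 - 1 / s2^2
  B <- -2 * (m1 / s1^2 - m2 / s2^2)
  C <- m1^2 / s1^2 - m2^2 / s2^2 + 2 * log(s1 / s2)
  disc <- B^2 - 4 * A * C
  if (disc < 0) return(mid)
  roots <- (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
  lo <- min(m1, m2); hi <- max(m1, m2)
  inside <- roots[roots > lo & roots < hi]
  if (length(inside)) inside[1] else mid
}

#' Predict from a binary PLS-DA model
#'
#' @param object A [plsda()] model.
#' @param newdata Matrix or [spectra_set()]. Raw absorbance when the model
#'   holds a pipeline (it is applied first), otherwise data already in the
#'   model's pre-processed space.
#' @param type `"response"` for the continuous predicted response,
#'   `"class"` for class labels. A response exactly at the threshold is
#'   assigned to class 1.
#' @param ... Ignored.
#' @return Numeric vector (`"response"`) or factor with the model's two
#'   display labels (`"class"`).
#' @export
predict.plsda <- function(object, newdata,
                          type = c("response", "class"), ...) {
  type <- match.arg(type)
  X <- if (!is.null(object$pipeline)) predict(object$pipeline, newdata)
       else as_absorbance(newdata)
  if (ncol(X) != length(object$x_center))
    stop("newdata has ", ncol(X), " variables; model expects ",
         length(object$x_center))
  resp <- as.vector(object$y_center +
                      (X - rep(object$x_center, each = nrow(X))) %*%
                      object$coefficients)
  if (type == "response") return(resp)
  side1 <- if (object$class1_high) resp >= object$threshold
           else resp <= object$threshold
  factor(ifelse(side1, object$labels["class1"], object$labels["class2"]),
         levels = unname(object$labels))
}

#' @export
fitted.plsda <- function(object, ...) object$cal$response

#' @export
residuals.plsda <- function(object, ...) {
  coded <- ifelse(object$cal$truth == object$labels["class1"], 1, -1)
  coded - object$cal$response
}

#' @export
coef.plsda <- function(object, ...) {
  stats::setNames(object$coefficients,
                  names(object$x_center) %||% NULL)
}

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf("<plsda> %s vs %s, %d LV(s), threshold %.4g (%s)\n",
              x$labels["class1"], x$labels["class2"], x$n_lv,
              x$threshold, x$threshold_method))
  if (!is.null(x$pipeline)) {
    cat("  pipeline: "); print(x$pipeline)
  }
  invisible(x)
}

#' @export
summary.plsda <- function(object, ...) {
  print(object)
  cls <- ifelse(if (object$class1_high) object$cal$response >= object$threshold
                else object$cal$response <= object$threshold,
                object$labels["class1"], object$labels["class2"])
  rep <- evaluate(object$cal$truth, cls,
                  positive = object$labels["class1"], context = "calibration")
  print(rep)
  invisible(object)
}

#' @export
plot.plsda <- function(x, ...) {
  truth1 <- x$cal$truth == x$labels["class1"]
  col <- ifelse(truth1, "#D7263D", "#1B998B")
  if (x$n_lv >= 2) {
    graphics::plot(x$scores[, 1], x$scores[, 2], col = col, pch = 19,
                   xlab = "LV 1 score", ylab = "LV 2 score", ...)
  } else {
    graphics::plot(seq_along(x$cal$response), x$cal$response, col = col,
                   pch = 19, xlab = "Calibration scan",
                   ylab = "Predicted response", ...)
    graphics::abline(h = x$threshold, lty = 2)
  }
  graphics::legend("topright", legend = unname(x$labels),
                   col = c("#D7263D", "#1B998B"), pch = 19, bty = "n")
  invisible(x)
}
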