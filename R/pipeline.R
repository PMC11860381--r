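#' Pre-processing pipeline steps
#'
#' Constructors for the six step kinds accepted by
#' [preprocess_pipeline()]. Stateless steps (detrend, SNV, Savitzky-Golay)
#' apply the same map to any data; state-bearing steps (MSC/EMSC reference,
#' mean-center means) acquire their state from the calibration data during
#' [fit_pipeline()] and apply it unchanged to validation or prediction data.
#'
#' @param order Polynomial order ([step_detrend()]: baseline order, default
#'   1; [step_emsc()]: baseline order, default 2).
#' @param window,polyorder,deriv See [savgol()].
#' @return A `"pp_step"` object.
#' @name pp_steps
NULL

pp_step <- function(kind, params = list()) {
  structure(list(kind = kind, params = params, state = NULL),
            class = "pp_step")
}

#' @rdname pp_steps
#' @export
step_detrend <- function(order = 1) pp_step("detrend", list(order = order))

#' @rdname pp_steps
#' @export
step_snv <- function() pp_step("snv")

#' @rdname pp_steps
#' @export
step_msc <- function() pp_step("msc")

#' @rdname pp_steps
#' @export
step_emsc <- function(order = 2) pp_step("emsc", list(order = order))

#' @rdname pp_steps
#' @export
step_savgol <- function(window = 15, polyorder = 2, deriv = 1)
  pp_step("savgol", list(window = window, polyorder = polyorder, deriv = deriv))

#' @rdname pp_steps
#' @export
step_mean_center <- function() pp_step("mean_center")

fit_step <- function(step, X) {
  step$state <- switch(step$kind,
    msc = list(reference = colMeans(X)),
    emsc = list(reference = colMeans(X)),
    mean_center = list(means = colMeans(X)),
    list())
  step
}

apply_step <- function(step, X) {
  switch(step$kind,
    detrend = detrend(X, step$params$order),
    snv = snv(X),
    msc = msc(X, step$state$reference),
    emsc = emsc(X, step$state$reference, step$params$order),
    savgol = savgol(X, step$params$window, step$params$polyorder,
                    step$params$deriv),
    mean_center = mean_center_apply(X, step$state$means),
    stop("unknown step kind: ", step$kind))
}

#' Composable pre-processing pipeline
#'
#' An ordered chain of [pp_steps]. Fit it on calibration data with
#' [fit_pipeline()] (state-bearing steps record their reference/means from
#' the calibration data only, each on the output of the preceding steps),
#' then apply it to any data with `predict()`. An empty pipeline is the
#' identity.
#'
#' @param ... `pp_step` objects, applied in the order given.
#' @return A `"preprocess_pipeline"` object (unfitted).
#' @examples
#' p <- preprocess_pipeline(step_detrend(1), step_snv(),
#'                          step_savgol(15, 2, 1), step_mean_center())
#' @seealso [cultivar_chain()], [endophyte_chain()]
#' @export
preprocess_pipeline <- function(...) {
  steps <- list(...)
  if (length(steps) == 1L && is.list(steps[[1]]) &&
      !inherits(steps[[1]], "pp_step"))
    steps <- steps[[1]]
  ok <- vapply(steps, inherits, logical(1), "pp_step")
  if (!all(ok)) stop("all pipeline components must be pp_step objects")
  structure(list(steps = steps, fitted = FALSE),
            class = "preprocess_pipeline")
}

#' Fit a pipeline on calibration data
#'
#' @param pipeline A [preprocess_pipeline()].
#' @param X_cal Calibration absorbance matrix or [spectra_set()].
#' @return The fitted pipeline; the transformed calibration matrix is
#'   attached as element `cal_transformed`.
#' @export
fit_pipeline <- function(pipeline, X_cal) {
  stopifnot(inherits(pipeline, "preprocess_pipeline"))
  X <- as_absorbance(X_cal)
  for (i in seq_along(pipeline$steps)) {
    pipeline$steps[[i]] <- fit_step(pipeline$steps[[i]], X)
    X <- apply_step(pipeline$steps[[i]], X)
  }
  pipeline$fitted <- TRUE
  pipeline$cal_transformed <- X
  pipeline
}

#' Apply a fitted pipeline to new data
#'
#' @param object A fitted [preprocess_pipeline()].
#' @param newdata Absorbance matrix or [spectra_set()] on the same grid.
#' @param ... Ignored.
#' @return Transformed matrix.
#' @export
predict.preprocess_pipeline <- function(object, newdata, ...) {
  if (!isTRUE(object$fitted))
    stop("pipeline must be fitted (see fit_pipeline()) before applying to new data")
  X <- as_absorbance(newdata)
  for (step in object$steps) X <- apply_step(step, X)
  X
}

#' @export
print.preprocess_pipeline <- function(x, ...) {
  desc <- vapply(x$steps, function(s) {
    ps <- if (length(s$params))
      paste0("(", paste(unlist(s$params), collapse = ","), ")") else ""
    paste0(s$kind, ps)
  }, character(1))
  cat("<preprocess_pipeline> ",
      if (length(desc)) paste(desc, collapse = " -> ") else "(identity)",
      if (isTRUE(x$fitted)) "  [fitted]" else "  [unfitted]", "\n", sep = "")
  invisible(x)
}

#' Optimized pre-treatment chains
#'
#' The two chains selected for the seed classification tasks:
#' `cultivar_chain()` = Detrend, MSC (mean reference), Savitzky-Golay
#' second derivative (window 15, order 2), mean centering;
#' `endophyte_chain()` = Detrend, SNV, Savitzky-Golay first derivative
#' (window 15, order 2), mean centering.
#'
#' @return An unfitted [preprocess_pipeline()].
#' @export
cultivar_chain <- function()
  preprocess_pipeline(step_detrend(1), step_msc(),
                      step_savgol(15, 2, 2), step_mean_center())

#' @rdname cultivar_chain
#' @export
endophyte_chain <- function()
  preprocess_pipeline(step_detrend(1), step_snv(),
                      step_savgol(15, 2, 1), step_mean_center())
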