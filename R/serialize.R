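MODEL_JSON_VERSION <- "1.0"

#' Serialize a PLS-DA model to JSON and back
#'
#' Writes a versioned JSON document holding everything `predict()` needs:
#' the latent-variable decomposition (weights, loadings, coefficients),
#' centers, decision threshold, class map, and the fitted pre-processing
#' pipeline (step kinds, parameters and fitted state). The round trip
#' reproduces predictions exactly.
#'
#' @param model A fitted [plsda()] model.
#' @param path Output/input file path.
#' @return `write_model_json()` returns `path` invisibly;
#'   `read_model_json()` returns the restored `"plsda"` object.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "plsda"))
  pipe <- NULL
  if (!is.null(model$pipeline)) {
    pipe <- list(
      fitted = model$pipeline$fitted,
      steps = lapply(model$pipeline$steps, function(s)
        list(kind = s$kind, params = s$params, state = s$state)))
  }
  doc <- list(
    format = "plsda-model", version = MODEL_JSON_VERSION,
    n_lv = model$n_lv,
    x_weights = model$x_weights, x_loadings = model$x_loadings,
    y_loadings = model$y_loadings,
    coefficients = model$coefficients,
    x_center = unname(model$x_center), y_center = model$y_center,
    threshold = model$threshold, threshold_method = model$threshold_method,
    class1_high = model$class1_high,
    class_map = model$class_map, labels = as.list(model$labels),
    pipeline = pipe)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "plsda-model"))
    stop("'", path, "' is not a plsda-model JSON document")
  num <- function(x) as.numeric(unlist(x))
  mat <- function(x) {  # list of rows -> matrix
    do.call(rbind, lapply(x, num))
  }
  pipe <- NULL
  if (!is.null(doc$pipeline) && length(doc$pipeline)) {
    steps <- lapply(doc$pipeline$steps, function(s) {
      st <- pp_step(s$kind, lapply(s$params, function(v) unlist(v)))
      st$state <- if (is.null(s$state) || !length(s$state)) list()
                  else lapply(s$state, num)
      st
    })
    pipe <- preprocess_pipeline(steps)
    pipe$fitted <- isTRUE(doc$pipeline$fitted)
  }
  structure(list(
    n_lv = as.integer(doc$n_lv),
    x_weights = mat(doc$x_weights),
    x_loadings = mat(doc$x_loadings),
    y_loadings = num(doc$y_loadings),
    coefficients = num(doc$coefficients),
    scores = NULL,
    x_center = num(doc$x_center),
    y_center = num(doc$y_center),
    threshold = num(doc$threshold),
    threshold_method = doc$threshold_method,
    class1_high = isTRUE(doc$class1_high),
    class_map = lapply(doc$class_map, function(v) as.character(unlist(v))),
    labels = vapply(doc$labels, as.character, character(1)),
    pipeline = pipe,
    cal = NULL), class = "plsda")
}
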