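#' Venetian-blinds cross-validation of a PLS-DA model
#'
#' For every fold, the pre-processing pipeline state and the PLS-DA model
#' are refitted on the retained scans only (no state leaks from the held-out
#' blind), the held-out scans are predicted, and all held-out predictions
#' are pooled into a single cross-validation report.
#'
#' @param x Raw spectra: matrix or [spectra_set()].
#' @param y Class labels.
#' @param folds A [venetian_blinds()] assignment for `nrow(x)` scans.
#' @param pipeline Unfitted [preprocess_pipeline()] (or `NULL` if `x` is
#'   already in model space).
#' @param n_lv Latent variables per refit.
#' @param positive Class-1 label set, as in [plsda()].
#' @param threshold_method See [decision_threshold()].
#' @return A `"plsda_cv"` object: list with `report`
#'   (a [evaluate()] report, context `"cross-validation"`), `response` and
#'   `predicted` (per-scan held-out predictions, original order).
#' @export
cross_validate <- function(x, y, folds, pipeline = NULL, n_lv,
                           positive = NULL,
                           threshold_method = "gaussian") {
  X <- as_absorbance(x)
  y <- as.character(y)
  stopifnot(inherits(folds, "cv_folds"),
            length(folds$assignment) == nrow(X))
  if (is.null(positive)) positive <- levels(factor(y))[1]
  response <- numeric(nrow(X))
  predicted <- character(nrow(X))
  lab1 <- lab2 <- NULL
  for (f in sort(unique(folds$assignment))) {
    test <- folds$assignment == f
    if (length(unique(y[!test])) < 2) {
      warning("fold ", f, ": training scans are single-class; fold skipped")
      response[test] <- NA_real_
      predicted[test] <- NA_character_
      next
    }
    m <- plsda(X[!test, , drop = FALSE], y[!test], n_lv,
               pipeline = pipeline, positive = positive,
               threshold_method = threshold_method)
    response[test] <- predict(m, X[test, , drop = FALSE], type = "response")
    predicted[test] <- as.character(
      predict(m, X[test, , drop = FALSE], type = "class"))
    lab1 <- m$labels["class1"]; lab2 <- m$labels["class2"]
  }
  truth <- ifelse(y %in% positive, lab1, lab2)
  ok <- !is.na(predicted)
  structure(list(report = evaluate(truth[ok], predicted[ok],
                                   positive = lab1,
                                   context = "cross-validation"),
                 response = response, predicted = predicted),
            class = "plsda_cv")
}

#' @export
print.plsda_cv <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' Choose the number of latent variables by cross-validation
#'
#' Runs venetian-blinds cross-validation for every latent-variable count
#' from 1 to `max_lv` (one NIPALS decomposition per fold serves all counts)
#' and returns the count minimizing the pooled cross-validation class
#' error; ties go to the smaller count (parsimony). Counts beyond the rank
#' attained in a fold reuse that fold's largest attainable model.
#'
#' @inheritParams cross_validate
#' @param max_lv Largest count to consider.
#' @return An `"lv_selection"`: list with `n_lv` (chosen),
#'   `cv_class_error` (per count), and `predicted` (list of pooled held-out
#'   label vectors per count).
#' @export
select_lv <- function(x, y, folds, pipeline = NULL, max_lv,
                      positive = NULL, threshold_method = "gaussian") {
  X <- as_absorbance(x)
  y <- as.character(y)
  stopifnot(inherits(folds, "cv_folds"),
            length(folds$assignment) == nrow(X))
  if (is.null(positive)) positive <- levels(factor(y))[1]
  negative <- setdiff(unique(y), positive)
  lab1 <- paste(positive, collapse = "+")
  lab2 <- paste(negative, collapse = "+")
  is1 <- y %in% positive
  ynum <- ifelse(is1, 1, -1)
  n <- nrow(X)
  pred <- matrix(NA_character_, n, max_lv)
  for (f in sort(unique(folds$assignment))) {
    test <- folds$assignment == f
    if (length(unique(y[!test])) < 2) next  # single-class fold: skip
    Xtr_raw <- X[!test, , drop = FALSE]
    if (!is.null(pipeline)) {
      fitted_pipe <- fit_pipeline(pipeline, Xtr_raw)
      Xtr <- fitted_pipe$cal_transformed
      Xte <- predict(fitted_pipe, X[test, , drop = FALSE])
    } else {
      Xtr <- Xtr_raw
      Xte <- X[test, , drop = FALSE]
    }
    xc <- colMeans(Xtr); yc <- mean(ynum[!test])
    Xtr_c <- Xtr - rep(xc, each = nrow(Xtr))
    Xte_c <- Xte - rep(xc, each = nrow(Xte))
    a_max <- min(max_lv, qr(Xtr_c)$rank)
    dec <- nipals_pls1(Xtr_c, ynum[!test] - yc, a_max)
    for (a in seq_len(max_lv)) {
      aa <- min(a, dec$n_lv)
      B <- pls_coefficients(dec, aa)
      cal_resp <- yc + as.vector(Xtr_c %*% B)
      thr <- decision_threshold(cal_resp, is1[!test],
                                method = threshold_method)
      hi <- mean(cal_resp[is1[!test]]) >= mean(cal_resp[!is1[!test]])
      te_resp <- yc + as.vector(Xte_c %*% B)
      side1 <- if (hi) te_resp >= thr else te_resp <= thr
      pred[test, a] <- ifelse(side1, lab1, lab2)
    }
  }
  truth <- ifelse(is1, lab1, lab2)
  errs <- vapply(seq_len(max_lv), function(a) {
    ok <- !is.na(pred[, a])
    evaluate(truth[ok], pred[ok, a], positive = lab1,
             context = "cross-validation")$class_error
  }, numeric(1))
  structure(list(n_lv = which.min(errs),  # ties -> smallest count
                 cv_class_error = errs,
                 predicted = lapply(seq_len(max_lv), function(a) pred[, a]),
                 labels = c(class1 = lab1, class2 = lab2)),
            class = "lv_selection")
}

#' @export
print.lv_selection <- function(x, ...) {
  cat(sprintf("<lv_selection> chosen n_lv = %d (CV class error %.1f%%)\n",
              x$n_lv, 100 * x$cv_class_error[x$n_lv]))
  invisible(x)
}

#' Nested class-elimination PLS-DA sequence
#'
#' Breaks a multiclass problem into ordered binary steps: step k models
#' `order[k]` against the pooled remaining classes, then removes that
#' class's scans from the working set; the final step is a plain two-class
#' model between the last two classes. Each step selects its own
#' latent-variable count by venetian-blinds cross-validation and stores a
#' cross-validation report. The default order for the four ryegrass
#' cultivars is Maxsyn, Alto, Bronsyn, Trojan (easiest class first);
#' `order = "auto"` picks greedily, at each step modelling the class whose
#' one-vs-rest cross-validation class error is lowest.
#'
#' @inheritParams cross_validate
#' @param order Character permutation of the observed classes, or
#'   `"auto"`, or `NULL` (the cultivar default when the observed classes
#'   are exactly the four cultivars, otherwise `"auto"`).
#' @param n_splits,blind_width Venetian-blinds parameters regenerated per
#'   step for the step's working set.
#' @param max_lv Largest latent-variable count considered per step.
#' @return A `"nested_plsda"`: list with `steps` (each holding `target`,
#'   `pool`, `model`, `n_lv`, `cv_report`) and `elimination_order`.
#' @export
fit_nested <- function(x, y, order = NULL, pipeline = NULL,
                       n_splits = 10, blind_width = 1, max_lv = 10,
                       threshold_method = "gaussian") {
  X <- as_absorbance(x)
  y <- as.character(y)
  classes <- unique(y)
  auto <- identical(order, "auto")
  if (is.null(order)) {
    if (setequal(classes, CULTIVARS))
      order <- c("Maxsyn", "Alto", "Bronsyn", "Trojan")
    else auto <- TRUE
  }
  if (!auto) {
    if (!setequal(order, classes) || length(order) != length(classes))
      stop("order must be a permutation of the observed classes: ",
           paste(sort(classes), collapse = ", "))
  }
  step_for <- function(target, keep) {
    idx <- which(keep)
    folds <- venetian_blinds(length(idx), min(n_splits, length(idx)),
                             blind_width)
    sel <- select_lv(X[idx, , drop = FALSE], y[idx], folds, pipeline,
                     max_lv = max_lv, positive = target,
                     threshold_method = threshold_method)
    list(idx = idx, sel = sel)
  }
  steps <- list()
  remaining <- classes
  keep <- rep(TRUE, length(y))
  elimination <- character(0)
  while (length(remaining) > 1) {
    k <- length(steps) + 1L
    if (auto) {
      cand <- sort(remaining)
      trials <- lapply(cand, step_for, keep = keep)
      errs <- vapply(trials, function(tr)
        tr$sel$cv_class_error[tr$sel$n_lv], numeric(1))
      best <- which.min(errs)
      target <- cand[best]; trial <- trials[[best]]
    } else {
      target <- order[k]
      trial <- step_for(target, keep)
    }
    idx <- trial$idx; sel <- trial$sel
    pool <- setdiff(remaining, target)
    model <- plsda(X[idx, , drop = FALSE], y[idx], n_lv = sel$n_lv,
                   pipeline = pipeline, positive = target,
                   threshold_method = threshold_method)
    truth <- ifelse(y[idx] == target, sel$labels["class1"],
                    sel$labels["class2"])
    cv_pred <- sel$predicted[[sel$n_lv]]
    ok <- !is.na(cv_pred)
    cv_report <- evaluate(truth[ok], cv_pred[ok],
                          positive = sel$labels["class1"],
                          context = "cross-validation")
    steps[[k]] <- list(target = target, pool = pool, model = model,
                       n_lv = sel$n_lv, cv_report = cv_report,
                       cv_class_error = sel$cv_class_error)
    elimination <- c(elimination, target)
    if (length(pool) == 1) {
      elimination <- c(elimination, pool)
      remaining <- pool
    } else {
      keep <- keep & y != target
      remaining <- pool
    }
  }
  structure(list(steps = steps, elimination_order = elimination),
            class = "nested_plsda")
}

#' @export
print.nested_plsda <- function(x, ...) {
  cat("<nested_plsda> elimination order:",
      paste(x$elimination_order, collapse = " -> "), "\n")
  for (k in seq_along(x$steps)) {
    s <- x$steps[[k]]
    cat(sprintf("  step %d: %s vs %s | %d LVs, CV class error %.1f%%\n",
                k, s$target, paste(s$pool, collapse = "+"), s$n_lv,
                100 * s$cv_report$class_error))
  }
  invisible(x)
}
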