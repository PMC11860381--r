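#' Run the full seed-classification pipeline on a benchmark suite
#'
#' The complete workflow on one dataset: trim to the modelling window
#' (9000--3952 cm-1), Kennard-Stone 75/25 calibration/validation split on
#' the pre-processed representation, nested cultivar PLS-DA
#' (Maxsyn, Alto, Bronsyn, Trojan elimination order) with per-step
#' latent-variable selection by venetian-blinds cross-validation,
#' per-cultivar endophyte models, assembly of the cultivar tree, the four
#' endophyte trees and the combined tree, and their evaluation.
#'
#' Reported quantities: `scan_accuracy`, the fraction of held-out
#' validation scans the cultivar tree labels correctly; `bag_accuracy`,
#' the fraction of bags whose 4-of-6 majority vote over all six sub-sample
#' scans matches the bag's cultivar; `combined_agreement`, the fraction of
#' non-Unclassified validation scans for which the combined tree's label
#' equals sequential cultivar-then-endophyte classification;
#' `endophyte_scan_accuracy`, the fraction of validation scans the
#' combined tree labels with the correct (cultivar, status) pair.
#'
#' @param suite A [benchmark_suite()] (or any list with `spectra`).
#' @param trim_high,trim_low Modelling window (cm-1).
#' @param fraction Kennard-Stone calibration fraction.
#' @param n_splits Venetian-blinds folds.
#' @param max_lv Largest latent-variable count per model.
#' @param vote_threshold Bag-vote threshold (of 6 scans).
#' @return A `"benchmark_result"` list; see Details.
#' @export
run_benchmark <- function(suite, trim_high = 9000, trim_low = 3952,
                          fraction = 0.75, n_splits = 10, max_lv = 8,
                          vote_threshold = 4) {
  s <- trim_spectra(suite$spectra, trim_high, trim_low)
  md <- s$metadata

  # split on the representation the cultivar models see
  repr <- fit_pipeline(cultivar_chain(), s$absorbance)$cal_transformed
  split <- kennard_stone(repr, fraction)
  cal <- s[split$calibration]
  val <- s[split$validation]

  nested <- fit_nested(cal$absorbance, cal$metadata$cultivar,
                       pipeline = cultivar_chain(),
                       n_splits = n_splits, max_lv = max_lv)
  ctree <- build_cultivar_tree(nested)

  val_pred <- classify_tree(ctree, val)
  scan_accuracy <- mean(val_pred == val$metadata$cultivar)

  # bag-level: vote over all six sub-sample scans of every bag
  all_pred <- classify_tree(ctree, s)
  bags <- aggregate_bags(all_pred, md$bag_id,
                         vote_threshold = vote_threshold)
  bag_truth <- md$cultivar[match(bags$bag_id, md$bag_id)]
  bag_accuracy <- mean(bags$majority_label == bag_truth)

  # per-cultivar endophyte models on the calibration scans
  etrees <- list()
  emodels <- list()
  for (cv in CULTIVARS) {
    idx <- which(cal$metadata$cultivar == cv)
    ycv <- cal$metadata$endophyte_status[idx]
    if (length(unique(ycv)) < 2) next
    folds <- venetian_blinds(length(idx), min(n_splits, length(idx)))
    sel <- select_lv(cal$absorbance[idx, , drop = FALSE], ycv, folds,
                     pipeline = endophyte_chain(), max_lv = max_lv,
                     positive = "E+")
    m <- plsda(cal$absorbance[idx, , drop = FALSE], ycv, n_lv = sel$n_lv,
               pipeline = endophyte_chain(), positive = "E+")
    emodels[[cv]] <- m
    etrees[[cv]] <- build_endophyte_tree(m, cv)
  }
  combined <- combine_trees(ctree, etrees)

  comb_pred <- classify_tree(combined, val)
  seq_pred <- sequential_labels(val_pred, etrees, val)
  usable <- comb_pred != "Unclassified" & seq_pred != "Unclassified"
  combined_agreement <- mean(comb_pred[usable] == seq_pred[usable])
  truth_pair <- paste(val$metadata$cultivar, val$metadata$endophyte_status)
  endophyte_scan_accuracy <- mean(comb_pred == truth_pair)

  structure(list(split = split, nested = nested,
                 cultivar_tree = ctree, endophyte_models = emodels,
                 combined_tree = combined,
                 validation_pred = val_pred,
                 scan_accuracy = scan_accuracy,
                 bag_accuracy = bag_accuracy,
                 bag_votes = bags,
                 combined_agreement = combined_agreement,
                 endophyte_scan_accuracy = endophyte_scan_accuracy,
                 report = hit_miss_report(val_pred, val$metadata$cultivar)),
            class = "benchmark_result")
}

# cultivar-tree label, then the matching endophyte tree: the two-stage
# application the combined tree must reproduce
sequential_labels <- function(cultivar_pred, etrees, scans) {
  out <- rep("Unclassified", length(cultivar_pred))
  for (cv in names(etrees)) {
    idx <- which(cultivar_pred == cv)
    if (length(idx))
      out[idx] <- classify_tree(etrees[[cv]], scans[idx])
  }
  out
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("<benchmark_result>\n")
  cat(sprintf("  validation scan-level cultivar accuracy: %.3f\n",
              x$scan_accuracy))
  cat(sprintf("  bag-level vote accuracy (4 of 6):        %.3f\n",
              x$bag_accuracy))
  cat(sprintf("  combined-tree vs sequential agreement:   %.3f\n",
              x$combined_agreement))
  cat(sprintf("  validation (cultivar, status) accuracy:  %.3f\n",
              x$endophyte_scan_accuracy))
  print(x$nested)
  invisible(x)
}
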