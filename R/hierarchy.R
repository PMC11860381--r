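#' Hierarchical decision trees of binary PLS-DA models
#'
#' A hierarchy node routes scans through its binary [plsda()] model: scans
#' assigned to class 1 go to `branch_class1`, the rest to `branch_class2`;
#' each branch is either a terminal label or a child node. Scans that
#' cannot be processed by a node (a pre-processing rejection such as a
#' constant spectrum, or a non-finite prediction) take the "otherwise"
#' branch and receive the label `"Unclassified"` rather than raising an
#' error. Each node applies its own stored, calibration-fitted
#' pre-processing pipeline.
#'
#' @param model A fitted [plsda()] model.
#' @param branch_class1,branch_class2 Terminal label (character) or child
#'   `hierarchy_node`.
#' @return A `"hierarchy_node"`.
#' @export
hierarchy_node <- function(model, branch_class1, branch_class2) {
  stopifnot(inherits(model, "plsda"))
  ok <- function(b) is.character(b) && length(b) == 1 ||
    inherits(b, "hierarchy_node")
  if (!ok(branch_class1) || !ok(branch_class2))
    stop("branches must be terminal labels or hierarchy_node objects")
  structure(list(model = model, branch_class1 = branch_class1,
                 branch_class2 = branch_class2,
                 otherwise_label = "Unclassified"),
            class = "hierarchy_node")
}

#' Build the cultivar decision tree from a nested sequence
#'
#' Chains the steps of a [fit_nested()] sequence into a decision tree:
#' rule 1 is the step-1 model (first target vs the pooled rest), its
#' class-2 branch leads to rule 2, and so on; the last rule's class-2
#' branch is the final remaining class. A K-class sequence yields a tree of
#' depth K-1 with K terminal labels.
#'
#' @param nested A [fit_nested()] result.
#' @return The root `"hierarchy_node"`.
#' @export
build_cultivar_tree <- function(nested) {
  stopifnot(inherits(nested, "nested_plsda"))
  steps <- nested$steps
  k <- length(steps)
  node <- hierarchy_node(steps[[k]]$model,
                         branch_class1 = steps[[k]]$target,
                         branch_class2 = paste(steps[[k]]$pool,
                                               collapse = "+"))
  if (k > 1) for (i in (k - 1):1)
    node <- hierarchy_node(steps[[i]]$model,
                           branch_class1 = steps[[i]]$target,
                           branch_class2 = node)
  node
}

#' Build a per-cultivar endophyte tree
#'
#' A single-rule tree classifying endophyte presence within one cultivar;
#' terminal labels carry the cultivar prefix (`"Maxsyn E+"`,
#' `"Maxsyn E-"`).
#'
#' @param model A fitted binary [plsda()] model whose class 1 is `"E+"`.
#' @param cultivar Cultivar name used as label prefix.
#' @return A `"hierarchy_node"`.
#' @export
build_endophyte_tree <- function(model, cultivar) {
  lab <- function(cls) paste(cultivar, cls)
  hierarchy_node(model,
                 branch_class1 = lab(model$class_map$class1[1]),
                 branch_class2 = lab(model$class_map$class2[1]))
}

#' Combine the cultivar tree with per-cultivar endophyte trees
#'
#' Replaces every cultivar terminal of the cultivar tree by that cultivar's
#' endophyte tree, producing a single tree whose terminals are
#' (cultivar, endophyte status) pairs -- eight class terminals for four
#' cultivars -- plus the implicit `"Unclassified"` fail branch.
#'
#' @param cultivar_tree Root node from [build_cultivar_tree()].
#' @param endophyte_trees Named list of [build_endophyte_tree()] nodes,
#'   names = cultivar terminals they replace.
#' @return The combined root `"hierarchy_node"`.
#' @export
combine_trees <- function(cultivar_tree, endophyte_trees) {
  graft <- function(branch) {
    if (inherits(branch, "hierarchy_node")) {
      branch$branch_class1 <- graft(branch$branch_class1)
      branch$branch_class2 <- graft(branch$branch_class2)
      branch
    } else if (branch %in% names(endophyte_trees)) {
      endophyte_trees[[branch]]
    } else branch
  }
  graft(cultivar_tree)
}

#' Classify scans with a hierarchy tree
#'
#' Routes every scan from the root down to a terminal label. Each node
#' pre-processes the raw scans with its own fitted pipeline and applies its
#' binary model; computational failures at a node (pre-processing
#' rejection, non-finite response) send the affected scans to
#' `"Unclassified"` instead of propagating the error.
#'
#' @param tree A `"hierarchy_node"`.
#' @param scans Raw spectra: [spectra_set()] or matrix on the grid the node
#'   models were trained on.
#' @return Character vector of terminal labels, one per scan.
#' @export
classify_tree <- function(tree, scans) {
  X <- as_absorbance(scans)
  out <- rep(NA_character_, nrow(X))
  route <- function(node, idx) {
    if (!length(idx)) return()
    if (is.character(node)) {
      out[idx] <<- node
      return()
    }
    resp <- safe_response(node$model, X[idx, , drop = FALSE])
    bad <- !is.finite(resp)
    if (any(bad)) out[idx[bad]] <<- node$otherwise_label
    idx <- idx[!bad]; resp <- resp[!bad]
    side1 <- if (node$model$class1_high) resp >= node$model$threshold
             else resp <= node$model$threshold
    route(node$branch_class1, idx[side1])
    route(node$branch_class2, idx[!side1])
  }
  route(tree, seq_len(nrow(X)))
  out
}

# vectorized predicted response with per-scan error containment: scans the
# node cannot process get NA
safe_response <- function(model, X) {
  tryCatch(predict(model, X, type = "response"),
           error = function(e) {
             vapply(seq_len(nrow(X)), function(i)
               tryCatch(predict(model, X[i, , drop = FALSE],
                                type = "response"),
                        error = function(e) NA_real_),
               numeric(1))
           })
}

#' @export
print.hierarchy_node <- function(x, ...) {
  show <- function(node, depth) {
    pad <- strrep("  ", depth)
    if (is.character(node)) {
      cat(pad, "- ", node, "\n", sep = "")
    } else {
      cat(sprintf("%srule: %s vs %s (%d LVs)\n", pad,
                  node$model$labels["class1"], node$model$labels["class2"],
                  node$model$n_lv))
      show(node$branch_class1, depth + 1)
      show(node$branch_class2, depth + 1)
    }
  }
  cat("<hierarchy_node>\n")
  show(x, 1)
  invisible(x)
}

#' Majority vote over a bag's sub-sample scans
#'
#' A bag of seed is accepted as the most frequent terminal label among its
#' scans when that label reaches the vote threshold (default 4 of 6);
#' otherwise the bag is `"Inconclusive"`. If the number of scans differs
#' from `scans_per_bag` the threshold is applied proportionally as
#' `ceiling(2/3 * n)`, with a warning.
#'
#' @param scan_labels Terminal labels of one bag's scans.
#' @param vote_threshold Minimum count for acceptance (default 4).
#' @param scans_per_bag Nominal scans per bag (default 6).
#' @return A `"bag_prediction"`: list with `scan_labels`, `majority_label`
#'   (or `"Inconclusive"`) and `votes`.
#' @export
aggregate_bag <- function(scan_labels, vote_threshold = 4,
                          scans_per_bag = 6) {
  n <- length(scan_labels)
  thr <- vote_threshold
  if (n != scans_per_bag) {
    warning("bag has ", n, " scans, expected ", scans_per_bag,
            "; using proportional threshold ceiling(2/3 * n)")
    thr <- ceiling(2 / 3 * n)
  }
  tab <- sort(table(scan_labels), decreasing = TRUE)
  votes <- as.integer(tab[1])
  majority <- if (votes >= thr) names(tab)[1] else "Inconclusive"
  structure(list(scan_labels = scan_labels, majority_label = majority,
                 votes = votes),
            class = "bag_prediction")
}

#' @export
print.bag_prediction <- function(x, ...) {
  cat(sprintf("<bag_prediction> %s (%d of %d votes)\n", x$majority_label,
              x$votes, length(x$scan_labels)))
  invisible(x)
}

#' Bag-level majority vote for a whole dataset
#'
#' @param scan_labels Terminal labels for all scans.
#' @param bag_ids Bag identifier per scan.
#' @inheritParams aggregate_bag
#' @return `data.frame` with one row per bag: `bag_id`, `majority_label`,
#'   `votes`, `n_scans`.
#' @export
aggregate_bags <- function(scan_labels, bag_ids, vote_threshold = 4,
                           scans_per_bag = 6) {
  ids <- unique(bag_ids)
  res <- lapply(ids, function(b) {
    bp <- aggregate_bag(scan_labels[bag_ids == b], vote_threshold,
                        scans_per_bag)
    data.frame(bag_id = b, majority_label = bp$majority_label,
               votes = bp$votes, n_scans = length(bp$scan_labels),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Hit/miss report against truth labels
#'
#' Tabulates, for each (predicted label, actual label) pair with at least
#' one misclassified scan, the count and the percentage of the actual
#' label's scans affected -- the per-rule misclassification tally of a
#' hierarchy run.
#'
#' @param predicted Terminal labels from [classify_tree()].
#' @param truth True labels on the same label scheme.
#' @return `data.frame` with columns `predicted`, `actual`, `n_misclassified`,
#'   `n_actual`, `pct_of_actual`; attribute `"hit_rate"` holds the overall
#'   fraction correct.
#' @export
hit_miss_report <- function(predicted, truth) {
  predicted <- as.character(predicted); truth <- as.character(truth)
  miss <- predicted != truth
  if (!any(miss)) {
    out <- data.frame(predicted = character(0), actual = character(0),
                      n_misclassified = integer(0), n_actual = integer(0),
                      pct_of_actual = numeric(0))
  } else {
    tab <- as.data.frame(table(predicted = predicted[miss],
                               actual = truth[miss]),
                         stringsAsFactors = FALSE)
    tab <- tab[tab$Freq > 0, ]
    n_act <- table(truth)
    out <- data.frame(predicted = tab$predicted, actual = tab$actual,
                      n_misclassified = tab$Freq,
                      n_actual = as.integer(n_act[tab$actual]),
                      pct_of_actual = 100 * tab$Freq /
                        as.integer(n_act[tab$actual]),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$n_misclassified), ]
    rownames(out) <- NULL
  }
  attr(out, "hit_rate") <- mean(!miss)
  out
}
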