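#' Mean-brightness threshold model (comparison method 1)
#'
#' Classifies an ROI as diseased when its mean echogenicity, expressed as a
#' fraction of saturation (255), falls *below* the threshold — inflamed
#' tissue is hypoechogenic. The clinical sweep covers thresholds 13% to 36%;
#' values outside that range are allowed with a warning.
#'
#' @param threshold_fraction threshold as a fraction of saturation, in (0,1).
#' @return an object of class `threshold_model`.
#' @export
threshold_model <- function(threshold_fraction) {
  if (is.na(threshold_fraction) || threshold_fraction <= 0 ||
      threshold_fraction >= 1)
    stop("threshold_fraction must lie in (0, 1)")
  if (threshold_fraction < 0.13 || threshold_fraction > 0.36)
    warning("threshold ", threshold_fraction,
            " is outside the 13%-36% protocol range")
  structure(list(threshold_fraction = threshold_fraction),
            class = "threshold_model")
}

#' Classify one ROI by mean brightness
#'
#' @param ls ROI image matrix (median-filtered, consistent with the main
#'   pipeline).
#' @param model a [threshold_model()].
#' @return `"patient"` if `mean(ls)/255 < threshold_fraction`, else
#'   `"healthy"` (exact equality counts as healthy).
#' @export
method1_classify <- function(ls, model) {
  ls <- as_gray_image(ls, "ROI")
  stopifnot(inherits(model, "threshold_model"))
  if (mean(ls) / 255 < model$threshold_fraction) "patient" else "healthy"
}

# 13% to 36% of saturation in increments of 2.9%: nine thresholds (the
# final one lands at 36.2% under exact 0.029 steps)
default_sweep_thresholds <- function() seq(0.13, by = 0.029, length.out = 9L)

#' Threshold sweep for method 1
#'
#' Evaluates mean-brightness thresholding over a whole cohort at each
#' threshold (resubstitution: the method has no parameters to train, so the
#' sweep is computed on all data). The default grid is 13% to 36% of
#' saturation in steps of 2.9% — 9 thresholds.
#'
#' @param cohort a `thyroid_cohort`.
#' @param thresholds numeric vector of threshold fractions.
#' @return data.frame with columns `threshold`, `TP`, `TN`, `FP`, `FN`,
#'   `ACC`.
#' @export
method1_threshold_sweep <- function(cohort,
                                    thresholds = default_sweep_thresholds()) {
  if (length(cohort) == 0L) stop("cohort is empty")
  means <- numeric(0); labels <- character(0)
  for (rec in cohort) {
    for (v in rec$views) {
      ls <- extract_roi(median_filter3(v$image), v$roi)
      means <- c(means, mean(ls) / 255)
      labels <- c(labels, rec$label)
    }
  }
  rows <- lapply(thresholds, function(thr) {
    pred <- ifelse(means < thr, "patient", "healthy")
    m <- confusion_metrics(labels, pred)
    data.frame(threshold = thr, TP = m$TP, TN = m$TN, FP = m$FP, FN = m$FN,
               ACC = m$ACC)
  })
  do.call(rbind, rows)
}

## ---- decision tree (comparison method 2) -----------------------------------

tree_leaf <- function(label, n, gini) {
  list(leaf = TRUE, label = label, n = n, gini = gini)
}

node_gini <- function(labels) {
  p <- mean(labels == "patient")
  2 * p * (1 - p)
}

majority_label <- function(labels) {
  # tie goes to healthy, consistent with the discriminant tie-break
  if (sum(labels == "patient") > sum(labels == "healthy")) "patient"
  else "healthy"
}

# exhaustive single-feature threshold search minimizing weighted Gini
best_split <- function(X, labels) {
  n <- length(labels)
  best <- NULL
  for (f in colnames(X)) {
    x <- X[, f]
    cuts <- sort(unique(x))
    if (length(cuts) < 2L) next
    mids <- (cuts[-1L] + cuts[-length(cuts)]) / 2
    for (s in mids) {
      left <- x <= s
      nl <- sum(left)
      imp <- (nl * node_gini(labels[left]) +
                (n - nl) * node_gini(labels[!left])) / n
      if (is.null(best) || imp < best$impurity - 1e-12) {
        best <- list(feature = f, value = s, impurity = imp)
      }
    }
  }
  best
}

grow_tree <- function(X, labels, min_node = 5L) {
  gini <- node_gini(labels)
  if (gini == 0 || length(labels) < min_node)
    return(tree_leaf(majority_label(labels), length(labels), gini))
  split <- best_split(X, labels)
  if (is.null(split) || split$impurity >= gini - 1e-12)
    return(tree_leaf(majority_label(labels), length(labels), gini))
  left <- X[, split$feature] <= split$value
  list(leaf = FALSE, feature = split$feature, value = split$value,
       n = length(labels), gini = gini, label = majority_label(labels),
       left = grow_tree(X[left, , drop = FALSE], labels[left], min_node),
       right = grow_tree(X[!left, , drop = FALSE], labels[!left], min_node))
}

count_leaves <- function(node) {
  if (node$leaf) 1L else count_leaves(node$left) + count_leaves(node$right)
}

predict_tree <- function(node, X) {
  out <- character(nrow(X))
  rec <- function(node, idx) {
    if (length(idx) == 0L) return()
    if (node$leaf) {
      out[idx] <<- node$label
    } else {
      left <- X[idx, node$feature] <= node$value
      rec(node$left, idx[left])
      rec(node$right, idx[!left])
    }
  }
  rec(node, seq_len(nrow(X)))
  out
}

# collapse the internal node with the weakest link (smallest increase in
# training error per pruned leaf); returns list(tree, alpha)
weakest_link_prune <- function(tree, X, labels) {
  best <- new.env()
  best$alpha <- Inf; best$path <- NULL
  walk <- function(node, path) {
    if (node$leaf) return()
    idx <- subset_index(X, path)
    node_err <- sum(labels[idx] != node$label)
    sub_err <- sum(predict_tree(node, X[idx, , drop = FALSE]) != labels[idx])
    leaves <- count_leaves(node)
    alpha <- (node_err - sub_err) / (leaves - 1L)
    if (alpha < best$alpha - 1e-12) {
      best$alpha <- alpha; best$path <- path
    }
    walk(node$left, c(path, list(list(node$feature, node$value, TRUE))))
    walk(node$right, c(path, list(list(node$feature, node$value, FALSE))))
  }
  walk(tree, list())
  if (is.null(best$path)) return(NULL)
  list(tree = collapse_at(tree, best$path), alpha = best$alpha)
}

subset_index <- function(X, path) {
  idx <- seq_len(nrow(X))
  for (step in path) {
    keep <- if (step[[3L]]) X[idx, step[[1L]]] <= step[[2L]]
            else X[idx, step[[1L]]] > step[[2L]]
    idx <- idx[keep]
  }
  idx
}

collapse_at <- function(node, path) {
  if (length(path) == 0L)
    return(tree_leaf(node$label, node$n, node$gini))
  step <- path[[1L]]
  if (step[[3L]]) node$left <- collapse_at(node$left, path[-1L])
  else node$right <- collapse_at(node$right, path[-1L])
  node
}

# cost-complexity pruning sequence: level 0 = full tree, successive levels
# collapse the weakest link until only the root leaf remains
pruning_sequence <- function(tree, X, labels) {
  seq_trees <- list(tree)
  alphas <- 0
  repeat {
    pruned <- weakest_link_prune(seq_trees[[length(seq_trees)]], X, labels)
    if (is.null(pruned)) break
    seq_trees[[length(seq_trees) + 1L]] <- pruned$tree
    alphas <- c(alphas, pruned$alpha)
  }
  list(trees = seq_trees, alphas = alphas)
}

#' Fit the decision-tree baseline (comparison method 2)
#'
#' Grows a binary CART-style classification tree on `(w1, w2, w3)` by
#' exhaustive single-feature threshold search minimizing Gini impurity
#' (stopping at pure nodes or fewer than `min_node` samples), builds the
#' cost-complexity (weakest-link) pruning sequence, and selects the pruning
#' level by the 1-SE rule on 10-fold cross-validated error: the smallest tree
#' whose CV error is within one standard error of the minimum.
#'
#' @param train feature data.frame with `label` and `w1`..`w3`.
#' @param validation optional held-out data.frame; accepted for interface
#'   compatibility but unused (selection is cross-validated on `train`).
#' @param seed integer seed for the CV fold assignment.
#' @param min_node minimum node size eligible for splitting.
#' @param n_folds cross-validation folds.
#' @return an object of class `tree_model` with elements `tree` (selected),
#'   `prune_level`, `sequence` (all pruned trees), `alphas`, `cv` (per-level
#'   CV error and SE).
#' @export
method2_fit <- function(train, validation = NULL, seed = 1L, min_node = 5L,
                        n_folds = 10L) {
  labels <- train$label
  if (length(unique(labels)) < 2L)
    stop("both classes must be present in the training set")
  X <- as.matrix(train[, feature_cols])
  full <- grow_tree(X, labels, min_node)
  seq_full <- pruning_sequence(full, X, labels)
  n <- nrow(X)
  n_folds <- min(n_folds, n)
  folds <- with_local_seed(seed, sample(rep(seq_len(n_folds), length.out = n)))
  # CV: refit per fold, evaluate each alpha of the master sequence using the
  # fold tree pruned at the matching complexity (standard CART CV scheme,
  # with geometric-mean representative alphas)
  k_levels <- length(seq_full$alphas)
  rep_alpha <- sqrt(seq_full$alphas *
                      c(seq_full$alphas[-1L],
                        if (k_levels > 1L) Inf else numeric(0)))
  if (k_levels == 1L) rep_alpha <- 0
  cv_err <- matrix(NA_real_, nrow = n, ncol = k_levels)
  for (f in seq_len(n_folds)) {
    in_fold <- folds == f
    if (all(in_fold) || all(!in_fold)) next
    Xf <- X[!in_fold, , drop = FALSE]; lf <- labels[!in_fold]
    if (length(unique(lf)) < 2L) {
      # degenerate fold: constant predictor
      lab <- majority_label(lf)
      for (k in seq_len(k_levels))
        cv_err[in_fold, k] <- as.numeric(labels[in_fold] != lab)
      next
    }
    fold_seq <- pruning_sequence(grow_tree(Xf, lf, min_node), Xf, lf)
    for (k in seq_len(k_levels)) {
      # smallest fold tree whose alpha threshold covers rep_alpha[k]
      pick <- max(which(fold_seq$alphas <= rep_alpha[k] + 1e-12))
      pred <- predict_tree(fold_seq$trees[[pick]],
                           X[in_fold, , drop = FALSE])
      cv_err[in_fold, k] <- as.numeric(pred != labels[in_fold])
    }
  }
  err_mean <- colMeans(cv_err, na.rm = TRUE)
  err_se <- apply(cv_err, 2L, function(e)
    sd(e, na.rm = TRUE) / sqrt(sum(!is.na(e))))
  cutoff <- min(err_mean) + err_se[which.min(err_mean)]
  selected <- max(which(err_mean <= cutoff + 1e-12))  # smallest tree wins
  structure(list(tree = seq_full$trees[[selected]],
                 prune_level = selected - 1L,
                 sequence = seq_full$trees, alphas = seq_full$alphas,
                 cv = data.frame(level = seq_len(k_levels) - 1L,
                                 error = err_mean, se = err_se)),
            class = "tree_model")
}

#' Prune a fitted tree to a given level
#'
#' Level 0 is the unpruned tree; each level collapses one more weakest link;
#' levels beyond the end of the sequence return the root leaf.
#'
#' @param model a `tree_model`.
#' @param level integer pruning level (0 = no pruning).
#' @return a `tree_model` pruned to `level`.
#' @export
method2_prune <- function(model, level) {
  stopifnot(inherits(model, "tree_model"), level >= 0L)
  idx <- min(level + 1L, length(model$sequence))
  model$tree <- model$sequence[[idx]]
  model$prune_level <- idx - 1L
  model
}

#' Predict with the decision-tree baseline
#'
#' Descends the tree comparing one feature per node; values less than or
#' equal to the split go left.
#'
#' @param model a `tree_model`.
#' @param features data.frame with `w1`..`w3`, or a named numeric vector.
#' @return character vector of labels.
#' @export
method2_predict <- function(model, features) {
  stopifnot(inherits(model, "tree_model"))
  X <- if (is.data.frame(features)) as.matrix(features[, feature_cols])
       else matrix(features, nrow = 1L,
                   dimnames = list(NULL, feature_cols))
  if (any(!is.finite(X))) stop("non-finite feature values in prediction")
  predict_tree(model$tree, X)
}

#' @export
predict.tree_model <- function(object, newdata, ...) {
  method2_predict(object, newdata)
}

# serialize tree nodes to plain lists for JSON export
tree_to_list <- function(node) {
  if (node$leaf) list(leaf = TRUE, label = node$label)
  else list(leaf = FALSE, feature = node$feature, value = node$value,
            left = tree_to_list(node$left), right = tree_to_list(node$right))
}

#' Serialize a tree model to JSON
#'
#' @param model a `tree_model`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_tree_json <- function(model, path) {
  jsonlite::write_json(list(prune_level = model$prune_level,
                            tree = tree_to_list(model$tree)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
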