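feature_cols <- c("w1", "w2", "w3")

as_sample_frame <- function(samples) {
  if (inherits(samples, "thyroid_cohort"))
    samples <- extract_cohort_features(samples)
  needed <- c("subject_id", "label", feature_cols)
  if (!is.data.frame(samples) || !all(needed %in% names(samples)))
    stop("samples must be a cohort or a data.frame with columns ",
         paste(needed, collapse = ", "))
  if (!all(samples$label %in% c("healthy", "patient")))
    stop("labels must be 'healthy' or 'patient'")
  samples
}

#' Subject-level stratified split into learning/validation/test thirds
#'
#' Subjects (not individual images) are assigned to partitions so that all
#' four views of a subject travel together — image-level splitting would leak
#' texture from the same gland across partitions. Within each class the
#' shuffled subjects are dealt into thirds; remainders go to learning, then
#' validation, so per-class partition sizes differ by at most one.
#'
#' @param samples a `thyroid_cohort` or feature data.frame (from
#'   [extract_cohort_features()]).
#' @param seed integer seed controlling the shuffle.
#' @return named list of data.frames: `train`, `validation`, `test`.
#' @export
split_cohort <- function(samples, seed) {
  samples <- as_sample_frame(samples)
  assign_part <- function(ids) {
    n <- length(ids)
    base <- n %/% 3L
    sizes <- rep(base, 3L) + (seq_len(3L) <= n %% 3L)
    rep(c("train", "validation", "test"), sizes)
  }
  parts <- character(0)
  ids <- character(0)
  with_local_seed(seed, {
    for (cls in c("healthy", "patient")) {
      cls_ids <- unique(samples$subject_id[samples$label == cls])
      if (length(cls_ids) < 3L)
        stop("need at least 3 subjects per class to split; class '", cls,
             "' has ", length(cls_ids))
      cls_ids <- sample(cls_ids)
      parts <- c(parts, assign_part(cls_ids))
      ids <- c(ids, cls_ids)
    }
  })
  lookup <- setNames(parts, ids)
  out <- split(samples, lookup[samples$subject_id])
  lapply(setNames(c("train", "validation", "test"),
                  c("train", "validation", "test")),
         function(p) {
           df <- out[[p]]
           rownames(df) <- NULL
           df
         })
}

#' Filter samples by view grouping
#'
#' The seven groupings pool the four atomic views (left/right lobe O =
#' transverse, D = longitudinal): `LO`, `RO`, `LD`, `RD` select one view;
#' `LRO` = LO + RO, `RLD` = LD + RD, `RLOD` = all four.
#'
#' @param samples feature data.frame with a `view` column.
#' @param group one of `"LO"`, `"RO"`, `"LRO"`, `"LD"`, `"RD"`, `"RLD"`,
#'   `"RLOD"`.
#' @return the filtered data.frame.
#' @export
select_view_group <- function(samples, group) {
  views <- switch(match.arg(group, c("LO", "RO", "LRO", "LD", "RD", "RLD",
                                     "RLOD")),
                  LO = "LO", RO = "RO", LD = "LD", RD = "RD",
                  LRO = c("LO", "RO"), RLD = c("LD", "RD"),
                  RLOD = c("LO", "RO", "LD", "RD"))
  out <- samples[samples$view %in% views, , drop = FALSE]
  rownames(out) <- NULL
  out
}

discriminant_variants <- c("linear", "diaglinear", "quadratic",
                           "diagquadratic", "mahalanobis")

regularize_cov <- function(S, lambda = 1e-6) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= .Machine$double.eps * max(abs(ev), 1)) {
    # ridge scaled by the mean variance; unit scale when the trace vanishes
    # (all-constant features), so degenerate fits stay well defined
    scale <- if (sum(diag(S)) > 0) sum(diag(S)) / nrow(S) else 1
    S <- S + lambda * scale * diag(nrow(S))
  }
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("covariance matrix not positive definite after regularization")
  S
}

#' Fit a Gaussian discriminant classifier
#'
#' Five variants on the feature triple `(w1, w2, w3)`:
#' \describe{
#'   \item{linear}{shared (pooled within-class) covariance — LDA.}
#'   \item{diaglinear}{pooled covariance with off-diagonals zeroed (naive
#'     Bayes with shared variances).}
#'   \item{quadratic}{per-class covariances — QDA.}
#'   \item{diagquadratic}{per-class diagonal covariances (naive Bayes).}
#'   \item{mahalanobis}{per-class ("stratified") covariances; prediction by
#'     smallest Mahalanobis distance, ignoring priors and determinants.}
#' }
#' Class means are sample means, covariances use the n-1 denominator, the
#' pooled estimate weights classes by their degrees of freedom, and priors
#' are the empirical class frequencies. A singular covariance is ridged by
#' `lambda * trace/3` on the diagonal.
#'
#' @param train feature data.frame with `label` and `w1`..`w3`.
#' @param variant one of `"linear"`, `"diaglinear"`, `"quadratic"`,
#'   `"diagquadratic"`, `"mahalanobis"`.
#' @param lambda ridge coefficient used only when a covariance is singular.
#' @return an object of class `discriminant_model`.
#' @export
fit_discriminant <- function(train, variant, lambda = 1e-6) {
  variant <- match.arg(variant, discriminant_variants)
  if (!all(c("healthy", "patient") %in% train$label))
    stop("both classes must be present in the training set")
  X <- as.matrix(train[, feature_cols])
  if (any(!is.finite(X))) stop("non-finite feature values in training set")
  classes <- c("healthy", "patient")
  per_class <- variant %in% c("quadratic", "diagquadratic", "mahalanobis")
  means <- list(); covs <- list(); n_k <- integer(0)
  for (cls in classes) {
    Xk <- X[train$label == cls, , drop = FALSE]
    if (per_class && nrow(Xk) < 4L)
      stop("variant '", variant, "' needs >= 4 samples per class")
    means[[cls]] <- colMeans(Xk)
    covs[[cls]] <- stats::cov(Xk)
    n_k[cls] <- nrow(Xk)
  }
  if (!per_class) {
    pooled <- Reduce(`+`, lapply(classes, function(cls)
      (n_k[cls] - 1L) * covs[[cls]])) / (sum(n_k) - length(classes))
    covs <- list(healthy = pooled, patient = pooled)
  }
  if (variant %in% c("diaglinear", "diagquadratic"))
    covs <- lapply(covs, function(S) diag(diag(S)))
  covs <- lapply(covs, regularize_cov, lambda = lambda)
  structure(list(variant = variant, classes = classes, means = means,
                 covariances = covs, priors = n_k / sum(n_k)),
            class = "discriminant_model")
}

#' @export
print.discriminant_model <- function(x, ...) {
  cat(sprintf("<discriminant_model variant=%s priors=%.2f/%.2f>\n",
              x$variant, x$priors[1L], x$priors[2L]))
  invisible(x)
}

# per-class decision scores (higher wins) for a feature matrix
discriminant_scores <- function(model, X) {
  scores <- sapply(model$classes, function(cls) {
    S <- model$covariances[[cls]]
    mu <- model$means[[cls]]
    d <- sweep(X, 2L, mu)
    maha <- rowSums((d %*% solve(S)) * d)
    if (model$variant == "mahalanobis") -maha
    else -0.5 * maha - 0.5 * determinant(S)$modulus +
      log(model$priors[[cls]])
  })
  matrix(scores, nrow = nrow(X), dimnames = list(NULL, model$classes))
}

#' Predict class labels
#'
#' Gaussian variants assign by the largest discriminant score
#' (log-likelihood plus log prior, with the -1/2 log|Sigma_k| term for
#' per-class covariances); the mahalanobis variant assigns by the smallest
#' Mahalanobis distance to a class mean, with no prior or determinant term.
#' Exact ties go to `"healthy"` (conservative for a screening setting).
#'
#' @param object a fitted `discriminant_model`.
#' @param newdata data.frame with `w1`, `w2`, `w3` columns, or a numeric
#'   matrix/vector of features.
#' @param ... unused.
#' @return character vector of `"healthy"`/`"patient"` labels.
#' @export
predict.discriminant_model <- function(object, newdata, ...) {
  X <- if (is.data.frame(newdata)) as.matrix(newdata[, feature_cols])
       else if (is.matrix(newdata)) newdata
       else matrix(newdata, nrow = 1L)
  if (any(!is.finite(X))) stop("non-finite feature values in prediction")
  s <- discriminant_scores(object, X)
  unname(ifelse(s[, "patient"] > s[, "healthy"], "patient", "healthy"))
}

#' Confusion counts and derived metrics
#'
#' `"patient"` is the positive class. Sensitivity TPR = TP/(TP+FN),
#' specificity SPC = TN/(FP+TN), accuracy ACC = (TP+TN)/total. A metric with
#' an empty denominator is reported as `NaN`.
#'
#' @param model a fitted `discriminant_model` (or any object whose `predict`
#'   method returns `"healthy"`/`"patient"`).
#' @param test feature data.frame with a `label` column.
#' @return list with `TP`, `TN`, `FP`, `FN`, `TPR`, `SPC`, `ACC`.
#' @export
evaluate <- function(model, test) {
  if (nrow(test) == 0L) stop("test set is empty")
  pred <- predict(model, test)
  confusion_metrics(truth = test$label, pred = pred)
}

confusion_metrics <- function(truth, pred) {
  TP <- sum(truth == "patient" & pred == "patient")
  TN <- sum(truth == "healthy" & pred == "healthy")
  FP <- sum(truth == "healthy" & pred == "patient")
  FN <- sum(truth == "patient" & pred == "healthy")
  list(TP = TP, TN = TN, FP = FP, FN = FN,
       TPR = if (TP + FN > 0) TP / (TP + FN) else NaN,
       SPC = if (FP + TN > 0) TN / (FP + TN) else NaN,
       ACC = (TP + TN) / (TP + TN + FP + FN))
}

#' Grouped evaluation over all variants and view groupings
#'
#' Splits the cohort into learning/validation/test thirds at subject level,
#' then for each of the seven view groupings fits all five discriminant
#' variants on the learning partition and scores them on the test partition:
#' a 7 x 5 = 35-row table. The validation partition is produced by the split
#' but intentionally unused here (it is reserved for the decision-tree
#' baseline's pruning selection).
#'
#' @param cohort a `thyroid_cohort` or feature data.frame.
#' @param seed integer seed for the split.
#' @param groups,variants subsets to evaluate (defaults: all).
#' @return data.frame with columns `group`, `variant`, `TP`, `TN`, `FP`,
#'   `FN`, `TPR`, `SPC`, `ACC`.
#' @export
run_grouped_evaluation <- function(cohort, seed,
                                   groups = c("LO", "RO", "LRO", "LD", "RD",
                                              "RLD", "RLOD"),
                                   variants = discriminant_variants) {
  samples <- as_sample_frame(cohort)
  parts <- split_cohort(samples, seed)
  rows <- list()
  for (group in groups) {
    train_g <- select_view_group(parts$train, group)
    test_g <- select_view_group(parts$test, group)
    for (variant in variants) {
      model <- fit_discriminant(train_g, variant)
      m <- evaluate(model, test_g)
      rows[[length(rows) + 1L]] <- data.frame(group = group,
                                              variant = variant, m)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
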