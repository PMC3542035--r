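# tiny cohort builder with hand-picked texture params per class
make_cohort <- function(n_per_class, healthy_params, patient_params, seed,
                        extent = c(96L, 96L), roi = c(50L, 50L)) {
  generate_cohort(cohort_config(
    n_per_class, n_per_class, image_extent = extent, roi_extent = roi,
    seed = seed,
    class_params = list(healthy = healthy_params,
                        patient = patient_params)))
}

test_that("method1 classifies by mean brightness with healthy ties", {
  model <- threshold_model(0.25)
  expect_identical(method1_classify(matrix(51L, 12, 12), model), "patient")
  expect_identical(method1_classify(matrix(102L, 12, 12), model), "healthy")
  # mean exactly at the threshold: tie goes to healthy
  tie <- matrix(round(0.25 * 255), 12, 12)  # 63.75 -> 64, just above
  exact <- threshold_model(64 / 255)
  expect_identical(method1_classify(matrix(64L, 12, 12), exact), "healthy")
  expect_error(threshold_model(0), "\\(0, 1\\)")
  expect_warning(threshold_model(0.05), "13%")
})

test_that("the default threshold sweep has nine steps of 2.9% from 13%", {
  thr <- thyrotex:::default_sweep_thresholds()
  expect_length(thr, 9L)
  expect_equal(thr[1], 0.13)
  expect_equal(unique(round(diff(thr), 10)), 0.029)

  cohort <- make_cohort(3, texture_params(100), texture_params(30), seed = 2)
  sweep <- method1_threshold_sweep(cohort)
  expect_identical(nrow(sweep), 9L)
  expect_error(method1_threshold_sweep(structure(list(),
                                                class = "thyroid_cohort")),
               "empty")
})

test_that("the sweep reaches ACC 1 on a separable-means fixture", {
  # class means 30/255 = 0.118 and 100/255 = 0.392 bracket every sweep point
  cohort <- make_cohort(4, texture_params(100, speckle_scale = 0.05),
                        texture_params(30, speckle_scale = 0.05), seed = 8)
  sweep <- method1_threshold_sweep(cohort)
  expect_true(all(sweep$ACC == 1))

  # brute-force recount at one sweep point
  thr <- sweep$threshold[4]
  correct <- 0; total <- 0
  for (rec in cohort) for (v in rec$views) {
    ls <- extract_roi(median_filter3(v$image), v$roi)
    pred <- if (mean(ls) / 255 < thr) "patient" else "healthy"
    correct <- correct + (pred == rec$label); total <- total + 1
  }
  expect_identical(sweep$ACC[4], correct / total)

  # identical images: ACC equals the larger class fraction at any threshold
  flat <- make_cohort(3, texture_params(60), texture_params(60), seed = 4)
  sflat <- method1_threshold_sweep(flat)
  expect_true(all(sflat$ACC == 0.5))
})

test_that("method2 grows a single split on a separable fixture", {
  train <- data.frame(subject_id = sprintf("S%d", 1:10), view = "LO",
                      label = rep(c("patient", "healthy"), each = 5),
                      w1 = 0.001, w2 = c(30, 33, 35, 38, 40,
                                         55, 58, 60, 63, 65), w3 = 25)
  fit <- method2_fit(train, seed = 42)
  unpruned <- method2_prune(fit, 0)
  expect_false(unpruned$tree$leaf)
  expect_identical(unpruned$tree$feature, "w2")
  expect_true(unpruned$tree$left$leaf && unpruned$tree$right$leaf)
  expect_identical(method2_predict(unpruned, train), train$label)

  # exhaustive-search check: split value separates the classes
  expect_gt(unpruned$tree$value, 40)
  expect_lt(unpruned$tree$value, 55)

  expect_identical(method2_fit(train, seed = 42)$sequence,
                   fit$sequence)
  expect_error(method2_fit(train[train$label == "patient", ], seed = 1),
               "both classes")
})

test_that("pruning to the root yields the majority class", {
  set.seed(61)
  train <- rand_feature_frame(20, c(0, 40, 20), c(0.5, 30, 30))
  fit <- method2_fit(train, seed = 7)
  root <- method2_prune(fit, 99L)
  expect_true(root$tree$leaf)
  preds <- method2_predict(root, train)
  expect_identical(unique(preds), root$tree$label)
  expect_identical(mean(preds == train$label), 0.5)  # balanced classes
})

test_that("training accuracy degrades monotonically with pruning level", {
  set.seed(77)
  train <- rand_feature_frame(30, c(0.2, 45, 25), c(0.45, 38, 32))
  fit <- method2_fit(train, seed = 3)
  accs <- vapply(seq_along(fit$sequence) - 1L, function(lev) {
    mean(method2_predict(method2_prune(fit, lev), train) == train$label)
  }, numeric(1))
  expect_gte(length(accs), 2L)
  expect_true(all(diff(accs) <= 1e-12))
})

test_that("tree traversal agrees with an independent recursive evaluator", {
  set.seed(83)
  train <- rand_feature_frame(25, c(0.1, 50, 20), c(0.3, 35, 30))
  fit <- method2_fit(train, seed = 5)
  walk <- function(node, x) {
    if (node$leaf) return(node$label)
    if (x[[node$feature]] <= node$value) walk(node$left, x)
    else walk(node$right, x)
  }
  queries <- rand_feature_frame(100, c(0.2, 42, 25), c(0.2, 42, 25))
  got <- method2_predict(fit, queries)
  want <- vapply(seq_len(nrow(queries)), function(k)
    walk(fit$tree, queries[k, ]), "")
  expect_identical(got, want)
  # single-split traversal contract
  single <- method2_prune(fit, length(fit$sequence) - 2L)
  expect_error(method2_predict(fit, data.frame(w1 = NA, w2 = 1, w3 = 1)),
               "non-finite")
})

test_that("trees beat mean thresholding when only heterogeneity differs", {
  # equal mean level: method 1 is uninformative; w1 separates the classes
  cohort <- make_cohort(9, texture_params(70, speckle_scale = 0.08),
                        texture_params(70, speckle_scale = 0.5),
                        seed = 31)
  best_m1 <- max(method1_threshold_sweep(cohort)$ACC)
  feats <- extract_cohort_features(cohort)
  parts <- split_cohort(feats, seed = 31)
  fit <- method2_fit(parts$train, seed = 31)
  acc_m2 <- mean(method2_predict(fit, parts$test) == parts$test$label)
  expect_gt(acc_m2, best_m1)
})

test_that("tree models serialize to JSON", {
  set.seed(97)
  train <- rand_feature_frame(15, c(0.1, 50, 20), c(0.4, 30, 30))
  fit <- method2_fit(train, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_tree_json(fit, path)
  parsed <- jsonlite::read_json(path)
  expect_identical(parsed$prune_level, fit$prune_level)
  expect_false(is.null(parsed$tree$leaf))
})
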