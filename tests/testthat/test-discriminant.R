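test_that("split_cohort partitions subjects into stratified thirds", {
  set.seed(3)
  samples <- rand_feature_frame(6, c(0, 0, 0), c(1, 1, 1))
  parts <- split_cohort(samples, seed = 9)
  sizes <- vapply(parts, nrow, integer(1))
  expect_identical(unname(sizes), c(4L, 4L, 4L))
  for (p in parts) expect_identical(as.vector(table(p$label)), c(2L, 2L))
  # no subject straddles partitions
  expect_length(Reduce(intersect, lapply(parts, function(p) p$subject_id)),
                0L)
  expect_identical(parts, split_cohort(samples, seed = 9))

  # remainders spread so per-class partition sizes differ by at most one
  samples7 <- rand_feature_frame(7, c(0, 0, 0), c(1, 1, 1))
  parts7 <- split_cohort(samples7, seed = 2)
  expect_identical(sum(vapply(parts7, nrow, integer(1))), 14L)
  for (cls in c("healthy", "patient")) {
    per_part <- vapply(parts7, function(p) sum(p$label == cls), integer(1))
    expect_lte(max(per_part) - min(per_part), 1L)
  }

  expect_error(split_cohort(rand_feature_frame(2, c(0, 0, 0), c(1, 1, 1)),
                            seed = 1),
               "at least 3 subjects")
})

test_that("select_view_group filters and pools the atomic views", {
  df <- expand.grid(subject_id = sprintf("S%02d", 1:10),
                    view = c("LO", "RO", "LD", "RD"),
                    stringsAsFactors = FALSE)
  df$label <- "healthy"; df$w1 <- 0; df$w2 <- 0; df$w3 <- 0
  expect_identical(nrow(select_view_group(df, "RLOD")), 40L)
  expect_identical(nrow(select_view_group(df, "LO")), 10L)
  only_ld <- df[df$view == "LD", ]
  expect_identical(nrow(select_view_group(only_ld, "LRO")), 0L)
  rld <- select_view_group(df, "RLD")
  expect_setequal(
    paste(rld$subject_id, rld$view),
    c(paste(select_view_group(df, "LD")$subject_id, "LD"),
      paste(select_view_group(df, "RD")$subject_id, "RD")))
  expect_error(select_view_group(df, "XX"))
})

test_that("fit_discriminant estimates means, covariances and priors", {
  set.seed(11)
  train <- rand_feature_frame(60, c(0, 0, 0), c(3, 3, 3))
  m <- fit_discriminant(train, "linear")
  Xh <- as.matrix(train[train$label == "healthy", c("w1", "w2", "w3")])
  Xp <- as.matrix(train[train$label == "patient", c("w1", "w2", "w3")])
  expect_equal(m$means$healthy, colMeans(Xh))
  pooled <- ((nrow(Xh) - 1) * cov(Xh) + (nrow(Xp) - 1) * cov(Xp)) /
    (nrow(Xh) + nrow(Xp) - 2)
  expect_equal(m$covariances$healthy, pooled)
  expect_identical(m$covariances$healthy, m$covariances$patient)
  expect_equal(unname(m$priors), c(0.5, 0.5))

  d <- fit_discriminant(train, "diaglinear")
  expect_true(all(d$covariances$healthy[upper.tri(diag(3))] == 0))

  # per-class covariance against a hand-computed n-1 estimate
  pts <- data.frame(subject_id = sprintf("S%d", 1:8), view = "LO",
                    label = rep(c("healthy", "patient"), each = 4),
                    w1 = c(0, 1, 2, 3, 10, 11, 12, 13),
                    w2 = c(0, 2, 4, 7, 1, 1, 1, 3),
                    w3 = c(5, 6, 4, 9, 0, 4, 8, 0))
  q <- fit_discriminant(pts, "quadratic")
  xh <- cbind(w1 = 0:3, w2 = c(0, 2, 4, 7), w3 = c(5, 6, 4, 9))
  manual <- crossprod(sweep(xh, 2, colMeans(xh))) / 3
  expect_equal(unname(q$covariances$healthy), unname(manual),
               tolerance = 1e-9)

  one_class <- train[train$label == "healthy", ]
  expect_error(fit_discriminant(one_class, "linear"), "both classes")
})

test_that("prediction follows the per-variant decision rules", {
  model <- structure(list(
    variant = "linear", classes = c("healthy", "patient"),
    means = list(healthy = c(0, 0, 0), patient = c(2, 2, 2)),
    covariances = list(healthy = diag(3), patient = diag(3)),
    priors = c(healthy = 0.5, patient = 0.5)),
    class = "discriminant_model")
  # nearest-mean reduction under the identity covariance
  expect_identical(predict(model, c(1.1, 1.1, 1.1)), "patient")
  expect_identical(predict(model, c(0.9, 0.9, 0.9)), "healthy")
  # exact midpoint is a tie: healthy wins
  expect_identical(predict(model, c(1, 1, 1)), "healthy")
  expect_error(predict(model, c(1, NA, 1)), "non-finite")
})

test_that("mahalanobis predictions equal a brute-force quadratic-form loop", {
  set.seed(19)
  train <- rand_feature_frame(40, c(0, 0, 0), c(1.5, 0.5, 1),
                              sigma = matrix(c(1, .3, .1, .3, 1, .2,
                                               .1, .2, 1), 3))
  m <- fit_discriminant(train, "mahalanobis")
  queries <- matrix(rnorm(500 * 3, mean = 0.7), 500, 3,
                    dimnames = list(NULL, c("w1", "w2", "w3")))
  got <- predict(m, queries)
  Sh <- solve(m$covariances$healthy); Sp <- solve(m$covariances$patient)
  for (k in seq_len(500)) {
    dh <- queries[k, ] - m$means$healthy
    dp <- queries[k, ] - m$means$patient
    want <- if (drop(t(dp) %*% Sp %*% dp) < drop(t(dh) %*% Sh %*% dh))
      "patient" else "healthy"
    if (got[k] != want) fail(sprintf("query %d: %s != %s", k, got[k], want))
  }
  succeed()
})

test_that("linear and mahalanobis coincide for equal priors, shared cov", {
  set.seed(23)
  for (rep in 1:10) {
    A <- matrix(rnorm(9), 3); S <- crossprod(A) + diag(3)
    mu_h <- rnorm(3); mu_p <- rnorm(3)
    model <- function(variant) structure(list(
      variant = variant, classes = c("healthy", "patient"),
      means = list(healthy = mu_h, patient = mu_p),
      covariances = list(healthy = S, patient = S),
      priors = c(healthy = 0.5, patient = 0.5)),
      class = "discriminant_model")
    q <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("w1", "w2", "w3")))
    expect_identical(predict(model("linear"), q),
                     predict(model("mahalanobis"), q))
  }
})

test_that("evaluate reproduces the confusion-matrix arithmetic", {
  perfect <- data.frame(label = rep(c("patient", "healthy"), c(8, 12)),
                        w1 = rep(c(1, 0), c(8, 12)), w2 = 0, w3 = 0)
  stub <- structure(list(), class = c("stub_model", "list"))
  # a fake model: predict dispatches on class
  assign("predict.stub_model",
         function(object, newdata, ...) ifelse(newdata$w1 > 0.5,
                                               "patient", "healthy"),
         envir = globalenv())
  on.exit(rm("predict.stub_model", envir = globalenv()))
  m <- evaluate(stub, perfect)
  expect_identical(c(m$TP, m$TN, m$FP, m$FN), c(8L, 12L, 0L, 0L))
  expect_identical(m$ACC, 1)

  counts <- thyrotex:::confusion_metrics(
    truth = rep(c("patient", "healthy"), c(25, 60)),
    pred = rep(c("patient", "healthy", "patient", "healthy"),
               c(19, 6, 3, 57)))
  expect_equal(counts$TPR, 0.76)
  expect_equal(counts$SPC, 0.95)
  expect_equal(counts$ACC, 76 / 85)

  # degenerate all-healthy predictor
  assign("predict.stub_model",
         function(object, newdata, ...) rep("healthy", nrow(newdata)),
         envir = globalenv())
  m0 <- evaluate(stub, perfect)
  expect_identical(m0$TPR, 0)
  expect_identical(m0$SPC, 1)

  # order invariance
  shuffled <- perfect[sample(nrow(perfect)), ]
  expect_identical(evaluate(stub, shuffled), m0)
})

test_that("linear-variant accuracy approaches the Gaussian Bayes limit", {
  set.seed(2000)
  sep <- c(2, 0, 0)  # Mahalanobis separation 2 under identity covariance
  train <- rand_feature_frame(1000, c(0, 0, 0), sep)
  test <- rand_feature_frame(1000, c(0, 0, 0), sep)
  model <- fit_discriminant(train, "linear")
  acc <- evaluate(model, test)$ACC
  bayes <- pnorm(1)
  expect_lt(abs(acc - bayes), 3 * sqrt(acc * (1 - acc) / 2000))
})

test_that("run_grouped_evaluation emits a deterministic 35-row table", {
  big <- default_cohort_60()
  tab <- run_grouped_evaluation(big$features, seed = 55)
  expect_identical(nrow(tab), 35L)
  expect_identical(length(unique(tab$group)), 7L)
  expect_identical(length(unique(tab$variant)), 5L)
  expect_identical(tab, run_grouped_evaluation(big$features, seed = 55))
  expect_true(all(tab$TP + tab$TN + tab$FP + tab$FN > 0))
})
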