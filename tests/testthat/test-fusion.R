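# Gradient-boosted stacking of per-ROI risks and operating-point selection.

mk_rv <- function(s, miss = rep(FALSE, 6)) {
  structure(list(s = stats::setNames(s, risk_classes()),
                 missing_mask = stats::setNames(miss, risk_classes())),
            class = "fg_risk_vector")
}

test_that("a perfectly separable feature gives training AUC 1", {
  set.seed(30)
  labs <- rep(0:1, each = 30)
  rvs <- lapply(labs, function(l) mk_rv(c(l, runif(5))))
  st <- train_fusion(rvs, labs, fusion_config(n_trees = 50, seed = 1))
  p <- predict_disorder(st, rvs)
  expect_equal(roc_auc(p, labs)$auc, 1)
})

test_that("label-permuted features give chance held-out AUC", {
  set.seed(31)
  labs <- rbinom(200, 1, 0.5)
  rvs <- lapply(seq_along(labs), function(i) mk_rv(runif(6)))
  st <- train_fusion(rvs[1:120], labs[1:120],
                     fusion_config(n_trees = 50, seed = 2))
  p <- predict_disorder(st, rvs[121:200])
  auc <- roc_auc(p, labs[121:200])$auc
  expect_gte(auc, 0.4 - 1e-9)
  expect_lte(auc, 0.6 + 1e-9)
})

test_that("degenerate inputs are rejected", {
  rvs <- lapply(1:10, function(i) mk_rv(runif(6)))
  expect_error(train_fusion(rvs, rep(1, 10), fusion_config()), "per class")
  expect_error(train_fusion(rvs, c(1, 0), fusion_config()),
               "length mismatch")
})

test_that("missing policies fill features as documented", {
  cfg <- fusion_config(missing_policy = "indicator")
  rv <- mk_rv(c(NA, 0.7, NA, 0.2, 0.9, NA), c(TRUE, FALSE, TRUE, FALSE,
                                              FALSE, TRUE))
  X <- fgscreen:::risk_feature_matrix(list(rv), cfg)
  expect_equal(ncol(X), 12)
  expect_equal(as.numeric(X[1, 1]), 0.5)          # imputed probability
  expect_equal(as.numeric(X[1, 7]), 1)            # indicator set
  cfg2 <- fusion_config(missing_policy = "impute_mean")
  X2 <- fgscreen:::risk_feature_matrix(list(rv, mk_rv(rep(0.4, 6))), cfg2)
  expect_equal(ncol(X2), 6)
  expect_equal(as.numeric(X2[1, 1]), 0.4)         # column mean of observed
})

test_that("prediction is deterministic; all-missing input follows the policy", {
  set.seed(32)
  labs <- rbinom(60, 1, 0.5); labs[1:2] <- 0:1
  rvs <- lapply(seq_along(labs), function(i)
    mk_rv(pmin(pmax(labs[i] * 0.5 + runif(6, 0, 0.5), 0), 1)))
  st <- train_fusion(rvs, labs, fusion_config(n_trees = 30, seed = 3))
  rv_miss <- mk_rv(rep(NA_real_, 6), rep(TRUE, 6))
  p1 <- predict_disorder(st, rv_miss)
  p2 <- predict_disorder(st, rv_miss)
  expect_s3_class(p1, "fg_prediction")
  expect_identical(p1$probability, p2$probability)
  expect_gte(p1$probability, 0)
  expect_lte(p1$probability, 1)
})

test_that("monotone constraints make P non-decreasing in each risk", {
  set.seed(33)
  labs <- rbinom(300, 1, 0.5)
  rvs <- lapply(seq_along(labs), function(i)
    mk_rv(pmin(pmax(rnorm(6, 0.3 + 0.4 * labs[i], 0.15), 0), 1)))
  st <- train_fusion(rvs, labs, fusion_config(n_trees = 60, monotone = TRUE,
                                              seed = 4))
  base <- mk_rv(rep(0.4, 6))
  grid <- seq(0, 1, 0.05)
  ps <- vapply(grid, function(v) {
    rv <- base; rv$s[["NT"]] <- v
    predict_disorder(st, rv)$probability
  }, numeric(1))
  expect_true(all(diff(ps) >= -1e-12))
})

test_that("operating-point policies behave per contract", {
  expect_equal(choose_operating_point(runif(10), rbinom(10, 1, 0.5),
                                      "fixed_0.5"), 0.5)
  # scores equal to labels: threshold strictly inside (0,1), sens = spec = 1
  thr <- choose_operating_point(c(0, 0, 1, 1), c(0, 0, 1, 1), "youden")
  expect_gt(thr, 0); expect_lt(thr, 1)
  pred <- c(0, 0, 1, 1) >= thr
  expect_equal(mean(pred[3:4]), 1)
  expect_equal(mean(!pred[1:2]), 1)
  expect_error(choose_operating_point(runif(5), rep(1, 5), "youden"),
               "both classes")
  # symmetric well-calibrated scores: youden near 0.5 across seeds
  thrs <- vapply(1:20, function(s) {
    set.seed(s)
    y <- rbinom(400, 1, 0.5)
    p <- plogis(rnorm(400, ifelse(y == 1, 1.5, -1.5)))
    choose_operating_point(p, y, "youden")
  }, numeric(1))
  expect_lt(abs(mean(thrs) - 0.5), 0.1)
})
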