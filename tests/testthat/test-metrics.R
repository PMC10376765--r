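# Classification metrics, ROC/AUC and detection AP against hand arithmetic
# and independent oracles.

test_that("classification metrics match hand arithmetic", {
  m <- classification_metrics(50, 10, 80, 20)
  expect_equal(m$sensitivity, 50 / 70, tolerance = 1e-12)
  expect_equal(m$specificity, 80 / 90, tolerance = 1e-12)
  expect_equal(m$precision, 50 / 60, tolerance = 1e-12)
  expect_equal(m$f1, 2 * (50 / 60) * (50 / 70) / (50 / 60 + 50 / 70),
               tolerance = 1e-12)
  expect_equal(m$accuracy, 130 / 160, tolerance = 1e-12)
  # perfect classifier
  p <- classification_metrics(30, 0, 40, 0)
  expect_true(all(unlist(p[c("accuracy", "sensitivity", "specificity",
                             "precision", "f1")]) == 1))
  # all-positive predictor on balanced data
  a <- classification_metrics(50, 50, 0, 0)
  expect_equal(a$sensitivity, 1)
  expect_equal(a$specificity, 0)
  # undefined ratios surface as NaN with a note, never silently 0
  expect_message(z <- classification_metrics(0, 0, 5, 0), "undefined")
  expect_true(is.nan(z$precision))
})

test_that("f1 computed two algebraically equivalent ways agrees to 1e-12", {
  set.seed(13)
  for (k in 1:50) {
    tp <- sample(0:50, 1) + 1; fp <- sample(0:50, 1); fn <- sample(0:50, 1)
    m <- suppressMessages(classification_metrics(tp, fp, 100, fn))
    f1_alt <- 2 * tp / (2 * tp + fp + fn)
    expect_equal(m$f1, f1_alt, tolerance = 1e-12)
  }
})

test_that("wilson intervals are inside [0,1] and contain the point estimate", {
  ci <- wilson_ci(75, 100)
  expect_true(ci[1] < 0.75 && 0.75 < ci[2])
  expect_true(all(ci >= 0 & ci <= 1))
  expect_true(all(is.nan(wilson_ci(0, 0))))
})

test_that("AUC equals the Mann-Whitney rank oracle and handles edge cases", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0, 0, 1, 1))$auc, 1)
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
  set.seed(14)
  for (k in 1:50) {
    n <- sample(10:40, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- round(rnorm(n), 1)  # coarse scores force ties
    expect_lt(abs(roc_auc(s, y)$auc - oracle_auc(s, y)), 1e-10)
  }
})

test_that("AUC of label-independent scores is 0.5 and is rank invariant", {
  set.seed(15)
  y <- rbinom(10000, 1, 0.5)
  s <- rnorm(10000)
  auc <- roc_auc(s, y)$auc
  expect_equal(auc, 0.5, tolerance = 0.02)
  # strictly monotone transform leaves the AUC unchanged
  expect_equal(roc_auc(exp(2 * s + 1), y)$auc, auc, tolerance = 1e-12)
})

test_that("AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(19)
  for (k in 1:10) {
    y <- rbinom(60, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- rnorm(60)
    ref <- as.numeric(suppressMessages(pROC::auc(y, s,
                                                 direction = "<")))
    expect_equal(roc_auc(s, y)$auc, ref, tolerance = 1e-10)
  }
})

test_that("ROC curve endpoints and monotonicity", {
  set.seed(16)
  r <- roc_auc(runif(50), rbinom(50, 1, 0.4))
  expect_equal(c(r$tpr[1], r$fpr[1]), c(0, 0))
  expect_equal(c(r$tpr[length(r$tpr)], r$fpr[length(r$fpr)]), c(1, 1))
  expect_true(all(diff(r$tpr) >= 0))
  expect_true(all(diff(r$fpr) >= 0))
})

test_that("detection AP: exact match, duplicate penalty, brute-force oracle", {
  gt <- data.frame(image = "a", class = "NT", x_min = 10, y_min = 10,
                   x_max = 50, y_max = 50)
  pr <- gt; pr$confidence <- 0.9
  expect_equal(detection_map(pr, gt)$map, 1)
  # a duplicated prediction is a false positive (one-match rule)
  pr2 <- rbind(pr, pr); pr2$confidence <- c(0.9, 0.8)
  r2 <- detection_map(pr2, gt)
  expect_equal(r2$map, 1)               # AP unaffected (TP ranked first)
  expect_equal(r2$per_class$precision, 0.5)
  set.seed(17)
  for (k in 1:5) {
    n_gt <- sample(3:6, 1); n_pr <- sample(4:10, 1)
    gt <- data.frame(image = sample(c("a", "b"), n_gt, TRUE), class = "x",
                     x_min = runif(n_gt, 0, 50), y_min = runif(n_gt, 0, 50))
    gt$x_max <- gt$x_min + runif(n_gt, 10, 40)
    gt$y_max <- gt$y_min + runif(n_gt, 10, 40)
    pr <- data.frame(image = sample(c("a", "b"), n_pr, TRUE), class = "x",
                     x_min = runif(n_pr, 0, 50), y_min = runif(n_pr, 0, 50))
    pr$x_max <- pr$x_min + runif(n_pr, 10, 40)
    pr$y_max <- pr$y_min + runif(n_pr, 10, 40)
    pr$confidence <- runif(n_pr)
    expect_lt(abs(detection_map(pr, gt)$per_class$ap - oracle_ap(pr, gt)),
              1e-9)
  }
})

test_that("mAP is invariant under uniform confidence rescaling", {
  set.seed(18)
  gt <- data.frame(image = "a", class = c("x", "y"),
                   x_min = c(0, 60), y_min = c(0, 60),
                   x_max = c(40, 100), y_max = c(40, 100))
  pr <- data.frame(image = "a", class = c("x", "x", "y"),
                   x_min = c(1, 30, 58), y_min = c(2, 30, 61),
                   x_max = c(41, 70, 99), y_max = c(40, 70, 99),
                   confidence = c(0.9, 0.5, 0.7))
  m1 <- detection_map(pr, gt)$map
  pr$confidence <- pr$confidence * 0.31
  expect_equal(detection_map(pr, gt)$map, m1, tolerance = 1e-12)
  # classes with no ground truth are excluded with a note
  pr2 <- pr; pr2$class[1] <- "ghost"
  expect_message(detection_map(pr2, gt), "absent from ground truth")
})
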