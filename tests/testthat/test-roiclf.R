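# ROI classifier architectures and the risk-vector contract.

test_that("both CNNs map a 256x256 crop to a probability in (0,1)", {
  x <- matrix(runif(256^2), 256, 256)
  for (m in list(build_cnn_a(width_mult = 0.0625, seed = 1),
                 build_cnn_b(seed = 1))) {
    p <- fgscreen:::classifier_predict(m, x)
    expect_gt(p, 0)
    expect_lt(p, 1)
    # eval-mode determinism
    expect_identical(p, fgscreen:::classifier_predict(m, x))
  }
})

test_that("CNN B has exactly 8 weighted layers on the main path", {
  m <- build_cnn_b(seed = 2)
  nms <- ls(m$params)
  main <- grep("^(stem|b[0-9]+\\.c[12]|head)\\.w$", nms, value = TRUE)
  expect_length(main, 8)
  # shortcut projections and CBAM gates are off the main path
  expect_true(any(grepl("\\.sc\\.w$", nms)))
  expect_true(any(grepl("cbam", nms)))
})

test_that("CNN A follows the 3/4/6/3 residual plan with 34 main-path layers", {
  m <- build_cnn_a(width_mult = 0.0625, seed = 2)
  nms <- ls(m$params)
  blocks <- grep("^s[1-4]\\.b[0-9]+\\.c1\\.w$", nms, value = TRUE)
  expect_length(blocks, 16)                       # 3 + 4 + 6 + 3 blocks
  main <- grep("^(stem|s[1-4]\\.b[0-9]+\\.c[12]|head)\\.w$", nms,
               value = TRUE)
  expect_length(main, 34)                         # stem + 32 convs + head
  # parameter count close to the plain residual baseline plus CBAM overhead
  total <- n_parameters(m)
  cbam <- sum(vapply(grep("cbam", nms, value = TRUE), function(nm)
    length(m$params[[nm]]$v), numeric(1)))
  plain <- total - cbam
  expect_lt(cbam / plain, 0.35)
  expect_gt(total / plain, 1)
  expect_lt(abs(total - (plain + cbam)), 1e-9)
  # CNN A is the larger architecture at matched width settings
  expect_gt(n_parameters(build_cnn_a(width_mult = 0.125, seed = 2)),
            3 * n_parameters(build_cnn_b(seed = 2)))
})

test_that("zeroed CBAM gates reduce the block to a 0.25 scaling", {
  m <- build_cnn_b(width = 4, seed = 3)
  for (nm in grep("^cbam\\.(cam1|cam2|sam)\\.w$", ls(m$params),
                  value = TRUE))
    m$params[[nm]]$v[] <- 0
  x <- rand_map(c(16, 8, 8))
  tape <- fgscreen:::ag_tape()
  out <- fgscreen:::cbam_forward(fgscreen:::ag_const(x), m$params, "cbam",
                                 tape)
  expect_equal(out$v, x / 4, tolerance = 1e-12)
})

test_that("training rejects single-class labels and learns a linear probe", {
  cfg <- roi_classifier_config(epochs = 2, seed = 5)
  crops <- lapply(1:12, function(i) matrix(runif(64^2), 64, 64))
  expect_error(train_roi_classifier(build_cnn_b(width = 4, seed = 1),
                                    crops, rep(1, 12), cfg),
               "single-class")
  # a trivially separable brightness signal is learned quickly
  labs <- rep(c(0, 1), 10)
  crops <- lapply(labs, function(l)
    matrix(runif(64^2, 0, 0.3) + 0.55 * l, 64, 64))
  cfg$augment <- FALSE
  m <- train_roi_classifier(build_cnn_b(width = 4, seed = 6), crops, labs,
                            cfg)
  pr <- vapply(crops, function(cr) fgscreen:::classifier_predict(m, cr),
               numeric(1))
  expect_gt(roc_auc(pr, labs)$auc, 0.95)
  expect_lt(tail(m$log$epoch_loss, 1), m$log$epoch_loss[1])
})

test_that("predict_risk honors missing crops and the risk-class order", {
  models <- stats::setNames(lapply(risk_classes(), function(cl)
    build_cnn_b(width = 4, seed = 7)), risk_classes())
  crops <- stats::setNames(vector("list", 6), risk_classes())
  rv <- predict_risk(models, crops)
  expect_s3_class(rv, "fg_risk_vector")
  expect_true(all(rv$missing_mask))
  expect_true(all(is.na(rv$s)))
  crops$NT <- matrix(runif(256^2), 256, 256)
  rv2 <- predict_risk(models, crops)
  expect_false(rv2$missing_mask[["NT"]])
  expect_true(rv2$s[["NT"]] > 0 && rv2$s[["NT"]] < 1)
  expect_equal(names(rv2$s), risk_classes())
})

test_that("the classifier config validates the ROI assignment", {
  expect_error(roi_classifier_config(roi_assignment = c(NT = "cnn_b")),
               "6 risk classes")
  expect_error(roi_classifier_config(
    roi_assignment = stats::setNames(rep("mlp", 6), risk_classes())),
    "cnn_a or cnn_b")
})
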