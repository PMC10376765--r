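# Detector unit behavior: head geometry, NMS, thresholds, crop selection,
# coordinate round trips. (Training-quality properties live in the
# acceptance tests, which share the session's trained study.)

test_that("tiny config heads have stride-derived shapes and channel counts", {
  cfg <- detector_config(input_size = 320)
  m <- build_detector(cfg)
  tape <- fgscreen:::ag_tape()
  heads <- fgscreen:::detector_forward(m, array(0.5, c(1, 320, 320)), tape)
  sizes <- vapply(heads, function(h) dim(h$v)[2], numeric(1))
  expect_equal(sizes, c(40, 20, 10))
  chans <- vapply(heads, function(h) dim(h$v)[1], numeric(1))
  expect_equal(chans, rep(3 * (5 + 7), 3))   # anchors x (5 + classes)
  expect_error(detector_config(pyramid_levels = 4))
  # five-level variant builds and adds strides 64/128
  m5 <- build_detector(detector_config(input_size = 128, pyramid_levels = 5))
  h5 <- fgscreen:::detector_forward(m5, array(0.5, c(1, 128, 128)),
                                    fgscreen:::ag_tape())
  expect_equal(vapply(h5, function(h) dim(h$v)[2], numeric(1)),
               c(16, 8, 4, 2, 1))
})

test_that("forward pass is deterministic and fusion weights stay non-negative", {
  m <- build_detector(detector_config(seed = 3))
  x <- array(runif(128^2), c(1, 128, 128))
  h1 <- fgscreen:::detector_forward(m, x, fgscreen:::ag_tape())[[1]]$v
  h2 <- fgscreen:::detector_forward(m, x, fgscreen:::ag_tape())[[1]]$v
  expect_identical(h1, h2)
  fw <- detector_fusion_weights(m)
  expect_gt(length(fw), 0)
  expect_true(all(unlist(fw) >= 0))
})

test_that("confidence threshold 1 yields no detections; untrained needs a flag", {
  m <- build_detector(detector_config(seed = 4))
  img <- matrix(runif(200^2), 200, 200)
  expect_error(detect_rois(m, img), "untrained")
  det <- detect_rois(m, img, conf_threshold = 1, allow_untrained = TRUE)
  expect_equal(nrow(det), 0)
})

test_that("NMS suppresses duplicates, keeps order deterministic, idempotent", {
  det <- data.frame(class = "NT",
                    x_min = c(10, 11, 80), y_min = c(10, 11, 80),
                    x_max = c(50, 51, 120), y_max = c(50, 51, 120),
                    confidence = c(0.9, 0.7, 0.6))
  out <- fgscreen:::nms_boxes(det, 0.45)
  expect_equal(nrow(out), 2)
  expect_equal(out$confidence, c(0.9, 0.6))
  # two identical boxes, same class: one survives
  dup <- det[c(1, 1), ]; dup$confidence <- c(0.8, 0.8)
  expect_equal(nrow(fgscreen:::nms_boxes(dup, 0.45)), 1)
  # idempotence
  expect_equal(fgscreen:::nms_boxes(out, 0.45), out)
  # equal confidences: lowest x_min wins
  tie <- data.frame(class = "NT", x_min = c(30, 5), y_min = c(10, 10),
                    x_max = c(70, 45), y_max = c(50, 50),
                    confidence = c(0.5, 0.5))
  kept <- fgscreen:::nms_boxes(tie, 0.2)
  expect_equal(kept$x_min[1], 5)
})

test_that("anchor assignment targets the box's cell and respects the gate", {
  cfg <- detector_config()
  b <- data.frame(class = "NT", x_min = 40, y_min = 56, x_max = 68,
                  y_max = 76)
  a <- fgscreen:::assign_anchors(b, cfg)
  expect_gte(nrow(a), 1)
  expect_equal(unname(a[1, "cls"]), match("NT", roi_classes()))
  stride <- cfg$strides[a[1, "level"]]
  expect_equal(unname(a[1, "gi"]), floor(54 / stride))
  expect_equal(unname(a[1, "gj"]), floor(66 / stride))
  # background image: no assignment
  expect_null(fgscreen:::assign_anchors(b[0, ], cfg))
})

test_that("select_roi_crops keeps top confidence, drops D, flags missing", {
  img <- matrix(runif(300^2), 300, 300)
  det <- data.frame(class = c("Chin", "Chin", "D", "NT"),
                    x_min = c(10, 150, 50, 200), y_min = c(10, 150, 50, 200),
                    x_max = c(80, 220, 120, 280), y_max = c(80, 220, 120, 280),
                    confidence = c(0.9, 0.7, 0.95, 0.6))
  crops <- select_roi_crops(img, det, crop_size = 64)
  expect_named(crops, risk_classes())
  expect_false("D" %in% names(crops))
  miss <- attr(crops, "missing")
  expect_false(miss[["Chin"]])
  expect_false(miss[["NT"]])
  expect_true(miss[["head1"]])
  expect_null(crops[["head1"]])
  expect_equal(dim(crops$Chin), c(64, 64))
  # the 0.9 Chin box (10..80) is the one cropped: reconstruct directly
  ref <- letterbox(img[11:80, 11:80], 64)$image
  expect_equal(crops$Chin, ref)
})

test_that("empty datasets and all-background data are rejected", {
  sp <- phantom_spec(image_size = 128, seed = 1)
  man <- generate_dataset(sp, 2, out_dir = NULL, write_images = FALSE,
                          splits = c(train = 1))
  man$ids <- character(0)
  m <- build_detector(detector_config(epochs = 1))
  expect_error(train_detector(m, man), "empty dataset")
})
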