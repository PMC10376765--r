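# The synthetic phantom generator: determinism, planted-signal geometry,
# box-layout constraints, and the dataset writer.

test_that("a (seed, index) pair fully determines a phantom", {
  sp <- phantom_spec(image_size = 256, seed = 7)
  p1 <- generate_phantom(sp, 3)
  p2 <- generate_phantom(sp, 3)
  expect_identical(p1$pixels, p2$pixels)
  expect_identical(p1$boxes, p2$boxes)
  expect_identical(p1$label, p2$label)
  p3 <- generate_phantom(sp, 4)
  expect_false(identical(p1$pixels, p3$pixels))
})

test_that("the noise-free limit is piecewise constant with measurable bands", {
  sp <- phantom_spec(image_size = 256, speckle_variance = 0,
                     illumination_amplitude = 0, seed = 3)
  p <- generate_phantom(sp, 0)
  # piecewise constant: a handful of distinct gray levels only
  expect_lte(length(unique(as.numeric(p$pixels))), 16)
  # the recorded mask reproduces the planted band thickness (pixel-exact)
  m <- p$meta$masks$NT
  cols <- colSums(m)
  measured <- mean(cols[cols > 0])
  expect_equal(measured, p$meta$truth$nt_thickness_px, tolerance = 1.0)
})

test_that("positive/negative NT thickness ratio matches the planted effect", {
  r <- fgscreen:::nt_thickness_ratio(202, n = 200)
  expect_equal(r, 1.5, tolerance = 0.05)
})

test_that("boxes stay inside bounds with pairwise IoU below 0.3", {
  sp <- phantom_spec(image_size = 64, seed = 12)
  worst <- 0
  for (i in seq_len(1000)) {
    p <- generate_phantom(sp, i)
    b <- p$boxes
    expect_true(all(b$x_min < b$x_max & b$y_min < b$y_max))
    expect_true(all(b$x_min >= 0 & b$y_min >= 0 &
                      b$x_max <= 64 & b$y_max <= 64))
    for (j in 1:6) for (k in (j + 1):7) {
      iou <- fgscreen:::box_iou(as.numeric(b[j, 2:5]), as.numeric(b[k, 2:5]))
      worst <- max(worst, iou)
    }
  }
  expect_lt(worst, 0.3)
})

test_that("every phantom carries exactly one box per ROI class", {
  sp <- phantom_spec(image_size = 128, seed = 5)
  p <- generate_phantom(sp, 1)
  expect_setequal(p$boxes$class, roi_classes())
  expect_equal(nrow(p$boxes), 7)
})

test_that("non-signal ROIs are statistically identical across labels", {
  # same (seed, index) with forced labels: only signal ROIs may differ
  sp_pos <- phantom_spec(image_size = 256, speckle_variance = 0,
                         illumination_amplitude = 0, prevalence = 1,
                         seed = 9)
  sp_neg <- phantom_spec(image_size = 256, speckle_variance = 0,
                         illumination_amplitude = 0, prevalence = 0,
                         seed = 9)
  p_pos <- generate_phantom(sp_pos, 2)
  p_neg <- generate_phantom(sp_neg, 2)
  crop <- function(p, cl) {
    b <- p$boxes[p$boxes$class == cl, ]
    p$pixels[(floor(b$y_min) + 1):ceiling(b$y_max),
             (floor(b$x_min) + 1):ceiling(b$x_max)]
  }
  for (cl in c("head1", "head2", "D", "max + mand"))
    expect_identical(crop(p_pos, cl), crop(p_neg, cl))
  expect_false(identical(crop(p_pos, "NT"), crop(p_neg, "NT")))
})

test_that("an empty signal set with positive prevalence warns (unlearnable)", {
  sp <- phantom_spec(image_size = 64, signal_rois = character(0),
                     effect_sizes = numeric(0), prevalence = 0.5, seed = 2)
  expect_warning(generate_phantom(sp, 0), "unlearnable")
})

test_that("generate_dataset writes n images, annotations and a labels CSV", {
  dir <- file.path(tempdir(), "phantom_ds_test")
  unlink(dir, recursive = TRUE)
  sp <- phantom_spec(image_size = 128, seed = 21)
  man <- generate_dataset(sp, 10, dir)
  expect_length(list.files(file.path(dir, "images"), pattern = "\\.png$"), 10)
  expect_length(list.files(file.path(dir, "labels"), pattern = "\\.txt$"), 10)
  csv <- read.csv(file.path(dir, "labels.csv"))
  expect_equal(nrow(csv), 10)
  expect_named(csv, c("image", "label", "split"))
  expect_setequal(unique(csv$split), c("train", "val", "test"))
  # YOLO round trip within 0.5 px
  p <- generate_phantom(sp, 0)
  back <- read_yolo_txt(man$label_files[1], 128, 128)
  expect_lt(max(abs(as.matrix(back[, 2:5]) - as.matrix(p$boxes[, 2:5]))), 0.5)
  expect_error(generate_dataset(sp, 2, dir), "minimum split size")
})

test_that("dataset label frequency matches the prevalence", {
  sp <- phantom_spec(image_size = 64, prevalence = 0.4, seed = 31)
  man <- generate_dataset(sp, 2000, out_dir = NULL, write_images = FALSE)
  # binomial standard error at n = 2000 is about 0.011
  expect_equal(mean(man$labels), 0.4, tolerance = 0.03)
})
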