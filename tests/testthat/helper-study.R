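# The desk-scale evaluation study is expensive (it trains every stage), so
# it runs once per test session and is shared by all tests that need trained
# models.

.study_cache <- new.env(parent = emptyenv())

get_study <- function() {
  if (is.null(.study_cache$res)) {
    dir <- file.path(tempdir(), "fgscreen_study")
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    .study_cache$res <- run_evaluation_study(seed = 1, work_dir = dir,
                                             verbose = FALSE)
  }
  .study_cache$res
}

# a small trained-enough pipeline bundle for fast contract tests
get_tiny_bundle <- function() {
  if (is.null(.study_cache$tiny)) {
    spec <- study_phantom_spec(404, image_size = 256)
    man <- generate_dataset(spec, 8, file.path(tempdir(), "tiny_man"),
                            splits = c(train = 1))
    det <- build_detector(detector_config(epochs = 1, seed = 2))
    det <- train_detector(det, man)
    classifiers <- stats::setNames(lapply(risk_classes(), function(cl)
      { m <- build_cnn_b(width = 4, seed = 3); m$trained <- TRUE; m }),
      risk_classes())
    rvs <- lapply(1:40, function(i) {
      s <- stats::setNames(runif(6), risk_classes())
      structure(list(s = s, missing_mask = stats::setNames(rep(FALSE, 6),
                                                           risk_classes())),
                class = "fg_risk_vector")
    })
    labs <- as.integer(vapply(rvs, function(r) r$s[["NT"]], numeric(1)) > 0.5)
    stacker <- train_fusion(rvs, labs, fusion_config(n_trees = 20, seed = 4))
    .study_cache$tiny <- list(detector = det, classifiers = classifiers,
                              stacker = stacker, hp = homomorphic_params(),
                              crop_size = 256, man = man)
  }
  .study_cache$tiny
}
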