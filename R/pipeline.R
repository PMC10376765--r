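# End-to-end orchestration of the three-stage ensemble:
# homomorphic filter -> ROI detection (Network A) -> per-ROI risk estimation
# (Network B) -> gradient-boosted stacking (Network C), with optional
# Grad-CAM heatmaps. Also the desk-scale study harness used by the
# evaluation scripts: fit all three stages on a phantom dataset with the
# out-of-fold protocol (classifiers on the training split, stacker on
# detector-derived risk vectors from the validation split).

#' Run the full screening pipeline on one image
#'
#' @param image Grayscale matrix in \[0, 1\] (raw, unfiltered).
#' @param bundle Model bundle from [fit_pipeline()] (or a list with
#'   `detector`, `classifiers`, `stacker`, optional `hp`).
#' @param explain Compute Grad-CAM heatmaps for the detected risk ROIs.
#' @param explain_rois Risk classes to explain when `explain = TRUE`.
#' @return A `fg_prediction`: final `probability`, the `risk_vector`, the
#'   `detections`, optional `heatmaps`, and a `meta` flag when the detector
#'   returned nothing.
#' @export
run_pipeline <- function(image, bundle, explain = FALSE,
                         explain_rois = "NT") {
  hp <- bundle$hp %||% homomorphic_params()
  filt <- homomorphic_filter(image, hp)
  det <- detect_rois(bundle$detector, filt)
  crops <- select_roi_crops(filt, det, bundle$crop_size %||% 256)
  rv <- predict_risk(bundle$classifiers, crops)
  heat <- NULL
  if (explain) {
    heat <- list()
    for (cl in intersect(explain_rois, risk_classes()))
      if (!is.null(crops[[cl]]) && !is.null(bundle$classifiers[[cl]]))
        heat[[cl]] <- grad_cam(bundle$classifiers[[cl]], crops[[cl]])
  }
  pred <- predict_disorder(bundle$stacker, rv, detections = det,
                           heatmaps = heat)
  pred$meta <- list(no_detections = nrow(det) == 0)
  pred
}

# detector-derived risk vectors for every image of a manifest
pipeline_risk_vectors <- function(detector, classifiers, man,
                                  hp = homomorphic_params(),
                                  crop_size = 256) {
  lapply(seq_along(man$ids), function(i) {
    img <- manifest_image(man, i)
    filt <- homomorphic_filter(img$pixels, hp)
    det <- detect_rois(detector, filt)
    crops <- select_roi_crops(filt, det, crop_size)
    predict_risk(classifiers, crops)
  })
}

#' Fit the full three-stage pipeline on phantom manifests
#'
#' Trains the detector on the training split, each per-ROI classifier on its
#' ground-truth training crops (validation crops for checkpointing), then the
#' stacker on detector-derived risk vectors from the validation split — the
#' out-of-fold protocol that keeps the stacker honest.
#'
#' @param train_man,val_man Manifests from [generate_dataset()].
#' @param det_config,clf_config,fus_config Stage configurations.
#' @param epochs_by_class Optional named list overriding classifier epochs
#'   per risk class (used to spend less compute on no-signal ROIs).
#' @param val_cap Maximum validation images used for classifier
#'   checkpointing.
#' @param verbose Log stage progress.
#' @return Bundle list: `detector`, `classifiers`, `stacker`, `hp`,
#'   `val_risk_vectors`, `configs`.
#' @export
fit_pipeline <- function(train_man, val_man,
                         det_config = detector_config(),
                         clf_config = roi_classifier_config(),
                         fus_config = fusion_config(),
                         epochs_by_class = NULL, val_cap = 100L,
                         verbose = FALSE) {
  hp <- homomorphic_params()
  if (verbose) log_stage("pipeline", "training detector")
  detector <- build_detector(det_config)
  detector <- train_detector(detector, train_man, val_man = NULL,
                             verbose = verbose)
  if (verbose) log_stage("pipeline", "extracting training crops")
  crops <- gt_roi_crops(train_man, crop_size = clf_config$input_size, hp = hp)
  vidx <- seq_len(min(val_cap, length(val_man$ids)))
  vman <- val_man
  vman$ids <- vman$ids[vidx]
  if (!is.null(vman$image_files)) {
    vman$image_files <- vman$image_files[vidx]
    vman$label_files <- vman$label_files[vidx]
  }
  if (!is.null(vman$images)) vman$images <- vman$images[vidx]
  vman$labels <- vman$labels[vidx]
  vcrops <- gt_roi_crops(vman, crop_size = clf_config$input_size, hp = hp)
  classifiers <- list()
  for (cl in risk_classes()) {
    arch <- clf_config$roi_assignment[[cl]]
    cfg <- clf_config
    if (!is.null(epochs_by_class[[cl]])) cfg$epochs <- epochs_by_class[[cl]]
    if (verbose) log_stage("pipeline", sprintf("training %s (%s, %d epochs)",
                                               cl, arch, cfg$epochs))
    model <- if (arch == "cnn_a")
      build_cnn_a(clf_config$width_mult, seed = cfg$seed) else
      build_cnn_b(clf_config$cnn_b_width, seed = cfg$seed)
    classifiers[[cl]] <- train_roi_classifier(
      model, crops[[cl]], train_man$labels, cfg,
      val_crops = vcrops[[cl]], val_labels = vman$labels)
  }
  if (verbose) log_stage("pipeline", "stacking on validation risk vectors")
  val_rvs <- pipeline_risk_vectors(detector, classifiers, val_man, hp,
                                   clf_config$input_size)
  stacker <- train_fusion(val_rvs, val_man$labels, fus_config)
  list(detector = detector, classifiers = classifiers, stacker = stacker,
       hp = hp, crop_size = clf_config$input_size,
       val_risk_vectors = val_rvs,
       configs = list(detector = det_config, roiclf = clf_config,
                      fusion = fus_config))
}

#' Evaluate the fitted pipeline on a held-out manifest
#'
#' @param bundle From [fit_pipeline()].
#' @param man Test manifest.
#' @return List with end-to-end `auc`, `probabilities`, `labels`,
#'   `risk_vectors`, and `per_roi_auc` computed from the detector-derived
#'   risk vectors.
#' @export
evaluate_pipeline <- function(bundle, man) {
  rvs <- pipeline_risk_vectors(bundle$detector, bundle$classifiers, man,
                               bundle$hp, bundle$crop_size)
  p <- predict_disorder(bundle$stacker, rvs)
  auc <- roc_auc(p, man$labels)$auc
  per_roi <- vapply(risk_classes(), function(cl) {
    s <- vapply(rvs, function(rv) rv$s[[cl]], numeric(1))
    ok <- !is.na(s)
    if (length(unique(man$labels[ok])) < 2) return(NA_real_)
    roc_auc(s[ok], man$labels[ok])$auc
  }, numeric(1))
  list(auc = auc, probabilities = p, labels = man$labels,
       risk_vectors = rvs, per_roi_auc = per_roi)
}

#' Save / load a fitted model bundle
#'
#' Parameter stores are environments, so bundles are flattened to plain
#' lists of arrays before serialization.
#'
#' @param bundle From [fit_pipeline()].
#' @param path File path (`.rds`).
#' @return `load_bundle()` returns the restored bundle.
#' @export
save_bundle <- function(bundle, path) {
  strip <- function(model) {
    if (is.null(model$params)) return(model)
    model$params <- lapply(params_list(model$params), function(p) p$v)
    model
  }
  out <- bundle
  out$detector <- strip(out$detector)
  out$classifiers <- lapply(out$classifiers, strip)
  out$stacker$model <- xgboost::xgb.save.raw(out$stacker$model)
  saveRDS(out, path)
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  b <- readRDS(path)
  restore <- function(model) {
    if (is.null(model$params) || is.environment(model$params)) return(model)
    ps <- new_param_store()
    for (nm in names(model$params)) ps[[nm]] <- ag_param(model$params[[nm]])
    model$params <- ps
    model
  }
  b$detector <- restore(b$detector)
  b$classifiers <- lapply(b$classifiers, restore)
  b$stacker$model <- xgboost::xgb.load.raw(b$stacker$model)
  b
}
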