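# Desk-scale evaluation study: the reproducible experiment that exercises
# every stage of the pipeline on synthetic phantoms and reports the
# quantities a practitioner would inspect — detector mAP on an easy set with
# its label-shuffled negative control, per-ROI AUCs (signal vs no-signal),
# the stacked vs best-single-ROI AUC, the end-to-end pipeline AUC, Grad-CAM
# localization fractions, and the preprocessing / phantom-geometry checks.
#
# Problem sizes are the package's desk-scale defaults (a single-CPU run):
# 280/100/160 phantoms for the main study, 200/50 for the easy detector
# study. The study spec plants signal in two ROIs (NT band thickness x1.5,
# nasal-bone streak dimmed to 0.4), leaving the others label-free.

study_sub_seed <- function(seed, k) {
  as.integer((as.double(seed) * 2654435761 + k * 97) %% 2147483629) + 1L
}

#' The 2-signal-ROI phantom specification of the evaluation study
#'
#' @param seed Integer seed.
#' @param ... Overrides forwarded to [phantom_spec()].
#' @return A `fg_phantom_spec`.
#' @export
study_phantom_spec <- function(seed, ...) {
  phantom_spec(signal_rois = c("NT", "NA + NB"),
               effect_sizes = c(NT = 1.5, `NA + NB` = 0.4), seed = seed, ...)
}

# a manifest whose annotation files are decoupled from their images
shuffle_manifest_labels <- function(man, seed) {
  perm <- with_seed_fast(seed, function() sample(length(man$ids)))
  if (!is.null(man$label_files)) man$label_files <- man$label_files[perm]
  if (!is.null(man$images)) {
    orig <- man$images
    for (i in seq_along(orig)) man$images[[i]]$boxes <- orig[[perm[i]]]$boxes
  }
  man
}

#' Run the full desk-scale evaluation study
#'
#' Generates the phantom datasets, trains the easy-set detector with its
#' label-shuffled negative control, fits the full three-stage pipeline on the
#' main (noisy) study, and measures all headline quantities. Everything is
#' deterministic in `seed`.
#'
#' @param seed Integer master seed.
#' @param work_dir Directory for the generated datasets.
#' @param n_train,n_val,n_test Main-study split sizes.
#' @param n_easy,n_easy_test Easy detector-study sizes.
#' @param verbose Log progress.
#' @return Named list of measured quantities plus the fitted `bundle`.
#' @export
run_evaluation_study <- function(seed = 1, work_dir = tempdir(),
                                 n_train = 280, n_val = 100, n_test = 160,
                                 n_easy = 200, n_easy_test = 50,
                                 verbose = TRUE) {
  res <- list()

  ## ---- easy detector study with label-shuffled control -------------------
  easy_spec <- study_phantom_spec(study_sub_seed(seed, 1),
                                  speckle_variance = 0,
                                  illumination_amplitude = 0)
  if (verbose) log_stage("study", "generating easy detector sets")
  man_e <- generate_dataset(easy_spec, n_easy,
                            file.path(work_dir, "easy_train"),
                            splits = c(train = 1))
  man_et <- generate_dataset(
    study_phantom_spec(study_sub_seed(seed, 2), speckle_variance = 0,
                       illumination_amplitude = 0),
    n_easy_test, file.path(work_dir, "easy_test"), splits = c(test = 1))
  dcfg <- detector_config(epochs = 20, seed = study_sub_seed(seed, 3))
  if (verbose) log_stage("study", "training easy-set detector")
  det_e <- train_detector(build_detector(dcfg), man_e)
  ev_e <- evaluate_detector(det_e, man_et)
  res$detector_map_easy <- ev_e$map
  res$detector_recall_easy <- mean(ev_e$per_class$recall)
  if (verbose) log_stage("study", sprintf("easy mAP %.3f", ev_e$map))

  if (verbose) log_stage("study", "training label-shuffled control")
  man_s <- shuffle_manifest_labels(man_e, study_sub_seed(seed, 4))
  det_s <- train_detector(build_detector(dcfg), man_s)
  res$detector_map_shuffled <- evaluate_detector(det_s, man_et)$map
  if (verbose) log_stage("study", sprintf("shuffled mAP %.3f",
                                          res$detector_map_shuffled))

  ## ---- main study: full pipeline -----------------------------------------
  if (verbose) log_stage("study", "generating main study sets")
  sp_tr <- study_phantom_spec(study_sub_seed(seed, 5))
  man_tr <- generate_dataset(sp_tr, n_train, file.path(work_dir, "main_train"),
                             splits = c(train = 1))
  man_va <- generate_dataset(study_phantom_spec(study_sub_seed(seed, 6)),
                             n_val, file.path(work_dir, "main_val"),
                             splits = c(val = 1))
  man_te <- generate_dataset(study_phantom_spec(study_sub_seed(seed, 7)),
                             n_test, file.path(work_dir, "main_test"),
                             splits = c(test = 1))
  bundle <- fit_pipeline(
    man_tr, man_va,
    det_config = detector_config(epochs = 10,
                                 seed = study_sub_seed(seed, 8)),
    clf_config = roi_classifier_config(epochs = 4,
                                       seed = study_sub_seed(seed, 9)),
    fus_config = fusion_config(seed = study_sub_seed(seed, 10)),
    epochs_by_class = list(Chin = 2, head2 = 2, `max + mand` = 2,
                           `NA + NB` = 5),
    verbose = verbose)
  ev <- evaluate_pipeline(bundle, man_te)
  res$end_to_end_auc <- ev$auc
  res$auc_nt <- ev$per_roi_auc[["NT"]]
  res$auc_nasal <- ev$per_roi_auc[["NA + NB"]]
  res$auc_nonsignal_head1 <- ev$per_roi_auc[["head1"]]
  res$max_single_roi_auc <- max(ev$per_roi_auc, na.rm = TRUE)
  res$stacked_auc <- ev$auc
  res$stacked_gain <- ev$auc - res$max_single_roi_auc
  if (verbose) log_stage("study", sprintf(
    "end-to-end AUC %.3f (best single ROI %.3f)", ev$auc,
    res$max_single_roi_auc))

  ## ---- Grad-CAM localization ---------------------------------------------
  if (verbose) log_stage("study", "Grad-CAM localization")
  res$gradcam_quadrant_fraction <- gradcam_quadrant_oracle()
  nt_loc <- gradcam_nt_localization(bundle, study_sub_seed(seed, 11),
                                    n_pos = 20)
  res$gradcam_nt_inband_fraction <- nt_loc$inband_fraction
  res$gradcam_nt_band_area_fraction <- nt_loc$band_area_fraction
  res$gradcam_nt_ratio <- nt_loc$inband_fraction / nt_loc$band_area_fraction

  ## ---- phantom and preprocessing oracles ---------------------------------
  res$nt_thickness_ratio <- nt_thickness_ratio(study_sub_seed(seed, 12),
                                               n = 200)
  res$homomorphic_gain_rate <- homomorphic_gain_rate(study_sub_seed(seed, 13),
                                                     n = 50)
  res$label_prevalence <- mean(c(man_tr$labels, man_va$labels, man_te$labels))
  res$bundle <- bundle
  res
}

# constructed-model oracle: the logit is the mean of one fixed image
# quadrant, realized as a fixed spatial mask followed by a convolution, so
# the Grad-CAM map must concentrate in that quadrant
gradcam_quadrant_oracle <- function(size = 64) {
  mask <- array(0, c(1, size, size))
  mask[1, seq_len(size / 2), seq_len(size / 2)] <- 1   # top-left quadrant
  kern <- matrix(0, 1, 9); kern[1, 5] <- 1             # identity 3x3 conv
  model <- list(forward = function(x_arr, tape) {
    xn <- ag_const(x_arr)
    masked <- ag_mul_const(xn, mask, tape)
    conv <- ag_conv(masked, ag_param(kern), ag_param(0), 3, 3, 1, 1, tape)
    logit <- ag_sum(conv, tape)
    list(logit = logit, prob = plogis(logit$v), layers = list(last_conv = conv))
  })
  crop <- with_seed_fast(99L, function()
    matrix(runif(size^2, 0.2, 1), size, size))
  hm <- grad_cam(model, crop)$values
  sum(hm[seq_len(size / 2), seq_len(size / 2)]) / sum(hm)
}

# Grad-CAM mass of the trained NT classifier inside the planted band, on
# fresh positive phantoms (uses the generator's hidden band masks)
gradcam_nt_localization <- function(bundle, seed, n_pos = 20) {
  spec <- study_phantom_spec(seed, prevalence = 1)
  inband <- numeric(n_pos); area <- numeric(n_pos)
  for (i in seq_len(n_pos)) {
    ph <- generate_phantom(spec, i)
    filt <- homomorphic_filter(ph$pixels, bundle$hp)
    b <- ph$boxes[ph$boxes$class == "NT", ]
    r <- (floor(b$y_min) + 1L):ceiling(b$y_max)
    cc <- (floor(b$x_min) + 1L):ceiling(b$x_max)
    lb <- letterbox(filt[r, cc], bundle$crop_size)
    mlb <- letterbox(ph$meta$masks$NT[r, cc] + 0, bundle$crop_size, fill = 0)
    band <- mlb$image > 0.5
    hm <- grad_cam(bundle$classifiers$NT, lb$image)$values
    tot <- sum(hm)
    inband[i] <- if (tot > 0) sum(hm[band]) / tot else 0
    area[i] <- mean(band)
  }
  list(inband_fraction = mean(inband), band_area_fraction = mean(area))
}

# planted-band oracle: measure NT band thickness from the recorded noise-free
# masks and compare positives to negatives (expected ratio = the effect size)
nt_thickness_ratio <- function(seed, n = 200) {
  spec <- phantom_spec(signal_rois = "NT", effect_sizes = c(NT = 1.5),
                       speckle_variance = 0, illumination_amplitude = 0,
                       prevalence = 0.5, seed = seed)
  th <- numeric(n); lab <- integer(n)
  for (i in seq_len(n)) {
    ph <- generate_phantom(spec, i)
    m <- ph$meta$masks$NT
    cols <- colSums(m)
    th[i] <- mean(cols[cols > 0])
    lab[i] <- ph$label
  }
  mean(th[lab == 1]) / mean(th[lab == 0])
}

# homomorphic-filter oracle: reflectance x smooth illumination; the filter
# should increase the correlation with the true reflectance
homomorphic_gain_rate <- function(seed, n = 50, size = 128) {
  with_seed_fast(seed, function() {
    wins <- logical(n)
    xs <- (seq_len(size) - 0.5) / size
    for (i in seq_len(n)) {
      refl <- 0.2 + 0.6 * (matrix(runif(size^2), size) > 0.6)
      refl <- .gauss_blur(refl, 1)
      fx <- runif(1, 0.4, 1); fy <- runif(1, 0.4, 1); ph <- runif(1, 0, 2 * pi)
      illum <- 1 + 0.5 * cos(outer(2 * pi * fy * xs, 2 * pi * fx * xs, "+") +
                               ph)
      img <- pmin(pmax(refl * illum / 1.5, 0), 1)
      filt <- homomorphic_filter(img)
      wins[i] <- cor(as.numeric(filt), as.numeric(refl)) >
        cor(as.numeric(img), as.numeric(refl))
    }
    mean(wins)
  })
}
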