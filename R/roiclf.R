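# Network B: per-ROI risk classifiers.
#
# Two residual CNN architectures, both with CBAM attention and a single
# sigmoid-logit head on 256x256 grayscale crops:
#   CNN A -- 34 weighted layers on the main path (7x7 stem, residual stages
#            of 3/4/6/3 two-conv blocks, CBAM after each stage), for ROIs
#            with complex disease information (chin, nose/jaw, cranium);
#   CNN B -- 8 weighted layers (7x7 stem, 3 two-conv residual blocks, one
#            CBAM before pooling), for simple markers such as NT thickness.
# The second conv of every residual block is zero-initialized so the network
# starts near an identity chain, which keeps the deep plain-trained (no batch
# normalization) stack optimizable.

#' ROI classifier configuration
#'
#' @param roi_assignment Named character vector mapping each risk class to
#'   `"cnn_a"` or `"cnn_b"`. Default: CNN A for Chin, NA + NB, max + mand and
#'   head2; CNN B for NT and head1 (the cranial-vault and NT markers).
#' @param input_size Crop side in pixels (letterboxed), 256.
#' @param epochs,lr,batch_size Training schedule.
#' @param width_mult Channel multiplier for CNN A (base plan 64/128/256/512).
#' @param cnn_b_width Stem width of CNN B.
#' @param augment Apply Trivial Augment to training crops.
#' @param seed Integer seed.
#' @return Validated config list.
#' @export
roi_classifier_config <- function(
    roi_assignment = c(Chin = "cnn_a", `NA + NB` = "cnn_a",
                       `max + mand` = "cnn_a", head2 = "cnn_a",
                       NT = "cnn_b", head1 = "cnn_b"),
    input_size = 256, epochs = 6, lr = 1e-3, batch_size = 8,
    width_mult = 0.0625, cnn_b_width = 8, augment = TRUE, seed = 1L) {
  if (!setequal(names(roi_assignment), risk_classes()))
    stop("roi_assignment must cover exactly the 6 risk classes")
  if (!all(roi_assignment %in% c("cnn_a", "cnn_b")))
    stop("arch must be cnn_a or cnn_b")
  list(roi_assignment = roi_assignment, input_size = as.integer(input_size),
       epochs = epochs, lr = lr, batch_size = batch_size,
       width_mult = width_mult, cnn_b_width = cnn_b_width,
       augment = augment, seed = as.integer(seed))
}

add_resblock_params <- function(ps, name, cin, cout, stride) {
  add_conv_param(ps, paste0(name, ".c1"), cout, cin)
  add_conv_param(ps, paste0(name, ".c2"), cout, cout, zero = TRUE)
  if (stride != 1 || cin != cout)
    add_conv_param(ps, paste0(name, ".sc"), cout, cin, 1, 1)
  invisible(NULL)
}

add_cbam_params <- function(ps, name, channels, reduction = 16) {
  cr <- max(1L, as.integer(channels / reduction))
  add_fc_param(ps, paste0(name, ".cam1"), cr, channels)
  add_fc_param(ps, paste0(name, ".cam2"), channels, cr)
  add_fc_param(ps, paste0(name, ".sam"), channels, channels)
  invisible(NULL)
}

resblock_forward <- function(x, ps, name, tape, stride = 1) {
  h <- ag_lrelu(ag_conv(x, ps[[paste0(name, ".c1.w")]],
                       ps[[paste0(name, ".c1.b")]], 3, 3, stride, 1, tape),
               tape)
  h <- ag_conv(h, ps[[paste0(name, ".c2.w")]], ps[[paste0(name, ".c2.b")]],
               3, 3, 1, 1, tape)
  sc <- if (!is.null(ps[[paste0(name, ".sc.w")]]))
    ag_conv(x, ps[[paste0(name, ".sc.w")]], ps[[paste0(name, ".sc.b")]],
            1, 1, stride, 0, tape) else x
  ag_lrelu(ag_add(sc, h, tape), tape)
}

cbam_forward <- function(x, ps, name, tape) {
  m <- ag_gap(x, tape)
  h <- ag_relu(ag_fc(m, ps[[paste0(name, ".cam1.w")]],
                     ps[[paste0(name, ".cam1.b")]], tape), tape)
  ac <- ag_sigmoid(ag_fc(h, ps[[paste0(name, ".cam2.w")]],
                         ps[[paste0(name, ".cam2.b")]], tape), tape)
  xc <- ag_scale_channels(x, ac, tape)
  mx <- ag_gmp(xc, tape)
  as_ <- ag_sigmoid(ag_fc(mx, ps[[paste0(name, ".sam.w")]],
                          ps[[paste0(name, ".sam.b")]], tape), tape)
  ag_scale_channels(xc, as_, tape)
}

#' Build CNN A: 34-layer residual network with CBAM
#'
#' Stages of 3/4/6/3 two-conv residual blocks (34 weighted layers on the main
#' path including the 7x7 stem and the final fully connected head), CBAM
#' appended after each stage, global average pooling and a single sigmoid
#' logit.
#'
#' @param width_mult Channel multiplier on the 64/128/256/512 plan.
#' @param seed Integer seed for initialization.
#' @return Object of class `fg_classifier`.
#' @export
build_cnn_a <- function(width_mult = 0.125, seed = 1L) {
  withr::with_seed(seed, {
    ps <- new_param_store()
    w <- pmax(4L, as.integer(round(c(64, 128, 256, 512) * width_mult)))
    add_conv_param(ps, "stem", w[1], 1, 7, 7)
    plan <- list(c(3, w[1], 1), c(4, w[2], 2), c(6, w[3], 2), c(3, w[4], 2))
    cin <- w[1]
    for (s in seq_along(plan)) {
      nb <- plan[[s]][1]; cout <- plan[[s]][2]; stride <- plan[[s]][3]
      for (b in seq_len(nb)) {
        add_resblock_params(ps, sprintf("s%d.b%d", s, b), cin, cout,
                            if (b == 1) stride else 1)
        cin <- cout
      }
      add_cbam_params(ps, sprintf("s%d.cbam", s), cout)
    }
    add_fc_param(ps, "head", 1, w[4])
    structure(list(arch = "cnn_a", params = ps, widths = w,
                   plan = plan, trained = FALSE),
              class = "fg_classifier")
  })
}

#' Build CNN B: 8-layer residual network with CBAM
#'
#' 7x7 stem, three two-conv residual blocks (each halving resolution), one
#' CBAM before pooling, global average pooling and a single sigmoid logit:
#' exactly 8 weighted conv/fc layers on the main path.
#'
#' @param width Stem channel width (doubling over the blocks).
#' @param seed Integer seed for initialization.
#' @return Object of class `fg_classifier`.
#' @export
build_cnn_b <- function(width = 8, seed = 1L) {
  withr::with_seed(seed, {
    ps <- new_param_store()
    w <- as.integer(width)
    add_conv_param(ps, "stem", w, 1, 7, 7)
    add_resblock_params(ps, "b1", w, 2L * w, 2)
    add_resblock_params(ps, "b2", 2L * w, 4L * w, 2)
    add_resblock_params(ps, "b3", 4L * w, 4L * w, 2)
    add_cbam_params(ps, "cbam", 4L * w)
    add_fc_param(ps, "head", 1, 4L * w)
    structure(list(arch = "cnn_b", params = ps, width = w, trained = FALSE),
              class = "fg_classifier")
  })
}

# forward pass; record = TRUE also returns the named intermediate layers
classifier_forward <- function(model, x_arr, tape, record = FALSE) {
  if (!is.null(model$forward)) return(model$forward(x_arr, tape))
  ps <- model$params
  x <- ag_const(x_arr)
  h <- ag_lrelu(ag_conv(x, ps[["stem.w"]], ps[["stem.b"]], 7, 7, 2, 3, tape),
               tape)
  h <- ag_maxpool2(h, tape)
  layers <- list()
  if (model$arch == "cnn_a") {
    for (s in seq_along(model$plan)) {
      nb <- model$plan[[s]][1]; stride <- model$plan[[s]][3]
      for (b in seq_len(nb))
        h <- resblock_forward(h, ps, sprintf("s%d.b%d", s, b), tape,
                              if (b == 1) stride else 1)
      h <- cbam_forward(h, ps, sprintf("s%d.cbam", s), tape)
      layers[[sprintf("stage%d", s)]] <- h
    }
  } else {
    for (b in 1:3) {
      h <- resblock_forward(h, ps, paste0("b", b), tape, 2)
      layers[[paste0("block", b)]] <- h
    }
    h <- cbam_forward(h, ps, "cbam", tape)
    layers[["cbam"]] <- h
  }
  layers[["last_conv"]] <- h
  pooled <- ag_gap(h, tape)
  logit <- ag_fc(pooled, ps[["head.w"]], ps[["head.b"]], tape)
  res <- list(logit = logit, prob = plogis(logit$v[1]))
  if (record) res$layers <- layers
  res
}

#' Count the trainable parameters of a model
#'
#' @param model An `fg_classifier` or `fg_detector`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(params_list(model$params), function(p) length(p$v), numeric(1)))
}

classifier_predict <- function(model, crop) {
  x <- array(crop, c(1, nrow(crop), ncol(crop)))
  classifier_forward(model, x, ag_tape())$prob
}

#' Train a per-ROI risk classifier
#'
#' Minimizes binary cross-entropy with Adam on letterboxed crops against the
#' image-level disorder label. Batches are sampled 1:1 from the two classes
#' (the positives are the minority in the default prevalence regime), Trivial
#' Augment is applied to training crops only, and the best validation-AUC
#' parameters are kept.
#'
#' @param model From [build_cnn_a()] or [build_cnn_b()].
#' @param crops List of grayscale crop matrices (training).
#' @param labels Binary vector, same length.
#' @param config From [roi_classifier_config()].
#' @param val_crops,val_labels Optional validation set for checkpointing.
#' @return The trained model with a `log` element.
#' @export
train_roi_classifier <- function(model, crops, labels, config,
                                 val_crops = NULL, val_labels = NULL) {
  stopifnot(length(crops) == length(labels))
  labels <- as.integer(labels)
  pos <- which(labels == 1); neg <- which(labels == 0)
  if (!length(pos) || !length(neg))
    stop("single-class training set; need both labels")
  params <- params_list(model$params)
  nb <- config$batch_size
  steps <- max(1L, ceiling(length(crops) / nb))
  epoch_loss <- numeric(config$epochs)
  val_auc <- rep(NA_real_, config$epochs)
  best <- list(auc = -Inf, params = NULL)
  step <- 0L
  withr::with_seed(config$seed + 17L, {
    for (ep in seq_len(config$epochs)) {
      tot <- 0
      for (st in seq_len(steps)) {
        idx <- c(sample(pos, ceiling(nb / 2), replace = TRUE),
                 sample(neg, floor(nb / 2), replace = TRUE))
        ag_zero_grad(params)
        for (i in idx) {
          crop <- crops[[i]]
          if (isTRUE(config$augment)) crop <- trivial_augment(crop)
          x <- array(crop, c(1, nrow(crop), ncol(crop)))
          tape <- ag_tape()
          out <- classifier_forward(model, x, tape)
          loss <- ag_bce_logits(out$logit, labels[i], tape,
                                norm = length(idx))
          ag_backward(loss, tape)
          tot <- tot + loss$v * length(idx)
        }
        step <- step + 1L
        # global-norm clipping keeps the unnormalized deep nets from
        # collapsing to constant output on a bad batch
        adam_step(params, config$lr, step, clip = 5)
      }
      epoch_loss[ep] <- tot / (steps * nb)
      if (!is.null(val_crops) && length(unique(val_labels)) == 2) {
        pr <- vapply(val_crops, function(cr) classifier_predict(model, cr),
                     numeric(1))
        val_auc[ep] <- roc_auc(pr, val_labels)$auc
        if (val_auc[ep] >= best$auc)
          best <- list(auc = val_auc[ep],
                       params = lapply(params, function(p) p$v))
      }
    }
  })
  if (!is.null(best$params))
    for (nm in names(best$params)) model$params[[nm]]$v <- best$params[[nm]]
  model$trained <- TRUE
  model$log <- list(epoch_loss = epoch_loss, val_auc = val_auc,
                    best_val_auc = if (is.finite(best$auc)) best$auc else NA)
  model
}

#' Per-ROI risk vector from trained classifiers
#'
#' Runs each risk class's classifier on its crop; missing crops are flagged
#' in the missing mask (their probability is `NA` until the fusion stage
#' applies its missing policy).
#'
#' @param models Named list of trained `fg_classifier`s over [risk_classes()].
#' @param crops Named crop list from [select_roi_crops()].
#' @return Object of class `fg_risk_vector`: list with `s` (named numeric,
#'   length 6) and `missing_mask`.
#' @export
predict_risk <- function(models, crops) {
  s <- stats::setNames(rep(NA_real_, length(risk_classes())), risk_classes())
  miss <- stats::setNames(rep(TRUE, length(risk_classes())), risk_classes())
  for (cl in risk_classes()) {
    crop <- crops[[cl]]
    if (is.null(crop)) next
    if (is.null(models[[cl]])) next
    s[cl] <- classifier_predict(models[[cl]], crop)
    miss[cl] <- FALSE
  }
  structure(list(s = s, missing_mask = miss), class = "fg_risk_vector")
}

# ---- crop extraction helpers ----------------------------------------------

# ground-truth crops for every risk class of every image in a manifest;
# raw (unletterboxed) crops are cached and letterboxed lazily by the caller
gt_roi_crops <- function(man, classes = risk_classes(), crop_size = 256,
                         hp = homomorphic_params()) {
  out <- stats::setNames(lapply(classes, function(cl)
    vector("list", length(man$ids))), classes)
  for (i in seq_along(man$ids)) {
    img <- manifest_image(man, i)
    filt <- homomorphic_filter(img$pixels, hp)
    for (cl in classes) {
      b <- img$boxes[img$boxes$class == cl, , drop = FALSE]
      if (!nrow(b)) next
      r0 <- max(1L, floor(b$y_min[1]) + 1L)
      r1 <- min(nrow(filt), ceiling(b$y_max[1]))
      c0 <- max(1L, floor(b$x_min[1]) + 1L)
      c1 <- min(ncol(filt), ceiling(b$x_max[1]))
      out[[cl]][[i]] <- letterbox(filt[r0:r1, c0:c1, drop = FALSE],
                                  crop_size)$image
    }
  }
  out
}
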