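# Network A: single-stage anchor-based ROI detector.
#
# Convolutional backbone with strides 8/16/32 (plus 64/128 for the 5-level
# variant), efficient channel attention after the stages feeding the neck, a
# BiFPN fusion neck with fast-normalized weights, and per-level heads
# predicting box offsets, objectness and the 7 class scores for each anchor.
# Trained with CIoU box loss + BCE objectness + BCE class on matched anchors.

#' Detector configuration
#'
#' @param input_size Square model input in pixels (letterboxed).
#' @param pyramid_levels 3 (tiny, strides 8/16/32) or 5 (adds strides 64/128).
#' @param width_mult Multiplier on the backbone channel plan (8/16/32/48/64).
#' @param neck_width BiFPN channel width.
#' @param anchors Optional per-level list of (w, h) matrices in input pixels;
#'   defaults scale with the stride.
#' @param conf_threshold Confidence threshold for [detect_rois()].
#' @param nms_iou Per-class non-maximum-suppression IoU threshold.
#' @param eca_placement Backbone stages that get an ECA block before the neck.
#' @param epochs,lr,batch_size Training schedule.
#' @param seed Integer seed for weight init and data order.
#' @return Validated config list.
#' @export
detector_config <- function(input_size = 128, pyramid_levels = 3,
                            width_mult = 1, neck_width = 16, anchors = NULL,
                            conf_threshold = 0.25, nms_iou = 0.45,
                            eca_placement = c("C3", "C4", "C5"),
                            epochs = 25, lr = 5e-3, batch_size = 4,
                            seed = 1L) {
  stopifnot(pyramid_levels %in% c(3, 5), conf_threshold > 0,
            conf_threshold <= 1, nms_iou > 0, nms_iou < 1,
            input_size %% 32 == 0)
  strides <- c(8, 16, 32, 64, 128)[seq_len(pyramid_levels)]
  if (is.null(anchors)) {
    anchors <- lapply(strides, function(s)
      rbind(c(2.5, 1.8), c(1.8, 2.5), c(3.0, 3.0)) * s)
  }
  if (length(anchors) != pyramid_levels)
    stop("anchors must have one (w,h) matrix per pyramid level")
  list(input_size = as.integer(input_size),
       pyramid_levels = as.integer(pyramid_levels),
       width_mult = width_mult, neck_width = as.integer(neck_width),
       anchors = anchors, strides = strides,
       conf_threshold = conf_threshold, nms_iou = nms_iou,
       eca_placement = eca_placement, epochs = epochs, lr = lr,
       batch_size = batch_size, seed = as.integer(seed),
       n_classes = 7L)
}

new_param_store <- function() new.env(parent = emptyenv())

add_conv_param <- function(ps, name, cout, cin, kh = 3, kw = 3, zero = FALSE) {
  w <- if (zero) matrix(0, cout, cin * kh * kw) else init_conv(cout, cin, kh, kw)
  ps[[paste0(name, ".w")]] <- ag_param(w)
  ps[[paste0(name, ".b")]] <- ag_param(numeric(cout))
  invisible(NULL)
}

add_fc_param <- function(ps, name, nout, nin) {
  ps[[paste0(name, ".w")]] <- ag_param(init_fc(nout, nin))
  ps[[paste0(name, ".b")]] <- ag_param(numeric(nout))
  invisible(NULL)
}

add_eca_params <- function(ps, name, channels, reduction = 4) {
  cr <- max(1L, as.integer(channels / reduction))
  add_fc_param(ps, paste0(name, ".fc1"), cr, channels)
  add_fc_param(ps, paste0(name, ".fc2"), channels, cr)
  ps[[paste0(name, ".gamma")]] <- ag_param(1)
  invisible(NULL)
}

params_list <- function(ps) mget(ls(ps), envir = ps)

conv_lrelu <- function(x, ps, name, tape, stride = 1, k = 3, pad = NULL) {
  pad <- pad %||% ((k - 1) %/% 2)
  h <- ag_conv(x, ps[[paste0(name, ".w")]], ps[[paste0(name, ".b")]],
               k, k, stride, pad, tape)
  ag_lrelu(h, tape)
}

# trainable ECA (printed form): per-channel gate from the pooled vector
eca_forward <- function(x, ps, name, tape) {
  m <- ag_gap(x, tape)
  h <- ag_relu(ag_fc(m, ps[[paste0(name, ".fc1.w")]],
                     ps[[paste0(name, ".fc1.b")]], tape), tape)
  w <- ag_sigmoid(ag_fc(h, ps[[paste0(name, ".fc2.w")]],
                        ps[[paste0(name, ".fc2.b")]], tape), tape)
  y <- ag_scale_channels(x, w, tape)
  ag_scalar_mul(y, ps[[paste0(name, ".gamma")]], tape)
}

#' Build the ROI detector (Network A)
#'
#' @param config From [detector_config()].
#' @return Object of class `fg_detector` with a parameter store and the
#'   architecture metadata.
#' @export
build_detector <- function(config = detector_config()) {
  withr::with_seed(config$seed, {
    ps <- new_param_store()
    wm <- config$width_mult
    wd <- pmax(4L, as.integer(round(c(8, 16, 32, 48, 64) * wm)))
    add_conv_param(ps, "b1", wd[1], 1)
    add_conv_param(ps, "b2", wd[1], wd[1])
    add_conv_param(ps, "b3", wd[2], wd[1])
    add_conv_param(ps, "b4", wd[2], wd[2])
    add_conv_param(ps, "b5", wd[3], wd[2])          # C3, stride 8
    add_conv_param(ps, "b6", wd[4], wd[3])          # C4, stride 16
    add_conv_param(ps, "b7", wd[5], wd[4])          # C5, stride 32
    stage_ch <- c(C3 = wd[3], C4 = wd[4], C5 = wd[5])
    if (config$pyramid_levels == 5) {
      add_conv_param(ps, "b8", wd[5], wd[5])        # C6, stride 64
      add_conv_param(ps, "b9", wd[5], wd[5])        # C7, stride 128
      stage_ch <- c(stage_ch, C6 = wd[5], C7 = wd[5])
    }
    for (st in config$eca_placement)
      if (st %in% names(stage_ch)) add_eca_params(ps, paste0("eca.", st),
                                                  stage_ch[[st]])
    nl <- config$pyramid_levels
    nw <- config$neck_width
    for (l in seq_len(nl)) {
      add_conv_param(ps, paste0("lat", l), nw, stage_ch[[l]], 1, 1)
      if (l < nl) {
        add_conv_param(ps, paste0("td", l), nw, nw)
        ps[[paste0("td", l, ".fw")]] <- ag_param(c(1, 1))
      }
      if (l > 1) {
        nfuse <- if (l < nl) 3 else 2
        add_conv_param(ps, paste0("out", l), nw, nw)
        ps[[paste0("out", l, ".fw")]] <- ag_param(rep(1, nfuse))
      }
      na <- nrow(config$anchors[[l]])
      add_conv_param(ps, paste0("head", l, ".a"), nw, nw)
      add_conv_param(ps, paste0("head", l, ".b"), na * (5 + config$n_classes),
                     nw, 1, 1)
      # low objectness prior: most positions are background
      bb <- ps[[paste0("head", l, ".b.b")]]
      bb$v[(seq_len(na) - 1L) * (5 + config$n_classes) + 5L] <- -3
    }
    structure(list(params = ps, config = config, trained = FALSE),
              class = "fg_detector")
  })
}

# forward pass producing one raw head output node per pyramid level
detector_forward <- function(model, x_arr, tape) {
  ps <- model$params
  cfg <- model$config
  x <- ag_const(x_arr)
  h <- conv_lrelu(x, ps, "b1", tape, stride = 2)
  h <- conv_lrelu(h, ps, "b2", tape)
  h <- conv_lrelu(h, ps, "b3", tape, stride = 2)
  h <- conv_lrelu(h, ps, "b4", tape)
  c3 <- conv_lrelu(h, ps, "b5", tape, stride = 2)
  c4 <- conv_lrelu(c3, ps, "b6", tape, stride = 2)
  c5 <- conv_lrelu(c4, ps, "b7", tape, stride = 2)
  stages <- list(c3, c4, c5)
  if (cfg$pyramid_levels == 5) {
    c6 <- conv_lrelu(c5, ps, "b8", tape, stride = 2)
    c7 <- conv_lrelu(c6, ps, "b9", tape, stride = 2)
    stages <- c(stages, list(c6, c7))
  }
  stage_names <- c("C3", "C4", "C5", "C6", "C7")[seq_along(stages)]
  for (i in seq_along(stages))
    if (stage_names[i] %in% cfg$eca_placement)
      stages[[i]] <- eca_forward(stages[[i]], ps,
                                 paste0("eca.", stage_names[i]), tape)
  nl <- cfg$pyramid_levels
  lat <- lapply(seq_len(nl), function(l)
    ag_conv(stages[[l]], ps[[paste0("lat", l, ".w")]],
            ps[[paste0("lat", l, ".b")]], 1, 1, 1, 0, tape))
  # top-down pass
  p <- vector("list", nl)
  p[[nl]] <- lat[[nl]]
  for (l in seq(nl - 1, 1)) {
    fused <- ag_fusion(list(lat[[l]], ag_resize_up2(p[[l + 1]], tape)),
                       ps[[paste0("td", l, ".fw")]], tape)
    p[[l]] <- ag_lrelu(ag_conv(fused, ps[[paste0("td", l, ".w")]],
                               ps[[paste0("td", l, ".b")]], 3, 3, 1, 1, tape),
                       tape)
  }
  # bottom-up pass
  n <- vector("list", nl)
  n[[1]] <- p[[1]]
  for (l in seq(2, nl)) {
    ins <- if (l < nl) list(lat[[l]], p[[l]], ag_resize_down2(n[[l - 1]], tape))
      else list(lat[[l]], ag_resize_down2(n[[l - 1]], tape))
    fused <- ag_fusion(ins, ps[[paste0("out", l, ".fw")]], tape)
    n[[l]] <- ag_lrelu(ag_conv(fused, ps[[paste0("out", l, ".w")]],
                               ps[[paste0("out", l, ".b")]], 3, 3, 1, 1, tape),
                       tape)
  }
  lapply(seq_len(nl), function(l) {
    hh <- conv_lrelu(n[[l]], ps, paste0("head", l, ".a"), tape)
    ag_conv(hh, ps[[paste0("head", l, ".b.w")]],
            ps[[paste0("head", l, ".b.b")]], 1, 1, 1, 0, tape)
  })
}

#' Projected (non-negative) BiFPN fusion weights of a detector
#'
#' @param model A trained or untrained `fg_detector`.
#' @return Named list of non-negative weight vectors, one per fusion node.
#' @export
detector_fusion_weights <- function(model) {
  nms <- grep("\\.fw$", ls(model$params), value = TRUE)
  out <- lapply(nms, function(nm) pmax(model$params[[nm]]$v, 0))
  names(out) <- sub("\\.fw$", "", nms)
  out
}

# ---- target assignment and loss -------------------------------------------

# 1 - CIoU for boxes given as (cx, cy, w, h)
ciou_loss_box <- function(p, g) {
  pa <- c(p[1] - p[3] / 2, p[2] - p[4] / 2, p[1] + p[3] / 2, p[2] + p[4] / 2)
  ga <- c(g[1] - g[3] / 2, g[2] - g[4] / 2, g[1] + g[3] / 2, g[2] + g[4] / 2)
  iw <- max(0, min(pa[3], ga[3]) - max(pa[1], ga[1]))
  ih <- max(0, min(pa[4], ga[4]) - max(pa[2], ga[2]))
  inter <- iw * ih
  union <- p[3] * p[4] + g[3] * g[4] - inter
  iou <- if (union <= 0) 0 else inter / union
  cw <- max(pa[3], ga[3]) - min(pa[1], ga[1])
  ch <- max(pa[4], ga[4]) - min(pa[2], ga[2])
  c2 <- cw^2 + ch^2 + 1e-9
  rho2 <- (p[1] - g[1])^2 + (p[2] - g[2])^2
  v <- 4 / pi^2 * (atan(g[3] / g[4]) - atan(p[3] / p[4]))^2
  alpha <- v / (1 - iou + v + 1e-9)
  1 - (iou - rho2 / c2 - alpha * v)
}

# CIoU loss node over gathered raw offsets t = (tx, ty, tw, th)
ag_ciou <- function(t4, anchor_wh, cell_ij, stride, gt, tape) {
  clamp <- function(t) pmin(pmax(t, -4), 4)
  decode <- function(t) c((plogis(t[1]) + cell_ij[1]) * stride,
                          (plogis(t[2]) + cell_ij[2]) * stride,
                          anchor_wh[1] * exp(clamp(t[3])),
                          anchor_wh[2] * exp(clamp(t[4])))
  bv <- decode(t4$v)
  v <- ciou_loss_box(bv, gt)
  ag_node(v, list(t4), function(g) {
    db <- numeric(4)
    for (k in 1:4) {
      e <- 1e-4 * max(1, abs(bv[k]))
      b1 <- bv; b1[k] <- b1[k] + e
      b2 <- bv; b2[k] <- b2[k] - e
      db[k] <- (ciou_loss_box(b1, gt) - ciou_loss_box(b2, gt)) / (2 * e)
    }
    s1 <- plogis(t4$v[1]); s2 <- plogis(t4$v[2])
    dt <- c(db[1] * s1 * (1 - s1) * stride,
            db[2] * s2 * (1 - s2) * stride,
            db[3] * bv[3] * (abs(t4$v[3]) < 4),
            db[4] * bv[4] * (abs(t4$v[4]) < 4))
    list(g * dt)
  }, tape)
}

# assign each ground-truth box to its best shape-matching anchor (IoU of the
# centered shapes, aspect-ratio gate 4) plus any anchor with shape IoU >= 0.5
# (extra positives speed up convergence)
assign_anchors <- function(boxes, cfg) {
  if (nrow(boxes) == 0) return(NULL)
  out <- NULL
  for (bi in seq_len(nrow(boxes))) {
    gw <- boxes$x_max[bi] - boxes$x_min[bi]
    gh <- boxes$y_max[bi] - boxes$y_min[bi]
    cand <- NULL
    for (l in seq_len(cfg$pyramid_levels)) {
      an <- cfg$anchors[[l]]
      for (a in seq_len(nrow(an))) {
        ratio <- max(gw / an[a, 1], an[a, 1] / gw, gh / an[a, 2],
                     an[a, 2] / gh)
        if (ratio >= 4) next
        iw <- min(gw, an[a, 1]); ih <- min(gh, an[a, 2])
        iou <- iw * ih / (gw * gh + an[a, 1] * an[a, 2] - iw * ih)
        cand <- rbind(cand, c(iou, l, a))
      }
    }
    if (is.null(cand)) next
    take <- cand[, 1] >= 0.5
    take[which.max(cand[, 1])] <- TRUE
    cx <- (boxes$x_min[bi] + boxes$x_max[bi]) / 2
    cy <- (boxes$y_min[bi] + boxes$y_max[bi]) / 2
    for (r in which(take)) {
      l <- cand[r, 2]; a <- cand[r, 3]
      stride <- cfg$strides[l]
      gsz <- cfg$input_size / stride
      gi <- min(gsz - 1, max(0, floor(cx / stride)))
      gj <- min(gsz - 1, max(0, floor(cy / stride)))
      out <- rbind(out, c(l, a, gi, gj, cx, cy, gw, gh,
                          match(boxes$class[bi], roi_classes())))
    }
  }
  if (is.null(out)) return(NULL)
  colnames(out) <- c("level", "anchor", "gi", "gj", "cx", "cy", "w", "h",
                     "cls")
  out
}

# flat 1-based index into a (C,h,w) feature array; all arguments 0-based.
# Images enter as (1, H, W) with dim 2 = image rows (y), dim 3 = columns (x).
flat_idx <- function(ch, y, x, C, H) ch + C * (y + H * x) + 1L

detector_loss <- function(model, x_arr, boxes, tape, scale = 1) {
  cfg <- model$config
  heads <- detector_forward(model, x_arr, tape)
  asg <- assign_anchors(boxes, cfg)
  n_cls <- cfg$n_classes
  total <- NULL
  add_term <- function(acc, node) if (is.null(acc)) node else
    ag_add(acc, node, tape)
  n_matched <- if (is.null(asg)) 0L else nrow(asg)
  for (l in seq_len(cfg$pyramid_levels)) {
    H <- heads[[l]]
    d <- dim(H$v)
    na <- nrow(cfg$anchors[[l]])
    obj_target <- array(0, d)
    is_obj <- array(FALSE, d)
    for (a in seq_len(na) - 1L)
      is_obj[a * (5 + n_cls) + 5L, , ] <- TRUE
    if (!is.null(asg)) {
      rows <- which(asg[, "level"] == l)
      for (r in rows) {
        a <- asg[r, "anchor"] - 1L
        gi <- asg[r, "gi"]; gj <- asg[r, "gj"]
        base <- a * (5 + n_cls)
        # dim 2 of the head is image rows (y), dim 3 is columns (x)
        obj_target[flat_idx(base + 4L, gj, gi, d[1], d[2])] <- 1
        t4 <- ag_gather(H, flat_idx(base + 0:3, gj, gi, d[1], d[2]), tape)
        bl <- ag_ciou(t4, cfg$anchors[[l]][a + 1L, ], c(asg[r, "gi"],
                                                        asg[r, "gj"]),
                      cfg$strides[l],
                      asg[r, c("cx", "cy", "w", "h")], tape)
        total <- add_term(total, ag_mul_const(bl, 2 * scale / n_matched,
                                              tape))
        cl <- ag_gather(H, flat_idx(base + 4L + seq_len(n_cls), gj, gi,
                                    d[1], d[2]), tape)
        y <- numeric(n_cls); y[asg[r, "cls"]] <- 1
        total <- add_term(total, ag_mul_const(
          ag_bce_logits(cl, y, tape), scale / n_matched, tape))
      }
    }
    # objectness: positives and negatives normalized separately so the few
    # positive cells are not drowned by the background
    pos <- is_obj & obj_target == 1
    neg <- is_obj & obj_target == 0
    w <- array(0, d)
    if (any(pos)) w[pos] <- 1 / (3 * sum(pos))  # spread over the 3 levels
    w[neg] <- 1 / (3 * sum(neg))
    total <- add_term(total, ag_mul_const(
      ag_bce_logits(H, obj_target, tape, w = w, norm = 1), scale, tape))
  }
  total
}

# preprocess one labeled image for the detector: homomorphic filter +
# letterbox to the model input, boxes mapped into the letterboxed frame
detector_preprocess <- function(img, cfg, hp = homomorphic_params()) {
  filt <- homomorphic_filter(img$pixels, hp)
  lb <- letterbox(filt, cfg$input_size)
  boxes <- img$boxes
  if (nrow(boxes)) {
    m <- letterbox_box(as.matrix(boxes[, c("x_min", "y_min", "x_max",
                                           "y_max")]), lb$transform)
    boxes[, c("x_min", "y_min", "x_max", "y_max")] <- m
  }
  list(x = array(lb$image, c(1, cfg$input_size, cfg$input_size)),
       boxes = boxes, transform = lb$transform, filtered = filt)
}

#' Train the ROI detector on a phantom dataset manifest
#'
#' Optimizes the composite loss (CIoU box + BCE objectness + BCE class) with
#' Adam, logging the running loss per epoch. When a validation manifest is
#' given, mAP@0.5 is evaluated every `eval_every` epochs and the best
#' parameters are kept.
#'
#' @param model From [build_detector()].
#' @param train_man Manifest from [generate_dataset()].
#' @param val_man Optional validation manifest.
#' @param eval_every Epoch interval for validation mAP.
#' @param verbose Print per-epoch loss.
#' @return The trained model, with a `log` element (per-epoch loss,
#'   validation mAP trace).
#' @export
train_detector <- function(model, train_man, val_man = NULL, eval_every = 5,
                           verbose = FALSE) {
  cfg <- model$config
  n <- length(train_man$ids)
  if (n == 0) stop("empty dataset")
  pre <- lapply(seq_len(n), function(i)
    detector_preprocess(manifest_image(train_man, i), cfg))
  if (all(vapply(pre, function(p) nrow(p$boxes) == 0, logical(1))))
    stop("all images are background; nothing to learn")
  params <- params_list(model$params)
  epoch_loss <- numeric(cfg$epochs)
  val_map <- rep(NA_real_, cfg$epochs)
  best <- list(map = -Inf, params = NULL)
  step <- 0L
  withr::with_seed(cfg$seed + 1L, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(n)
      bl <- 0
      for (bstart in seq(1, n, cfg$batch_size)) {
        idx <- ord[bstart:min(bstart + cfg$batch_size - 1L, n)]
        ag_zero_grad(params)
        for (i in idx) {
          tape <- ag_tape()
          loss <- detector_loss(model, pre[[i]]$x, pre[[i]]$boxes, tape,
                                scale = 1 / length(idx))
          ag_backward(loss, tape)
          bl <- bl + loss$v * length(idx)
        }
        step <- step + 1L
        adam_step(params, cfg$lr, step)
      }
      epoch_loss[ep] <- bl / n
      if (verbose) log_stage("detector", sprintf("epoch %d loss %.4f", ep,
                                                 epoch_loss[ep]))
      if (!is.null(val_man) && (ep %% eval_every == 0 || ep == cfg$epochs)) {
        m <- evaluate_detector(model, val_man)$map
        val_map[ep] <- m
        if (m >= best$map)
          best <- list(map = m, params = lapply(params, function(p) p$v))
      }
    }
  })
  if (!is.null(best$params))
    for (nm in names(best$params)) model$params[[nm]]$v <- best$params[[nm]]
  model$trained <- TRUE
  model$log <- list(epoch_loss = epoch_loss, val_map = val_map,
                    best_val_map = if (is.finite(best$map)) best$map else NA)
  model
}

# per-class greedy NMS with deterministic ordering (confidence desc, then
# lowest x_min)
nms_boxes <- function(det, iou_thr) {
  n <- nrow(det)
  if (n <= 1) return(det)
  ord <- order(-det$confidence, det$x_min)
  b <- as.matrix(det[ord, c("x_min", "y_min", "x_max", "y_max")])
  areas <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  alive <- rep(TRUE, n)
  keep <- integer(0)
  for (i in seq_len(n)) {
    if (!alive[i]) next
    keep <- c(keep, i)
    alive[i] <- FALSE
    rest <- which(alive)
    if (!length(rest)) break
    iw <- pmax(0, pmin(b[rest, 3], b[i, 3]) - pmax(b[rest, 1], b[i, 1]))
    ih <- pmax(0, pmin(b[rest, 4], b[i, 4]) - pmax(b[rest, 2], b[i, 2]))
    inter <- iw * ih
    iou <- inter / (areas[rest] + areas[i] - inter)
    alive[rest[iou > iou_thr]] <- FALSE
  }
  det[ord[keep], , drop = FALSE]
}

#' Detect ROIs on a grayscale image
#'
#' Letterboxes the (already illumination-corrected) image to the model input,
#' runs the forward pass, filters by confidence (objectness times class
#' probability), applies per-class NMS and maps boxes back to the original
#' image coordinates.
#'
#' @param model A `fg_detector`.
#' @param image Grayscale matrix in \[0, 1\].
#' @param conf_threshold,nms_iou Optional overrides of the config values.
#' @param allow_untrained Permit inference with random weights.
#' @return data.frame `class`, `x_min`, `y_min`, `x_max`, `y_max`,
#'   `confidence` (possibly 0 rows).
#' @export
detect_rois <- function(model, image, conf_threshold = NULL, nms_iou = NULL,
                        allow_untrained = FALSE) {
  cfg <- model$config
  if (!isTRUE(model$trained) && !allow_untrained)
    stop("model is untrained; pass allow_untrained = TRUE to override")
  conf_threshold <- conf_threshold %||% cfg$conf_threshold
  nms_iou <- nms_iou %||% cfg$nms_iou
  lb <- letterbox(image, cfg$input_size)
  x <- array(lb$image, c(1, cfg$input_size, cfg$input_size))
  tape <- ag_tape()
  heads <- detector_forward(model, x, tape)
  n_cls <- cfg$n_classes
  rows <- list()
  for (l in seq_len(cfg$pyramid_levels)) {
    H <- heads[[l]]$v
    d <- dim(H)
    stride <- cfg$strides[l]
    na <- nrow(cfg$anchors[[l]])
    gy <- matrix(seq_len(d[2]) - 1L, d[2], d[3])         # row = y cell
    gx <- matrix(seq_len(d[3]) - 1L, d[2], d[3], byrow = TRUE)
    for (a in seq_len(na) - 1L) {
      base <- a * (5 + n_cls)
      obj <- plogis(H[base + 5L, , ])
      clsm <- matrix(H[base + 5L + seq_len(n_cls), , ], n_cls)
      cls_best <- max.col(t(clsm), ties.method = "first")
      cls_p <- plogis(clsm[cbind(cls_best, seq_len(ncol(clsm)))])
      conf <- obj * matrix(cls_p, d[2], d[3])
      hit <- which(conf >= conf_threshold)
      if (!length(hit)) next
      cx <- (plogis(H[base + 1L, , ][hit]) + gx[hit]) * stride
      cy <- (plogis(H[base + 2L, , ][hit]) + gy[hit]) * stride
      bw <- cfg$anchors[[l]][a + 1L, 1] *
        exp(pmin(pmax(H[base + 3L, , ][hit], -4), 4))
      bh <- cfg$anchors[[l]][a + 1L, 2] *
        exp(pmin(pmax(H[base + 4L, , ][hit], -4), 4))
      rows[[length(rows) + 1L]] <- data.frame(
        class = roi_classes()[cls_best[hit]],
        x_min = cx - bw / 2, y_min = cy - bh / 2,
        x_max = cx + bw / 2, y_max = cy + bh / 2,
        confidence = conf[hit], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(class = character(0), x_min = numeric(0),
                      y_min = numeric(0), x_max = numeric(0),
                      y_max = numeric(0), confidence = numeric(0),
                      stringsAsFactors = FALSE))
  det <- do.call(rbind, rows)
  if (nrow(det) > 300)   # cap candidates entering NMS
    det <- det[order(-det$confidence, det$x_min)[1:300], , drop = FALSE]
  det <- do.call(rbind, lapply(split(det, det$class), nms_boxes,
                               iou_thr = nms_iou))
  rownames(det) <- NULL
  m <- invert_letterbox_box(as.matrix(det[, c("x_min", "y_min", "x_max",
                                              "y_max")]), lb$transform)
  m[, c(1, 3)] <- pmin(pmax(m[, c(1, 3)], 0), ncol(image))
  m[, c(2, 4)] <- pmin(pmax(m[, c(2, 4)], 0), nrow(image))
  det[, c("x_min", "y_min", "x_max", "y_max")] <- m
  det[order(det$class, -det$confidence), , drop = FALSE]
}

#' Evaluate detector mAP on a manifest
#'
#' @param model Trained `fg_detector`.
#' @param man Dataset manifest.
#' @param iou_threshold Matching IoU for [detection_map()].
#' @param conf_threshold Confidence floor (low by default so the full
#'   precision-recall curve is scored).
#' @return The [detection_map()] result.
#' @export
evaluate_detector <- function(model, man, iou_threshold = 0.5,
                              conf_threshold = 0.05) {
  preds <- list(); gts <- list()
  for (i in seq_along(man$ids)) {
    img <- manifest_image(man, i)
    filt <- homomorphic_filter(img$pixels)
    det <- detect_rois(model, filt, conf_threshold = conf_threshold,
                       allow_untrained = TRUE)
    if (nrow(det)) { det$image <- man$ids[i]; preds[[length(preds) + 1]] <- det }
    gt <- img$boxes; gt$image <- man$ids[i]
    gts[[length(gts) + 1]] <- gt
  }
  preds <- if (length(preds)) do.call(rbind, preds) else
    data.frame(class = character(0), x_min = numeric(0), y_min = numeric(0),
               x_max = numeric(0), y_max = numeric(0),
               confidence = numeric(0), image = character(0))
  detection_map(preds, do.call(rbind, gts), iou_threshold)
}

#' Crop the highest-confidence detection of each risk class
#'
#' For each of the six risk classes, keeps the highest-confidence detection
#' (ties broken by lowest `x_min`), crops the illumination-corrected image
#' and letterboxes the crop to `crop_size`. The diencephalon is excluded.
#' Classes with no detection map to `NULL`, flagged in the `missing`
#' attribute.
#'
#' @param image Grayscale matrix (the filtered image).
#' @param detections From [detect_rois()].
#' @param crop_size Square crop side, default 256.
#' @return Named list over [risk_classes()] of crop matrices (or `NULL`),
#'   with a logical `missing` attribute.
#' @export
select_roi_crops <- function(image, detections, crop_size = 256) {
  out <- stats::setNames(vector("list", length(risk_classes())),
                         risk_classes())
  missing <- stats::setNames(rep(TRUE, length(risk_classes())),
                             risk_classes())
  for (cl in risk_classes()) {
    d <- detections[detections$class == cl, , drop = FALSE]
    if (!nrow(d)) next
    d <- d[order(-d$confidence, d$x_min), , drop = FALSE]
    b <- as.numeric(d[1, c("x_min", "y_min", "x_max", "y_max")])
    r0 <- max(1L, floor(b[2]) + 1L); r1 <- min(nrow(image), ceiling(b[4]))
    c0 <- max(1L, floor(b[1]) + 1L); c1 <- min(ncol(image), ceiling(b[3]))
    if (r1 <= r0 || c1 <= c0) next
    crop <- image[r0:r1, c0:c1, drop = FALSE]
    out[[cl]] <- letterbox(crop, crop_size)$image
    missing[cl] <- FALSE
  }
  attr(out, "missing") <- missing
  out
}
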