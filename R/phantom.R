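# Synthetic midsagittal fetal-profile phantoms.
#
# A phantom is a speckle-textured profile silhouette on a dark background with
# a smooth multiplicative illumination field and seven planted ROI structures
# in anatomically plausible relative positions (cranial arcs, a diencephalon
# blob, a nasal bright streak, jaw bars, a chin contour arc and a dark nuchal
# translucency band). A configurable subset of ROIs carries label-dependent
# morphology (NT band thickness shift, nasal-bone streak dimming, chin-contour
# curvature change); all other ROIs are statistically identical across labels,
# so classifiers trained on them can only reach chance performance. The
# generator records hidden ground truth (band masks, planted parameter values)
# for oracle tests; the pipeline itself never reads it.

# ROI layout template: fixed anatomical arrangement, fractions of image side
phantom_template <- function() {
  # spacing leaves every pair of jittered boxes clear of the IoU < 0.3
  # constraint and keeps the signal-carrying boxes (Chin, NA + NB, NT) from
  # ever overlapping another box, so label signal cannot leak across crops
  t <- rbind(
    Chin         = c(0.50, 0.84, 0.13, 0.11),
    head1        = c(0.40, 0.16, 0.20, 0.13),
    head2        = c(0.70, 0.32, 0.18, 0.14),
    D            = c(0.44, 0.40, 0.13, 0.11),
    `NA + NB`    = c(0.17, 0.52, 0.15, 0.10),
    `max + mand` = c(0.22, 0.76, 0.15, 0.12),
    NT           = c(0.72, 0.62, 0.18, 0.11))
  colnames(t) <- c("cx", "cy", "w", "h")
  t[roi_classes(), , drop = FALSE]
}

#' Specification of a phantom population
#'
#' Defines the study conditions under which phantoms are generated. Defaults:
#' positive prevalence 0.385 (the minority-positive regime typical of clinical
#' screening collections), moderate speckle and illumination, and three
#' signal-carrying ROIs — the NT band thickness increased 1.5-fold in
#' positives, the nasal-bone streak dimmed to 0.4 of its amplitude, and the
#' chin contour curvature increased 1.4-fold.
#'
#' @param image_size Square image side in pixels.
#' @param speckle_variance Variance of the multiplicative Rayleigh speckle
#'   field on the silhouette (0 disables all noise).
#' @param illumination_amplitude Amplitude in \[0, 1) of the smooth
#'   multiplicative illumination field applied last.
#' @param prevalence Probability of a positive disorder label.
#' @param signal_rois Subset of [roi_classes()] that carries label signal.
#' @param effect_sizes Named multipliers applied to the planted feature of
#'   each signal ROI when the label is positive.
#' @param jitter_center Per-image jitter of each box center, as a fraction of
#'   the image side.
#' @param jitter_scale Relative jitter of each box size.
#' @param seed Integer seed; together with the image index it fully
#'   determines a phantom.
#' @return Object of class `fg_phantom_spec`.
#' @export
phantom_spec <- function(image_size = 640, speckle_variance = 0.08,
                         illumination_amplitude = 0.25, prevalence = 0.385,
                         signal_rois = c("NT", "NA + NB", "Chin"),
                         effect_sizes = c(NT = 1.5, `NA + NB` = 0.4,
                                          Chin = 1.4),
                         jitter_center = 0.05, jitter_scale = 0.10,
                         seed = 1L) {
  stopifnot(image_size >= 64, speckle_variance >= 0,
            illumination_amplitude >= 0, illumination_amplitude < 1,
            prevalence >= 0, prevalence <= 1)
  if (!all(signal_rois %in% roi_classes()))
    stop("signal_rois must be a subset of roi_classes()")
  if (!all(signal_rois %in% names(effect_sizes)))
    stop("every signal ROI needs an entry in effect_sizes")
  spec <- list(image_size = as.integer(image_size),
               speckle_variance = speckle_variance,
               illumination_amplitude = illumination_amplitude,
               prevalence = prevalence, signal_rois = signal_rois,
               effect_sizes = effect_sizes, jitter_center = jitter_center,
               jitter_scale = jitter_scale, seed = as.integer(seed))
  spec$hash <- substr(paste(vapply(spec, function(x)
    paste(format(x, digits = 10), collapse = ","), character(1)),
    collapse = ";"), 1, 1e6)
  class(spec) <- "fg_phantom_spec"
  spec
}

phantom_image_seed <- function(spec, index) {
  as.integer((as.double(spec$seed) * 48271 + index * 16807) %% 2147483646) + 1L
}

# light-weight seeded evaluation (restores the caller's RNG state)
with_seed_fast <- function(seed, fn) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (has) assign(".Random.seed", old, globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  fn()
}

#' Generate one phantom image with boxes, label and hidden ground truth
#'
#' The label is Bernoulli(`prevalence`); for each ROI in `signal_rois` the
#' planted texture or geometry is shifted by its effect size when the label is
#' positive. `(seed, index)` fully determines the phantom. Order of
#' rendering: clean reflectance with planted structures, multiplicative
#' Rayleigh speckle on the silhouette with a 1-px Gaussian blur, then the
#' smooth multiplicative illumination field.
#'
#' @param spec A [phantom_spec()].
#' @param index Non-negative image index.
#' @return Object of class `fg_labeled_image`: list with `pixels` (matrix in
#'   \[0, 1\]), `boxes` (data.frame `class`, `x_min`, `y_min`, `x_max`,
#'   `y_max` in pixels), binary `label`, and `meta` (seed, spec hash, planted
#'   truth values and the NT band mask).
#' @export
generate_phantom <- function(spec, index) {
  stopifnot(inherits(spec, "fg_phantom_spec"), index >= 0)
  if (length(spec$signal_rois) == 0 && spec$prevalence > 0)
    warning("no signal ROIs with positive prevalence: ",
            "the dataset is unlearnable by design")
  with_seed_fast(phantom_image_seed(spec, index), function() {
    S <- spec$image_size
    label <- rbinom(1, 1, spec$prevalence)
    tmpl <- phantom_template()
    # per-image jitter of box centers and sizes
    jc <- spec$jitter_center; js <- spec$jitter_scale
    boxes <- tmpl
    boxes[, "cx"] <- tmpl[, "cx"] + runif(7, -jc, jc)
    boxes[, "cy"] <- tmpl[, "cy"] + runif(7, -jc, jc)
    boxes[, "w"] <- tmpl[, "w"] * (1 + runif(7, -js, js))
    boxes[, "h"] <- tmpl[, "h"] * (1 + runif(7, -js, js))
    # keep boxes fully inside the image
    boxes[, "cx"] <- pmin(pmax(boxes[, "cx"], boxes[, "w"] / 2 + 0.005),
                          1 - boxes[, "w"] / 2 - 0.005)
    boxes[, "cy"] <- pmin(pmax(boxes[, "cy"], boxes[, "h"] / 2 + 0.005),
                          1 - boxes[, "h"] / 2 - 0.005)

    xs <- ((seq_len(S)) - 0.5) / S
    ell <- function(cx, cy, ax, ay)   # outer() keeps the big ops to a minimum
      outer(((xs - cy) / ay)^2, ((xs - cx) / ax)^2, "+") <= 1

    img <- matrix(0.08, S, S)
    head_m <- ell(0.50, 0.40, 0.31, 0.28)
    face_m <- ell(0.36, 0.63, 0.18, 0.20)
    img[head_m] <- 0.32
    img[face_m] <- 0.38
    rim <- head_m & !ell(0.50, 0.40, 0.29, 0.26)
    img[rim] <- 0.70
    silhouette <- head_m | face_m

    eff <- function(cls) {
      if (cls %in% spec$signal_rois && label == 1)
        spec$effect_sizes[[cls]] else 1
    }
    truth <- list(label = label)
    masks <- list()

    bx <- function(cls) {
      b <- boxes[cls, ]
      c(x0 = b[["cx"]] - b[["w"]] / 2, x1 = b[["cx"]] + b[["w"]] / 2,
        y0 = b[["cy"]] - b[["h"]] / 2, y1 = b[["cy"]] + b[["h"]] / 2,
        cx = b[["cx"]], cy = b[["cy"]], w = b[["w"]], h = b[["h"]])
    }
    # subwindow grid around a box: all per-ROI drawing stays local
    sg <- function(b, m = 0.02) {
      rows <- max(1L, floor((b["y0"] - m) * S) + 1L):
        min(S, ceiling((b["y1"] + m) * S))
      cols <- max(1L, floor((b["x0"] - m) * S) + 1L):
        min(S, ceiling((b["x1"] + m) * S))
      list(rows = rows, cols = cols,
           X = matrix((cols - 0.5) / S, length(rows), length(cols),
                      byrow = TRUE),
           Y = matrix((rows - 0.5) / S, length(rows), length(cols)))
    }
    inbox <- function(g, b) g$X >= b["x0"] & g$X <= b["x1"] &
      g$Y >= b["y0"] & g$Y <= b["y1"]
    paint <- function(g, mask, value) {
      sub <- img[g$rows, g$cols]
      sub[mask] <- value
      img[g$rows, g$cols] <<- sub
    }

    # head1 / head2: bright cranial arcs (parabolic bands), no label signal
    b <- bx("head1"); g <- sg(b)
    paint(g, abs(g$Y - (b["cy"] + 3.5 * (g$X - b["cx"])^2)) < 0.012 &
            inbox(g, b), 0.80)
    b <- bx("head2"); g <- sg(b)
    paint(g, abs(g$X - (b["cx"] + 3.5 * (g$Y - b["cy"])^2)) < 0.012 &
            inbox(g, b), 0.78)

    # D: dark diencephalon blob with a faint rim
    b <- bx("D"); g <- sg(b)
    e2 <- function(g, cx, cy, ax, ay)
      ((g$X - cx) / ax)^2 + ((g$Y - cy) / ay)^2 <= 1
    blob <- e2(g, b["cx"], b["cy"], b["w"] * 0.35, b["h"] * 0.35)
    ring <- e2(g, b["cx"], b["cy"], b["w"] * 0.42, b["h"] * 0.42) & !blob
    paint(g, ring, 0.55)
    paint(g, blob, 0.15)

    # NA + NB: nasal-bone bright streak; positives have it dimmed (absent)
    b <- bx("NA + NB"); g <- sg(b)
    amp <- 0.55 * eff("NA + NB")
    ang <- 0.35  # radians, slight upward slant
    u <- (g$X - b["cx"]) * cos(ang) + (g$Y - b["cy"]) * sin(ang)
    vdist <- abs(-(g$X - b["cx"]) * sin(ang) + (g$Y - b["cy"]) * cos(ang))
    streak <- vdist < 0.004 & abs(u) < b["w"] * 0.42 & inbox(g, b)
    sub <- img[g$rows, g$cols]
    sub[streak] <- pmin(1, sub[streak] + amp)
    img[g$rows, g$cols] <- sub
    truth$streak_amplitude <- amp

    # max + mand: maxilla and mandible bars, no label signal by default
    b <- bx("max + mand"); g <- sg(b)
    m1 <- e2(g, b["cx"] - b["w"] * 0.15, b["cy"] - b["h"] * 0.22,
             b["w"] * 0.28, b["h"] * 0.14)
    m2 <- e2(g, b["cx"] - b["w"] * 0.10, b["cy"] + b["h"] * 0.24,
             b["w"] * 0.32, b["h"] * 0.15)
    paint(g, m1 | m2, 0.75)

    # Chin: contour arc whose curvature shifts with the label
    b <- bx("Chin"); g <- sg(b)
    kappa <- 6 * eff("Chin")
    paint(g, abs(g$X - (b["cx"] - b["w"] * 0.15 +
                          kappa * (g$Y - b["cy"])^2)) < 0.008 & inbox(g, b),
          0.80)
    truth$chin_curvature <- kappa

    # NT: dark nuchal band between two bright skin lines; thickness shifts
    b <- bx("NT"); g <- sg(b)
    th_frac <- 0.18 * b[["h"]] * eff("NT")
    th_px <- th_frac * S
    band <- abs(g$Y - b["cy"]) < th_frac / 2 & abs(g$X - b["cx"]) <
      b["w"] * 0.45
    line_up <- abs(g$Y - (b["cy"] - th_frac / 2 - 0.006)) < 0.005 &
      abs(g$X - b["cx"]) < b["w"] * 0.45
    line_dn <- abs(g$Y - (b["cy"] + th_frac / 2 + 0.006)) < 0.005 &
      abs(g$X - b["cx"]) < b["w"] * 0.45
    paint(g, band, 0.05)
    paint(g, line_up | line_dn, 0.85)
    truth$nt_thickness_px <- th_px
    full_band <- matrix(FALSE, S, S)
    full_band[g$rows, g$cols] <- band
    masks$NT <- full_band

    # speckle (multiplicative Rayleigh on the silhouette) + 1-px blur
    if (spec$speckle_variance > 0) {
      sigma_r <- 1 / sqrt(pi / 2)            # Rayleigh with unit mean
      r <- sigma_r * sqrt(-2 * log(runif(S * S)))
      rel_sd <- sqrt(4 / pi - 1)
      mult <- 1 + sqrt(spec$speckle_variance) * (r - 1) / rel_sd
      mult <- matrix(pmax(mult, 0), S, S)
      sil <- silhouette | img > 0.4
      img[sil] <- img[sil] * mult[sil]
      img <- .gauss_blur(img, 1)
    }

    # smooth multiplicative illumination field, applied last
    if (spec$illumination_amplitude > 0) {
      fx <- runif(1, 0.3, 1.0); fy <- runif(1, 0.3, 1.0)
      ph <- runif(1, 0, 2 * pi)
      g <- cos(outer(2 * pi * fy * xs, 2 * pi * fx * xs, "+") + ph)
      img <- img * (1 + spec$illumination_amplitude * g)
      truth$illumination <- c(fx = fx, fy = fy, phase = ph)
    }
    img <- pmin(pmax(img, 0), 1)

    box_df <- data.frame(
      class = rownames(boxes),
      x_min = (boxes[, "cx"] - boxes[, "w"] / 2) * S,
      y_min = (boxes[, "cy"] - boxes[, "h"] / 2) * S,
      x_max = (boxes[, "cx"] + boxes[, "w"] / 2) * S,
      y_max = (boxes[, "cy"] + boxes[, "h"] / 2) * S,
      row.names = NULL, stringsAsFactors = FALSE)

    structure(list(pixels = img, boxes = box_df, label = label,
                   meta = list(seed = spec$seed, index = index,
                               spec_hash = spec$hash, truth = truth,
                               masks = masks)),
              class = "fg_labeled_image")
  })
}

#' Generate a phantom dataset on disk
#'
#' Writes `n` 8-bit grayscale PNGs, YOLO-txt annotations (one
#' `class_index cx cy w h` line per box, normalized), a `labels.csv` with
#' header `image,label,split`, and a `truth.json` sidecar with the planted
#' ground-truth values (oracle use only). Split assignment is stratified
#' random by the spec seed.
#'
#' @param spec A [phantom_spec()].
#' @param n Number of images (>= number of non-empty splits).
#' @param out_dir Output directory (created if needed).
#' @param splits Named fractions summing to 1.
#' @param write_images Set `FALSE` to skip PNG/txt writing and keep images
#'   in memory (`manifest$images`).
#' @return Manifest list: file paths, labels, splits, spec; also written as
#'   `manifest.json` (paths and labels only).
#' @export
generate_dataset <- function(spec, n, out_dir,
                             splits = c(train = 0.7, val = 0.15, test = 0.15),
                             write_images = TRUE) {
  stopifnot(n >= 1, abs(sum(splits) - 1) < 1e-8)
  n_splits <- sum(splits > 0)
  if (n < n_splits)
    stop("n = ", n, " is below the minimum split size (", n_splits, ")")
  if (write_images) {
    dir.create(file.path(out_dir, "images"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(out_dir, "labels"), recursive = TRUE,
               showWarnings = FALSE)
    if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  }
  counts <- diff(round(cumsum(c(0, splits)) * n))
  counts[which.max(counts)] <- counts[which.max(counts)] + (n - sum(counts))
  split_vec <- withr::with_seed(spec$seed,
    sample(rep(names(splits), counts)))
  ids <- sprintf("img_%05d", seq_len(n) - 1L)
  labels <- integer(n)
  truth <- vector("list", n)
  images <- if (write_images) NULL else vector("list", n)
  S <- spec$image_size
  for (i in seq_len(n)) {
    ph <- generate_phantom(spec, i - 1L)
    labels[i] <- ph$label
    truth[[i]] <- ph$meta$truth
    if (write_images) {
      png::writePNG(ph$pixels, file.path(out_dir, "images",
                                         paste0(ids[i], ".png")))
      write_yolo_txt(ph$boxes, file.path(out_dir, "labels",
                                         paste0(ids[i], ".txt")), S, S)
    } else {
      images[[i]] <- ph
    }
  }
  names(truth) <- ids
  man <- list(ids = ids, labels = labels, split = split_vec,
              image_size = S, spec = spec,
              dir = if (write_images) out_dir else NULL,
              image_files = if (write_images)
                file.path(out_dir, "images", paste0(ids, ".png")) else NULL,
              label_files = if (write_images)
                file.path(out_dir, "labels", paste0(ids, ".txt")) else NULL,
              images = images, truth = truth)
  if (write_images) {
    write.csv(data.frame(image = paste0(ids, ".png"), label = labels,
                         split = split_vec),
              file.path(out_dir, "labels.csv"), row.names = FALSE)
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(list(ids = ids, labels = labels, split = split_vec,
                              image_size = S),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(man)
}

# fetch a phantom from a manifest regardless of on-disk vs in-memory mode
manifest_image <- function(man, i) {
  if (!is.null(man$images)) return(man$images[[i]])
  px <- png::readPNG(man$image_files[i])
  if (length(dim(px)) == 3) px <- px[, , 1]
  boxes <- read_yolo_txt(man$label_files[i], man$image_size, man$image_size)
  structure(list(pixels = px, boxes = boxes, label = man$labels[i],
                 meta = list(index = i - 1L)), class = "fg_labeled_image")
}
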