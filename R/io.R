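# Annotation and configuration plumbing: YOLO-txt and COCO-JSON readers and
# writers, the YAML pipeline config, and run manifests. Coordinate
# convention: pixel coordinates, origin top-left, boxes half-open
# [x_min, x_max); YOLO-txt stores normalized centers (format-mandated). All
# conversions are centralized here.

#' Write / read YOLO-txt bounding-box annotations
#'
#' One line per box: `class_index cx cy w h`, all normalized to \[0, 1\],
#' with the class index following the [roi_classes()] order. The writer emits
#' canonical 6-decimal formatting, so write-read-write round trips are
#' byte-identical and coordinates round-trip within 0.5 px at typical image
#' sizes.
#'
#' @param boxes data.frame with `class`, `x_min`, `y_min`, `x_max`, `y_max`.
#' @param path File path.
#' @param img_w,img_h Image dimensions in pixels.
#' @return `read_yolo_txt()`: a `boxes` data.frame (empty for an empty file).
#' @export
write_yolo_txt <- function(boxes, path, img_w, img_h) {
  cls <- match(boxes$class, roi_classes()) - 1L
  if (anyNA(cls)) stop("unknown ROI class in boxes: ",
                       paste(setdiff(boxes$class, roi_classes()),
                             collapse = ", "))
  lines <- sprintf("%d %.6f %.6f %.6f %.6f", cls,
                   (boxes$x_min + boxes$x_max) / 2 / img_w,
                   (boxes$y_min + boxes$y_max) / 2 / img_h,
                   (boxes$x_max - boxes$x_min) / img_w,
                   (boxes$y_max - boxes$y_min) / img_h)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_yolo_txt
#' @export
read_yolo_txt <- function(path, img_w, img_h) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  empty <- data.frame(class = character(0), x_min = numeric(0),
                      y_min = numeric(0), x_max = numeric(0),
                      y_max = numeric(0), stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(parts) != 5)
  if (length(bad))
    stop("malformed YOLO line in ", path, " at line ", bad[1], ": '",
         lines[bad[1]], "'")
  m <- do.call(rbind, lapply(parts, as.numeric))
  if (anyNA(m)) stop("non-numeric field in ", path)
  data.frame(class = roi_classes()[m[, 1] + 1L],
             x_min = (m[, 2] - m[, 4] / 2) * img_w,
             y_min = (m[, 3] - m[, 5] / 2) * img_h,
             x_max = (m[, 2] + m[, 4] / 2) * img_w,
             y_max = (m[, 3] + m[, 5] / 2) * img_h,
             stringsAsFactors = FALSE)
}

#' Write / read COCO-JSON annotations
#'
#' A minimal COCO dialect: `images` (id, file_name, width, height),
#' `categories` (ids follow [roi_classes()] order, 1-based), and
#' `annotations` with `bbox = [x_min, y_min, width, height]`.
#'
#' @param anns Named list: one element per image, each a list with `file`,
#'   `width`, `height`, `boxes` (data.frame as in [write_yolo_txt()]).
#' @param path File path.
#' @return `read_coco_json()`: a named list in the same shape as `anns`.
#' @export
write_coco_json <- function(anns, path) {
  images <- lapply(seq_along(anns), function(i)
    list(id = i, file_name = anns[[i]]$file, width = anns[[i]]$width,
         height = anns[[i]]$height))
  categories <- lapply(seq_along(roi_classes()), function(i)
    list(id = i, name = roi_classes()[i]))
  annotations <- list(); k <- 0L
  for (i in seq_along(anns)) {
    b <- anns[[i]]$boxes
    for (j in seq_len(nrow(b))) {
      k <- k + 1L
      annotations[[k]] <- list(
        id = k, image_id = i,
        category_id = match(b$class[j], roi_classes()),
        bbox = c(b$x_min[j], b$y_min[j], b$x_max[j] - b$x_min[j],
                 b$y_max[j] - b$y_min[j]))
    }
  }
  jsonlite::write_json(list(images = images, categories = categories,
                            annotations = annotations),
                       path, auto_unbox = TRUE, digits = 6)
  invisible(path)
}

#' @rdname write_coco_json
#' @export
read_coco_json <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = FALSE)
  cats <- vapply(d$categories, function(c) c$name, character(1))
  out <- lapply(d$images, function(im)
    list(file = im$file_name, width = im$width, height = im$height,
         boxes = data.frame(class = character(0), x_min = numeric(0),
                            y_min = numeric(0), x_max = numeric(0),
                            y_max = numeric(0), stringsAsFactors = FALSE)))
  names(out) <- vapply(d$images, function(im) im$file_name, character(1))
  for (a in d$annotations) {
    i <- a$image_id
    bb <- as.numeric(unlist(a$bbox))
    out[[i]]$boxes <- rbind(out[[i]]$boxes, data.frame(
      class = cats[a$category_id], x_min = bb[1], y_min = bb[2],
      x_max = bb[1] + bb[3], y_max = bb[2] + bb[4],
      stringsAsFactors = FALSE))
  }
  out
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file with nested sections (`phantom`, `preprocess`,
#' `detector`, `roiclf`, `fusion`, `augment`, `explain`, `metrics`, `seeds`,
#' `paths`); unknown top-level keys are rejected, and defaults fill the rest.
#'
#' @param path YAML file, or `NULL` for the defaults.
#' @return Nested config list with a `hash` attribute.
#' @export
load_config <- function(path = NULL) {
  defaults <- list(
    phantom = list(image_size = 640, speckle_variance = 0.08,
                   illumination_amplitude = 0.25, prevalence = 0.385,
                   signal_rois = c("NT", "NA + NB", "Chin"),
                   effect_sizes = list(NT = 1.5, `NA + NB` = 0.4,
                                       Chin = 1.4)),
    preprocess = list(gamma_low = 0.5, gamma_high = 1.5, cutoff = 30 / 512,
                      sharpness = 1, epsilon_log = 1e-3, letterbox_fill = 114 / 255),
    detector = list(input_size = 128, conf_threshold = 0.25, nms_iou = 0.45,
                    epochs = 25, lr = 5e-3, batch_size = 4),
    roiclf = list(input_size = 256, epochs = 6, lr = 1e-3, batch_size = 8,
                  width_mult = 0.0625),
    fusion = list(n_trees = 200, max_depth = 3, learning_rate = 0.1,
                  subsample = 0.8, missing_policy = "indicator"),
    augment = list(positive_oversample = 2),
    explain = list(alpha = 0.5),
    metrics = list(iou_threshold = 0.5, conf_level = 0.95),
    seeds = list(global = 1),
    paths = list(work_dir = "fgscreen_run"))
  cfg <- defaults
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown))
      stop("unknown config section(s): ", paste(unknown, collapse = ", "))
    for (sec in names(user)) cfg[[sec]] <- utils::modifyList(cfg[[sec]],
                                                             user[[sec]])
  }
  attr(cfg, "hash") <- substr(rlang_hash(cfg), 1, 12)
  cfg
}

# small structural hash (no extra deps): serialize and fold
rlang_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  paste(sprintf("%02x", as.integer(raw[seq(1, length(raw),
                                           length.out = 32)])), collapse = "")
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste0(..., collapse = " ")))
}
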