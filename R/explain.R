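# Grad-CAM interpretability over ROI crops.
#
# For a target convolutional feature map A with channels A_c, the channel
# weights are the spatial means of the gradient of the positive-class logit
# with respect to A_c; the localization map is ReLU(sum_c w_c A_c),
# bilinearly upsampled to the crop and max-normalized.

#' Grad-CAM heatmap for a classifier on one crop
#'
#' @param model An `fg_classifier` (or any model exposing a `forward`
#'   function returning `list(logit, layers)`).
#' @param crop Grayscale matrix.
#' @param target_layer Name of a recorded convolutional layer; defaults to
#'   the last convolutional feature map before pooling.
#' @return Object of class `fg_heatmap`: list with `values` (matrix the size
#'   of the crop, in \[0, 1\], all-zero when the gradient vanishes
#'   identically), `target_layer` and `raw` (the unupsampled map).
#' @export
grad_cam <- function(model, crop, target_layer = "last_conv") {
  x <- array(crop, c(1, nrow(crop), ncol(crop)))
  tape <- ag_tape()
  out <- classifier_forward(model, x, tape, record = TRUE)
  if (is.null(out$layers[[target_layer]]))
    stop("unknown target layer: ", target_layer, " (available: ",
         paste(names(out$layers), collapse = ", "), ")")
  ag_backward(out$logit, tape)
  A <- out$layers[[target_layer]]
  if (is.null(A$g))
    stop("target layer has no gradient path to the output")
  d <- dim(A$v)
  w <- rowMeans(matrix(A$g, nrow = d[1]))
  cam <- matrix(0, d[2], d[3])
  for (c in seq_len(d[1])) cam <- cam + w[c] * A$v[c, , ]
  cam <- pmax(cam, 0)
  up <- EBImage::resize(cam, w = nrow(crop), h = ncol(crop))
  up <- pmax(matrix(as.numeric(up), nrow(crop), ncol(crop)), 0)
  if (max(up) > 0) up <- up / max(up)
  structure(list(values = up, target_layer = target_layer, raw = cam),
            class = "fg_heatmap")
}

#' Pseudocolor overlay of a heatmap on its crop
#'
#' Alpha blending is weighted by the heatmap itself:
#' `out = gray * (1 - alpha * h) + colormap(h) * alpha * h`, so zero-heat
#' regions show the unmodified crop (as gray RGB) and `alpha = 0` returns the
#' crop exactly.
#'
#' @param crop Grayscale matrix.
#' @param heatmap A `fg_heatmap` or matrix matching the crop.
#' @param colormap Palette name for [grDevices::hcl.colors()].
#' @param alpha Blend strength in \[0, 1\].
#' @param path Optional PNG output path.
#' @return `height x width x 3` RGB array in \[0, 1\].
#' @export
render_overlay <- function(crop, heatmap, colormap = "Inferno", alpha = 0.5,
                           path = NULL) {
  h <- if (inherits(heatmap, "fg_heatmap")) heatmap$values else heatmap
  if (!identical(dim(h), dim(crop)))
    stop("heatmap and crop shapes differ")
  pal <- grDevices::hcl.colors(256, colormap)
  idx <- pmin(255L, pmax(0L, as.integer(round(h * 255)))) + 1L
  rgb <- grDevices::col2rgb(pal[idx]) / 255
  out <- array(0, c(nrow(crop), ncol(crop), 3))
  wgt <- alpha * h
  for (k in 1:3)
    out[, , k] <- crop * (1 - wgt) + matrix(rgb[k, ], nrow(crop)) * wgt
  if (!is.null(path)) png::writePNG(out, path)
  out
}
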