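# Trivial Augment for ROI crops: per sample, draw ONE operation uniformly
# from a fixed set and ONE strength uniformly from that operation's range.
# The set is the canonical list minus colour-space operations (inputs are
# grayscale) and minus horizontal flip (facial-profile chirality matters).

#' The Trivial Augment operation set
#'
#' Geometric magnitudes are bounded (rotation within 15 degrees, translation
#' within 10% of the side); intensity operations keep values in \[0, 1\].
#'
#' @return Named list of operations, each with a `magnitude_range`.
#' @export
augment_ops <- function() {
  list(
    identity    = list(magnitude_range = c(0, 0)),
    rotate      = list(magnitude_range = c(-15, 15)),       # degrees
    translate_x = list(magnitude_range = c(-0.10, 0.10)),   # fraction of side
    translate_y = list(magnitude_range = c(-0.10, 0.10)),
    shear_x     = list(magnitude_range = c(-0.15, 0.15)),   # shear factor
    shear_y     = list(magnitude_range = c(-0.15, 0.15)),
    brightness  = list(magnitude_range = c(-0.20, 0.20)),   # additive
    contrast    = list(magnitude_range = c(0.70, 1.30)),    # gain about 0.5
    sharpness   = list(magnitude_range = c(0, 1)),          # unsharp amount
    equalize    = list(magnitude_range = c(0, 0)),
    posterize   = list(magnitude_range = c(4, 8))           # bit depth
  )
}

apply_augment_op <- function(image, op, mag, fill = 114 / 255) {
  clip01 <- function(x) pmin(pmax(x, 0), 1)
  d <- dim(image)
  switch(op,
    identity = image,
    rotate = clip01(EBImage::rotate(image, mag, output.dim = d,
                                    bg.col = fill)),
    translate_y = clip01(EBImage::translate(image,
                                            c(round(mag * d[1]), 0),
                                            bg.col = fill)),
    translate_x = clip01(EBImage::translate(image,
                                            c(0, round(mag * d[2])),
                                            bg.col = fill)),
    shear_x = clip01(EBImage::affine(image,
                                     rbind(c(1, 0), c(mag, 1), c(0, 0)),
                                     output.dim = d, bg.col = fill)),
    shear_y = clip01(EBImage::affine(image,
                                     rbind(c(1, mag), c(0, 1), c(0, 0)),
                                     output.dim = d, bg.col = fill)),
    brightness = clip01(image + mag),
    contrast = clip01(0.5 + (image - 0.5) * mag),
    sharpness = {
      blur <- EBImage::gblur(image, sigma = 1)
      clip01(image + mag * (image - blur))
    },
    equalize = clip01(EBImage::equalize(image, range = c(0, 1), levels = 256)),
    posterize = {
      levels <- 2^round(mag) - 1
      round(image * levels) / levels
    },
    stop("unknown augment op: ", op))
}

#' Trivial Augment: one uniformly drawn operation at a uniform strength
#'
#' @param image Grayscale matrix in \[0, 1\].
#' @param seed Optional integer; when given, the draw and output are fully
#'   deterministic.
#' @param ops Operation set, default [augment_ops()].
#' @param fill Fill value for geometric operations (letterbox convention).
#' @param force_op Optional operation name, bypassing the random draw (the
#'   magnitude is still drawn unless `force_mag` is given).
#' @param force_mag Optional fixed magnitude.
#' @return Transformed image, same shape, values in \[0, 1\].
#' @export
#' @examples
#' x <- matrix(runif(64^2), 64, 64)
#' identical(trivial_augment(x, force_op = "identity"), x)
trivial_augment <- function(image, seed = NULL, ops = augment_ops(),
                            fill = 114 / 255, force_op = NULL,
                            force_mag = NULL) {
  stopifnot(is.matrix(image), min(image) >= 0, max(image) <= 1)
  draw <- function() {
    op <- force_op %||% sample(names(ops), 1L)
    r <- ops[[op]]$magnitude_range
    mag <- force_mag %||% runif(1, r[1], r[2])
    list(op = op, mag = mag)
  }
  dr <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  out <- apply_augment_op(image, dr$op, dr$mag, fill)
  out <- matrix(as.numeric(out), nrow(image), ncol(image))
  attr(out, "augment_op") <- dr$op
  attr(out, "augment_magnitude") <- dr$mag
  out
}
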