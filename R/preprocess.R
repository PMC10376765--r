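# Illumination correction and letterbox resizing.
#
# Ultrasound acquisitions carry a smooth multiplicative illumination field
# (gain, probe coupling, depth attenuation) on top of tissue reflectance.
# Homomorphic filtering removes it by taking logs -- turning the
# multiplicative field into an additive low-frequency component -- and
# applying a high-emphasis filter in the frequency domain.

#' Parameters of the homomorphic illumination filter
#'
#' @param gamma_low Gain applied to low frequencies (the illumination band);
#'   `< 1` attenuates illumination.
#' @param gamma_high Gain applied to high frequencies (the reflectance band).
#' @param cutoff Transition radius in the frequency domain, as a fraction of
#'   the spectrum (cycles per pixel).
#' @param sharpness Slope of the Gaussian transition between the two gains.
#' @param epsilon_log Constant added before the log to keep it finite at zero.
#' @return List of validated parameters.
#' @export
homomorphic_params <- function(gamma_low = 0.5, gamma_high = 1.5,
                               cutoff = 30 / 512, sharpness = 1,
                               epsilon_log = 1e-3) {
  stopifnot(gamma_low > 0, gamma_high >= gamma_low, cutoff > 0,
            sharpness > 0, epsilon_log > 0)
  list(gamma_low = gamma_low, gamma_high = gamma_high, cutoff = cutoff,
       sharpness = sharpness, epsilon_log = epsilon_log)
}

#' Homomorphic filtering of a grayscale image
#'
#' Computes `exp(IFFT(H * FFT(log(image + epsilon_log))))` where `H` is a
#' Gaussian-shaped high-emphasis filter interpolating from `gamma_low` at zero
#' frequency to `gamma_high` far above the cutoff:
#' \deqn{H(u,v) = \gamma_L + (\gamma_H - \gamma_L)\,
#'   (1 - e^{-s\,D^2(u,v) / (2 c^2)})}
#' The result is min-max rescaled to \[0, 1\]. With
#' `gamma_low == gamma_high == 1` the filter is the identity. Constant images
#' (no illumination gradient to remove) are returned unchanged; an all-zero
#' image additionally emits a warning.
#'
#' @param image Numeric matrix with values in \[0, 1\], at least 8x8.
#' @param params From [homomorphic_params()].
#' @return Matrix of the same shape, values in \[0, 1\].
#' @export
homomorphic_filter <- function(image, params = homomorphic_params()) {
  if (!is.matrix(image) || nrow(image) < 8 || ncol(image) < 8)
    stop("image must be a numeric matrix of at least 8x8")
  if (!all(is.finite(image))) stop("image contains non-finite pixels")
  if (diff(range(image)) < 1e-12) {
    if (max(image) == 0)
      warning("degenerate constant-zero image; returned unchanged")
    return(image)
  }
  n1 <- nrow(image); n2 <- ncol(image)
  lg <- log(image + params$epsilon_log)
  sp <- stats::fft(lg)
  u <- (seq_len(n1) - 1L); u <- ifelse(u > n1 / 2, u - n1, u) / n1
  v <- (seq_len(n2) - 1L); v <- ifelse(v > n2 / 2, v - n2, v) / n2
  d2 <- outer(u^2, v^2, "+")
  h <- params$gamma_low + (params$gamma_high - params$gamma_low) *
    (1 - exp(-params$sharpness * d2 / (2 * params$cutoff^2)))
  out <- exp(Re(stats::fft(sp * h, inverse = TRUE)) / (n1 * n2)) -
    params$epsilon_log
  rng <- range(out)
  if (diff(rng) < 1e-12) return(pmin(pmax(out, 0), 1))
  (out - rng[1]) / diff(rng)
}

#' Letterbox resize with invertible transform record
#'
#' Resizes a grayscale image to a square target, preserving the aspect ratio
#' with a single scalar scale and padding the remainder symmetrically with a
#' constant fill (114/255 by default, the common detector convention). The
#' returned transform maps coordinates between the original and letterboxed
#' frames; the round trip is exact to below half a pixel.
#'
#' @param image Numeric matrix (rows = y, cols = x), values in \[0, 1\].
#' @param target Side of the square output in pixels (>= 8).
#' @param fill Pad value.
#' @return List with `image` (target x target matrix) and `transform`
#'   (`scale`, `pad_left`, `pad_top`, `pad_right`, `pad_bottom`, `target`).
#' @export
#' @examples
#' lb <- letterbox(matrix(runif(256 * 512), 256, 512), 256)
#' dim(lb$image)
#' lb$transform$pad_top  # 64-px bands top and bottom
letterbox <- function(image, target, fill = 114 / 255) {
  stopifnot(is.matrix(image), target >= 8)
  h <- nrow(image); w <- ncol(image)
  scale <- target / max(h, w)
  nh <- max(1L, round(h * scale)); nw <- max(1L, round(w * scale))
  if (nh < 1 || nw < 1) stop("target too small for this image")
  content <- if (nh == h && nw == w) image else
    EBImage::resize(image, w = nh, h = nw)
  pad_top <- (target - nh) %/% 2L
  pad_left <- (target - nw) %/% 2L
  out <- matrix(fill, target, target)
  out[pad_top + seq_len(nh), pad_left + seq_len(nw)] <- content
  list(image = out,
       transform = list(scale = scale, pad_left = pad_left,
                        pad_top = pad_top,
                        pad_right = target - nw - pad_left,
                        pad_bottom = target - nh - pad_top,
                        target = target))
}

#' Map boxes through a letterbox transform and back
#'
#' Boxes are `(x_min, y_min, x_max, y_max)` in pixel coordinates, origin at
#' the top-left corner.
#'
#' @param box Numeric vector of length 4 or a 4-column matrix.
#' @param transform A transform record from [letterbox()].
#' @return Box(es) in the other coordinate frame.
#' @export
letterbox_box <- function(box, transform) {
  b <- rbind(box)
  cbind(b[, 1] * transform$scale + transform$pad_left,
        b[, 2] * transform$scale + transform$pad_top,
        b[, 3] * transform$scale + transform$pad_left,
        b[, 4] * transform$scale + transform$pad_top)[seq_len(nrow(b)), ,
                                                      drop = !is.matrix(box)]
}

#' @rdname letterbox_box
#' @export
invert_letterbox_box <- function(box, transform) {
  b <- rbind(box)
  cbind((b[, 1] - transform$pad_left) / transform$scale,
        (b[, 2] - transform$pad_top) / transform$scale,
        (b[, 3] - transform$pad_left) / transform$scale,
        (b[, 4] - transform$pad_top) / transform$scale)[seq_len(nrow(b)), ,
                                                        drop = !is.matrix(box)]
}
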