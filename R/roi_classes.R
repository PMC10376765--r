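#' The seven anatomical ROI classes of the midsagittal fetal profile
#'
#' Ordered class names used consistently across annotations, detector outputs
#' and risk vectors: chin, two cranial regions, diencephalon, nasal apex +
#' nasal bone, maxilla + mandible, and nuchal translucency. The diencephalon
#' (`"D"`) is detected as an anatomical landmark but excluded from risk
#' scoring because it carries no screening information for genetic disorders.
#'
#' @return Character vector of length 7 (fixed order).
#' @export
#' @examples
#' roi_classes()
#' risk_classes()
roi_classes <- function() {
  c("Chin", "head1", "head2", "D", "NA + NB", "max + mand", "NT")
}

#' @rdname roi_classes
#' @return `risk_classes()`: the 6 classes used for risk estimation
#'   (all except `"D"`).
#' @export
risk_classes <- function() {
  setdiff(roi_classes(), "D")
}
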