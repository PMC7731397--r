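# Basic first-order statistics of the masked region. Moments are population
# moments; skewness and excess kurtosis are defined as 0 when the region has
# zero variance so vectors stay finite on degenerate inputs.

#' Basic intensity features (6)
#'
#' Mean, standard deviation, skewness, excess kurtosis, minimum and maximum of
#' the masked pixel intensities.
#'
#' @param image numeric matrix or [radiograph()].
#' @param mask binary matrix of the same shape; foreground = 1.
#' @return Named numeric vector of length 6.
#' @export
extract_intensity <- function(image, mask) {
  x <- masked_values(image, mask)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  skew <- if (m2 > 0) mean((x - m)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((x - m)^4) / m2^2 - 3 else 0
  c("i-Intensity Mean" = m,
    "i-Intensity SD" = sqrt(m2),
    "i-Intensity Skewness" = skew,
    "i-Intensity Kurtosis" = kurt,
    "i-Intensity Min" = min(x),
    "i-Intensity Max" = max(x))
}

#' Basic contrast features (5)
#'
#' Michelson contrast `(max - min)/(max + min)`, RMS contrast (population sd
#' of the masked pixels), Weber contrast of the masked region against the
#' background mean, intensity range, and interquartile range. Undefined ratios
#' (zero denominators) are reported as 0.
#'
#' @inheritParams extract_intensity
#' @return Named numeric vector of length 5.
#' @export
extract_contrast <- function(image, mask) {
  px <- as_pixels(image)
  mk <- as_mask(mask, px)
  x <- px[mk > 0]
  if (length(x) == 0) stop_param("mask is empty")
  bg <- px[mk == 0]
  mn <- min(x); mx <- max(x)
  michelson <- if (mx + mn > 0) (mx - mn) / (mx + mn) else 0
  rms <- sqrt(mean((x - mean(x))^2))
  weber <- if (length(bg) > 0 && mean(bg) > 0) (mean(x) - mean(bg)) / mean(bg) else 0
  c("i-Contrast Michelson" = michelson,
    "i-Contrast RMS" = rms,
    "i-Contrast Weber" = weber,
    "i-Contrast Range" = mx - mn,
    "i-Contrast IQR" = unname(stats::quantile(x, 0.75) - stats::quantile(x, 0.25)))
}

masked_values <- function(image, mask) {
  px <- as_pixels(image)
  mk <- as_mask(mask, px)
  x <- px[mk > 0]
  if (length(x) == 0) stop_param("mask is empty")
  x
}

as_mask <- function(mask, px) {
  if (is.null(mask)) return(matrix(1L, nrow(px), ncol(px)))
  mk <- if (is.matrix(mask)) mask else as_pixels(mask)
  if (!all(dim(mk) == dim(px))) stop_param("mask shape does not match image")
  (mk > 0) * 1L
}
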