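# Gabor filter bank responses.
#
# Complex Gabor kernels (Gaussian envelope times complex sinusoid) at 4
# frequencies x 8 orientations; the envelope sigma follows the one-octave
# bandwidth rule sigma ~ 0.56/f with aspect ratio gamma = 0.5. Filtering is
# circular convolution via the FFT; kernel spectra are cached per image size
# and bank configuration.

.gabor_cache <- new.env(parent = emptyenv())

gabor_kernel_ffts <- function(n, m, freqs, n_orient) {
  key <- paste(c(n, m, signif(freqs, 8), n_orient), collapse = "|")
  if (!is.null(.gabor_cache[[key]])) return(.gabor_cache[[key]])
  # centred coordinate grids, wrapped so the kernel peak sits at (1,1)
  ry <- ifelse(seq_len(n) - 1 > n / 2, seq_len(n) - 1 - n, seq_len(n) - 1)
  rx <- ifelse(seq_len(m) - 1 > m / 2, seq_len(m) - 1 - m, seq_len(m) - 1)
  Y <- matrix(ry, n, m); X <- matrix(rx, n, m, byrow = TRUE)
  gamma <- 0.5
  ffts <- vector("list", length(freqs) * n_orient)
  i <- 0
  for (f in freqs) {
    sigma <- 0.56 / f
    for (b in seq_len(n_orient)) {
      th <- (b - 1) * pi / n_orient
      xp <- X * cos(th) + Y * sin(th)
      yp <- -X * sin(th) + Y * cos(th)
      env <- exp(-(xp^2 + gamma^2 * yp^2) / (2 * sigma^2))
      kern <- env * exp(2i * pi * f * xp)
      kern <- kern - mean(kern)        # zero DC response
      i <- i + 1
      ffts[[i]] <- stats::fft(kern)
    }
  }
  .gabor_cache[[key]] <- ffts
  ffts
}

#' Gabor filter-bank features (67)
#'
#' Responds with, per filter of a 4-frequency x 8-orientation complex Gabor
#' bank, the mean response magnitude and the response energy over the masked
#' region (64 values), plus three pooled statistics: the total energy J
#' summed over the bank, and the mean and standard deviation of the 32
#' per-filter mean magnitudes. Frequencies default to a one-octave ladder
#' 0.25, 0.125, 0.0625, 0.03125 cycles/pixel.
#'
#' @inheritParams extract_lbp
#' @return Named numeric vector of length `2 * n_filters + 3` (default 67).
#' @export
extract_gabor <- function(image, mask, config = feature_bank()) {
  px <- as_pixels(image)
  mk <- as_mask(mask, px) > 0
  if (!any(mk)) stop_param("mask is empty")
  freqs <- config$gabor_frequencies
  n_or <- config$gabor_orientations
  ffts <- gabor_kernel_ffts(nrow(px), ncol(px), freqs, n_or)
  fimg <- stats::fft(px)
  npx <- length(px)
  out <- numeric(2 * length(ffts))
  nms <- character(2 * length(ffts))
  means <- numeric(length(ffts))
  energies <- numeric(length(ffts))
  i <- 0
  for (a in seq_along(freqs)) {
    for (b in seq_len(n_or)) {
      i <- i + 1
      resp <- stats::fft(fimg * ffts[[i]], inverse = TRUE) / npx
      mag <- Mod(resp)[mk]
      means[i] <- mean(mag)
      energies[i] <- sum(mag^2)
      out[2 * i - 1] <- means[i]; nms[2 * i - 1] <- sprintf("i-Gabor(%d,%d)[Mean]", a, b)
      out[2 * i] <- energies[i];  nms[2 * i] <- sprintf("i-Gabor(%d,%d)[Energy]", a, b)
    }
  }
  names(out) <- nms
  c(out,
    "i-Gabor-J" = sum(energies),
    "i-Gabor-Mean" = mean(means),
    "i-Gabor-SD" = stats::sd(means) * sqrt((length(means) - 1) / length(means)))
}
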