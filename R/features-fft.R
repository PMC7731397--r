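# Local Fourier texture features.
#
# The masked image (background zero-filled) is transformed by the 2D FFT and
# the spectrum is partitioned into 4 radial frequency bands of equal width
# 0.125 cycles/pixel (the outermost band absorbs the spectrum corners). Per
# band: the fraction of total non-DC spectral energy ("Abs"), and the
# magnitude-weighted circular mean phase in radians ("Ang"). DC is excluded,
# so spectrally flat (constant) images score 0 in every band.

#' Local Fourier texture features (8)
#'
#' @inheritParams extract_lbp
#' @return Named numeric vector of length `2 * fft_bands` (default 8):
#'   band-energy fractions then band phases, interleaved per band.
#' @export
extract_local_fft <- function(image, mask, config = feature_bank()) {
  px <- as_pixels(image)
  mk <- as_mask(mask, px)
  z <- px * mk
  n <- nrow(z); m <- ncol(z)
  FF <- stats::fft(z)
  fu <- ifelse((seq_len(n) - 1) / n <= 0.5, (seq_len(n) - 1) / n, (seq_len(n) - 1) / n - 1)
  fv <- ifelse((seq_len(m) - 1) / m <= 0.5, (seq_len(m) - 1) / m, (seq_len(m) - 1) / m - 1)
  fr <- sqrt(outer(fu^2, fv^2, `+`))
  nb <- config$fft_bands
  edges <- seq(0, 0.5, length.out = nb + 1)
  edges[nb + 1] <- Inf   # outermost band takes the corners
  pow <- Mod(FF)^2
  total <- sum(pow[fr > 0])
  out <- numeric(2 * nb)
  nms <- character(2 * nb)
  for (k in seq_len(nb)) {
    inband <- fr > edges[k] & fr <= edges[k + 1]
    e <- if (total > 0) sum(pow[inband]) / total else 0
    s <- sum(FF[inband])     # magnitude-weighted phase resultant
    ang <- if (Mod(s) > 0) Arg(s) else 0
    out[2 * k - 1] <- e;   nms[2 * k - 1] <- sprintf("Fourier Abs (%d,1)", k)
    out[2 * k] <- ang;     nms[2 * k] <- sprintf("Fourier Ang (%d,1)[rad]", k)
  }
  stats::setNames(out, nms)
}
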