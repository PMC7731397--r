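# Local binary patterns with 8 circularly interpolated neighbours.
#
# At each masked pixel the 8 neighbours on a circle of radius d are sampled
# by bilinear interpolation; bit k is set when the neighbour is strictly
# brighter than the centre, giving an 8-bit code. "Uniform" (u2) codes have
# at most two 0/1 transitions around the circle; there are 58 of them, and
# all non-uniform codes share one residual bin.

# mapping from code 0..255 to u2 bin: 1..58 for uniform codes (ascending
# code order), 0 for non-uniform.
u2_table <- local({
  trans <- function(code) {
    bits <- as.integer(intToBits(code))[1:8]
    sum(bits != bits[c(2:8, 1)])
  }
  tr <- vapply(0:255, trans, integer(1))
  uni <- which(tr <= 2) - 1L            # uniform codes, ascending
  tab <- integer(256)
  tab[uni + 1L] <- seq_along(uni)       # 58 bins
  tab
})

# Bilinear sample of img at every pixel of the valid interior, shifted by a
# constant fractional offset (dr, dc). Returns a matrix over rows r0:r1,
# cols c0:c1 of img.
shift_sample <- function(img, dr, dc, r0, r1, c0, c1) {
  fr <- floor(dr); fc <- floor(dc)
  wr <- dr - fr; wc <- dc - fc
  g <- function(ar, ac) img[(r0 + ar):(r1 + ar), (c0 + ac):(c1 + ac)]
  (1 - wr) * (1 - wc) * g(fr, fc) + (1 - wr) * wc * g(fr, fc + 1) +
    wr * (1 - wc) * g(fr + 1, fc) + wr * wc * g(fr + 1, fc + 1)
}

# u2 bin index (0..58) for every valid interior pixel at the given radius.
lbp_code_map <- function(img, radius) {
  n <- nrow(img); m <- ncol(img)
  rr <- ceiling(radius) + 1L   # +1 keeps bilinear upper neighbours in bounds
  r0 <- 1 + rr; r1 <- n - rr; c0 <- 1 + rr; c1 <- m - rr
  if (r1 < r0 || c1 < c0) stop_param("radius too large for image")
  ctr <- img[r0:r1, c0:c1]
  code <- matrix(0L, nrow(ctr), ncol(ctr))
  for (k in 0:7) {
    a <- 2 * pi * k / 8
    dr <- -radius * sin(a); dc <- radius * cos(a)
    nb <- shift_sample(img, dr, dc, r0, r1, c0, c1)
    code <- code + (nb > ctr) * (2L^k)
  }
  list(bin = matrix(u2_table[code + 1L], nrow(ctr), ncol(ctr)),
       rows = r0:r1, cols = c0:c1)
}

#' Local binary pattern features (234)
#'
#' For each radius in `config$lbp_radii` (default 1..4) an 8-neighbour
#' uniform-pattern (u2) code is computed at every masked pixel and summarized
#' as a 58-bin histogram normalized by the number of masked pixels (residual
#' non-uniform mass is excluded from the 58 bins but counted in the
#' normalizer, so bins sum to 1 minus the non-uniform fraction). Two pooled
#' statistics over the combined 59-code distribution across all radii --
#' energy and Shannon entropy (bits) -- complete the family:
#' 4 x 58 + 2 = 234 values.
#'
#' @inheritParams extract_intensity
#' @param config a [feature_bank()] configuration.
#' @return Named numeric vector of length `58 * length(radii) + 2`.
#' @export
extract_lbp <- function(image, mask, config = feature_bank()) {
  px <- as_pixels(image)
  mk <- as_mask(mask, px)
  radii <- config$lbp_radii
  if (any(radii < 1)) stop_param("LBP radii must be >= 1")
  out <- numeric(0)
  pooled <- numeric(59)  # index 1 = non-uniform residual, 2..59 = u2 bins
  for (d in radii) {
    cm <- lbp_code_map(px, d)
    msub <- mk[cm$rows, cm$cols] > 0
    bins <- cm$bin[msub]
    total <- length(bins)
    if (total == 0) stop_param("mask is empty inside the LBP-valid interior")
    counts <- tabulate(bins + 1L, nbins = 59)
    hist58 <- counts[2:59] / total
    names(hist58) <- sprintf("i-LBP(%d,%d)[8,u2]", d, 1:58)
    out <- c(out, hist58)
    pooled <- pooled + counts
  }
  p <- pooled / sum(pooled)
  energy <- sum(p^2)
  entropy <- -sum(ifelse(p > 0, p * log2(p), 0))
  c(out, "i-LBP(Energy)[8,u2]" = energy, "i-LBP(Entropy)[8,u2]" = entropy)
}
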