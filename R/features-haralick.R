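# Haralick co-occurrence features.
#
# The grey-level co-occurrence matrix (GLCM) is built at distance 1 along the
# four offsets 0/45/90/135 degrees from intensities quantized to
# `glcm_levels` (default 32) bins spanning the masked intensity range; only
# pixel pairs with both ends inside the mask are counted. Each GLCM is
# symmetrized and normalized, 14 classical statistics are computed per
# offset, and each statistic is summarized by its mean and range over the
# four offsets (14 x 2 = 28 values). Statistics whose denominators vanish on
# degenerate regions (e.g. correlation at zero variance) are defined as 0.

glcm_offsets <- function(distance = 1L) {
  d <- as.integer(distance)
  list(`0` = c(0L, d), `45` = c(-d, d), `90` = c(-d, 0L), `135` = c(-d, -d))
}

# co-occurrence counts (levels x levels), symmetric, for one (dr, dc) offset
glcm_matrix <- function(q, mk, offset, levels) {
  n <- nrow(q); m <- ncol(q)
  dr <- offset[1]; dc <- offset[2]
  r0 <- max(1, 1 - dr); r1 <- min(n, n - dr)
  c0 <- max(1, 1 - dc); c1 <- min(m, m - dc)
  a <- q[r0:r1, c0:c1]
  b <- q[(r0 + dr):(r1 + dr), (c0 + dc):(c1 + dc)]
  ok <- (mk[r0:r1, c0:c1] > 0) & (mk[(r0 + dr):(r1 + dr), (c0 + dc):(c1 + dc)] > 0)
  G <- matrix(0, levels, levels)
  if (any(ok)) {
    tab <- table(factor(a[ok], levels = 1:levels), factor(b[ok], levels = 1:levels))
    G <- matrix(as.numeric(tab), levels, levels)
  }
  G <- G + t(G)
  if (sum(G) > 0) G <- G / sum(G)
  G
}

haralick_stats <- function(P) {
  L <- nrow(P)
  i <- matrix(1:L, L, L); j <- t(i)
  px <- rowSums(P)
  mu <- sum(1:L * px)
  sig2 <- sum((1:L - mu)^2 * px)
  sig <- sqrt(sig2)
  xlog <- function(x) ifelse(x > 0, log(x), 0)

  pxy_sum <- vapply(2:(2 * L), function(k) sum(P[i + j == k]), numeric(1))   # p_{x+y}
  pxy_dif <- vapply(0:(L - 1), function(k) sum(P[abs(i - j) == k]), numeric(1)) # p_{x-y}

  asm <- sum(P^2)
  contrast <- sum((0:(L - 1))^2 * pxy_dif)
  corr <- if (sig2 > 0) (sum(i * j * P) - mu^2) / sig2 else 0
  variance <- sum((i - mu)^2 * P)
  idm <- sum(P / (1 + (i - j)^2))
  sum_avg <- sum((2:(2 * L)) * pxy_sum)
  sum_var <- sum(((2:(2 * L)) - sum_avg)^2 * pxy_sum)
  sum_ent <- -sum(pxy_sum * xlog(pxy_sum))
  entropy <- -sum(P * xlog(P))
  dif_var <- sum(((0:(L - 1)) - sum((0:(L - 1)) * pxy_dif))^2 * pxy_dif)
  dif_ent <- -sum(pxy_dif * xlog(pxy_dif))
  # information measures of correlation
  ppxy <- outer(px, px)
  hxy1 <- -sum(P * xlog(ppxy))
  hxy2 <- -sum(ppxy * xlog(ppxy))
  hx <- -sum(px * xlog(px))
  imc1 <- if (hx > 0) (entropy - hxy1) / hx else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - entropy)), 0))
  # maximal correlation coefficient: sqrt of 2nd-largest eigenvalue of Q
  mcc <- 0
  if (sig2 > 0 && sum(px > 0) > 1) {
    nz <- px > 0
    Q <- (P[nz, nz, drop = FALSE] / px[nz]) %*%
      t(P[nz, nz, drop = FALSE] / px[nz])
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    if (length(ev) >= 2) mcc <- sqrt(pmax(ev[2], 0))
  }
  c(ASM = asm, Contrast = contrast, Correlation = corr, Variance = variance,
    IDM = idm, SumAverage = sum_avg, SumVariance = sum_var,
    SumEntropy = sum_ent, Entropy = entropy, DifferenceVariance = dif_var,
    DifferenceEntropy = dif_ent, IMC1 = imc1, IMC2 = imc2, MCC = mcc)
}

# quantize masked intensities to 1..levels over the masked range
glcm_quantize <- function(px, mk, levels) {
  x <- px[mk > 0]
  lo <- min(x); hi <- max(x)
  q <- matrix(1L, nrow(px), ncol(px))
  if (hi > lo) {
    qq <- 1L + as.integer(floor((px - lo) / (hi - lo) * levels))
    qq[qq > levels] <- levels
    qq[qq < 1L] <- 1L
    q <- matrix(qq, nrow(px), ncol(px))
  }
  q
}

#' Haralick texture features (28)
#'
#' @inheritParams extract_lbp
#' @return Named numeric vector of length 28: 14 statistics, each summarized
#'   by its mean and range over the four GLCM offsets.
#' @export
extract_haralick <- function(image, mask, config = feature_bank()) {
  px <- as_pixels(image)
  mk <- as_mask(mask, px)
  if (sum(mk) < 2) stop_param("mask must contain at least 2 pixels")
  levels <- config$glcm_levels
  q <- glcm_quantize(px, mk, levels)
  offs <- glcm_offsets(config$glcm_distance)
  S <- vapply(offs, function(o) haralick_stats(glcm_matrix(q, mk, o, levels)),
              numeric(14))
  means <- rowMeans(S)
  ranges <- apply(S, 1, max) - apply(S, 1, min)
  out <- c(rbind(means, ranges))
  names(out) <- as.vector(rbind(sprintf("i-Haralick(%s)[Mean]", rownames(S)),
                                sprintf("i-Haralick(%s)[Range]", rownames(S))))
  out
}
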