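# Independent brute-force oracles and tiny fixtures used across tests.
# Oracles are written scalar-wise / by enumeration, independent of the
# vectorized implementations they check.

# Per-pixel circular LBP oracle: loops over pixels and neighbours, bilinear
# interpolation by hand, strict > comparison, u2 binning by counting bit
# transitions. Returns the 58-bin histogram normalized by masked count.
oracle_lbp_hist <- function(img, mask, radius) {
  n <- nrow(img); m <- ncol(img)
  rr <- ceiling(radius) + 1
  u2bin <- function(code) {
    bits <- as.integer(intToBits(code))[1:8]
    if (sum(bits != bits[c(2:8, 1)]) > 2) return(0L)
    uni <- which(vapply(0:255, function(cd) {
      b <- as.integer(intToBits(cd))[1:8]
      sum(b != b[c(2:8, 1)]) <= 2
    }, logical(1))) - 1L
    which(uni == code)
  }
  counts <- numeric(58); total <- 0
  for (i in (1 + rr):(n - rr)) for (j in (1 + rr):(m - rr)) {
    if (mask[i, j] == 0) next
    code <- 0
    for (k in 0:7) {
      a <- 2 * pi * k / 8
      ri <- i - radius * sin(a); cj <- j + radius * cos(a)
      f1 <- floor(ri); f2 <- floor(cj)
      wy <- ri - f1; wx <- cj - f2
      v <- (1 - wy) * (1 - wx) * img[f1, f2] + (1 - wy) * wx * img[f1, f2 + 1] +
        wy * (1 - wx) * img[f1 + 1, f2] + wy * wx * img[f1 + 1, f2 + 1]
      if (v > img[i, j]) code <- code + 2^k
    }
    b <- u2bin(code)
    total <- total + 1
    if (b > 0) counts[b] <- counts[b] + 1
  }
  counts / total
}

# Hand-enumerated symmetric GLCM for one offset on a quantized grid
oracle_glcm <- function(q, mask, dr, dc, levels) {
  G <- matrix(0, levels, levels)
  n <- nrow(q); m <- ncol(q)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    i2 <- i + dr; j2 <- j + dc
    if (i2 < 1 || i2 > n || j2 < 1 || j2 > m) next
    if (mask[i, j] == 0 || mask[i2, j2] == 0) next
    G[q[i, j], q[i2, j2]] <- G[q[i, j], q[i2, j2]] + 1
  }
  G <- G + t(G)
  G / sum(G)
}

# All-pairs KNN oracle with nearest-neighbour tie-break
oracle_knn <- function(Xtr, ytr, Xte, k) {
  apply(Xte, 1, function(x) {
    d <- sqrt(colSums((t(Xtr) - x)^2))
    ord <- order(d)
    nb <- ytr[ord[1:k]]
    tb <- table(nb)
    top <- names(tb)[tb == max(tb)]
    if (length(top) == 1) top else ytr[ord[1]]
  })
}

# Gaussian clouds for classifier tests
make_clouds <- function(n, d = 2, sep = 3, seed = 1) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n * d), n, d),
               matrix(rnorm(n * d, mean = sep), n, d))
    colnames(X) <- paste0("f", 1:d)
    list(X = X, y = rep(c("viable", "nonviable_abnormal"), each = n))
  })
}

# Feature table with a few informative dimensions among noise
make_informative <- function(n_per_class = 30, n_informative = 5, n_noise = 50,
                             delta = 2, seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    X <- matrix(rnorm(n * (n_informative + n_noise)), n)
    X[seq_len(n_per_class), seq_len(n_informative)] <-
      X[seq_len(n_per_class), seq_len(n_informative)] + delta
    colnames(X) <- c(sprintf("info%02d", seq_len(n_informative)),
                     sprintf("noise%02d", seq_len(n_noise)))
    list(X = X, y = rep(c("viable", "nonviable_abnormal"), each = n_per_class))
  })
}

# A cached small labelled synthetic dataset shared by feature-level tests
small_seed_cache <- new.env()
cached_seed <- function(label, rng_seed = 11, size = 160) {
  key <- paste(label, rng_seed, size)
  if (is.null(small_seed_cache[[key]]))
    small_seed_cache[[key]] <- generate_seed(label, rng_seed = rng_seed, size = size)
  small_seed_cache[[key]]
}

# Fold-honest reference pipeline: per CV fold, rank by Fisher score on the
# training portion, keep the top-k features, fit LDA, score the held-out fold.
reference_cv_accuracy <- function(features, labels, k = 12, folds = 10, rng_seed = 1) {
  fisher_lda_cv(features, labels, k = k, folds = folds, rng_seed = rng_seed)
}
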