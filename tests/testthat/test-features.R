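# shared labelled fixture: one enhanced synthetic seed
seed_fixture <- local({
  r <- NULL
  function() {
    if (is.null(r)) {
      rad <- cached_seed("nonviable_abnormal")
      trip <- enhance_sets(rad)
      mk <- compute_mask(radiograph(trip$set_A))
      r <<- list(rad = rad, trip = trip, mask = mk)
    }
    r
  }
})

test_that("per-family counts and the 348/1044 totals hold on any seed", {
  fx <- seed_fixture()
  bank <- feature_bank()
  expect_identical(unname(bank$counts),
                   c(6L, 234L, 67L, 5L, 28L, 8L))
  expect_identical(sum(bank$counts), 348L)
  fv <- extract_all(fx$trip, fx$mask, bank, seed_id = "s1")
  expect_length(fv, 1044L)
  info <- parse_feature_name(names(fv))
  expect_false(anyDuplicated(names(fv)) > 0)
  for (set in c("A", "B", "C"))
    expect_identical(sum(info$set == set), 348L)
  counts_by_family <- table(info$family)
  expect_identical(unname(counts_by_family[names(bank$counts)]),
                   unname(3L * as.table(bank$counts)[names(bank$counts)]))
  # re-extraction is bit-identical
  expect_identical(as.numeric(fv), as.numeric(extract_all(fx$trip, fx$mask, bank)))
})

test_that("intensity features match direct moment computation; degenerate cases", {
  fx <- seed_fixture()
  img <- fx$trip$set_A
  mk <- fx$mask
  v <- extract_intensity(img, mk)
  x <- img[mk > 0]
  m <- mean(x); m2 <- mean((x - m)^2)
  expect_equal(unname(v["i-Intensity Mean"]), m)
  expect_equal(unname(v["i-Intensity SD"]), sqrt(m2))
  expect_equal(unname(v["i-Intensity Skewness"]), mean((x - m)^3) / m2^1.5)
  expect_equal(unname(v["i-Intensity Kurtosis"]), mean((x - m)^4) / m2^2 - 3)
  expect_equal(unname(v["i-Intensity Min"]), min(x))
  expect_equal(unname(v["i-Intensity Max"]), max(x))

  const <- extract_intensity(matrix(0.4, 10, 10), matrix(1, 10, 10))
  expect_equal(unname(const[c(1, 2, 5, 6)]), c(0.4, 0, 0.4, 0.4))
  half <- extract_intensity(matrix(c(0, 1), 10, 10), matrix(1, 10, 10))
  expect_equal(unname(half["i-Intensity Mean"]), 0.5)
  expect_equal(unname(half["i-Intensity Skewness"]), 0)
})

test_that("contrast features: closed-form cases and sd equivalence", {
  mk <- matrix(1, 8, 8)
  const <- extract_contrast(matrix(0.3, 8, 8), mk)
  expect_equal(unname(const), rep(0, 5))
  fullrange <- extract_contrast(matrix(c(0, 1), 8, 8), mk)
  expect_equal(unname(fullrange["i-Contrast Michelson"]), 1)
  expect_equal(unname(fullrange["i-Contrast Range"]), 1)

  fx <- seed_fixture()
  v <- extract_contrast(fx$trip$set_A, fx$mask)
  x <- fx$trip$set_A[fx$mask > 0]
  expect_equal(unname(v["i-Contrast RMS"]), sqrt(mean((x - mean(x))^2)))
})

test_that("LBP histograms equal brute-force per-pixel enumeration", {
  withr::with_seed(7, {
    img <- matrix(runif(64), 8, 8)
  })
  mk <- matrix(1, 8, 8)
  v <- extract_lbp(img, mk, feature_bank(lbp_radii = 1L))
  expect_length(v, 60)  # 58 bins + 2 pooled
  expect_equal(unname(v[1:58]), oracle_lbp_hist(img, mk, 1), tolerance = 1e-12)

  # larger grid, radius 2, partial mask
  withr::with_seed(8, img2 <- matrix(runif(196), 14, 14))
  mk2 <- matrix(0, 14, 14); mk2[4:11, 4:11] <- 1
  v2 <- extract_lbp(img2, mk2, feature_bank(lbp_radii = 2L))
  expect_equal(unname(v2[1:58]), oracle_lbp_hist(img2, mk2, 2), tolerance = 1e-12)
})

test_that("LBP on constant images concentrates on the all-zeros bin with zero entropy", {
  v <- extract_lbp(matrix(0.5, 20, 20), matrix(1, 20, 20), feature_bank())
  per_radius <- matrix(v[1:232], 58)
  expect_equal(per_radius[1, ], rep(1, 4))   # all-zeros uniform code bin
  expect_equal(sum(per_radius[-1, ]), 0)
  expect_equal(unname(v["i-LBP(Entropy)[8,u2]"]), 0)
  expect_equal(unname(v["i-LBP(Energy)[8,u2]"]), 1)
})

test_that("each per-radius LBP histogram plus its non-uniform residual sums to 1", {
  fx <- seed_fixture()
  bank <- feature_bank()
  for (img in list(fx$trip$set_A, fx$trip$set_B)) {
    v <- extract_lbp(img, fx$mask, bank)
    sums <- colSums(matrix(v[1:232], 58))
    expect_true(all(sums <= 1 + 1e-9))
    # residual mass is the non-uniform fraction; recompute it from raw codes
    for (ri in 1:4) {
      expect_gte(sums[ri], 0.5)  # most codes are uniform on smooth images
    }
  }
})

test_that("Gabor features: zero input, orientation selectivity, count", {
  bank <- feature_bank()
  mk <- matrix(1, 64, 64)
  z <- extract_gabor(matrix(0, 64, 64), mk, bank)
  expect_length(z, 67)
  expect_equal(unname(z), rep(0, 67))

  # grating matching bank orientation 3 (45 degrees) at frequency 1 (0.25 c/px)
  n <- 96
  i <- matrix(rep(1:n, n), n); j <- t(i)
  th <- 2 * pi / 8
  grating <- 0.5 + 0.5 * cos(2 * pi * 0.25 * (j * cos(th) + i * sin(th)))
  g <- extract_gabor(grating, matrix(1, n, n), bank)
  means <- g[sprintf("i-Gabor(1,%d)[Mean]", 1:8)]
  expect_identical(unname(which.max(means)), 3L)
  expect_length(g, 67)
})

test_that("Haralick GLCM matches hand-enumerated co-occurrence on stripes", {
  # 6x6 two-level vertical stripes
  img <- matrix(rep(c(0.2, 0.8), length.out = 6), 6, 6, byrow = TRUE)
  mk <- matrix(1, 6, 6)
  q <- ifelse(img > 0.5, 2L, 1L)
  # offset 0 degrees = (0, +1); contrast of hand-built GLCM
  G <- oracle_glcm(q, mk, 0, 1, 2)
  contrast_oracle <- sum(outer(1:2, 1:2, function(a, b) (a - b)^2) * G)
  v <- extract_haralick(img, mk, feature_bank(glcm_levels = 2L))
  # 0-degree contrast equals mean + range combination: recover per-offset via
  # a direct internal recomputation on the quantized grid
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  contrasts <- vapply(offs, function(o) {
    Go <- oracle_glcm(q, mk, o[1], o[2], 2)
    sum(outer(1:2, 1:2, function(a, b) (a - b)^2) * Go)
  }, numeric(1))
  expect_equal(unname(v["i-Haralick(Contrast)[Mean]"]), mean(contrasts))
  expect_equal(unname(v["i-Haralick(Contrast)[Range]"]),
               max(contrasts) - min(contrasts))
  expect_equal(contrasts[1], contrast_oracle)
  expect_length(v, 28)
})

test_that("Haralick on constant regions: energy 1, contrast 0", {
  v <- extract_haralick(matrix(0.6, 12, 12), matrix(1, 12, 12), feature_bank())
  expect_equal(unname(v["i-Haralick(ASM)[Mean]"]), 1)
  expect_equal(unname(v["i-Haralick(Contrast)[Mean]"]), 0)
  expect_true(all(is.finite(v)))
})

test_that("rotating the image by 90 degrees permutes offset-wise GLCM statistics", {
  withr::with_seed(5, img <- matrix(runif(100), 10, 10))
  mk <- matrix(1, 10, 10)
  bank <- feature_bank(glcm_levels = 8L)
  q <- 1L + as.integer(floor((img - min(img)) / (max(img) - min(img)) * 8))
  q[q > 8] <- 8L
  q <- matrix(q, 10, 10)
  rot <- t(q)[, 10:1]   # 90-degree rotation
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  stat <- function(qq) sort(vapply(offs, function(o) {
    G <- oracle_glcm(qq, mk, o[1], o[2], 8)
    sum(outer(1:8, 1:8, function(a, b) (a - b)^2) * G)
  }, numeric(1)))
  expect_equal(stat(q), stat(rot), tolerance = 1e-12)
})

test_that("local FFT features: spectral flatness, band concentration, count", {
  mk <- matrix(1, 64, 64)
  v0 <- extract_local_fft(matrix(0.7, 64, 64), mk, feature_bank())
  expect_length(v0, 8)
  expect_equal(unname(v0[c(1, 3, 5, 7)]), rep(0, 4))  # band energies

  # horizontal grating at 0.1875 c/px falls in band 2 (0.125, 0.25]
  n <- 64
  j <- matrix(rep(1:n, each = n), n)
  grating <- 0.5 + 0.5 * cos(2 * pi * 0.1875 * j)
  vg <- extract_local_fft(grating, mk, feature_bank())
  bands <- unname(vg[c(1, 3, 5, 7)])
  expect_identical(which.max(bands), 2L)
  expect_gte(bands[2], 0.9)
})

test_that("a family/config count mismatch raises a configuration error", {
  fx <- seed_fixture()
  bank <- feature_bank()
  bank$counts[["gabor"]] <- 99L
  expect_error(extract_all(fx$trip, fx$mask, bank),
               class = "seedxray_config_error")
})

test_that("published-style and package feature names both parse", {
  own <- parse_feature_name(c("i-LBP(2,17)[8,u2][B]", "i-Gabor(1,3)[Mean][A]",
                              "Fourier Abs (2,1)[C]", "i-Haralick(ASM)[Mean][A]"))
  expect_identical(own$family, c("lbp", "gabor", "local_fft", "haralick"))
  expect_identical(own$set, c("B", "A", "C", "A"))
  published <- parse_feature_name(c("i-LBP(3,34)[8,u2][sd-C]", "i-Gabor(1,1)[Max-A]",
                                    "Fourier Ang (2,1)[rad][Max-C]",
                                    "i-Intensity Skewness[Max-C]", "i-Gabor-J[sd-A]"))
  expect_identical(published$family,
                   c("lbp", "gabor", "local_fft", "intensity", "gabor"))
  expect_identical(published$set, c("C", "A", "C", "C", "A"))
})
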