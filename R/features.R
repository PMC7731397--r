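#' Feature bank configuration
#'
#' Fixes the parameterization of the six texture-feature families and the
#' per-family output counts. With the defaults the families contribute
#' intensity 6, LBP 234, Gabor 67, contrast 5, Haralick 28 and local FFT 8
#' values -- 348 per image and 1044 per seed over the three enhancement sets.
#' The configuration is a plain serializable list so a run can be reproduced
#' from its config alone.
#'
#' @param lbp_radii integer radii of the 8-neighbour u2 LBP operators.
#' @param gabor_frequencies Gabor carrier frequencies in cycles/pixel.
#' @param gabor_orientations number of evenly spaced orientations in \[0, pi).
#' @param glcm_levels grey levels for GLCM quantization.
#' @param glcm_distance GLCM pair distance in pixels.
#' @param fft_bands number of radial frequency bands.
#' @return A list of class `feature_bank` with a `counts` element giving the
#'   per-family feature counts.
#' @export
#' @examples
#' bank <- feature_bank()
#' bank$counts          # 6 234 67 5 28 8
#' sum(bank$counts)     # 348
feature_bank <- function(lbp_radii = 1:4,
                         gabor_frequencies = 0.25 / 2^(0:3),
                         gabor_orientations = 8L,
                         glcm_levels = 32L,
                         glcm_distance = 1L,
                         fft_bands = 4L) {
  cfg <- list(lbp_radii = as.integer(lbp_radii),
              gabor_frequencies = as.numeric(gabor_frequencies),
              gabor_orientations = as.integer(gabor_orientations),
              glcm_levels = as.integer(glcm_levels),
              glcm_distance = as.integer(glcm_distance),
              fft_bands = as.integer(fft_bands),
              version = "1")
  cfg$counts <- c(intensity = 6L,
                  lbp = 58L * length(cfg$lbp_radii) + 2L,
                  gabor = 2L * length(cfg$gabor_frequencies) * cfg$gabor_orientations + 3L,
                  contrast = 5L,
                  haralick = 28L,
                  local_fft = 2L * cfg$fft_bands)
  structure(cfg, class = "feature_bank")
}

# All families for one image (no enhancement-set tag): 348 values by default.
extract_image_features <- function(image, mask, config = feature_bank()) {
  fam <- list(intensity = extract_intensity(image, mask),
              lbp = extract_lbp(image, mask, config),
              gabor = extract_gabor(image, mask, config),
              contrast = extract_contrast(image, mask),
              haralick = extract_haralick(image, mask, config),
              local_fft = extract_local_fft(image, mask, config))
  for (f in names(fam)) {
    if (length(fam[[f]]) != config$counts[[f]])
      stop_param(sprintf("family '%s' produced %d features, config promises %d",
                         f, length(fam[[f]]), config$counts[[f]]),
                 class = "seedxray_config_error")
  }
  unlist(unname(fam))
}

#' Extract the full feature vector of one seed
#'
#' Runs all six feature families on each image of the enhancement triplet,
#' tagging names with the enhancement set (`[A]`, `[B]`, `[C]`). With the
#' default bank this yields 348 features per set and 1044 per seed. For
#' efficiency the images are cropped to the mask bounding box (8-pixel
#' margin) before extraction; all features are masked-region statistics, so
#' this leaves values unchanged up to the FFT-size convention, which is fixed
#' by the crop rule and therefore deterministic.
#'
#' @param triplet an [enhance_sets()] result.
#' @param mask binary seed mask matching the triplet's shape.
#' @param config a [feature_bank()].
#' @param seed_id identifier attached to the result.
#' @return Named numeric vector of length `3 * sum(config$counts)` (default
#'   1044) with attribute `seed_id`.
#' @export
extract_all <- function(triplet, mask, config = feature_bank(), seed_id = NULL) {
  if (!inherits(triplet, "enhanced_triplet"))
    stop_param("triplet must be an enhanced_triplet")
  mk <- as_mask(mask, triplet$set_A)
  bb <- mask_bbox(mk, margin = 8L)
  mkc <- mk[bb$rows, bb$cols]
  out <- numeric(0)
  for (set in c("A", "B", "C")) {
    img <- triplet[[paste0("set_", set)]][bb$rows, bb$cols]
    v <- extract_image_features(img, mkc, config)
    names(v) <- paste0(names(v), "[", set, "]")
    out <- c(out, v)
  }
  if (anyDuplicated(names(out)))
    stop_param("feature names are not unique", class = "seedxray_config_error")
  if (any(!is.finite(out)))
    stop_param("non-finite feature values produced")
  attr(out, "seed_id") <- seed_id
  out
}

mask_bbox <- function(mk, margin = 8L) {
  idx <- which(mk > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop_param("mask is empty")
  r <- range(idx[, 1]); c <- range(idx[, 2])
  list(rows = max(1, r[1] - margin):min(nrow(mk), r[2] + margin),
       cols = max(1, c[1] - margin):min(ncol(mk), c[2] + margin))
}

#' Parse a feature name into family and enhancement set
#'
#' Understands both this package's names (e.g. `i-LBP(2,17)[8,u2][B]`) and
#' the field's published naming style with block-aggregation tags in the set
#' bracket (e.g. `i-LBP(3,34)[8,u2][sd-C]`, `i-Gabor(1,1)[Max-A]`,
#' `Fourier Ang (2,1)[rad][Max-C]`, `i-Intensity Skewness[Max-C]`).
#'
#' @param names character vector of feature names.
#' @return data.frame with columns `name`, `family` (intensity/lbp/gabor/
#'   contrast/haralick/local_fft), `set` (A/B/C or NA).
#' @export
parse_feature_name <- function(names) {
  family <- rep(NA_character_, length(names))
  family[grepl("^i-LBP", names)] <- "lbp"
  family[grepl("^i-Gabor", names)] <- "gabor"
  family[grepl("^Fourier", names)] <- "local_fft"
  family[grepl("^i-Intensity", names)] <- "intensity"
  family[grepl("^i-Contrast", names)] <- "contrast"
  family[grepl("^i-Haralick", names)] <- "haralick"
  set <- rep(NA_character_, length(names))
  has <- grepl("\\[[^][]*\\]$", names)
  bracket <- rep(NA_character_, length(names))
  bracket[has] <- regmatches(names, regexpr("\\[[^][]*\\]$", names))
  tag <- sub("^\\[(?:Max-|sd-)?([ABC])\\]$", "\\1", bracket)
  ok <- !is.na(tag) & tag %in% c("A", "B", "C")
  set[ok] <- tag[ok]
  data.frame(name = names, family = family, set = set, stringsAsFactors = FALSE)
}

#' Extract features for a whole dataset
#'
#' Convenience wrapper: mask (on `set_A`, reused for all three sets), enhance
#' and extract for every radiograph in a list, returning a feature table.
#'
#' @param images list of [radiograph()] objects.
#' @param config a [feature_bank()].
#' @param s sd-scaling gain passed to [enhance_sets()].
#' @return A list with `features` (numeric matrix, one row per seed, columns
#'   named) and `labels` (character vector, NA where unlabelled).
#' @export
extract_dataset <- function(images, config = feature_bank(), s = 0.15) {
  rows <- lapply(images, function(im) {
    trip <- enhance_sets(im, s = s)
    mk <- compute_mask(radiograph(trip$set_A, im$seed_id, im$cultivar, im$label))
    extract_all(trip, mk, config, seed_id = im$seed_id)
  })
  X <- do.call(rbind, rows)
  rownames(X) <- vapply(images, function(im) im$seed_id, character(1))
  list(features = X,
       labels = vapply(images, function(im) im$label %||% NA_character_, character(1)))
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
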