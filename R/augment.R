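# Six-way geometric augmentation: rotation, reflection, x/y translation,
# x/y scaling. Each source image yields exactly six variants (the original
# is not among them), so 1282 inputs produce 7692 augmented images.

#' Augmentation specification
#'
#' Parameter ranges for the six variant slots. Draws are uniform within each
#' range; translations are rounded to whole pixels (exact shifts), rotation
#' and scaling use bilinear resampling about the image centre. Defaults are
#' mild, label-preserving perturbations: rotation +/-25 degrees, translation
#' +/-10 px, scaling 0.9--1.1, horizontal reflection.
#'
#' @param rotation_range rotation angle range in degrees.
#' @param translation_range translation range in pixels (applies to x and y
#'   slots separately).
#' @param scaling_range scale-factor range (applies to x and y slots
#'   separately); must be positive.
#' @param rng_seed master seed for parameter draws.
#' @return A list of class `augmentation_spec`.
#' @export
augmentation_spec <- function(rotation_range = c(-25, 25),
                              translation_range = c(-10, 10),
                              scaling_range = c(0.9, 1.1),
                              rng_seed = 1L) {
  if (any(scaling_range <= 0)) stop_param("scaling factors must be positive")
  structure(list(rotation_range = rotation_range,
                 translation_range = translation_range,
                 scaling_range = scaling_range,
                 rng_seed = as.integer(rng_seed),
                 variants = c("rotation", "reflection", "translate-x",
                              "translate-y", "scale-x", "scale-y")),
            class = "augmentation_spec")
}

# Bilinear affine warp: out(r, c) = img at A %*% (r,c) about the centre.
# Identity parameters reproduce the input bit-for-bit because sampling
# coordinates then coincide with the pixel grid. Out-of-frame samples fill
# with the image minimum (background).
warp_affine <- function(img, sx = 1, sy = 1, angle = 0, tx = 0, ty = 0) {
  n <- nrow(img); m <- ncol(img)
  cy <- (n + 1) / 2; cx <- (m + 1) / 2
  rc <- matrix(rep(seq_len(n), m), n, m) - cy
  cc <- matrix(rep(seq_len(m), each = n), n, m) - cx
  th <- angle * pi / 180
  # inverse map: source = R(-th) %*% diag(1/sy, 1/sx) %*% dest - t
  ry <- (cos(th) * rc + sin(th) * cc) / sy + cy - ty
  rx <- (-sin(th) * rc + cos(th) * cc) / sx + cx - tx
  fy <- floor(ry); fx <- floor(rx)
  wy <- ry - fy; wx <- rx - fx
  fill <- min(img)
  at <- function(r, c) {
    ok <- r >= 1 & r <= n & c >= 1 & c <= m
    v <- matrix(fill, n, m)
    v[ok] <- img[cbind(r[ok], c[ok])]
    v
  }
  (1 - wy) * (1 - wx) * at(fy, fx) + (1 - wy) * wx * at(fy, fx + 1) +
    wy * (1 - wx) * at(fy + 1, fx) + wy * wx * at(fy + 1, fx + 1)
}

#' Produce the six augmentation variants of one radiograph
#'
#' One output per variant slot -- rotation, horizontal reflection,
#' x-translation, y-translation, x-scaling, y-scaling -- each the input's
#' size, deterministic given the spec's `rng_seed` and `draw_index`.
#'
#' @param image a [radiograph()].
#' @param spec an [augmentation_spec()].
#' @param draw_index index decorrelating parameter draws across images of a
#'   dataset (default 1).
#' @return Named list of six [radiograph()] objects with a `"transform"`
#'   attribute each recording the drawn parameters.
#' @export
augment_six <- function(image, spec = augmentation_spec(), draw_index = 1L) {
  px <- as_pixels(image)
  sid <- if (inherits(image, "radiograph")) image$seed_id else "img"
  cv <- if (inherits(image, "radiograph")) image$cultivar else "cv"
  lb <- if (inherits(image, "radiograph")) image$label else NA_character_
  pars <- with_local_seed(derive_seed(spec$rng_seed, draw_index), list(
    angle = runif(1, spec$rotation_range[1], spec$rotation_range[2]),
    tx = round(runif(1, spec$translation_range[1], spec$translation_range[2])),
    ty = round(runif(1, spec$translation_range[1], spec$translation_range[2])),
    sx = runif(1, spec$scaling_range[1], spec$scaling_range[2]),
    sy = runif(1, spec$scaling_range[1], spec$scaling_range[2])))
  if (pars$sx <= 0 || pars$sy <= 0) stop_param("degenerate scale factor")
  variants <- list(
    rotation = list(px = warp_affine(px, angle = pars$angle),
                    params = list(angle = pars$angle)),
    reflection = list(px = px[, rev(seq_len(ncol(px)))],
                      params = list(axis = "horizontal")),
    `translate-x` = list(px = warp_affine(px, tx = pars$tx),
                         params = list(tx = pars$tx)),
    `translate-y` = list(px = warp_affine(px, ty = pars$ty),
                         params = list(ty = pars$ty)),
    `scale-x` = list(px = warp_affine(px, sx = pars$sx),
                     params = list(sx = pars$sx)),
    `scale-y` = list(px = warp_affine(px, sy = pars$sy),
                     params = list(sy = pars$sy)))
  out <- lapply(names(variants), function(v) {
    r <- radiograph(clip01(variants[[v]]$px),
                    seed_id = paste0(sid, ".", v), cultivar = cv, label = lb)
    attr(r, "transform") <- c(list(variant = v, source_id = sid),
                              variants[[v]]$params)
    r
  })
  stats::setNames(out, names(variants))
}

#' Build the full augmented dataset
#'
#' Applies [augment_six()] to every input; the output holds exactly six
#' variants per source image plus a manifest linking each variant to its
#' source and drawn transform parameters. Regeneration with the same spec is
#' identical.
#'
#' @param images non-empty list of [radiograph()] objects.
#' @param spec an [augmentation_spec()].
#' @return List with `images` (length `6 * length(images)`) and `manifest`
#'   (data.frame: id, source_id, variant, label, params as JSON).
#' @export
build_augmented_dataset <- function(images, spec = augmentation_spec()) {
  if (length(images) == 0) stop_param("images must be non-empty")
  out <- vector("list", 6L * length(images))
  rows <- vector("list", 6L * length(images))
  k <- 0L
  for (i in seq_along(images)) {
    for (v in augment_six(images[[i]], spec, draw_index = i)) {
      k <- k + 1L
      out[[k]] <- v
      tf <- attr(v, "transform")
      rows[[k]] <- data.frame(id = v$seed_id, source_id = tf$source_id,
                              variant = tf$variant,
                              label = ifelse(is.na(v$label), NA, v$label),
                              params = as.character(jsonlite::toJSON(
                                tf[setdiff(names(tf), c("variant", "source_id"))],
                                auto_unbox = TRUE)),
                              stringsAsFactors = FALSE)
    }
  }
  list(images = out, manifest = do.call(rbind, rows))
}

#' Leakage-safe stratified train/validation/test split
#'
#' Splits items into partitions at the given ratios, stratified by label. All
#' items sharing a `group` (e.g. all augmentation variants of one source
#' image) are kept in the same partition, so augmented near-duplicates can
#' never leak between training and test sets. Deterministic given
#' `rng_seed`.
#'
#' @param labels class label per item.
#' @param groups source-image group per item; defaults to one group per item.
#' @param ratios three percentages summing to 100 (default `c(70, 15, 15)`).
#' @param rng_seed shuffle seed.
#' @return Character vector (`"train"`, `"validation"`, `"test"`) per item.
#' @export
split_dataset <- function(labels, groups = seq_along(labels),
                          ratios = c(70, 15, 15), rng_seed = 1L) {
  if (length(ratios) != 3 || abs(sum(ratios) - 100) > 1e-9)
    stop_param("ratios must be three percentages summing to 100")
  labels <- as.character(labels)
  groups <- as.character(groups)
  # label of a group = label of its members (variants inherit the source label)
  gl <- tapply(labels, groups, function(x) x[1])
  part_of_group <- character(0)
  # cumulative rounding across classes keeps every partition's total at the
  # exact ratio while per-class counts stay within one item of proportional
  cum_tr <- 0; got_tr <- 0; cum_va <- 0; got_va <- 0
  with_local_seed(rng_seed, {
    for (lb in sort(unique(gl))) {
      g <- names(gl)[gl == lb]
      if (length(g) < 3) stop_param(sprintf("class '%s' too small to split", lb))
      g <- sample(g)
      n <- length(g)
      cum_tr <- cum_tr + n * ratios[1] / 100
      n_tr <- round(cum_tr) - got_tr; got_tr <- got_tr + n_tr
      cum_va <- cum_va + n * ratios[2] / 100
      n_va <- round(cum_va) - got_va; got_va <- got_va + n_va
      n_tr <- max(1, min(n_tr, n - 2)); n_va <- max(1, min(n_va, n - n_tr - 1))
      p <- rep("test", n)
      p[seq_len(n_tr)] <- "train"
      p[n_tr + seq_len(n_va)] <- "validation"
      part_of_group <- c(part_of_group, stats::setNames(p, g))
    }
  })
  unname(part_of_group[groups])
}
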