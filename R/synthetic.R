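#' Morphology parameters for the synthetic radiograph generator
#'
#' Controls the generative regime of a synthetic seed radiograph. A viable
#' seed is an ellipse with a bright coat rim and a uniformly bright, regularly
#' shaped endosperm. A nonviable or abnormal seed additionally carries dark
#' internal blobs (air spaces) covering a target fraction of the endosperm
#' area and/or an irregular, perturbed boundary. Setting
#' `air_space_fraction = 0` and `irregularity = 0` yields the viable-class
#' generative regime regardless of label.
#'
#' @param coat_intensity coat-rim intensity, in (0, 1].
#' @param endosperm_intensity endosperm plateau intensity, in (0, 1].
#' @param air_space_fraction target fraction of the endosperm area occupied by
#'   dark air-space blobs, in \[0, 0.5\].
#' @param n_blobs number of air-space blobs (>= 0).
#' @param irregularity amplitude of the low-order harmonic boundary
#'   perturbation (0 = regular ellipse).
#' @param noise_sd standard deviation of additive Gaussian pixel noise.
#' @param blur_sigma Gaussian point-spread sigma in pixels.
#' @param cultivar_shift additive intensity offset applied to the whole seed,
#'   emulating cultivar-level attenuation differences.
#' @return A list of class `morphology_params`.
#' @export
morphology_params <- function(coat_intensity = 0.85, endosperm_intensity = 0.62,
                              air_space_fraction = 0, n_blobs = 0,
                              irregularity = 0, noise_sd = 0.02,
                              blur_sigma = 1.0, cultivar_shift = 0) {
  for (nm in c("coat_intensity", "endosperm_intensity", "air_space_fraction",
               "irregularity", "noise_sd", "blur_sigma", "cultivar_shift")) {
    v <- get(nm)
    if (!is_scalar_num(v)) stop_param(paste0(nm, " must be a finite scalar"))
  }
  if (coat_intensity <= 0 || coat_intensity > 1)
    stop_param("coat_intensity must be in (0, 1]")
  if (endosperm_intensity <= 0 || endosperm_intensity > 1)
    stop_param("endosperm_intensity must be in (0, 1]")
  if (air_space_fraction < 0 || air_space_fraction > 0.5)
    stop_param("air_space_fraction must be in [0, 0.5]")
  if (n_blobs < 0 || n_blobs != round(n_blobs))
    stop_param("n_blobs must be a non-negative integer")
  if (irregularity < 0) stop_param("irregularity must be >= 0")
  if (noise_sd < 0) stop_param("noise_sd must be >= 0")
  if (blur_sigma < 0) stop_param("blur_sigma must be >= 0")
  structure(list(coat_intensity = coat_intensity,
                 endosperm_intensity = endosperm_intensity,
                 air_space_fraction = air_space_fraction,
                 n_blobs = as.integer(n_blobs), irregularity = irregularity,
                 noise_sd = noise_sd, blur_sigma = blur_sigma,
                 cultivar_shift = cultivar_shift),
            class = "morphology_params")
}

#' @rdname morphology_params
#' @param label class label; `"viable"` gives the uniform-endosperm regime,
#'   `"nonviable_abnormal"` the air-space/irregular regime.
#' @export
default_morphology <- function(label) {
  switch(label,
         viable = morphology_params(),
         nonviable_abnormal = morphology_params(air_space_fraction = 0.2,
                                                n_blobs = 3, irregularity = 0.15),
         stop_param("label must be 'viable' or 'nonviable_abnormal'"))
}

# Intensity drop of an air-space blob below the endosperm plateau.
AIR_CONTRAST <- 0.35
# Endosperm boundary as a fraction of the seed radius (coat rim occupies the rest).
RIM_FRACTION <- 0.82

# Normalized elliptical radius rho and angle theta for every pixel of a
# size x size frame, for an ellipse centred at (cx, cy) with semi-axes
# (sa, sb) rotated by phi.
ellipse_field <- function(size, cx, cy, sa, sb, phi) {
  x <- matrix(rep(seq_len(size), each = size), size, size)   # column index
  y <- matrix(rep(seq_len(size), times = size), size, size)  # row index
  dx <- x - cx; dy <- y - cy
  u <- (dx * cos(phi) + dy * sin(phi)) / sa
  v <- (-dx * sin(phi) + dy * cos(phi)) / sb
  list(rho = sqrt(u^2 + v^2), theta = atan2(v, u))
}

# Radial modulation 1 + irregularity * (low-order harmonics), evaluated at theta.
radial_modulation <- function(theta, irregularity, coefs) {
  if (irregularity == 0) return(1)
  mod <- 0
  for (k in seq_len(nrow(coefs)))
    mod <- mod + coefs[k, 1] * cos((k + 1) * theta) + coefs[k, 2] * sin((k + 1) * theta)
  1 + irregularity * mod
}

#' Generate one synthetic seed radiograph
#'
#' Draws a single labelled synthetic X-ray projection image: an elliptical
#' seed (semi-axes spanning 30--60 percent of the frame, uniformly random
#' orientation) rendered bright on a dark background, with a coat rim, a
#' uniform endosperm, optional internal air-space blobs and boundary
#' irregularity, degraded by Gaussian blur then additive Gaussian noise and
#' clipped to \[0, 1\]. Fully deterministic given `rng_seed`.
#'
#' Ground truth (seed, endosperm and blob masks, plus centroid and the
#' parameters used) is attached as attribute `"truth"` for downstream
#' validation.
#'
#' @param label `"viable"` or `"nonviable_abnormal"`.
#' @param params a [morphology_params()] object; defaults to
#'   [default_morphology()] for the label.
#' @param rng_seed integer seed for this image.
#' @param size frame side length in pixels (default 224).
#' @param seed_id,cultivar identifiers stored on the radiograph.
#' @return A [radiograph()] with a `"truth"` attribute.
#' @export
#' @examples
#' r <- generate_seed("nonviable_abnormal", rng_seed = 7)
#' truth <- attr(r, "truth")
#' sum(truth$blob_mask) / sum(truth$endosperm_mask)  # ~ air_space_fraction
generate_seed <- function(label, params = default_morphology(label),
                          rng_seed = 1L, size = 224L,
                          seed_id = "s1", cultivar = "cv1") {
  if (!label %in% c("viable", "nonviable_abnormal"))
    stop_param("label must be 'viable' or 'nonviable_abnormal'")
  if (!inherits(params, "morphology_params"))
    params <- do.call(morphology_params, as.list(params))
  size <- as.integer(size)
  if (size < 16) stop_param("size must be >= 16")

  with_local_seed(rng_seed, {
    cx <- size / 2 + runif(1, -0.03, 0.03) * size
    cy <- size / 2 + runif(1, -0.03, 0.03) * size
    sa <- runif(1, 0.15, 0.30) * size
    sb <- runif(1, 0.15, 0.30) * size
    phi <- runif(1, 0, pi)
    irr_coefs <- matrix(rnorm(8, sd = 0.5 / (1:4 + 1)), ncol = 2)

    ef <- ellipse_field(size, cx, cy, sa, sb, phi)
    rmod <- radial_modulation(ef$theta, params$irregularity, irr_coefs)
    seed_mask <- ef$rho <= rmod
    endo_mask <- ef$rho <= RIM_FRACTION * rmod

    img <- matrix(0.08, size, size)
    img[seed_mask] <- params$coat_intensity
    img[endo_mask] <- params$endosperm_intensity

    blob_mask <- matrix(FALSE, size, size)
    if (params$air_space_fraction > 0 && params$n_blobs > 0) {
      blob_mask <- place_blobs(size, cx, cy, sa, sb, phi, endo_mask,
                               params$air_space_fraction, params$n_blobs)
      img[blob_mask] <- params$endosperm_intensity - AIR_CONTRAST
    }
    img[seed_mask] <- img[seed_mask] + params$cultivar_shift
    img <- clip01(img)

    if (params$blur_sigma > 0)
      img <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = params$blur_sigma))
    if (params$noise_sd > 0)
      img <- img + matrix(rnorm(size^2, sd = params$noise_sd), size, size)
    img <- clip01(img)

    r <- radiograph(img, seed_id = seed_id, cultivar = cultivar, label = label)
    centroid <- c(row = mean(which(seed_mask, arr.ind = TRUE)[, 1]),
                  col = mean(which(seed_mask, arr.ind = TRUE)[, 2]))
    attr(r, "truth") <- list(seed_mask = seed_mask, endosperm_mask = endo_mask,
                             blob_mask = blob_mask, centroid = centroid,
                             params = params, rng_seed = rng_seed)
    r
  })
}

# Place n elliptical air-space blobs inside the endosperm whose merged area
# hits target_frac of the endosperm area. Blob centres and shapes are drawn
# once; a single global radius scale is then bisected so that the union
# (overlaps merged) matches the target to within 0.5 percent of the endosperm
# area. Blobs are clipped to the endosperm.
place_blobs <- function(size, cx, cy, sa, sb, phi, endo_mask, target_frac, n) {
  area_e <- sum(endo_mask)
  target <- target_frac * area_e
  # centres at elliptical radius <= 0.6 of the endosperm, in ellipse coords
  t <- runif(n, 0, 2 * pi)
  rr <- sqrt(runif(n)) * 0.6 * RIM_FRACTION
  bx <- cx + rr * sa * cos(t) * cos(phi) - rr * sb * sin(t) * sin(phi)
  by <- cy + rr * sa * cos(t) * sin(phi) + rr * sb * sin(t) * cos(phi)
  r0 <- sqrt(target / (n * pi)) * runif(n, 0.7, 1.3)
  ratio <- runif(n, 0.6, 1)
  ang <- runif(n, 0, pi)

  union_at <- function(s) {
    m <- matrix(FALSE, size, size)
    for (i in seq_len(n)) {
      efi <- ellipse_field(size, bx[i], by[i], s * r0[i] / sqrt(ratio[i]),
                           s * r0[i] * sqrt(ratio[i]), ang[i])
      m <- m | (efi$rho <= 1)
    }
    m & endo_mask
  }
  lo <- 0.1; hi <- 4
  for (iter in 1:28) {
    mid <- (lo + hi) / 2
    a <- sum(union_at(mid))
    if (abs(a - target) <= 0.005 * area_e) break
    if (a < target) lo <- mid else hi <- mid
  }
  union_at((lo + hi) / 2)
}

#' Generate a balanced labelled dataset of synthetic radiographs
#'
#' Emits exactly `n_per_class` seeds per class, assigned round-robin to the
#' cultivars, together with a manifest recording seed id, cultivar, label and
#' the per-image RNG seed. Each image draws from its own seed derived from
#' `rng_seed`, so regeneration with the same arguments is bit-identical.
#'
#' @param n_per_class number of seeds per class (>= 1).
#' @param cultivars non-empty character vector of cultivar names.
#' @param params_by_cultivar optional named list: for each cultivar, a list
#'   with elements `viable` and `nonviable_abnormal` giving
#'   [morphology_params()]. Defaults to [default_morphology()] with small
#'   per-cultivar intensity shifts.
#' @param rng_seed integer master seed.
#' @param size frame side length in pixels.
#' @param dir optional directory; when given, PNGs and `manifest.csv` are
#'   written there.
#' @return A list with `images` (list of [radiograph()]) and `manifest`
#'   (data.frame with columns seed_id, cultivar, label, rng_seed).
#' @export
generate_dataset <- function(n_per_class, cultivars = c("cv1", "cv2", "cv3"),
                             params_by_cultivar = NULL, rng_seed = 1L,
                             size = 224L, dir = NULL) {
  if (!is_scalar_num(n_per_class) || n_per_class < 1)
    stop_param("n_per_class must be >= 1")
  if (length(cultivars) == 0) stop_param("cultivars must be non-empty")
  labels <- c("viable", "nonviable_abnormal")
  if (is.null(params_by_cultivar)) {
    shifts <- seq(-0.02, 0.02, length.out = max(length(cultivars), 2))[seq_along(cultivars)]
    params_by_cultivar <- stats::setNames(lapply(seq_along(cultivars), function(i) {
      lapply(stats::setNames(labels, labels), function(lb) {
        p <- default_morphology(lb); p$cultivar_shift <- shifts[i]; p
      })
    }), cultivars)
  }
  n_total <- 2L * as.integer(n_per_class)
  images <- vector("list", n_total)
  man <- data.frame(seed_id = character(n_total), cultivar = character(n_total),
                    label = character(n_total), rng_seed = integer(n_total),
                    stringsAsFactors = FALSE)
  idx <- 0L
  for (lb in labels) {
    for (i in seq_len(n_per_class)) {
      idx <- idx + 1L
      cv <- cultivars[((i - 1L) %% length(cultivars)) + 1L]
      s <- derive_seed(rng_seed, idx)
      sid <- sprintf("%s%04d", substr(lb, 1, 1), i)
      images[[idx]] <- generate_seed(lb, params_by_cultivar[[cv]][[lb]],
                                     rng_seed = s, size = size,
                                     seed_id = sid, cultivar = cv)
      man[idx, ] <- list(sid, cv, lb, s)
    }
  }
  if (!is.null(dir)) {
    for (im in images) write_radiograph(im, dir)
    utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  list(images = images, manifest = man)
}
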