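#' Radiograph container
#'
#' A radiograph is a single-seed 2D X-ray projection image: a square matrix of
#' intensities in \[0, 1\] (by convention the seed is bright, the background
#' dark, i.e. higher attenuation is rendered bright) together with seed and
#' cultivar identifiers and an optional viability label.
#'
#' @param pixels numeric matrix with values in \[0, 1\]. The standard frame is
#'   224 x 224 pixels; other square sizes are accepted for reduced-scale work.
#' @param seed_id character identifier of the seed.
#' @param cultivar character cultivar identifier.
#' @param label optional class label, one of `"viable"` or
#'   `"nonviable_abnormal"`, or `NA`.
#' @return An object of class `radiograph`: a list with elements `pixels`,
#'   `seed_id`, `cultivar`, `label`.
#' @export
radiograph <- function(pixels, seed_id = "seed", cultivar = "cultivar",
                       label = NA_character_) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop_param("pixels must be a numeric matrix")
  if (any(!is.finite(pixels)))
    stop_param("pixels must be finite")
  if (min(pixels) < 0 || max(pixels) > 1)
    stop_param("pixel values must lie in [0, 1]")
  if (!is.na(label) && !label %in% c("viable", "nonviable_abnormal"))
    stop_param("label must be 'viable', 'nonviable_abnormal' or NA")
  structure(list(pixels = pixels, seed_id = as.character(seed_id),
                 cultivar = as.character(cultivar), label = label),
            class = "radiograph")
}

#' @export
print.radiograph <- function(x, ...) {
  cat(sprintf("<radiograph> %s/%s  %dx%d  label=%s\n",
              x$cultivar, x$seed_id, nrow(x$pixels), ncol(x$pixels),
              ifelse(is.na(x$label), "?", x$label)))
  invisible(x)
}

#' @export
dim.radiograph <- function(x) dim(x$pixels)

as_pixels <- function(x) {
  if (inherits(x, "radiograph")) x$pixels
  else if (is.matrix(x)) x
  else stop_param("expected a radiograph or a numeric matrix")
}

#' Read and write radiographs as 8-bit grayscale PNG
#'
#' Images are stored as `{cultivar}_{seed_id}.png`. Writing quantizes to 8
#' bits; reading back therefore reproduces intensities to within 1/255.
#'
#' @param x a `radiograph`.
#' @param dir output directory (created if missing).
#' @return `write_radiograph` returns the file path invisibly;
#'   `read_radiograph` returns a `radiograph`.
#' @export
write_radiograph <- function(x, dir = ".") {
  stopifnot(inherits(x, "radiograph"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, paste0(x$cultivar, "_", x$seed_id, ".png"))
  png::writePNG(x$pixels, path)
  invisible(path)
}

#' @rdname write_radiograph
#' @param path path to a grayscale PNG file.
#' @param label optional class label to attach.
#' @export
read_radiograph <- function(path, label = NA_character_) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1L]  # collapse grayscale-with-alpha
  id <- sub("\\.png$", "", basename(path))
  parts <- strsplit(id, "_", fixed = TRUE)[[1]]
  cultivar <- if (length(parts) >= 2) parts[1] else "unknown"
  seed_id <- if (length(parts) >= 2) paste(parts[-1], collapse = "_") else id
  radiograph(px, seed_id = seed_id, cultivar = cultivar, label = label)
}
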