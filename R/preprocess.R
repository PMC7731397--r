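#' Crop individual seeds out of a multi-seed scan
#'
#' Raw scans contain several seeds; each supplied rectangle is cut out and
#' resampled (bilinear) to the standard square frame, preserving the order of
#' the boxes.
#'
#' @param raw_scan numeric matrix (intensities in \[0, 1\]).
#' @param boxes list of boxes, each a numeric vector or list with elements
#'   `x`, `y`, `w`, `h`: 1-based column/row of the top-left corner and width/
#'   height in pixels.
#' @param size output side length (default 224).
#' @param cultivar cultivar identifier stamped on the outputs.
#' @return List of [radiograph()] objects, one per box, in box order.
#' @export
crop_seeds <- function(raw_scan, boxes, size = 224L, cultivar = "cv1") {
  raw_scan <- as_pixels(raw_scan)
  if (length(boxes) == 0) return(list())
  out <- vector("list", length(boxes))
  for (i in seq_along(boxes)) {
    b <- as.list(boxes[[i]])
    if (is.null(names(b)) || !all(c("x", "y", "w", "h") %in% names(b)))
      b <- stats::setNames(b[1:4], c("x", "y", "w", "h"))
    x0 <- as.integer(b$x); y0 <- as.integer(b$y)
    w <- as.integer(b$w); h <- as.integer(b$h)
    if (w < 1 || h < 1 || x0 < 1 || y0 < 1 ||
        x0 + w - 1 > ncol(raw_scan) || y0 + h - 1 > nrow(raw_scan))
      stop_param(sprintf("box %d out of scan bounds", i))
    sub <- raw_scan[y0:(y0 + h - 1), x0:(x0 + w - 1), drop = FALSE]
    if (!(h == size && w == size))
      sub <- as.matrix(EBImage::resize(EBImage::Image(sub), w = size, h = size))
    out[[i]] <- radiograph(clip01(sub), seed_id = sprintf("crop%02d", i),
                           cultivar = cultivar)
  }
  out
}

#' Compute the binary seed mask of a radiograph
#'
#' The optimum threshold is chosen by Otsu's between-class-variance criterion
#' on a 256-bin histogram (the balanced-histogram rule). The mask is
#' polarity-aware: the foreground is whichever side of the threshold contains
#' the central pixel, so both bright-seed and dark-seed conventions segment
#' correctly. Holes are filled and only the largest connected component is
#' kept, leaving exactly one foreground region.
#'
#' @param image a [radiograph()] or numeric matrix with at least two distinct
#'   intensity values.
#' @return A binary (0/1) integer matrix of the same shape, with attribute
#'   `"threshold"` recording the Otsu threshold.
#' @export
compute_mask <- function(image) {
  px <- as_pixels(image)
  if (max(px) - min(px) < 1e-12)
    stop_degenerate("constant image: no threshold separates foreground from background")
  thr <- EBImage::otsu(EBImage::Image(px), range = c(0, 1), levels = 256)
  # Polarity: the seed does not touch the frame edge, so the foreground is
  # the threshold side in the minority on the image border. A border tie
  # falls back to the side containing the central pixel.
  border <- c(px[1, ], px[nrow(px), ], px[, 1], px[, ncol(px)])
  bright_border <- mean(border > thr)
  fg <- if (bright_border < 0.5) px > thr
        else if (bright_border > 0.5) px <= thr
        else if (px[round(nrow(px) / 2), round(ncol(px) / 2)] > thr) px > thr
        else px <= thr
  fg <- EBImage::fillHull(EBImage::Image(fg * 1))
  lab <- EBImage::bwlabel(fg)
  labm <- as.matrix(EBImage::imageData(lab))
  if (max(labm) >= 1) {
    counts <- tabulate(labm[labm > 0])
    keep <- which.max(counts)
    m <- matrix(as.integer(labm == keep), nrow(px), ncol(px))
  } else {
    stop_degenerate("empty foreground after thresholding")
  }
  if (sum(m) == 0) stop_degenerate("empty foreground after thresholding")
  attr(m, "threshold") <- as.numeric(thr)
  m
}

# Exact 3x3 median via a comparison network (19 min/max exchanges),
# vectorized over all pixels; edges use replicate padding.
median3x3 <- function(x) {
  n <- nrow(x); m <- ncol(x)
  pad <- rbind(x[1, , drop = FALSE], x, x[n, , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, m, drop = FALSE])
  sh <- function(dr, dc) pad[(1 + dr):(n + dr), (1 + dc):(m + dc)]
  p <- list(sh(0, 0), sh(0, 1), sh(0, 2), sh(1, 0), sh(1, 1), sh(1, 2),
            sh(2, 0), sh(2, 1), sh(2, 2))
  swap <- function(i, j) {
    lo <- pmin(p[[i]], p[[j]]); hi <- pmax(p[[i]], p[[j]])
    p[[i]] <<- lo; p[[j]] <<- hi
  }
  # Paeth's 19-exchange median-of-9 network
  swap(1, 2); swap(4, 5); swap(7, 8); swap(2, 3); swap(5, 6); swap(8, 9)
  swap(1, 2); swap(4, 5); swap(7, 8); swap(1, 4); swap(4, 7); swap(2, 5)
  swap(5, 8); swap(3, 6); swap(6, 9); swap(5, 3); swap(5, 7); swap(3, 5)
  p[[5]]
}

#' Enhancement triplet: max-normalized, sd-scaled, median-filtered
#'
#' Produces the three derived images used for feature extraction. `set_A` is
#' the image divided by its maximum. `set_B` stretches `set_A` by its standard
#' deviation around mid-gray, `clip((set_A - mean)/sd * s + 0.5, 0, 1)`, with
#' contrast gain `s` (default 0.15, i.e. about +/-3.3 sd of usable span).
#' `set_C` is the 3x3 median filter of `set_B` (replicate padding), which
#' removes impulse noise while preserving shape and size.
#'
#' @param image a [radiograph()] or numeric matrix; must be nonconstant.
#' @param s sd-scaling contrast gain.
#' @return A list of class `enhanced_triplet` with matrices `set_A`, `set_B`,
#'   `set_C`, all the input's shape, values in \[0, 1\].
#' @export
enhance_sets <- function(image, s = 0.15) {
  px <- as_pixels(image)
  mx <- max(px)
  if (mx <= 0) stop_degenerate("zero-max image cannot be max-normalized")
  set_A <- px / mx
  sdA <- stats::sd(as.vector(set_A))
  if (sdA < 1e-12) stop_degenerate("zero-sd image cannot be sd-scaled")
  set_B <- clip01((set_A - mean(set_A)) / sdA * s + 0.5)
  set_C <- median3x3(set_B)
  structure(list(set_A = set_A, set_B = set_B, set_C = set_C),
            class = "enhanced_triplet")
}
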