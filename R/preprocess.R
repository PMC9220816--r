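# MRI intensity processing: cohort histogram-landmark standardization
# (Nyul-style) and prostate-region Z-score normalization.

DEFAULT_PERCENTILES <- c(1, seq(10, 90, by = 10), 99)

#' Landmark set for histogram standardization
#'
#' Holds the percentile positions and the cohort-mean intensities observed at
#' those percentiles for one MRI sequence. Applying [standardize()] with a
#' landmark set maps an image's own percentile values onto the cohort means
#' by a piecewise-linear monotone transform, so that all cases share a
#' similar intensity distribution irrespective of scanner or protocol.
#'
#' @param percentiles Strictly increasing percentile positions in (0, 100).
#' @param values Strictly increasing mean intensities at those percentiles.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(percentiles, values) {
  percentiles <- as.numeric(percentiles)
  values <- as.numeric(values)
  if (length(percentiles) < 2L || length(values) != length(percentiles))
    stop("need at least two matching percentiles and values")
  if (any(percentiles <= 0) || any(percentiles >= 100) ||
      any(diff(percentiles) <= 0))
    stop("'percentiles' must be strictly increasing within (0, 100)")
  if (any(diff(values) <= 0))
    stop("'values' must be strictly increasing (degenerate histogram?)")
  structure(list(percentiles = percentiles, values = values),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set>\n")
  print(data.frame(percentile = x$percentiles, value = signif(x$values, 6)),
        row.names = FALSE)
  invisible(x)
}

# intensities of one image at the landmark percentiles, optionally within a
# mask; errors on a (near-)constant sample because the monotone map is then
# undefined
image_percentiles <- function(image, percentiles, mask = NULL) {
  stopifnot_vol3d(image)
  vals <- if (is.null(mask)) {
    as.vector(image$data)
  } else {
    stopifnot_vol3d(mask, kind = "mask")
    check_aligned(list(image = image, mask = mask))
    image$data[mask$data != 0]
  }
  if (length(vals) == 0L) stop("no voxels to compute percentiles from")
  q <- unname(stats::quantile(vals, probs = percentiles / 100, names = FALSE))
  if (any(diff(q) <= 0))
    stop("image has non-increasing percentile values (constant region?)")
  q
}

#' Learn cohort histogram landmarks
#'
#' For each training image, intensities at the configured percentiles are
#' computed (within the corresponding prostate mask when one is supplied,
#' else over the whole volume); the landmark set is the per-percentile mean
#' across the cohort.
#'
#' @param images List of [vol3d] intensity volumes (one MRI sequence).
#' @param masks Optional list of [vol3d] masks, same length as `images`, with
#'   `NULL` entries allowed; restricts the histogram to the masked region.
#' @param percentiles Percentile positions; default deciles with robust
#'   1/99 endpoints.
#' @return A [landmark_set].
#' @export
learn_landmarks <- function(images, masks = NULL,
                            percentiles = DEFAULT_PERCENTILES) {
  if (!is.list(images) || length(images) == 0L)
    stop("'images' must be a non-empty list of volumes")
  if (!is.null(masks) && length(masks) != length(images))
    stop("'masks' must match 'images' in length")
  qs <- vapply(seq_along(images), function(i) {
    image_percentiles(images[[i]], percentiles,
                      mask = if (is.null(masks)) NULL else masks[[i]])
  }, numeric(length(percentiles)))
  qs <- matrix(qs, nrow = length(percentiles))
  landmark_set(percentiles, rowMeans(qs))
}

#' Standardize an image against learned landmarks
#'
#' Applies the piecewise-linear monotone intensity map sending the image's
#' own percentile values (within `mask` when given) onto the landmark means.
#' Values beyond the outer landmarks are extrapolated linearly with the
#' slope of the adjacent end segment. Grid and spacing are unchanged.
#'
#' @param image A [vol3d] intensity volume.
#' @param lm A [landmark_set].
#' @param mask Optional [vol3d] prostate mask used to compute the image's
#'   own percentile knots.
#' @return A [vol3d] intensity volume.
#' @export
standardize <- function(image, lm, mask = NULL) {
  stopifnot_vol3d(image)
  if (!inherits(lm, "landmark_set")) stop("'lm' must be a landmark_set")
  knots <- image_percentiles(image, lm$percentiles, mask = mask)
  mapped <- piecewise_linear(as.vector(image$data), knots, lm$values)
  out <- image
  out$data <- array(mapped, dim = dim(image$data))
  out
}

# monotone piecewise-linear map through (x_knots, y_knots) with linear
# extrapolation from the end segments
piecewise_linear <- function(x, xk, yk) {
  y <- stats::approx(xk, yk, xout = x, rule = 2, ties = "ordered")$y
  n <- length(xk)
  lo <- x < xk[1]
  hi <- x > xk[n]
  if (any(lo)) {
    s <- (yk[2] - yk[1]) / (xk[2] - xk[1])
    y[lo] <- yk[1] + s * (x[lo] - xk[1])
  }
  if (any(hi)) {
    s <- (yk[n] - yk[n - 1]) / (xk[n] - xk[n - 1])
    y[hi] <- yk[n] + s * (x[hi] - xk[n])
  }
  y
}

#' Z-score normalize an image over a region
#'
#' Subtracts the within-region mean and divides by the within-region
#' population standard deviation, applied to the whole grid, so that the
#' region has mean 0 and standard deviation 1 afterwards.
#'
#' @param image A [vol3d] intensity volume.
#' @param region A [vol3d] mask (typically the prostate segmentation).
#' @return A [vol3d] intensity volume.
#' @export
zscore_region <- function(image, region) {
  stopifnot_vol3d(image)
  stopifnot_vol3d(region, kind = "mask")
  check_aligned(list(image = image, region = region))
  vals <- image$data[region$data != 0]
  if (length(vals) == 0L) stop("region is empty")
  mu <- mean(vals)
  sdev <- sqrt(mean((vals - mu)^2))  # population sd: deterministic voxel semantics
  if (sdev == 0) stop("region has zero intensity variance")
  out <- image
  out$data <- (image$data - mu) / sdev
  out
}

#' Persist / restore a landmark set as JSON
#'
#' @param lm A [landmark_set].
#' @param path JSON file path.
#' @return `write_landmarks` invisibly returns `path`; `read_landmarks`
#'   returns a [landmark_set].
#' @export
write_landmarks <- function(lm, path) {
  if (!inherits(lm, "landmark_set")) stop("'lm' must be a landmark_set")
  jsonlite::write_json(list(percentiles = lm$percentiles, values = lm$values),
                       path, digits = NA)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  landmark_set(x$percentiles, x$values)
}
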