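# Volume container and NIfTI plumbing shared by all pipeline stages.
#
# All volumes live on a common axis convention: x = left-right,
# y = posterior-anterior, z = slice (inferior -> superior, i.e. prostate
# apex -> base). Files are reoriented to RAS on load when the header
# carries orientation information. Voxel indices are 1-based (R arrays);
# physical lengths are always derived from the spacing in mm.

VOLUME_KINDS <- c("probability", "intensity", "mask", "labelmap")

#' Construct a 3D volume with physical spacing
#'
#' A `vol3d` bundles a 3D numeric array with its voxel spacing in mm and a
#' semantic kind that fixes value-range invariants: `probability` volumes
#' must lie in \[0, 1\], `mask` volumes in \{0, 1\}, `labelmap` volumes hold
#' non-negative integer labels, and `intensity` volumes are unconstrained.
#'
#' @param data 3D numeric array indexed (x, y, z).
#' @param spacing Numeric length-3 vector `(dx, dy, dz)` in mm, all strictly
#'   positive. `dx`/`dy` are the in-plane pixel sizes, `dz` the slice distance.
#' @param kind One of `"probability"`, `"intensity"`, `"mask"`, `"labelmap"`.
#' @return An object of class `vol3d` with fields `data`, `spacing`, `kind`.
#' @examples
#' v <- vol3d(array(runif(8 * 8 * 2), c(8, 8, 2)), c(0.29, 0.29, 3), "probability")
#' dim(v)
#' @export
vol3d <- function(data, spacing, kind = "intensity") {
  kind <- match.arg(kind, VOLUME_KINDS)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3D array")
  if (!is.numeric(spacing) || length(spacing) != 3L || any(!is.finite(spacing)) ||
      any(spacing <= 0))
    stop("'spacing' must be three strictly positive values in mm")
  data <- array(as.double(data), dim = dim(data))  # drop foreign classes/attrs
  if (any(!is.finite(data)))
    stop("volume contains non-finite voxel values")
  if (kind == "probability" && (min(data) < 0 || max(data) > 1))
    stop("probability volume has values outside [0, 1]")
  if (kind == "mask" && !all(data %in% c(0, 1)))
    stop("mask volume has values other than {0, 1}")
  if (kind == "labelmap" && (any(data < 0) || any(data != round(data))))
    stop("labelmap volume must hold non-negative integer labels")
  structure(list(data = data, spacing = as.numeric(spacing), kind = kind),
            class = "vol3d")
}

#' @export
dim.vol3d <- function(x) dim(x$data)

#' @export
print.vol3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<vol3d %s> %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
              x$kind, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  value range [%.4g, %.4g], %d nonzero\n",
              min(x$data), max(x$data), sum(x$data != 0)))
  invisible(x)
}

is_vol3d <- function(x) inherits(x, "vol3d")

stopifnot_vol3d <- function(x, name = deparse(substitute(x)), kind = NULL) {
  if (!is_vol3d(x)) stop(sprintf("'%s' must be a vol3d volume", name))
  if (!is.null(kind) && !(x$kind %in% kind))
    stop(sprintf("'%s' must be of kind %s, got '%s'", name,
                 paste(kind, collapse = "/"), x$kind))
  invisible(x)
}

#' Read a NIfTI volume
#'
#' Loads a 3D NIfTI file, normalizes its orientation to RAS
#' (x = left-right, y = posterior-anterior, z = inferior-superior) when the
#' header defines one, and returns a [vol3d] with spacing taken from the
#' header `pixdim`.
#'
#' @param path Path to a `.nii` or `.nii.gz` file containing a 3D image.
#' @param kind Semantic kind to assign (and validate) on load; see [vol3d].
#' @return A [vol3d].
#' @seealso [write_volume()], [check_aligned()]
#' @export
read_volume <- function(path, kind = "intensity") {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  orient <- tryCatch(RNifti::orientation(img), error = function(e) NA_character_)
  if (!is.na(orient) && nzchar(orient) && orient != "RAS") {
    # reorder data axes so that downstream left/right and apex/base logic
    # is orientation-independent
    RNifti::orientation(img) <- "RAS"
  }
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- arr[, , , 1L, drop = TRUE]
  if (length(dim(arr)) != 3L)
    stop(sprintf("expected a 3D image, got %d dimensions: %s",
                 length(dim(arr)), path))
  sp <- RNifti::pixdim(img)[seq_len(3)]
  vol3d(arr, sp, kind = kind)
}

#' Write a volume to NIfTI
#'
#' @param v A [vol3d].
#' @param path Output path ending in `.nii` or `.nii.gz`; the parent
#'   directory must exist.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(v, path) {
  stopifnot_vol3d(v)
  if (!dir.exists(dirname(path)))
    stop(sprintf("directory does not exist: %s", dirname(path)))
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Check that volumes share one grid
#'
#' All pipeline stages assume co-registered inputs on an identical voxel
#' grid. This verifies that every volume has the same array shape and the
#' same spacing (within `tol` mm) and raises an error naming the first
#' offending volume otherwise.
#'
#' @param vs List of [vol3d] objects (names, when present, are used in error
#'   messages), at least two.
#' @param tol Spacing tolerance in mm.
#' @return Invisibly `TRUE` on success.
#' @export
check_aligned <- function(vs, tol = 1e-6) {
  if (!is.list(vs) || length(vs) < 2L)
    stop("'vs' must be a list of at least two volumes")
  nms <- names(vs)
  if (is.null(nms)) nms <- rep("", length(vs))
  nms <- ifelse(nzchar(nms), nms, paste0("volume ", seq_along(vs)))
  for (i in seq_along(vs)) stopifnot_vol3d(vs[[i]], nms[i])
  ref <- vs[[1]]
  for (i in seq_along(vs)[-1]) {
    if (!identical(dim(vs[[i]]$data), dim(ref$data)))
      stop(sprintf("'%s' shape (%s) differs from '%s' (%s)",
                   nms[i], paste(dim(vs[[i]]$data), collapse = "x"),
                   nms[1], paste(dim(ref$data), collapse = "x")))
    if (any(abs(vs[[i]]$spacing - ref$spacing) > tol))
      stop(sprintf("'%s' spacing (%s mm) differs from '%s' (%s mm)",
                   nms[i], paste(signif(vs[[i]]$spacing, 7), collapse = ", "),
                   nms[1], paste(signif(ref$spacing, 7), collapse = ", ")))
  }
  invisible(TRUE)
}
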