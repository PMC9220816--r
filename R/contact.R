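# Tumor-capsule contact line length (TCL).
#
# The prostate boundary on each axial slice is extracted as the sub-pixel
# 0.5-level iso-contour of the binary mask. A contour point is "in contact"
# with a lesion candidate when the nearest candidate voxel center on that
# slice lies within one pixel diagonal (sqrt(2) * dx); sub-pixel contours
# never coincide exactly with voxel centers, so the tolerance is explicit.
# The slice TCL is the arc length (mm) of the longest contiguous contact
# run along the contour; the candidate TCL is the maximum over slices. TCL
# is a clinical in-plane measurement and the slice distance is an order of
# magnitude larger than the pixel size, hence max rather than sum.

# per-slice iso-contours of a mask slice; list of list(x, y, closed),
# coordinates in pixel index units. Contours with fewer than 3 points are
# degenerate and dropped (they contribute 0 TCL).
slice_contours <- function(sl) {
  nx <- nrow(sl); ny <- ncol(sl)
  cls <- grDevices::contourLines(x = seq_len(nx), y = seq_len(ny), z = sl,
                                 levels = 0.5)
  out <- list()
  for (cl in cls) {
    x <- cl$x; y <- cl$y
    n <- length(x)
    closed <- n > 1L && abs(x[1] - x[n]) < 1e-9 && abs(y[1] - y[n]) < 1e-9
    if (closed) { x <- x[-n]; y <- y[-n]; n <- n - 1L }
    if (n < 3L) next
    out[[length(out) + 1L]] <- list(x = x, y = y, closed = closed)
  }
  out
}

# lazily memoized per-slice prostate contours, shared across candidates and
# alpha values within one case
contour_cache <- function(prostate) {
  env <- new.env(parent = emptyenv())
  env$prostate <- prostate
  env$contours <- vector("list", dim(prostate$data)[3])
  env$done <- logical(dim(prostate$data)[3])
  env
}

cache_contours_for_slice <- function(cache, z) {
  if (!cache$done[z]) {
    sl <- cache$prostate$data[, , z]
    cache$contours[[z]] <- if (any(sl != 0)) slice_contours(sl) else list()
    cache$done[z] <- TRUE
  }
  cache$contours[[z]]
}

# contact flags for contour points against a candidate slice mask (logical
# matrix); a point is in contact when some candidate voxel center is within
# `tol` pixels (Euclidean)
contour_contact <- function(px, py, cand_sl, tol) {
  nx <- nrow(cand_sl); ny <- ncol(cand_sl)
  hit <- logical(length(px))
  # candidate voxels within tol < 2 px of a contour point lie within +/-2 of
  # its rounded coordinates
  rx <- round(px); ry <- round(py)
  for (ox in -2:2) {
    for (oy in -2:2) {
      ix <- rx + ox; iy <- ry + oy
      ok <- !hit & ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
      if (!any(ok)) next
      d2 <- (ix[ok] - px[ok])^2 + (iy[ok] - py[ok])^2
      inr <- d2 <= tol^2 + 1e-12
      if (any(inr)) {
        sel <- which(ok)[inr]
        vox <- cand_sl[cbind(ix[sel], iy[sel])]
        hit[sel[vox]] <- TRUE
      }
    }
  }
  hit
}

# arc length (pixel units) of the longest contiguous run of TRUE flags
# along an (optionally circular) polyline; a single-point run has length 0
longest_contact_run <- function(x, y, contact, closed) {
  n <- length(contact)
  if (!any(contact)) return(0)
  seg <- sqrt(diff(x)^2 + diff(y)^2)      # seg[i] joins point i and i+1
  if (closed) {
    if (all(contact)) {
      return(sum(seg) + sqrt((x[1] - x[n])^2 + (y[1] - y[n])^2))
    }
    # rotate so the sequence starts at a non-contact point, then treat as open
    s <- which(!contact)[1]
    rot <- c(s:n, seq_len(s - 1L))
    x <- x[rot]; y <- y[rot]; contact <- contact[rot]
    seg <- sqrt(diff(x)^2 + diff(y)^2)
  }
  best <- 0
  i <- 1L
  while (i <= n) {
    if (contact[i]) {
      j <- i
      while (j < n && contact[j + 1L]) j <- j + 1L
      if (j > i) best <- max(best, sum(seg[i:(j - 1L)]))
      i <- j + 1L
    } else i <- i + 1L
  }
  best
}

contact_length_cached <- function(c, cache, tol_px = sqrt(2)) {
  prostate <- cache$prostate
  dx <- prostate$spacing[1]; dy <- prostate$spacing[2]
  if (abs(dx - dy) > 1e-6 * max(dx, dy))
    stop("contact length requires in-plane isotropic spacing")
  d <- c$dim
  pos <- arrayInd(c$idx, d)
  best <- 0
  for (z in sort(unique(pos[, 3]))) {
    conts <- cache_contours_for_slice(cache, z)
    if (length(conts) == 0L) next
    sel <- pos[, 3] == z
    cand_sl <- matrix(FALSE, d[1], d[2])
    cand_sl[pos[sel, 1:2, drop = FALSE]] <- TRUE
    for (ct in conts) {
      hit <- contour_contact(ct$x, ct$y, cand_sl, tol_px)
      best <- max(best, longest_contact_run(ct$x, ct$y, hit, ct$closed))
    }
  }
  best * dx
}

#' Tumor-capsule contact line length (Rule II measurement)
#'
#' Measures, in mm, the curvilinear length of the prostate-boundary segment
#' in contact with a lesion candidate. Per axial slice the boundary is the
#' sub-pixel 0.5-level contour of the prostate mask; contour points within
#' one pixel diagonal of a candidate voxel center are in contact, and the
#' slice value is the arc length of the longest contiguous contact run. The
#' returned TCL is the maximum over the slices spanned by the candidate.
#'
#' @param c A `lesion_candidate` (see [components_3d()]).
#' @param prostate A [vol3d] prostate mask on the same grid; in-plane
#'   spacing must be isotropic.
#' @param tol_px Contact tolerance in pixels; default `sqrt(2)`, one pixel
#'   diagonal.
#' @return Contact length in mm; 0 when the candidate never touches the
#'   boundary (a single contacted contour point is a degenerate run of
#'   length 0).
#' @export
contact_length <- function(c, prostate, tol_px = sqrt(2)) {
  if (!inherits(c, "lesion_candidate")) stop("'c' must be a lesion_candidate")
  stopifnot_vol3d(prostate, kind = "mask")
  if (!identical(as.integer(dim(prostate$data)), c$dim))
    stop("candidate and prostate grids differ")
  contact_length_cached(c, contour_cache(prostate), tol_px = tol_px)
}
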