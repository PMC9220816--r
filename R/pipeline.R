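# Core rule-based post-processing: from a voxelwise cancer probability map
# and a prostate segmentation to localized extraprostatic-extension (EPE)
# predictions.
#
# Stages: dilate the prostate mask per slice (cancer-model output is
# unreliable far outside the gland) -> mask the probability map -> binary
# threshold at alpha -> 26-connected components = lesion candidates ->
# Rule I (candidate must cross the capsule) -> Rule II (tumor-capsule
# contact line length >= threshold). Accepted candidates, carrying their
# thresholded probabilities, form the EPE map Q.

#' Pipeline parameters
#'
#' @param alpha Probability threshold in \[0, 1\]; voxels with probability
#'   strictly greater than `alpha` are retained. Default 0.30, the operating
#'   point balancing sextant-level sensitivity and specificity.
#' @param tcl_threshold Tumor-capsule contact line length threshold in mm;
#'   capsule-crossing candidates with contact length below it are discarded.
#'   Default 10 mm, within the 10-25 mm range used in clinical nomograms.
#' @param dilation_radius Half-width, in pixels, of the square structuring
#'   element used to dilate the prostate mask per slice (full width
#'   `2 * dilation_radius + 1`). Default 32 px, i.e. a 65 x 65 element
#'   (about 1.88 cm at 0.29 mm pixels), sized after the largest EPE lesions.
#' @param tcl_comparator Either `">="` (default) or `">"`: how the contact
#'   length is compared with `tcl_threshold`.
#' @return An object of class `pipeline_params`.
#' @export
pipeline_params <- function(alpha = 0.30, tcl_threshold = 10,
                            dilation_radius = 32, tcl_comparator = ">=") {
  tcl_comparator <- match.arg(tcl_comparator, c(">=", ">"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1)
    stop("'alpha' must be a single value in [0, 1]")
  if (!is.numeric(tcl_threshold) || length(tcl_threshold) != 1L ||
      tcl_threshold < 0)
    stop("'tcl_threshold' must be a single non-negative length in mm")
  if (!is.numeric(dilation_radius) || length(dilation_radius) != 1L ||
      dilation_radius < 0 || dilation_radius != round(dilation_radius))
    stop("'dilation_radius' must be a single non-negative integer")
  structure(list(alpha = alpha, tcl_threshold = tcl_threshold,
                 dilation_radius = as.integer(dilation_radius),
                 tcl_comparator = tcl_comparator),
            class = "pipeline_params")
}

#' @export
print.pipeline_params <- function(x, ...) {
  cat(sprintf(
    "<pipeline_params> alpha = %.3g, TCL threshold %s %.3g mm, dilation radius %d px\n",
    x$alpha, x$tcl_comparator, x$tcl_threshold, x$dilation_radius))
  invisible(x)
}

#' Dilate a prostate mask slice-by-slice
#'
#' Morphological 2D dilation of every axial slice with a square structuring
#' element of half-width `radius` pixels. The result contains the input.
#'
#' @param prostate A [vol3d] mask.
#' @param radius Structuring-element half-width in pixels (full width
#'   `2 * radius + 1`); 0 returns the mask unchanged.
#' @return A [vol3d] mask.
#' @export
dilate_mask <- function(prostate, radius = 32) {
  stopifnot_vol3d(prostate, kind = "mask")
  radius <- as.integer(radius)
  if (length(radius) != 1L || is.na(radius) || radius < 0)
    stop("'radius' must be a single non-negative integer")
  if (radius == 0L || all(prostate$data == 0)) return(prostate)
  kern <- EBImage::makeBrush(2L * radius + 1L, shape = "box")
  out <- prostate$data
  for (z in seq_len(dim(out)[3])) {
    sl <- out[, , z]
    if (any(sl != 0)) out[, , z] <- EBImage::dilate(sl, kern)
  }
  vol3d(out, prostate$spacing, kind = "mask")
}

#' Mask a probability map
#'
#' Voxelwise product of a probability volume with a binary mask: values are
#' kept inside the mask and zeroed outside.
#'
#' @param p_ca A [vol3d] probability volume.
#' @param m A [vol3d] mask aligned with `p_ca`.
#' @return A [vol3d] probability volume.
#' @export
apply_mask <- function(p_ca, m) {
  stopifnot_vol3d(p_ca, kind = "probability")
  stopifnot_vol3d(m, kind = "mask")
  check_aligned(list(p_ca = p_ca, mask = m))
  vol3d(p_ca$data * m$data, p_ca$spacing, kind = "probability")
}

#' Threshold a probability map
#'
#' Voxels with probability strictly greater than `alpha` keep their value;
#' all others are set to zero.
#'
#' @param p A [vol3d] probability volume.
#' @param alpha Threshold in \[0, 1\].
#' @return A [vol3d] probability volume.
#' @export
threshold_map <- function(p, alpha) {
  stopifnot_vol3d(p, kind = "probability")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1)
    stop("'alpha' must be a single value in [0, 1]")
  out <- p$data
  out[out <= alpha] <- 0
  vol3d(out, p$spacing, kind = "probability")
}

# ---- lesion candidates -----------------------------------------------------

new_lesion_candidate <- function(idx, dim, spacing) {
  structure(list(idx = as.integer(idx), dim = as.integer(dim),
                 spacing = spacing, size = length(idx),
                 inside_count = NA_integer_, outside_count = NA_integer_,
                 crosses_capsule = NA, contact_length_mm = NA_real_,
                 accepted = NA),
            class = "lesion_candidate")
}

#' @export
print.lesion_candidate <- function(x, ...) {
  cat(sprintf(
    "<lesion_candidate> %d voxels (in %s / out %s), crosses capsule: %s, TCL %s mm, accepted: %s\n",
    x$size, x$inside_count, x$outside_count, x$crosses_capsule,
    if (is.na(x$contact_length_mm)) "NA" else sprintf("%.2f", x$contact_length_mm),
    x$accepted))
  invisible(x)
}

#' Binary mask of one lesion candidate
#'
#' @param c A `lesion_candidate` as returned by [components_3d()] or
#'   [detect_epe()].
#' @return A [vol3d] mask on the candidate's grid.
#' @export
candidate_mask <- function(c) {
  if (!inherits(c, "lesion_candidate")) stop("'c' must be a lesion_candidate")
  arr <- array(0, dim = c$dim)
  arr[c$idx] <- 1
  vol3d(arr, c$spacing, kind = "mask")
}

# offsets covering half of the 26-neighborhood (each undirected adjacency
# visited once): lexicographic forward in (z, y, x)
half_offsets_26 <- function() {
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off <- off[!(off$dx == 0 & off$dy == 0 & off$dz == 0), ]
  keep <- off$dz > 0 | (off$dz == 0 & off$dy > 0) |
    (off$dz == 0 & off$dy == 0 & off$dx > 0)
  as.matrix(off[keep, c("dx", "dy", "dz")])
}

#' 26-connected components of a thresholded volume
#'
#' Partitions the nonzero voxels of a volume into maximal 26-connected
#' components (face, edge and corner neighbors are adjacent); connectivity is
#' evaluated on the voxel grid, ignoring spacing anisotropy. Each component
#' is returned as a `lesion_candidate`. Components are ordered by voxel
#' count descending, ties broken by smallest linear voxel index, so the
#' output is deterministic.
#'
#' @param p_alpha A [vol3d] (typically the alpha-thresholded probability
#'   volume); any nonzero voxel belongs to some component.
#' @return List of `lesion_candidate` objects (empty for an all-zero volume).
#' @export
components_3d <- function(p_alpha) {
  stopifnot_vol3d(p_alpha)
  d <- dim(p_alpha$data)
  nz <- which(p_alpha$data != 0)
  if (length(nz) == 0L) return(list())
  pos <- arrayInd(nz, d)
  offs <- half_offsets_26()
  ei <- integer(0); ej <- integer(0)
  for (k in seq_len(nrow(offs))) {
    o <- offs[k, ]
    ok <- pos[, 1] + o[1] >= 1L & pos[, 1] + o[1] <= d[1] &
      pos[, 2] + o[2] >= 1L & pos[, 2] + o[2] <= d[2] &
      pos[, 3] + o[3] >= 1L & pos[, 3] + o[3] <= d[3]
    if (!any(ok)) next
    nbr <- nz[ok] + o[1] + o[2] * d[1] + o[3] * d[1] * d[2]
    j <- match(nbr, nz)
    hit <- !is.na(j)
    ei <- c(ei, which(ok)[hit])
    ej <- c(ej, j[hit])
  }
  memb <- if (length(ei)) {
    g <- igraph::make_graph(edges = rbind(ei, ej), n = length(nz),
                            directed = FALSE)
    igraph::components(g)$membership
  } else {
    seq_along(nz)
  }
  groups <- split(nz, memb)
  sizes <- lengths(groups)
  firsts <- vapply(groups, function(g) g[1], numeric(1))  # groups are sorted
  ord <- order(-sizes, firsts)
  lapply(groups[ord], function(g)
    new_lesion_candidate(g, d, p_alpha$spacing))
}

#' Does a candidate cross the prostate capsule? (Rule I)
#'
#' A lesion candidate is a viable EPE candidate only if it predicts cancer
#' both inside and outside the prostate segmentation; components fully
#' inside or fully outside are rejected.
#'
#' @param c A `lesion_candidate`.
#' @param prostate A [vol3d] mask on the same grid.
#' @return `TRUE` iff the candidate has at least one voxel inside and one
#'   outside the prostate.
#' @export
crosses_capsule <- function(c, prostate) {
  if (!inherits(c, "lesion_candidate")) stop("'c' must be a lesion_candidate")
  stopifnot_vol3d(prostate, kind = "mask")
  if (!identical(as.integer(dim(prostate$data)), c$dim))
    stop("candidate and prostate grids differ")
  inside <- sum(prostate$data[c$idx] != 0)
  inside > 0L && inside < c$size
}

#' End-to-end EPE detection
#'
#' Runs the full post-processing pipeline on one case: dilates the prostate
#' mask, masks and thresholds the cancer probability map, extracts
#' 26-connected lesion candidates, and filters them by Rule I
#' (capsule crossing, [crosses_capsule()]) and Rule II (tumor-capsule
#' contact line length, [contact_length()], compared against
#' `params$tcl_threshold`). The EPE probability map `q` is the union of
#' accepted candidates carrying the thresholded probability values; it is
#' identically zero iff no candidate is accepted.
#'
#' @param p_ca A [vol3d] probability volume (upstream cancer-model output).
#' @param prostate A [vol3d] prostate mask on the same grid.
#' @param params A [pipeline_params] object.
#' @return A list of class `epe_result` with elements `q` (the EPE
#'   probability [vol3d]) and `candidates` (all lesion candidates with
#'   `inside_count`, `outside_count`, `crosses_capsule`,
#'   `contact_length_mm` and `accepted` filled in).
#' @examples
#' ph <- make_case(phantom_spec(
#'   shape = c(96, 96, 8), spacing = c(0.6, 0.6, 3),
#'   semiaxes_mm = c(22, 18, 11),
#'   lesions = list(lesion_desc(6, placement = "straddling", contact_mm = 11)),
#'   noise = 0, seed = 1))
#' res <- detect_epe(ph$p_ca, ph$prostate, pipeline_params(alpha = 0.3))
#' sum(res$q$data > 0) > 0
#' @export
detect_epe <- function(p_ca, prostate, params = pipeline_params()) {
  stopifnot_vol3d(p_ca, kind = "probability")
  stopifnot_vol3d(prostate, kind = "mask")
  if (!inherits(params, "pipeline_params"))
    stop("'params' must be a pipeline_params object")
  check_aligned(list(p_ca = p_ca, prostate = prostate))
  m <- dilate_mask(prostate, params$dilation_radius)
  p <- apply_mask(p_ca, m)
  cache <- contour_cache(prostate)
  detect_epe_core(p, prostate, cache, params)
}

# inner stage shared with roc_sweep(): takes the already-masked probability
# map and a per-slice prostate contour cache so threshold sweeps do not
# redo the dilation and contour extraction
detect_epe_core <- function(p_masked, prostate, cache, params) {
  p_alpha <- threshold_map(p_masked, params$alpha)
  cands <- components_3d(p_alpha)
  q <- array(0, dim = dim(p_alpha$data))
  cmp <- if (params$tcl_comparator == ">=") `>=` else `>`
  cands <- lapply(cands, function(cc) {
    cc$inside_count <- sum(prostate$data[cc$idx] != 0)
    cc$outside_count <- cc$size - cc$inside_count
    cc$crosses_capsule <- cc$inside_count > 0L && cc$outside_count > 0L
    if (cc$crosses_capsule) {
      cc$contact_length_mm <- contact_length_cached(cc, cache)
      cc$accepted <- cmp(cc$contact_length_mm, params$tcl_threshold)
    } else {
      cc$accepted <- FALSE
    }
    if (cc$accepted) q[cc$idx] <<- p_alpha$data[cc$idx]
    cc
  })
  structure(list(q = vol3d(q, p_masked$spacing, kind = "probability"),
                 candidates = cands, params = params),
            class = "epe_result")
}

#' @export
print.epe_result <- function(x, ...) {
  n_acc <- sum(vapply(x$candidates, function(cc) isTRUE(cc$accepted), logical(1)))
  cat(sprintf("<epe_result> %d candidate(s), %d accepted; Q has %d nonzero voxels\n",
              length(x$candidates), n_acc, sum(x$q$data != 0)))
  for (cc in x$candidates) print(cc)
  invisible(x)
}
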