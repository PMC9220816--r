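# Geometric phantom generator: ellipsoidal prostate, blob lesions with
# controlled capsule-contact geometry, and a smooth probability field that
# stands in for the upstream cancer-detection model, so every downstream
# stage is testable with known ground truth.
#
# Lesion probability kernel: cosine taper, value = peak * (1 + cos(pi r/R))/2
# for r <= R (3D physical distance). The kernel is smooth, compactly
# supported, and its alpha-level support is an analytically known ball of
# radius (R/pi) * acos(2 alpha / peak - 1), so oracle contact lengths can be
# computed at any threshold from continuous geometry.

#' Phantom case specification
#'
#' Defines the grid, the ellipsoidal prostate, the lesions and the noise of
#' one synthetic case. Defaults mirror the imaging conditions the pipeline
#' targets: a 224 x 224 in-plane grid at 0.29 mm pixels with 3 mm slices,
#' and a prostate of roughly 40 x 34 x 30 mm extent.
#'
#' @param shape Integer grid dimensions `(nx, ny, nz)`.
#' @param spacing Voxel spacing `(dx, dy, dz)` in mm.
#' @param semiaxes_mm Ellipsoid semi-axes `(a, b, c)` in mm along x
#'   (left-right), y (posterior-anterior) and z (apex-base).
#' @param center_mm Ellipsoid center in mm (voxel i sits at `(i - 1) * dx`);
#'   default is the grid center.
#' @param lesions List of [lesion_desc()] descriptors.
#' @param noise Uniform noise amplitude added to the probability field
#'   (drawn on \[0, noise\], then clipped to \[0, 1\]). Default 0.05, small
#'   enough never to cross the default threshold alpha = 0.30 on its own.
#' @param seed Integer seed for the noise generator; geometry is
#'   deterministic given the descriptors.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(224, 224, 16), spacing = c(0.29, 0.29, 3),
                         semiaxes_mm = c(20, 17, 15), center_mm = NULL,
                         lesions = list(), noise = 0.05, seed = 1) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("'shape' must be three positive integers")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be three positive values in mm")
  if (length(semiaxes_mm) != 3L || any(semiaxes_mm <= 0))
    stop("'semiaxes_mm' must be three strictly positive lengths in mm")
  if (is.null(center_mm)) center_mm <- (shape - 1) / 2 * spacing
  if (length(center_mm) != 3L) stop("'center_mm' must have three components")
  if (!is.numeric(noise) || noise < 0) stop("'noise' must be >= 0")
  for (l in lesions)
    if (!inherits(l, "lesion_desc")) stop("'lesions' must be lesion_desc objects")
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 semiaxes_mm = as.numeric(semiaxes_mm),
                 center_mm = as.numeric(center_mm), lesions = lesions,
                 noise = noise, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Lesion descriptor
#'
#' Describes one blob lesion by its size, peak probability and placement
#' relative to the prostate capsule. The lesion center is derived from the
#' capsule boundary point at azimuth `theta` on the axial cross-section at
#' slice offset `z_mm`, moved inward by a depth that depends on the
#' placement:
#' * `"straddling"`: depth `sqrt(R^2 - (contact_mm / 2)^2)`, so that under a
#'   locally straight capsule the full-support contact line has length
#'   about `contact_mm` (the recorded oracle value is computed from the
#'   exact curved geometry);
#' * `"interior"`: depth `radius_mm + 2` mm (or `depth_mm` when given), so
#'   the lesion is fully inside the gland;
#' * `"exterior"`: negative depth `-(radius_mm + 1)` mm, fully outside.
#'
#' @param radius_mm Lesion radius (kernel support) in mm.
#' @param peak Peak probability at the lesion center, in (0, 1\].
#' @param placement `"interior"`, `"straddling"` or `"exterior"`.
#' @param contact_mm Target full-support contact length in mm (straddling
#'   only); must satisfy `0 <= contact_mm <= 2 * radius_mm`, else the
#'   requested arc is geometrically infeasible.
#' @param theta Azimuth (radians) of the anchoring capsule point in the
#'   axial plane.
#' @param z_mm Slice offset of the lesion center from the prostate center,
#'   in mm.
#' @param depth_mm Optional explicit inward depth in mm, overriding the
#'   placement default (interior/exterior only).
#' @return An object of class `lesion_desc`.
#' @export
lesion_desc <- function(radius_mm, peak = 0.9,
                        placement = c("interior", "straddling", "exterior"),
                        contact_mm = NULL, theta = 0, z_mm = 0,
                        depth_mm = NULL) {
  placement <- match.arg(placement)
  if (!is.numeric(radius_mm) || radius_mm <= 0) stop("'radius_mm' must be > 0")
  if (!is.numeric(peak) || peak <= 0 || peak > 1)
    stop("'peak' must lie in (0, 1]")
  if (placement == "straddling") {
    if (is.null(contact_mm)) stop("straddling lesions need 'contact_mm'")
    if (contact_mm < 0 || contact_mm > 2 * radius_mm)
      stop(sprintf(
        "requested contact arc %.3g mm is geometrically infeasible for radius %.3g mm",
        contact_mm, radius_mm))
  }
  structure(list(radius_mm = radius_mm, peak = peak, placement = placement,
                 contact_mm = contact_mm, theta = theta, z_mm = z_mm,
                 depth_mm = depth_mm),
            class = "lesion_desc")
}

# axial cross-section semi-axes of the ellipsoid at continuous z (mm);
# returns c(a_z, b_z), zero outside the gland span
ellipsoid_section <- function(spec, z) {
  f <- 1 - ((z - spec$center_mm[3]) / spec$semiaxes_mm[3])^2
  if (f <= 0) return(c(0, 0))
  sqrt(f) * spec$semiaxes_mm[1:2]
}

# resolve a lesion descriptor to an absolute center (mm) and inward depth
resolve_lesion <- function(desc, spec) {
  zc <- spec$center_mm[3] + desc$z_mm
  ab <- ellipsoid_section(spec, zc)
  if (all(ab == 0))
    stop("lesion slice offset places it outside the prostate span")
  bp <- spec$center_mm[1:2] + ab * c(cos(desc$theta), sin(desc$theta))
  u <- spec$center_mm[1:2] - bp
  u <- u / sqrt(sum(u^2))
  depth <- switch(desc$placement,
    straddling = sqrt(desc$radius_mm^2 - (desc$contact_mm / 2)^2),
    interior = if (is.null(desc$depth_mm)) desc$radius_mm + 2 else desc$depth_mm,
    exterior = if (is.null(desc$depth_mm)) -(desc$radius_mm + 1) else -abs(desc$depth_mm))
  list(center = c(bp + depth * u, zc), radius = desc$radius_mm,
       peak = desc$peak, placement = desc$placement, depth_mm = depth)
}

#' Ellipsoidal prostate mask
#'
#' Voxels whose physical centers lie inside the specified ellipsoid are set
#' to 1.
#'
#' @param spec A [phantom_spec].
#' @return A [vol3d] mask.
#' @export
make_prostate <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("'spec' must be a phantom_spec")
  extent <- (spec$shape - 1) * spec$spacing
  if (any(spec$center_mm - spec$semiaxes_mm < 0) ||
      any(spec$center_mm + spec$semiaxes_mm > extent))
    stop("prostate ellipsoid exceeds the grid bounds")
  xs <- (seq_len(spec$shape[1]) - 1) * spec$spacing[1]
  ys <- (seq_len(spec$shape[2]) - 1) * spec$spacing[2]
  zs <- (seq_len(spec$shape[3]) - 1) * spec$spacing[3]
  qx <- ((xs - spec$center_mm[1]) / spec$semiaxes_mm[1])^2
  qy <- ((ys - spec$center_mm[2]) / spec$semiaxes_mm[2])^2
  qz <- ((zs - spec$center_mm[3]) / spec$semiaxes_mm[3])^2
  arr <- outer(outer(qx, qy, `+`), qz, `+`)
  vol3d(array(as.numeric(arr <= 1), dim = spec$shape), spec$spacing,
        kind = "mask")
}

# cosine-taper kernel values of one lesion over its bounding box; returns
# list(idx, values, support_idx)
lesion_field <- function(les, spec) {
  sp <- spec$spacing; d <- spec$shape
  lo <- pmax(1L, floor(les$center / sp - les$radius / sp) + 1L)
  hi <- pmin(d, ceiling(les$center / sp + les$radius / sp) + 1L)
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  dx2 <- ((ix - 1) * sp[1] - les$center[1])^2
  dy2 <- ((iy - 1) * sp[2] - les$center[2])^2
  dz2 <- ((iz - 1) * sp[3] - les$center[3])^2
  r <- sqrt(outer(outer(dx2, dy2, `+`), dz2, `+`))
  sup <- r < les$radius
  if (!any(sup)) return(list(idx = integer(0), values = numeric(0)))
  grid_idx <- which(sup)
  pos <- arrayInd(grid_idx, dim(r))
  lin <- (ix[pos[, 1]] - 1L) + (iy[pos[, 2]] - 1L) * d[1] +
    (iz[pos[, 3]] - 1L) * d[1] * d[2] + 1L
  vals <- les$peak * (1 + cos(pi * r[sup] / les$radius)) / 2
  list(idx = lin, values = vals)
}

# alpha-level support radius of the cosine-taper kernel (mm)
support_radius <- function(radius_mm, peak, alpha) {
  if (alpha <= 0) return(radius_mm)
  if (alpha >= peak) return(0)
  radius_mm / pi * acos(2 * alpha / peak - 1)
}

# contact length of the continuous lesion/capsule geometry: per grid slice,
# sample the ellipsoid cross-section contour finely, flag points within the
# lesion's in-plane support radius, take the longest contiguous arc; max
# over slices. Independent of the voxel pipeline.
oracle_contact_geom <- function(les, spec, r_support, n_angle = 4096L) {
  if (r_support <= 0) return(0)
  zs <- (seq_len(spec$shape[3]) - 1) * spec$spacing[3]
  tt <- seq(0, 2 * pi, length.out = n_angle + 1L)[-(n_angle + 1L)]
  best <- 0
  for (z in zs) {
    dz <- z - les$center[3]
    if (abs(dz) >= r_support) next
    rho <- sqrt(r_support^2 - dz^2)
    ab <- ellipsoid_section(spec, z)
    if (all(ab == 0)) next
    px <- spec$center_mm[1] + ab[1] * cos(tt)
    py <- spec$center_mm[2] + ab[2] * sin(tt)
    contact <- (px - les$center[1])^2 + (py - les$center[2])^2 <= rho^2
    best <- max(best, longest_contact_run(px, py, contact, closed = TRUE))
  }
  best
}

#' Generate one phantom case
#'
#' Builds the prostate mask, the lesion probability field (voxelwise
#' maximum over lesion kernels plus seeded uniform noise, clipped to
#' \[0, 1\]), the ground-truth cancer mask (union of lesion supports) and
#' the ground-truth EPE mask (extracapsular part of the cancer mask), and
#' records per-lesion oracle geometry: capsule-crossing status and the
#' full-support contact line length computed from the continuous
#' lesion/capsule intersection.
#'
#' Interior (exterior) lesions are verified to be fully inside (outside)
#' the voxelized prostate; a violation is an error, not a silent
#' mislabeling.
#'
#' @param spec A [phantom_spec].
#' @return An object of class `phantom_case`: list with [vol3d] elements
#'   `p_ca`, `prostate`, `gt_cancer`, `gt_epe`, a data frame `lesions`
#'   (placement, geometry, `crosses`, `contact_full_mm`), and `spec`.
#' @seealso [oracle_contact()] for contact lengths at nonzero thresholds.
#' @export
make_case <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("'spec' must be a phantom_spec")
  prostate <- make_prostate(spec)
  d <- spec$shape
  p <- array(0, dim = d)
  cancer <- array(0, dim = d)
  recs <- list()
  for (i in seq_along(spec$lesions)) {
    les <- resolve_lesion(spec$lesions[[i]], spec)
    fld <- lesion_field(les, spec)
    if (length(fld$idx) == 0L)
      stop(sprintf("lesion %d has empty voxel support", i))
    p[fld$idx] <- pmax(p[fld$idx], fld$values)
    cancer[fld$idx] <- 1
    n_in <- sum(prostate$data[fld$idx] != 0)
    n_out <- length(fld$idx) - n_in
    if (les$placement == "interior" && n_out > 0L)
      stop(sprintf("interior lesion %d leaks outside the prostate (%d voxels)",
                   i, n_out))
    if (les$placement == "exterior" && n_in > 0L)
      stop(sprintf("exterior lesion %d overlaps the prostate (%d voxels)",
                   i, n_in))
    recs[[i]] <- data.frame(
      lesion = i, placement = les$placement, radius_mm = les$radius,
      peak = les$peak, center_x_mm = les$center[1],
      center_y_mm = les$center[2], center_z_mm = les$center[3],
      depth_mm = les$depth_mm,
      crosses = n_in > 0L && n_out > 0L,
      contact_full_mm = oracle_contact_geom(les, spec, les$radius))
  }
  if (spec$noise > 0) {
    set.seed(spec$seed)
    p <- p + stats::runif(length(p), 0, spec$noise)
  }
  p <- pmin(pmax(p, 0), 1)
  gt_epe <- cancer * (1 - prostate$data)
  structure(list(
    p_ca = vol3d(array(p, d), spec$spacing, kind = "probability"),
    prostate = prostate,
    gt_cancer = vol3d(cancer, spec$spacing, kind = "mask"),
    gt_epe = vol3d(gt_epe, spec$spacing, kind = "mask"),
    lesions = if (length(recs)) do.call(rbind, recs) else
      data.frame(lesion = integer(0)),
    spec = spec),
    class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> grid %s, %d lesion(s), GT EPE %s\n",
              paste(x$spec$shape, collapse = "x"), nrow(x$lesions),
              if (any(x$gt_epe$data != 0)) "positive" else "negative"))
  if (nrow(x$lesions))
    print(x$lesions[, c("lesion", "placement", "radius_mm", "peak",
                        "crosses", "contact_full_mm")], row.names = FALSE)
  invisible(x)
}

#' Oracle contact length of a phantom lesion at a threshold
#'
#' Contact line length, in mm, between the capsule and the alpha-level
#' support of lesion `i`'s probability kernel (an analytically known ball),
#' computed from the continuous geometry independently of the voxel
#' pipeline. `alpha = 0` gives the full-support contact recorded in
#' `case$lesions$contact_full_mm`.
#'
#' [contact_length()] flags boundary points within an explicit tolerance
#' (one pixel diagonal) of candidate voxel centers, so its value sits
#' between the bare geometric contact and the contact of the
#' tolerance-inflated support; `inflate_mm` widens the support radius to
#' compute that upper envelope.
#'
#' @param case A `phantom_case`.
#' @param i Lesion index.
#' @param alpha Probability threshold.
#' @param inflate_mm Added to the support radius before intersecting with
#'   the capsule (default 0: bare geometric contact).
#' @return Contact length in mm.
#' @export
oracle_contact <- function(case, i, alpha = 0, inflate_mm = 0) {
  if (!inherits(case, "phantom_case")) stop("'case' must be a phantom_case")
  spec <- case$spec
  if (i < 1 || i > length(spec$lesions)) stop("lesion index out of range")
  les <- resolve_lesion(spec$lesions[[i]], spec)
  r <- support_radius(les$radius, les$peak, alpha)
  oracle_contact_geom(les, spec, if (r > 0) r + inflate_mm else 0)
}

#' Generate a phantom cohort
#'
#' Produces `n` cases with randomized prostate and lesion geometry. Each
#' case is EPE positive (it contains one capsule-straddling lesion, with
#' probability `epe_prevalence`) or EPE negative (interior lesions only).
#' Straddling lesions have radius 6.5-9 mm, peak probability 0.8-0.95 and a
#' near-maximal target contact arc (85-100% of the lesion diameter);
#' interior lesions have radius 3.5-5.5 mm and peak 0.7-0.95. All
#' randomness is driven by one seeded generator per case derived from
#' `(seed, case index)`, so any case is reproducible independently of
#' cohort size.
#'
#' @param n Number of cases.
#' @param epe_prevalence Probability that a case carries a straddling
#'   lesion.
#' @param seed Integer cohort seed.
#' @param shape,spacing,noise Passed to [phantom_spec()].
#' @return List of `phantom_case` objects (directly usable as the `cases`
#'   argument of [roc_sweep()]).
#' @export
make_cohort <- function(n, epe_prevalence = 0.5, seed = 1,
                        shape = c(224, 224, 16), spacing = c(0.29, 0.29, 3),
                        noise = 0.05) {
  if (n < 1) stop("'n' must be >= 1")
  if (epe_prevalence < 0 || epe_prevalence > 1)
    stop("'epe_prevalence' must lie in [0, 1]")
  lapply(seq_len(n), function(i) {
    case_seed <- as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647)
    set.seed(case_seed)
    semi <- c(20, 17, 15) * stats::runif(3, 0.85, 1.15)
    positive <- stats::runif(1) < epe_prevalence
    lesions <- list()
    if (positive) {
      r <- stats::runif(1, 6.5, 9)
      lesions <- c(lesions, list(lesion_desc(
        r, peak = stats::runif(1, 0.8, 0.95), placement = "straddling",
        contact_mm = stats::runif(1, 0.85, 1.0) * 2 * r,
        theta = stats::runif(1, 0, 2 * pi), z_mm = stats::runif(1, -3, 3))))
    }
    n_int <- if (positive) stats::rbinom(1, 1, 0.5) else 1L + stats::rbinom(1, 1, 0.5)
    for (k in seq_len(n_int)) {
      r <- stats::runif(1, 3.5, 5.5)
      lesions <- c(lesions, list(lesion_desc(
        r, peak = stats::runif(1, 0.7, 0.95), placement = "interior",
        theta = stats::runif(1, 0, 2 * pi), z_mm = stats::runif(1, -3, 3),
        depth_mm = r + 2.5)))
    }
    make_case(phantom_spec(
      shape = shape, spacing = spacing, semiaxes_mm = semi,
      lesions = lesions, noise = noise,
      seed = as.integer((case_seed + 1000003) %% 2147483647)))
  })
}

#' Write a phantom cohort to disk
#'
#' Writes per-case NIfTI volumes, a manifest CSV matching the evaluation
#' CLI schema (`case_id, prob_path, prostate_path, gt_epe_path`) and a
#' per-case oracle JSON with the lesion records.
#'
#' @param cases List of `phantom_case` objects.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cases, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(cases), function(i) {
    id <- sprintf("case%03d", i)
    paths <- file.path(dir, paste0(id, c("_prob.nii.gz", "_prostate.nii.gz",
                                         "_gt_epe.nii.gz")))
    write_volume(cases[[i]]$p_ca, paths[1])
    write_volume(cases[[i]]$prostate, paths[2])
    write_volume(cases[[i]]$gt_epe, paths[3])
    jsonlite::write_json(cases[[i]]$lesions,
                         file.path(dir, paste0(id, "_oracle.json")),
                         dataframe = "rows", digits = NA)
    data.frame(case_id = id, prob_path = paths[1], prostate_path = paths[2],
               gt_epe_path = paths[3])
  })
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}
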