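# Sextant partition: {apex, mid, base} x {left, right}, mirroring the
# systematic 12-core biopsy convention. The zone of a voxel depends only on
# its slice index, the side only on its x coordinate, and the partition
# covers the whole grid so that EPE predictions extending beyond the
# capsule are still attributable to a sextant.

SEXTANT_LEGEND <- data.frame(
  label = 1:6,
  zone = rep(c("apex", "mid", "base"), each = 2),
  side = rep(c("left", "right"), 3),
  stringsAsFactors = FALSE)

#' Partition a volume into prostate sextants
#'
#' Slices containing prostate voxels are ordered apex to base (ascending z
#' under the package's RAS axis convention) and allocated
#' apex / mid / base: each zone gets `floor(n/3)` slices, with a remainder
#' of one slice going to the base and a remainder of two split between mid
#' and base. Slices before and after the prostate span inherit apex and
#' base respectively. The left/right split is the sagittal plane through
#' the prostate-mask centroid x coordinate (voxels with x below the
#' centroid are labeled left: under RAS, +x points to the patient's right);
#' `side_split = "midline"` uses the image midline instead.
#'
#' @param prostate A non-empty [vol3d] prostate mask.
#' @param side_split `"centroid"` (default) or `"midline"`.
#' @return An object of class `sextant_partition`: a list with `labelmap`
#'   (a [vol3d] labelmap with values 1-6 covering every voxel) and `legend`
#'   (data frame mapping label to zone and side).
#' @export
sextant_partition <- function(prostate, side_split = c("centroid", "midline")) {
  stopifnot_vol3d(prostate, kind = "mask")
  side_split <- match.arg(side_split)
  d <- dim(prostate$data)
  nz_slice <- which(apply(prostate$data, 3, function(sl) any(sl != 0)))
  if (length(nz_slice) == 0L) stop("prostate mask is empty")
  n <- length(nz_slice)
  base_n <- n %/% 3L
  rem <- n %% 3L
  counts <- c(apex = base_n,
              mid = base_n + as.integer(rem == 2L),
              base = base_n + as.integer(rem >= 1L) + as.integer(rem == 2L) * 0L)
  counts["base"] <- n - counts["apex"] - counts["mid"]
  zone_of_span <- rep(c(1L, 2L, 3L), times = counts)  # 1 apex, 2 mid, 3 base
  zone_z <- integer(d[3])
  zone_z[nz_slice] <- zone_of_span
  if (nz_slice[1] > 1L) zone_z[seq_len(nz_slice[1] - 1L)] <- 1L
  if (nz_slice[n] < d[3]) zone_z[(nz_slice[n] + 1L):d[3]] <- 3L
  # zero zones can only occur for gaps inside the prostate span; carry the
  # previous zone forward
  for (z in seq_len(d[3])) if (zone_z[z] == 0L) zone_z[z] <- zone_z[z - 1L]

  cx <- if (side_split == "centroid") {
    pos <- arrayInd(which(prostate$data != 0), d)
    mean(pos[, 1])
  } else {
    (d[1] + 1) / 2
  }
  side_x <- ifelse(seq_len(d[1]) < cx, 1L, 2L)  # 1 left (low x), 2 right

  lab <- array(0L, dim = d)
  for (z in seq_len(d[3]))
    lab[, , z] <- matrix((zone_z[z] - 1L) * 2L + side_x, d[1], d[2])
  structure(list(labelmap = vol3d(lab, prostate$spacing, kind = "labelmap"),
                 legend = SEXTANT_LEGEND),
            class = "sextant_partition")
}

#' @export
print.sextant_partition <- function(x, ...) {
  cat("<sextant_partition>\n")
  counts <- tabulate(as.integer(x$labelmap$data), nbins = 6)
  print(cbind(x$legend, voxels = counts), row.names = FALSE)
  invisible(x)
}

#' Per-sextant positivity flags
#'
#' For each of the six sextants, reports whether a volume (an EPE
#' probability map Q or a ground-truth label volume) has any nonzero voxel
#' inside the sextant region. Because the partition covers the whole grid,
#' prediction voxels outside the anatomic prostate count toward the sextant
#' whose region contains them.
#'
#' @param v A [vol3d] aligned with the partition.
#' @param part A `sextant_partition`.
#' @return Named logical vector of length 6, ordered by label and named
#'   `"zone_side"` (e.g. `"apex_left"`).
#' @export
region_flags <- function(v, part) {
  stopifnot_vol3d(v)
  if (!inherits(part, "sextant_partition"))
    stop("'part' must be a sextant_partition")
  check_aligned(list(v = v, labelmap = part$labelmap))
  hit <- unique(part$labelmap$data[v$data != 0])
  flags <- part$legend$label %in% hit
  names(flags) <- paste(part$legend$zone, part$legend$side, sep = "_")
  flags
}

# flags from a set of voxel linear indices (used by roc_sweep to avoid
# materializing Q volumes)
region_flags_idx <- function(idx, part) {
  hit <- unique(part$labelmap$data[idx])
  flags <- part$legend$label %in% hit
  names(flags) <- paste(part$legend$zone, part$legend$side, sep = "_")
  flags
}
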