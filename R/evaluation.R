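# Patient-level and sextant-level scoring, ROC construction over the alpha
# grid, and the TCL-threshold grid-search harness.

#' Patient-level EPE call
#'
#' A patient is predicted EPE positive iff the final EPE probability map Q
#' is nonzero anywhere; the same rule applied to a ground-truth EPE label
#' volume yields the ground-truth patient label.
#'
#' @param q A [vol3d] (EPE map or label volume).
#' @return Logical.
#' @export
patient_call <- function(q) {
  stopifnot_vol3d(q)
  any(q$data != 0)
}

#' Confusion counts over paired binary calls
#'
#' @param pred,gt Logical vectors of equal length (one element per scored
#'   unit: patient or sextant).
#' @return An object of class `confusion_counts` with integer fields `tp`,
#'   `fp`, `tn`, `fn` summing to the number of units.
#' @export
confusion <- function(pred, gt) {
  pred <- as.logical(pred); gt <- as.logical(gt)
  if (length(pred) != length(gt)) stop("'pred' and 'gt' lengths differ")
  if (anyNA(pred) || anyNA(gt)) stop("calls must not contain NA")
  structure(list(tp = sum(pred & gt), fp = sum(pred & !gt),
                 tn = sum(!pred & !gt), fn = sum(!pred & gt)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> tp=%d fp=%d tn=%d fn=%d (n=%d)\n",
              x$tp, x$fp, x$tn, x$fn, x$tp + x$fp + x$tn + x$fn))
  invisible(x)
}

#' Sensitivity and specificity
#'
#' Sensitivity = tp / (tp + fn); specificity = tn / (tn + fp). A component
#' whose denominator is zero is undefined and reported as `NA`, never
#' silently as 0 (small cohorts routinely hit these edges).
#'
#' @param c A `confusion_counts` object.
#' @return List with numeric fields `sensitivity` and `specificity`
#'   (fractions in \[0, 1\] or `NA`).
#' @export
sens_spec <- function(c) {
  if (!inherits(c, "confusion_counts")) stop("'c' must be confusion_counts")
  list(sensitivity = if (c$tp + c$fn > 0) c$tp / (c$tp + c$fn) else NA_real_,
       specificity = if (c$tn + c$fp > 0) c$tn / (c$tn + c$fp) else NA_real_)
}

#' Area under an ROC polyline
#'
#' Trapezoidal area over the (fpr, tpr) points augmented with the corners
#' (0, 0) and (1, 1) and sorted by fpr (ties by tpr); invariant under
#' re-ordering of the input points.
#'
#' @param curve A `roc_curve` (see [roc_sweep()]) or a data frame with
#'   columns `fpr` and `tpr`.
#' @return Numeric area in \[0, 1\], or `NA` if any point is undefined.
#' @export
auc <- function(curve) {
  pts <- if (inherits(curve, "roc_curve")) curve$points else curve
  if (!is.data.frame(pts) || !all(c("fpr", "tpr") %in% names(pts)))
    stop("'curve' must be a roc_curve or data frame with fpr/tpr columns")
  if (nrow(pts) == 0L || anyNA(pts$fpr) || anyNA(pts$tpr)) return(NA_real_)
  fpr <- c(0, pts$fpr, 1)
  tpr <- c(0, pts$tpr, 1)
  ord <- order(fpr, tpr)
  fpr <- fpr[ord]; tpr <- tpr[ord]
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

new_roc_curve <- function(points, level) {
  structure(list(points = points, auc = auc(points), level = level),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %s-level, %d points, AUC = %s\n", x$level,
              nrow(x$points),
              if (is.na(x$auc)) "NA" else sprintf("%.3f", x$auc)))
  invisible(x)
}

# precompute everything about a case that does not depend on alpha or the
# TCL threshold: the dilated-mask product, the sextant partition, the
# ground-truth labels and the prostate contour cache
prepare_case <- function(case, params) {
  p_ca <- case$p_ca; prostate <- case$prostate; gt <- case$gt_epe
  check_aligned(list(p_ca = p_ca, prostate = prostate, gt_epe = gt))
  part <- sextant_partition(prostate)
  list(p_masked = apply_mask(p_ca, dilate_mask(prostate, params$dilation_radius)),
       prostate = prostate,
       cache = contour_cache(prostate),
       part = part,
       gt_patient = patient_call(gt),
       gt_sextant = region_flags(gt, part))
}

#' ROC sweep over the probability threshold
#'
#' Runs the full pipeline at every alpha in `grid` on every case,
#' aggregates patient-level and sextant-level confusion counts across the
#' cohort (sextant units pooled, six per patient), and records
#' (tpr, fpr) per alpha. AUC at a level is `NA` when the cohort has no
#' positive or no negative unit at that level.
#'
#' @param cases List of cases; each case is a list with elements `p_ca`
#'   (probability [vol3d]), `prostate` (mask [vol3d]) and `gt_epe`
#'   (ground-truth EPE label [vol3d]).
#' @param grid Increasing vector of alpha values; default
#'   `seq(0, 1, by = 0.05)` (21 thresholds).
#' @param params A [pipeline_params]; its `alpha` is ignored in favor of
#'   the grid.
#' @return List of class `roc_sweep` with `roc_curve` elements `patient`
#'   and `sextant`, plus `details`: per-alpha per-case predictions
#'   (`patient_pred` is an alpha-by-case logical matrix; `sextant_pred` and
#'   `sextant_gt` are alpha-by-unit and per-unit structures for the pooled
#'   sextant units).
#' @export
roc_sweep <- function(cases, grid = seq(0, 1, by = 0.05),
                      params = pipeline_params()) {
  if (!is.list(cases) || length(cases) == 0L) stop("'cases' must be non-empty")
  grid <- as.numeric(grid)
  if (any(diff(grid) <= 0)) stop("'grid' must be strictly increasing")
  if (any(grid < 0 | grid > 1)) stop("alpha grid must lie in [0, 1]")
  preps <- lapply(cases, prepare_case, params = params)
  gt_patient <- vapply(preps, `[[`, logical(1), "gt_patient")
  gt_sextant <- as.vector(vapply(preps, `[[`, logical(6), "gt_sextant"))
  na <- length(grid)
  patient_pred <- matrix(FALSE, na, length(cases))
  sextant_pred <- matrix(FALSE, na, 6L * length(cases))
  for (ai in seq_len(na)) {
    pars <- params
    pars$alpha <- grid[ai]
    for (ci in seq_along(preps)) {
      pr <- preps[[ci]]
      res <- detect_epe_core(pr$p_masked, pr$prostate, pr$cache, pars)
      acc_idx <- unlist(lapply(res$candidates,
                               function(cc) if (isTRUE(cc$accepted)) cc$idx),
                        use.names = FALSE)
      patient_pred[ai, ci] <- length(acc_idx) > 0L
      sextant_pred[ai, (6L * (ci - 1L) + 1L):(6L * ci)] <-
        region_flags_idx(acc_idx, pr$part)
    }
  }
  mk_points <- function(pred, gt) {
    pts <- data.frame(alpha = grid, tpr = NA_real_, fpr = NA_real_)
    for (ai in seq_len(na)) {
      cc <- confusion(pred[ai, ], gt)
      pts$tpr[ai] <- if (cc$tp + cc$fn > 0) cc$tp / (cc$tp + cc$fn) else NA_real_
      pts$fpr[ai] <- if (cc$fp + cc$tn > 0) cc$fp / (cc$fp + cc$tn) else NA_real_
    }
    pts
  }
  structure(list(
    patient = new_roc_curve(mk_points(patient_pred, gt_patient), "patient"),
    sextant = new_roc_curve(mk_points(sextant_pred, gt_sextant), "sextant"),
    details = list(grid = grid, patient_pred = patient_pred,
                   patient_gt = gt_patient, sextant_pred = sextant_pred,
                   sextant_gt = gt_sextant)),
    class = "roc_sweep")
}

#' @export
print.roc_sweep <- function(x, ...) {
  print(x$patient); print(x$sextant)
  invisible(x)
}

DEFAULT_TCL_GRID <- c(2.5, 5.0, 7.5, 10.0, 12.5, 15.0, 17.5, 20.0)

#' Grid search over the contact-length threshold
#'
#' Runs one [roc_sweep()] per TCL threshold value (per fold when a fold
#' assignment is given) and tabulates the resulting patient-level and
#' sextant-level AUCs, averaged over folds.
#'
#' @param cases As in [roc_sweep()].
#' @param tcl_values Contact-length thresholds in mm; default
#'   `{2.5, 5, 7.5, 10, 12.5, 15, 17.5, 20}`.
#' @param grid Alpha grid passed to [roc_sweep()].
#' @param params A [pipeline_params].
#' @param folds Optional integer fold assignment, one entry per case;
#'   AUCs are computed within each fold and averaged (`NA` folds dropped
#'   from the mean).
#' @return Data frame with columns `tcl_mm`, `patient_auc`, `sextant_auc`.
#' @export
grid_search_tcl <- function(cases, tcl_values = DEFAULT_TCL_GRID,
                            grid = seq(0, 1, by = 0.05),
                            params = pipeline_params(), folds = NULL) {
  if (length(tcl_values) == 0L) stop("'tcl_values' must be non-empty")
  if (!is.null(folds) && length(folds) != length(cases))
    stop("'folds' must assign one fold per case")
  one <- function(tcl, subset) {
    pars <- params
    pars$tcl_threshold <- tcl
    sw <- roc_sweep(cases[subset], grid = grid, params = pars)
    c(patient = sw$patient$auc, sextant = sw$sextant$auc)
  }
  rows <- lapply(tcl_values, function(tcl) {
    if (is.null(folds)) {
      a <- one(tcl, seq_along(cases))
    } else {
      per <- vapply(unique(folds), function(f) one(tcl, which(folds == f)),
                    numeric(2))
      a <- rowMeans(per, na.rm = TRUE)
    }
    data.frame(tcl_mm = tcl, patient_auc = a[["patient"]],
               sextant_auc = a[["sextant"]])
  })
  do.call(rbind, rows)
}
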