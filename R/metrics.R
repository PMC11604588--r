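# Segmentation evaluation: per-class confusion counts, the four overlap/rate
# metrics, average volume difference, average symmetric surface distance, and
# cohort-level mean +/- SD aggregation with explicit NaN (undefined) handling.

#' Per-class confusion counts
#'
#' Voxel counts of true/false positives/negatives for one class on one
#' subject.
#'
#' @param pred,truth Integer label arrays on the same grid.
#' @param class_id The label value treated as positive.
#' @return A `confusion_counts` list with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(pred, truth, class_id) {
  if (is.null(dim(pred)) || is.null(dim(truth)) ||
      length(dim(pred)) != length(dim(truth)) || !all(dim(pred) == dim(truth)))
    stop("confusion: pred and truth must share one grid")
  p <- pred == class_id
  t <- truth == class_id
  structure(list(tp = sum(p & t), fp = sum(p & !t),
                 tn = sum(!p & !t), fn = sum(!p & t)),
            class = "confusion_counts")
}

check_counts <- function(cc) {
  v <- unlist(cc[c("tp", "fp", "tn", "fn")])
  if (any(v < 0)) stop("confusion counts must be non-negative")
  v
}

#' Overlap and rate metrics from confusion counts
#'
#' `recall` = TP/(TP+FN); `precision` = TP/(TP+FP); `dice` =
#' 2TP/(2TP+FP+FN), the harmonic mean of precision and recall; `lfpr`
#' (lesion false positive rate) = FP/(FP+TN).
#'
#' Zero-denominator conventions: recall with no positive truth voxels is
#' undefined (`NaN`, excluded from cohort means); precision of an empty
#' prediction is 0; dice with TP=FP=FN=0 is undefined; LFPR with no negative
#' truth voxels is undefined. An empty prediction against a non-empty truth
#' scores 0 on recall, precision and dice.
#'
#' @param cc A [confusion()] result.
#' @return A number in `[0, 1]`, or `NaN` when undefined.
#' @export
recall <- function(cc) {
  check_counts(cc)
  if (cc$tp + cc$fn == 0) return(NaN)
  cc$tp / (cc$tp + cc$fn)
}

#' @rdname recall
#' @export
precision <- function(cc) {
  check_counts(cc)
  if (cc$tp + cc$fp == 0) return(0)
  cc$tp / (cc$tp + cc$fp)
}

#' @rdname recall
#' @export
dice <- function(cc) {
  check_counts(cc)
  den <- 2 * cc$tp + cc$fp + cc$fn
  if (den == 0) return(NaN)
  2 * cc$tp / den
}

#' @rdname recall
#' @export
lfpr <- function(cc) {
  check_counts(cc)
  if (cc$fp + cc$tn == 0) return(NaN)
  cc$fp / (cc$fp + cc$tn)
}

#' Average volume difference
#'
#' Mean over regions of `|V_pred - V_true| / V_true`. Pairs with zero truth
#' volume are excluded (and counted); an empty effective list yields `NaN`.
#'
#' @param pairs A list of `c(v_pred, v_true)` pairs, or a 2-column matrix
#'   (pred, true), in any consistent volume unit.
#' @return List with `avd` (the mean relative difference, `NaN` if no valid
#'   pair) and `n_excluded` (pairs dropped for zero truth volume).
#' @export
avd <- function(pairs) {
  if (is.matrix(pairs)) pairs <- asplit(pairs, 1L)
  vp <- vapply(pairs, `[`, numeric(1), 1L)
  vt <- vapply(pairs, `[`, numeric(1), 2L)
  if (any(vp < 0) || any(vt < 0)) stop("avd: volumes must be >= 0")
  keep <- vt > 0
  if (!any(keep)) return(list(avd = NaN, n_excluded = sum(!keep)))
  list(avd = mean(abs(vp[keep] - vt[keep]) / vt[keep]),
       n_excluded = sum(!keep))
}

#' Surface point set of a binary mask
#'
#' A mask voxel belongs to the surface when at least one of its 6
#' face-neighbors is outside the mask; the volume border counts as outside.
#' Coordinates are voxel centers scaled to physical units.
#'
#' @param mask Logical or 0/1 3D array.
#' @param spacing Voxel spacing per axis in mm (length 1 or 3).
#' @return An n x 3 matrix of surface point coordinates (mm); 0 rows for an
#'   empty mask.
#' @export
surface_points <- function(mask, spacing = c(1, 1, 1)) {
  if (length(dim(mask)) != 3L) stop("surface_points: mask must be 3D")
  spacing <- rep_len(as.numeric(spacing), 3L)
  m <- mask != 0
  if (!any(m)) return(matrix(numeric(0), ncol = 3L))
  d <- dim(m)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  interior <-
    pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  surf <- m & !interior
  w <- which(surf, arr.ind = TRUE)
  sweep(w - 1, 2L, spacing, `*`)
}

#' Average symmetric surface distance
#'
#' Half the sum of (i) the mean nearest-neighbor Euclidean distance from
#' each predicted-surface point to the truth surface and (ii) the mean from
#' each truth-surface point to the predicted surface, in physical units.
#' Undefined (`NaN`) when either mask is empty — the convention used when a
#' method predicts no lesion at all.
#'
#' @param pred_mask,true_mask Binary 3D arrays on the same grid.
#' @param spacing Voxel spacing per axis in mm.
#' @return Non-negative distance in mm, or `NaN`.
#' @export
assd <- function(pred_mask, true_mask, spacing = c(1, 1, 1)) {
  if (!all(dim(pred_mask) == dim(true_mask)))
    stop("assd: masks must share one grid")
  P <- surface_points(pred_mask, spacing)
  G <- surface_points(true_mask, spacing)
  if (nrow(P) == 0L || nrow(G) == 0L) return(NaN)
  d_pg <- cpp_nn_dist(P, G)
  d_gp <- cpp_nn_dist(G, P)
  (mean(d_pg) + mean(d_gp)) / 2
}

#' Evaluate one subject across tumor subregions
#'
#' Computes all six metrics per subregion class for a predicted / ground
#' truth label-map pair.
#'
#' @param pred,truth Integer label arrays (same grid).
#' @param classes Named integer vector of subregion label values
#'   (default `c(NC = 1, ED = 2, ET = 3)`).
#' @param spacing Voxel spacing in mm.
#' @return A data.frame with one row per subregion: recall, precision, dice,
#'   lfpr, avd (per-subject relative volume difference; `NaN` when the truth
#'   region is empty) and assd.
#' @export
evaluate_subject <- function(pred, truth, classes = c(NC = 1, ED = 2, ET = 3),
                             spacing = c(1, 1, 1)) {
  rows <- lapply(seq_along(classes), function(k) {
    cl <- classes[k]
    cc <- confusion(pred, truth, cl)
    vt <- cc$tp + cc$fn
    vp <- cc$tp + cc$fp
    data.frame(
      subregion = names(classes)[k],
      recall = recall(cc), precision = precision(cc), dice = dice(cc),
      lfpr = lfpr(cc),
      avd = if (vt > 0) abs(vp - vt) / vt else NaN,
      assd = assd(pred == cl, truth == cl, spacing),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Whole-tumor Dice
#'
#' Dice of the union of all tumor subregions (any nonzero label) against the
#' ground-truth union — the coarsest sanity measure of a segmentation.
#'
#' @param pred,truth Integer label arrays on one grid (0 = background).
#' @return Dice in `[0, 1]`, `NaN` if both unions are empty.
#' @export
whole_tumor_dice <- function(pred, truth) {
  dice(confusion(pred > 0, truth > 0, TRUE))
}

#' Aggregate per-subject metrics into a cohort report
#'
#' Mean and population standard deviation per subregion and metric, with
#' undefined (`NaN`) entries excluded from the aggregation and their count
#' reported — so a method that never predicts a region shows `NaN` rather
#' than a contaminated mean.
#'
#' @param subject_reports A list of [evaluate_subject()] data.frames, or one
#'   long data.frame with a `subregion` column.
#' @param method Optional method label attached to every row.
#' @return A `metric_report` data.frame: one row per subregion, and per
#'   metric the columns `<m>_mean`, `<m>_sd`, `<m>_n_excluded` plus a
#'   display column `<m>` formatted "mean±sd".
#' @export
evaluate_cohort <- function(subject_reports, method = "FusionNet") {
  if (is.data.frame(subject_reports)) subject_reports <- list(subject_reports)
  if (length(subject_reports) < 1L) stop("need at least one subject")
  long <- do.call(rbind, subject_reports)
  metrics <- c("recall", "precision", "dice", "lfpr", "avd", "assd")
  out <- lapply(unique(long$subregion), function(sr) {
    sub <- long[long$subregion == sr, , drop = FALSE]
    row <- data.frame(method = method, subregion = sr,
                      n_subjects = nrow(sub), stringsAsFactors = FALSE)
    for (m in metrics) {
      v <- sub[[m]]
      ok <- is.finite(v)
      mu <- if (any(ok)) mean(v[ok]) else NaN
      sdv <- if (any(ok)) sqrt(mean((v[ok] - mu)^2)) else NaN
      row[[paste0(m, "_mean")]] <- mu
      row[[paste0(m, "_sd")]] <- sdv
      row[[paste0(m, "_n_excluded")]] <- sum(!ok)
      row[[m]] <- if (is.nan(mu)) "NaN" else
        sprintf("%.2f±%.2f", mu, sdv)
    }
    row
  })
  structure(do.call(rbind, out), class = c("metric_report", "data.frame"))
}

#' Write a metric report to CSV
#'
#' One row per (method, subregion) with both the formatted "mean±sd" display
#' columns and the machine-readable mean/sd/exclusion-count columns.
#'
#' @param report A [evaluate_cohort()] result (or several rbind-ed).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
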