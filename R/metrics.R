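# Semantic and instance segmentation metrics. Conventions for degenerate
# inputs are declared explicitly (the underlying definitions are silent):
# Dice = IoU = BF1 = 1 when both masks are empty, PQ = DQ = SQ = 1 when
# both instance maps are empty.

#' Dice coefficient between two binary masks
#'
#' `2 |pred & gt| / (|pred| + |gt|)`; 1 if both masks are empty.
#'
#' @param pred,gt aligned binary 0/1 matrices.
#' @return value in `[0, 1]`.
#' @export
dice_coefficient <- function(pred, gt) {
  assert_binary_mask(pred, "pred"); assert_binary_mask(gt, "gt")
  assert_same_shape(pred, gt, "pred", "gt")
  denom <- sum(pred) + sum(gt)
  if (denom == 0) return(1)
  2 * sum(pred * gt) / denom
}

#' Intersection over union between two binary masks
#'
#' `|pred & gt| / |pred | gt|`; 1 if both masks are empty.
#'
#' @inheritParams dice_coefficient
#' @return value in `[0, 1]`.
#' @export
iou_score <- function(pred, gt) {
  assert_binary_mask(pred, "pred"); assert_binary_mask(gt, "gt")
  assert_same_shape(pred, gt, "pred", "gt")
  uni <- sum(pred + gt > 0)
  if (uni == 0) return(1)
  sum(pred * gt) / uni
}

# contingency of instance overlaps: tibble(gt_id, pred_id, inter)
instance_overlaps <- function(pred, gt) {
  sel <- which(pred > 0 & gt > 0)
  if (length(sel) == 0L) {
    return(tibble(gt_id = integer(0), pred_id = integer(0), inter = integer(0)))
  }
  tab <- table(gt_id = gt[sel], pred_id = pred[sel])
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  df <- df[df$Freq > 0, ]
  tibble(gt_id = as.integer(df$gt_id), pred_id = as.integer(df$pred_id),
         inter = as.integer(df$Freq))
}

#' Aggregated Jaccard Index
#'
#' Each ground-truth instance is matched to the prediction maximizing
#' their Jaccard index; the numerator accumulates matched intersections
#' and the denominator matched unions plus the areas of all predictions
#' never used in a match.
#'
#' @param pred,gt aligned instance masks (non-negative integer matrices,
#'   0 = background).
#' @return value in `[0, 1]`; 1 when both maps are empty.
#' @export
aji <- function(pred, gt) {
  assert_same_shape(pred, gt, "pred", "gt")
  gt_ids <- setdiff(sort(unique(as.vector(gt))), 0L)
  pred_ids <- setdiff(sort(unique(as.vector(pred))), 0L)
  if (length(gt_ids) == 0L && length(pred_ids) == 0L) return(1)
  if (length(gt_ids) == 0L || length(pred_ids) == 0L) return(0)

  gt_area <- table(factor(gt[gt > 0], levels = gt_ids))
  pred_area <- table(factor(pred[pred > 0], levels = pred_ids))
  ov <- instance_overlaps(pred, gt)

  used <- logical(length(pred_ids))
  names(used) <- pred_ids
  num <- 0; den <- 0
  for (g in gt_ids) {
    cand <- ov[ov$gt_id == g, ]
    ga <- as.numeric(gt_area[[as.character(g)]])
    if (nrow(cand) == 0L) {
      den <- den + ga
      next
    }
    uni <- ga + as.numeric(pred_area[as.character(cand$pred_id)]) - cand$inter
    jac <- cand$inter / uni
    best <- which.max(jac)  # ties: first, i.e. smallest pred id
    num <- num + cand$inter[best]
    den <- den + uni[best]
    used[as.character(cand$pred_id[best])] <- TRUE
  }
  den <- den + sum(as.numeric(pred_area[!used]))
  if (den == 0) return(1)
  num / den
}

#' Panoptic quality, detection quality and segmentation quality
#'
#' Instance pairs with IoU strictly above `iou_threshold` are matched
#' (unique by the > 0.5 theorem at the default). `DQ = TP / (TP + FP/2 +
#' FN/2)`, `SQ` is the mean IoU over matched pairs (0 when there are no
#' matches), and `PQ = DQ * SQ`. Both maps empty gives PQ = DQ = SQ = 1.
#'
#' @inheritParams aji
#' @param iou_threshold matching threshold (default 0.5, strict `>`).
#' @return a list with `pq`, `dq`, `sq`, `tp`, `fp`, `fn`.
#' @export
panoptic_quality <- function(pred, gt, iou_threshold = 0.5) {
  assert_same_shape(pred, gt, "pred", "gt")
  gt_ids <- setdiff(sort(unique(as.vector(gt))), 0L)
  pred_ids <- setdiff(sort(unique(as.vector(pred))), 0L)
  if (length(gt_ids) == 0L && length(pred_ids) == 0L) {
    return(list(pq = 1, dq = 1, sq = 1, tp = 0L, fp = 0L, fn = 0L))
  }
  gt_area <- table(factor(gt[gt > 0], levels = gt_ids))
  pred_area <- table(factor(pred[pred > 0], levels = pred_ids))
  ov <- instance_overlaps(pred, gt)
  if (nrow(ov) > 0L) {
    uni <- as.numeric(gt_area[as.character(ov$gt_id)]) +
      as.numeric(pred_area[as.character(ov$pred_id)]) - ov$inter
    ov$iou <- ov$inter / uni
    matches <- ov[ov$iou > iou_threshold, ]
  } else {
    matches <- ov
  }
  tp <- nrow(matches)
  fp <- length(pred_ids) - tp
  fn <- length(gt_ids) - tp
  dq <- if (tp + fp / 2 + fn / 2 == 0) 0 else tp / (tp + fp / 2 + fn / 2)
  sq <- if (tp == 0) 0 else mean(matches$iou)
  list(pq = dq * sq, dq = dq, sq = sq, tp = tp, fp = fp, fn = fn)
}

#' Boundary F1 score between two binary masks
#'
#' Boundary pixels are foreground pixels 4-adjacent to background (pixels
#' beyond the image border count as background). Precision is the
#' fraction of predicted boundary pixels within `tolerance` (Euclidean)
#' of the reference boundary; recall is symmetric; BF1 is their harmonic
#' mean. Both boundaries empty gives 1; exactly one empty gives 0.
#'
#' @inheritParams dice_coefficient
#' @param tolerance matching distance in pixels (default 2).
#' @return value in `[0, 1]`.
#' @export
boundary_f1 <- function(pred, gt, tolerance = 2) {
  assert_binary_mask(pred, "pred"); assert_binary_mask(gt, "gt")
  assert_same_shape(pred, gt, "pred", "gt")
  if (tolerance < 0) abort("`tolerance` must be non-negative.")
  bp <- boundary_pixels(pred)
  bg_ <- boundary_pixels(gt)
  if (!any(bp) && !any(bg_)) return(1)
  if (!any(bp) || !any(bg_)) return(0)
  dist_to_gt <- distance_to_set(bg_, tolerance)
  dist_to_pred <- distance_to_set(bp, tolerance)
  precision <- mean(dist_to_gt[bp] <= tolerance)
  recall <- mean(dist_to_pred[bg_] <= tolerance)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

# Euclidean distance from every pixel to the nearest TRUE pixel of `set`,
# exact within `tolerance` (the image is padded so border effects cannot
# alter any <= tolerance decision).
distance_to_set <- function(set, tolerance) {
  pad <- as.integer(ceiling(tolerance)) + 2L
  h <- nrow(set); w <- ncol(set)
  padded <- matrix(1, h + 2L * pad, w + 2L * pad)
  padded[pad + (1:h), pad + (1:w)] <- 1 - set  # set pixels become 0
  d <- EBImage::distmap(padded, metric = "euclidean")
  as.matrix(d)[pad + (1:h), pad + (1:w)]
}

#' Full metric report for a prediction/ground-truth pair
#'
#' Computes the semantic metrics (Dice, IoU) on the foreground of the two
#' instance maps, plus AJI, PQ (with DQ and SQ) and Boundary-F1.
#'
#' @inheritParams aji
#' @param bf1_tolerance boundary matching tolerance in pixels (default 2).
#' @param iou_threshold PQ matching threshold (default 0.5).
#' @return a one-row tibble with columns `dice`, `iou`, `aji`, `pq`,
#'   `dq`, `sq`, `bf1`, `n_pred_instances`, `n_gt_instances`.
#' @export
metric_report <- function(pred, gt, bf1_tolerance = 2, iou_threshold = 0.5) {
  pred_bin <- matrix(as.numeric(pred > 0), nrow(pred), ncol(pred))
  gt_bin <- matrix(as.numeric(gt > 0), nrow(gt), ncol(gt))
  pqres <- panoptic_quality(pred, gt, iou_threshold)
  tibble(
    dice = dice_coefficient(pred_bin, gt_bin),
    iou = iou_score(pred_bin, gt_bin),
    aji = aji(pred, gt),
    pq = pqres$pq, dq = pqres$dq, sq = pqres$sq,
    bf1 = boundary_f1(pred_bin, gt_bin, bf1_tolerance),
    n_pred_instances = length(setdiff(unique(as.vector(pred)), 0L)),
    n_gt_instances = length(setdiff(unique(as.vector(gt)), 0L))
  )
}
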