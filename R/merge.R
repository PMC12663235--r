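# Mask-merging baselines: plain averaging (AP, threshold 0.5),
# low-precision averaging (LP, threshold 0.9) and a validation-weighted
# sum with grid-tuned weights. Binarization uses >= so that at the
# default thresholds AP behaves as pixelwise OR and LP as pixelwise AND
# on disagreement pixels.

#' Merge two masks by element-wise averaging
#'
#' Averages the two binary masks and binarizes at `threshold` with the
#' `>=` convention. At threshold 0.5 this is the inclusive "AP" baseline
#' (disagreement pixels become foreground); at threshold 0.9 it is the
#' exclusive low-precision "LP" baseline keeping only high-confidence
#' (agreed) foreground.
#'
#' @param mask_d,mask_s aligned binary 0/1 matrices.
#' @param threshold binarization threshold in `[0, 1]` (default 0.5).
#' @return a binary mask.
#' @export
merge_average <- function(mask_d, mask_s, threshold = 0.5) {
  assert_binary_mask(mask_d, "mask_d")
  assert_binary_mask(mask_s, "mask_s")
  assert_same_shape(mask_d, mask_s, "mask_d", "mask_s")
  if (threshold < 0 || threshold > 1) abort("`threshold` must be in [0, 1].")
  matrix(as.numeric((mask_d + mask_s) / 2 >= threshold),
         nrow(mask_d), ncol(mask_d))
}

#' Merge two masks by a weighted sum
#'
#' Computes `weight_d * mask_d + weight_s * mask_s` and binarizes at
#' `threshold` (`>=` convention). The weights must sum to 1.
#'
#' @inheritParams merge_average
#' @param weight_d,weight_s non-negative weights summing to 1.
#' @return a binary mask.
#' @export
merge_weighted <- function(mask_d, mask_s, weight_d, weight_s,
                           threshold = 0.5) {
  assert_binary_mask(mask_d, "mask_d")
  assert_binary_mask(mask_s, "mask_s")
  assert_same_shape(mask_d, mask_s, "mask_d", "mask_s")
  if (abs(weight_d + weight_s - 1) > 1e-6) {
    abort("`weight_d` and `weight_s` must sum to 1 (tolerance 1e-6).")
  }
  matrix(as.numeric(weight_d * mask_d + weight_s * mask_s >= threshold),
         nrow(mask_d), ncol(mask_d))
}

#' Merge two masks by a named baseline strategy
#'
#' Dispatches to the named baseline: `"ap"` is element-wise averaging
#' binarized at 0.5, `"lp"` (low-precision averaging) the same at 0.9,
#' and `"weighted"` a weighted sum (weights required, renormalized to
#' sum to 1 if slightly off).
#'
#' @inheritParams merge_average
#' @param strategy `"ap"`, `"lp"` or `"weighted"`.
#' @param weight_d,weight_s weights for `"weighted"`.
#' @param threshold optional threshold override.
#' @return a binary mask.
#' @export
merge_masks <- function(mask_d, mask_s, strategy = c("ap", "lp", "weighted"),
                        weight_d = NULL, weight_s = NULL, threshold = NULL) {
  strategy <- match.arg(strategy)
  if (strategy == "ap") {
    merge_average(mask_d, mask_s, threshold %||% 0.5)
  } else if (strategy == "lp") {
    merge_average(mask_d, mask_s, threshold %||% 0.9)
  } else {
    if (is.null(weight_d) || is.null(weight_s)) {
      abort("Strategy 'weighted' requires `weight_d` and `weight_s`.")
    }
    tot <- weight_d + weight_s
    if (abs(tot - 1) > 0.05) abort("Weights must (approximately) sum to 1.")
    merge_weighted(mask_d, mask_s, weight_d / tot, weight_s / tot,
                   threshold %||% 0.5)
  }
}

#' Tune merge weights on labeled mask pairs
#'
#' Grid-searches `weight_d` over `{0, step, ..., 1}` (with
#' `weight_s = 1 - weight_d`) and returns the pair maximizing the mean
#' Dice of the weighted merge against the ground truth across the
#' supplied triplets. Ties are broken toward the most balanced pair
#' (`weight_d` closest to 0.5).
#'
#' @param pairs a list of triplets, each a list with elements `mask_d`,
#'   `mask_s`, `gt` (aligned binary matrices).
#' @param grid_step grid resolution in `(0, 0.5]` (default 0.05).
#' @param threshold binarization threshold passed to [merge_weighted()].
#' @return a list with `weight_d`, `weight_s` and `grid`, a tibble of the
#'   full search (`weight_d`, `mean_dice`).
#' @export
tune_weights <- function(pairs, grid_step = 0.05, threshold = 0.5) {
  if (length(pairs) == 0L) abort("`pairs` must be a non-empty list of triplets.")
  if (grid_step <= 0 || grid_step > 0.5) abort("`grid_step` must be in (0, 0.5].")
  wd_grid <- unique(c(seq(0, 1, by = grid_step), 1))
  grid <- purrr::map_dfr(wd_grid, function(wd) {
    scores <- vapply(pairs, function(tr) {
      m <- merge_weighted(tr$mask_d, tr$mask_s, wd, 1 - wd, threshold)
      dice_coefficient(m, tr$gt)
    }, numeric(1))
    tibble(weight_d = wd, mean_dice = mean(scores))
  })
  best <- max(grid$mean_dice)
  cand <- grid$weight_d[grid$mean_dice >= best - 1e-12]
  wd <- cand[which.min(abs(cand - 0.5))]
  list(weight_d = wd, weight_s = 1 - wd, grid = grid)
}
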