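#' Partition pixels into agreed-foreground, agreed-background and ambiguous sets
#'
#' Given two aligned binary masks, classifies every pixel into one of three
#' disjoint sets: F (both masks foreground), B (both background), and A
#' (the masks disagree). Only A-pixels are relabeled by [reconcile()]; F and
#' B labels are accepted as-is.
#'
#' @param mask_d binary 0/1 matrix, the detector-derived candidate mask.
#' @param mask_s binary 0/1 matrix, the segmenter-derived candidate mask.
#' @return an object of class `ambiguity_partition`: a list with logical
#'   matrices `f`, `b`, `a` and the integer counts `n_f`, `n_b`, `n_a`.
#' @examples
#' d <- matrix(c(1, 1, 0, 0), 2, 2)
#' s <- matrix(c(1, 0, 0, 1), 2, 2)
#' p <- partition_pixels(d, s)
#' c(p$n_f, p$n_b, p$n_a)
#' @export
partition_pixels <- function(mask_d, mask_s) {
  assert_binary_mask(mask_d, "mask_d")
  assert_binary_mask(mask_s, "mask_s")
  assert_same_shape(mask_d, mask_s, "mask_d", "mask_s")
  f <- mask_d == 1 & mask_s == 1
  b <- mask_d == 0 & mask_s == 0
  a <- mask_d != mask_s
  structure(
    list(f = f, b = b, a = a,
         n_f = sum(f), n_b = sum(b), n_a = sum(a),
         height = nrow(mask_d), width = ncol(mask_d)),
    class = "ambiguity_partition"
  )
}

#' @export
print.ambiguity_partition <- function(x, ...) {
  cat(sprintf(
    "<ambiguity_partition> %d x %d: |F| = %d, |B| = %d, |A| = %d\n",
    x$height, x$width, x$n_f, x$n_b, x$n_a
  ))
  invisible(x)
}

#' Split an image into a K x K grid of patches
#'
#' The image is divided into K^2 mutually exclusive, collectively exhaustive
#' rectangular patches. The base patch size is `floor(H/K) x floor(W/K)`;
#' remainder rows and columns are absorbed by the last patch row/column.
#' Patch IDs run 0..K^2-1 in row-major order.
#'
#' @param height,width image dimensions in pixels.
#' @param k grid order K (>= 1, <= min(height, width)).
#' @return an object of class `patch_grid`: list with `k`, `patch_index`
#'   (H x W integer matrix of patch IDs) and `patch_bounds` (a tibble with
#'   one row per patch: `patch`, `row_start`, `row_end`, `col_start`,
#'   `col_end`, 1-based inclusive).
#' @export
make_patch_grid <- function(height, width, k) {
  if (k < 1 || k > min(height, width)) {
    abort("`k` must satisfy 1 <= k <= min(height, width).")
  }
  k <- as.integer(k)
  base_h <- height %/% k
  base_w <- width %/% k
  row_start <- (seq_len(k) - 1L) * base_h + 1L
  row_end <- c(row_start[-1L] - 1L, height)
  col_start <- (seq_len(k) - 1L) * base_w + 1L
  col_end <- c(col_start[-1L] - 1L, width)

  row_block <- pmin((seq_len(height) - 1L) %/% base_h, k - 1L)
  col_block <- pmin((seq_len(width) - 1L) %/% base_w, k - 1L)
  patch_index <- outer(row_block, col_block, function(r, c) r * k + c)
  storage.mode(patch_index) <- "integer"

  bounds <- tibble(
    patch = 0:(k * k - 1L),
    row_start = rep(row_start, each = k),
    row_end = rep(row_end, each = k),
    col_start = rep(col_start, times = k),
    col_end = rep(col_end, times = k)
  )
  structure(
    list(k = k, height = as.integer(height), width = as.integer(width),
         patch_index = patch_index, patch_bounds = bounds),
    class = "patch_grid"
  )
}

#' @export
print.patch_grid <- function(x, ...) {
  cat(sprintf("<patch_grid> %d x %d image, K = %d (%d patches)\n",
              x$height, x$width, x$k, x$k^2))
  invisible(x)
}
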