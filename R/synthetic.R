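# Seeded generator of histology-like synthetic scenes: elliptical cells
# on a pale background, per-patch additive color drift emulating staining
# variation across the slide, pixelwise Gaussian noise, and two corrupted
# candidate masks emulating the failure modes of a detector-driven mask
# (good localization, shape errors, missed cells) and a segmenter mask
# (good shapes, boundary overshoot).

#' Specification of a synthetic scene
#'
#' Collects all generator parameters. Identical specs (including the
#' seed) produce bit-identical scenes.
#'
#' @param height,width image size in pixels.
#' @param n_cells number of cells to place (>= 0).
#' @param radius_range (min, max) ellipse semi-axis length in pixels.
#' @param fg_mean_rgb,bg_mean_rgb mean RGB color (0-255) of cell and
#'   background pixels; defaults mimic hematoxylin-stained nuclei on a
#'   pale eosin background.
#' @param intensity_sd pixelwise Gaussian noise sd (0-255 scale).
#' @param patch_drift_sd sd of the per-patch additive RGB shift (0-255
#'   scale), applied on the same K = 5 grid the intensity model uses.
#' @param detector_miss_rate probability that a cell is absent from the
#'   detector mask.
#' @param detector_shape_noise radius (pixels) by which each surviving
#'   detector cell is randomly dilated or eroded.
#' @param segmenter_overshoot radius (pixels) of the uniform dilation
#'   applied to the ground truth to form the segmenter mask.
#' @param seed integer seed.
#' @return an object of class `synthetic_spec` (a named list).
#' @export
synthetic_spec <- function(height = 128, width = 128, n_cells = 12,
                           radius_range = c(5, 10),
                           fg_mean_rgb = c(90, 40, 120),
                           bg_mean_rgb = c(220, 205, 225),
                           intensity_sd = 10, patch_drift_sd = 12,
                           detector_miss_rate = 0.2,
                           detector_shape_noise = 2,
                           segmenter_overshoot = 2,
                           seed = 0L) {
  spec <- list(
    height = as.integer(height), width = as.integer(width),
    n_cells = as.integer(n_cells), radius_range = as.numeric(radius_range),
    fg_mean_rgb = as.numeric(fg_mean_rgb), bg_mean_rgb = as.numeric(bg_mean_rgb),
    intensity_sd = intensity_sd, patch_drift_sd = patch_drift_sd,
    detector_miss_rate = detector_miss_rate,
    detector_shape_noise = detector_shape_noise,
    segmenter_overshoot = segmenter_overshoot,
    seed = as.integer(seed)
  )
  if (spec$n_cells < 0) abort("`n_cells` must be >= 0.")
  if (length(spec$radius_range) != 2L ||
      spec$radius_range[1] > spec$radius_range[2] || spec$radius_range[1] <= 0) {
    abort("`radius_range` must be (min, max) with 0 < min <= max.")
  }
  if (spec$detector_miss_rate < 0 || spec$detector_miss_rate > 1) {
    abort("`detector_miss_rate` must be in [0, 1].")
  }
  structure(spec, class = "synthetic_spec")
}

# inside-test rasterization of a rotated ellipse on pixel centers
rasterize_ellipse <- function(height, width, cy, cx, a, b, phi) {
  rows <- matrix(seq_len(height), height, width)
  cols <- matrix(seq_len(width), height, width, byrow = TRUE)
  dx <- cols - cx
  dy <- rows - cy
  u <- (dx * cos(phi) + dy * sin(phi)) / a
  v <- (-dx * sin(phi) + dy * cos(phi)) / b
  (u^2 + v^2) <= 1
}

JITTER_PROB <- 0.25  # flip probability on the segmenter mask's boundary band
PLACEMENT_ATTEMPTS <- 500L
DRIFT_GRID_K <- 5L

#' Generate a synthetic scene
#'
#' Places non-overlapping random ellipses by rejection sampling, renders
#' the image with per-patch color drift and pixel noise, and derives the
#' ground truth plus two corrupted candidate masks:
#' \describe{
#'   \item{mask_d}{each cell is dropped with `detector_miss_rate`;
#'     survivors are randomly dilated or eroded by
#'     `detector_shape_noise` pixels. Surviving cells keep their
#'     ground-truth instance IDs in `itd_instances`, and `boxes` are
#'     recomputed tightly around the surviving pixels.}
#'   \item{mask_s}{the ground-truth foreground dilated uniformly by
#'     `segmenter_overshoot` pixels, followed by random flips on the
#'     boundary band.}
#' }
#' Randomness is drawn from sub-streams derived in fixed order from the
#' spec seed (placement, drift, noise, detector corruption, segmenter
#' corruption), so results do not depend on internal call order.
#'
#' @param spec a `synthetic_spec`.
#' @return an object of class `synthetic_scene`: list with `image`
#'   (H x W x 3, 0-255), `gt_instances`, `gt_semantic`, `mask_d`,
#'   `itd_instances`, `boxes` (tibble: `x_min`, `y_min`, `x_max`,
#'   `y_max`, `instance_id`; 0-based inclusive), `mask_s`, `spec`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  h <- spec$height; w <- spec$width
  stage_seeds <- with_seed(spec$seed, sample.int(2147483646L, 5L))

  # --- placement ------------------------------------------------------
  gt_instances <- matrix(0L, h, w)
  with_seed(stage_seeds[1], {
    occupied <- matrix(FALSE, h, w)
    for (cell in seq_len(spec$n_cells)) {
      placed <- FALSE
      for (attempt in seq_len(PLACEMENT_ATTEMPTS)) {
        a <- runif(1, spec$radius_range[1], spec$radius_range[2])
        b <- runif(1, spec$radius_range[1], spec$radius_range[2])
        phi <- runif(1, 0, pi)
        m <- ceiling(max(a, b))
        if (2 * m + 2 >= min(h, w)) next
        cy <- runif(1, 1 + m, h - m)
        cx <- runif(1, 1 + m, w - m)
        ell <- rasterize_ellipse(h, w, cy, cx, a, b, phi)
        if (!any(ell & occupied) && any(ell)) {
          occupied <- occupied | ell
          gt_instances[ell] <- cell
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort(sprintf("Could not place cell %d after %d attempts; reduce n_cells or radius_range.",
                      cell, PLACEMENT_ATTEMPTS))
      }
    }
  })
  gt_semantic <- matrix(as.numeric(gt_instances > 0), h, w)

  # --- image: means + per-patch drift + pixel noise -------------------
  image <- array(0, c(h, w, 3))
  for (ch in 1:3) {
    image[, , ch] <- ifelse(gt_semantic == 1,
                            spec$fg_mean_rgb[ch], spec$bg_mean_rgb[ch])
  }
  k <- min(DRIFT_GRID_K, h, w)
  grid <- make_patch_grid(h, w, k)
  with_seed(stage_seeds[2], {
    drift <- matrix(rnorm(k * k * 3, 0, spec$patch_drift_sd), k * k, 3)
    for (ch in 1:3) {
      image[, , ch] <- image[, , ch] + drift[grid$patch_index + 1L, ch]
    }
  })
  with_seed(stage_seeds[3], {
    noise <- array(rnorm(h * w * 3, 0, spec$intensity_sd), c(h, w, 3))
    image <- image + noise
  })
  image <- round(pmin(pmax(image, 0), 255))

  # --- detector corruption -------------------------------------------
  itd_instances <- matrix(0L, h, w)
  with_seed(stage_seeds[4], {
    for (cell in seq_len(spec$n_cells)) {
      keep <- runif(1) >= spec$detector_miss_rate
      op <- sample(c("dilate", "erode"), 1L)
      if (!keep) next
      cell_mask <- matrix(as.numeric(gt_instances == cell), h, w)
      if (sum(cell_mask) == 0) next
      cell_mask <- switch(op,
        dilate = disc_dilate(cell_mask, spec$detector_shape_noise),
        erode = disc_erode(cell_mask, spec$detector_shape_noise)
      )
      itd_instances[cell_mask == 1] <- cell
    }
  })
  mask_d <- matrix(as.numeric(itd_instances > 0), h, w)

  surviving <- setdiff(sort(unique(as.vector(itd_instances))), 0L)
  boxes <- purrr::map_dfr(surviving, function(id) {
    lin <- which(itd_instances == id)
    rows <- ((lin - 1L) %% h) + 1L
    cols <- ((lin - 1L) %/% h) + 1L
    tibble(x_min = min(cols) - 1L, y_min = min(rows) - 1L,
           x_max = max(cols) - 1L, y_max = max(rows) - 1L,
           instance_id = id)
  })
  if (nrow(boxes) == 0L) {
    boxes <- tibble(x_min = integer(0), y_min = integer(0),
                    x_max = integer(0), y_max = integer(0),
                    instance_id = integer(0))
  }

  # --- segmenter corruption ------------------------------------------
  mask_s <- disc_dilate(gt_semantic, spec$segmenter_overshoot)
  with_seed(stage_seeds[5], {
    band <- disc_dilate(mask_s, 1) != disc_erode(mask_s, 1)
    idx <- which(band)
    if (length(idx)) {
      flip <- idx[runif(length(idx)) < JITTER_PROB]
      mask_s[flip] <- 1 - mask_s[flip]
    }
  })

  structure(
    list(image = image, gt_instances = gt_instances,
         gt_semantic = gt_semantic, mask_d = mask_d,
         itd_instances = itd_instances, boxes = boxes, mask_s = mask_s,
         spec = spec),
    class = "synthetic_scene"
  )
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "<synthetic_scene> %d x %d, %d cell(s), %d detector box(es), seed %d\n",
    x$spec$height, x$spec$width, max(x$gt_instances), nrow(x$boxes),
    x$spec$seed
  ))
  invisible(x)
}

#' Summarize a synthetic scene
#'
#' @param scene a `synthetic_scene`.
#' @return a one-row tibble: `n_cells`, `fg_fraction` (mean of the
#'   ground-truth semantic mask), `dice_d` and `dice_s` (Dice of each
#'   candidate mask against the ground truth) and `n_ambiguous`
#'   (disagreement pixel count of the mask pair).
#' @export
scene_report <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  part <- partition_pixels(scene$mask_d, scene$mask_s)
  tibble(
    n_cells = max(scene$gt_instances),
    fg_fraction = mean(scene$gt_semantic),
    dice_d = dice_coefficient(scene$mask_d, scene$gt_semantic),
    dice_s = dice_coefficient(scene$mask_s, scene$gt_semantic),
    n_ambiguous = part$n_a
  )
}
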