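# Conversion of the reconciled semantic mask to an instance mask, guided
# by the detector's instance labels and boxes, plus detector-agnostic
# baselines (connected components, watershed) and small-object removal.

#' Remove small connected components
#'
#' Zeroes every 8-connected foreground component whose area is strictly
#' below `min_area` pixels (default 20, matching the pipeline's
#' small-object filter).
#'
#' @param mask binary 0/1 matrix.
#' @param min_area minimum area in pixels to keep (>= 0).
#' @return a binary mask.
#' @export
remove_small_objects <- function(mask, min_area = 20) {
  assert_binary_mask(mask)
  if (min_area < 0) abort("`min_area` must be non-negative.")
  if (min_area == 0) return(mask)
  lab <- label_components(mask)
  if (max(lab) == 0L) return(mask)
  areas <- tabulate(lab[lab > 0])
  drop <- which(areas < min_area)
  if (length(drop)) mask[lab %in% drop] <- 0
  mask
}

#' Instance conversion by connected components
#'
#' Detector-agnostic baseline: every 8-connected component of the
#' semantic mask becomes one instance, numbered from 1 in raster order.
#'
#' @param semantic binary 0/1 matrix.
#' @return an instance mask (integer matrix).
#' @export
instances_by_connected_components <- function(semantic) {
  label_components(semantic)
}

#' Instance conversion by watershed
#'
#' Detector-agnostic baseline: markers are the maxima of the distance
#' transform of the semantic mask and instances are the watershed basins
#' of the negated distance map, so touching convex blobs are split at
#' their neck.
#'
#' @param semantic binary 0/1 matrix.
#' @return an instance mask (integer matrix).
#' @export
instances_by_watershed <- function(semantic) {
  assert_binary_mask(semantic)
  if (sum(semantic) == 0) return(matrix(0L, nrow(semantic), ncol(semantic)))
  d <- EBImage::distmap(semantic, metric = "euclidean")
  ws <- EBImage::watershed(d)
  out <- matrix(as.integer(as.matrix(ws)), nrow(semantic), ncol(semantic))
  renumber_raster_order(out)
}

renumber_raster_order <- function(inst) {
  ids <- setdiff(unique(as.vector(inst)), 0L)
  if (length(ids) == 0L) return(inst)
  h <- nrow(inst)
  fg <- which(inst > 0)
  rows <- ((fg - 1L) %% h) + 1L
  cols <- ((fg - 1L) %/% h) + 1L
  rank <- (rows - 1L) * ncol(inst) + cols
  first <- tapply(rank, inst[fg], min)
  relabel <- integer(max(ids))
  relabel[as.integer(names(first))[order(first)]] <- seq_along(first)
  inst[fg] <- relabel[inst[fg]]
  inst
}

#' Convert a semantic mask to instances using detector guidance
#'
#' Each 8-connected component of the semantic mask is resolved against
#' the detector's instance labels: a component overlapping exactly one
#' detector instance inherits its ID; a component overlapping two or more
#' is split by k-means on pixel coordinates (k = number of overlapping
#' instances, centers initialized at the corresponding box centers), each
#' cluster taking its initializing instance's ID; a component overlapping
#' none receives a fresh ID greater than all existing IDs. Overlap means
#' at least one shared pixel.
#'
#' @param semantic binary 0/1 matrix (e.g. the reconciled mask).
#' @param itd_instances instance mask of the detector's cells (nonzero
#'   exactly on the detector mask).
#' @param boxes a tibble/data.frame with columns `x_min`, `y_min`,
#'   `x_max`, `y_max`, `instance_id` (0-based inclusive pixel
#'   coordinates; x = column, y = row), as produced by
#'   [generate_scene()] or [read_boxes()].
#' @return an instance mask (integer matrix).
#' @export
convert_to_instances <- function(semantic, itd_instances, boxes) {
  assert_binary_mask(semantic, "semantic")
  assert_same_shape(semantic, itd_instances, "semantic", "itd_instances")
  h <- nrow(semantic)
  comp <- label_components(semantic)
  out <- matrix(0L, h, ncol(semantic))
  if (max(comp) == 0L) return(out)

  boxes <- as.data.frame(boxes)
  existing_ids <- unique(c(0L, as.vector(itd_instances)))
  next_id <- max(existing_ids) + 1L

  for (cid in seq_len(max(comp))) {
    lin <- which(comp == cid)
    over_ids <- setdiff(unique(itd_instances[lin]), 0L)
    if (length(over_ids) == 0L) {
      out[lin] <- next_id
      next_id <- next_id + 1L
    } else if (length(over_ids) == 1L) {
      out[lin] <- over_ids
    } else {
      rows <- ((lin - 1L) %% h) + 1L
      cols <- ((lin - 1L) %/% h) + 1L
      centers <- t(vapply(over_ids, function(id) {
        b <- boxes[boxes$instance_id == id, , drop = FALSE]
        if (nrow(b) == 1L) {
          # box coords are 0-based: center in 1-based (row, col)
          c((b$y_min + b$y_max) / 2 + 1, (b$x_min + b$x_max) / 2 + 1)
        } else {
          inform(sprintf(
            "No box for detector instance %d; using its pixel centroid as the cluster center.", id))
          sel <- which(itd_instances == id)
          c(mean(((sel - 1L) %% h) + 1L), mean(((sel - 1L) %/% h) + 1L))
        }
      }, numeric(2)))
      coords <- cbind(rows, cols)
      assign_k <- tryCatch({
        km <- suppressWarnings(
          kmeans(coords, centers = centers, iter.max = 100,
                 algorithm = "Lloyd")
        )
        km$cluster
      }, error = function(e) {
        # degenerate clustering (e.g. an emptied cluster): fall back to
        # nearest initial center
        d2 <- sapply(seq_len(nrow(centers)), function(k) {
          (rows - centers[k, 1])^2 + (cols - centers[k, 2])^2
        })
        if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1L)
        max.col(-d2, ties.method = "first")
      })
      out[lin] <- over_ids[assign_k]
    }
  }
  out
}
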