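#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn inform
#' @importFrom tibble tibble as_tibble
#' @importFrom stats kmeans rnorm runif
NULL

# Rasters are plain R objects indexed [row, col] with row 1 at the top:
# an RGB image is a numeric H x W x 3 array on the 0-255 scale, a binary
# mask a 0/1 matrix, an instance mask a non-negative integer matrix with
# 0 meaning background.

assert_binary_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask)) {
    abort(sprintf("`%s` must be a matrix (H x W raster).", arg))
  }
  if (!all(mask %in% c(0, 1))) {
    abort(sprintf("`%s` must contain only 0/1 values.", arg))
  }
  invisible(mask)
}

assert_same_shape <- function(a, b, arg_a = "first", arg_b = "second") {
  da <- dim(a)[1:2]
  db <- dim(b)[1:2]
  if (!identical(da, db)) {
    abort(sprintf(
      "`%s` (%d x %d) and `%s` (%d x %d) must share the same height and width.",
      arg_a, da[1], da[2], arg_b, db[1], db[2]
    ))
  }
  invisible(NULL)
}

assert_rgb_image <- function(image, arg = "image") {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L) {
    abort(sprintf("`%s` must be an H x W x 3 array.", arg))
  }
  if (min(image) < 0 || max(image) > 255) {
    abort(sprintf("`%s` must be on the 0-255 intensity scale.", arg))
  }
  invisible(image)
}

# Linear index helpers (column-major, as R stores matrices).
rc_to_lin <- function(row, col, height) (col - 1L) * height + row

#' Label 8-connected components of a binary mask
#'
#' Each 8-connected foreground component receives a distinct positive
#' integer ID; components are numbered from 1 in raster order (row-major,
#' by the first pixel of each component).
#'
#' @param mask binary 0/1 matrix.
#' @return integer matrix of the same shape with component labels.
#' @export
label_components <- function(mask) {
  assert_binary_mask(mask)
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(0L, h, w)
  fg <- which(mask == 1)
  if (length(fg) == 0L) return(out)

  fgm <- mask == 1
  edge_from <- integer(0); edge_to <- integer(0)
  # pair offsets: E, S, SE, SW cover all 8-neighbor adjacencies once
  offs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  for (o in offs) {
    di <- o[1]; dj <- o[2]
    ri <- seq_len(h - di)
    cj <- if (dj >= 0) seq_len(w - dj) else seq(1L - dj, w)
    a <- fgm[ri, cj, drop = FALSE]
    b <- fgm[ri + di, cj + dj, drop = FALSE]
    both <- which(a & b)
    if (length(both)) {
      sub_h <- length(ri)
      r0 <- ((both - 1L) %% sub_h) + 1L
      c0 <- ((both - 1L) %/% sub_h) + 1L
      edge_from <- c(edge_from, rc_to_lin(ri[r0], cj[c0], h))
      edge_to <- c(edge_to, rc_to_lin(ri[r0] + di, cj[c0] + dj, h))
    }
  }

  idx_of <- integer(h * w)
  idx_of[fg] <- seq_along(fg)
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(edge_from)) {
    g <- igraph::add_edges(g, rbind(idx_of[edge_from], idx_of[edge_to]))
  }
  memb <- igraph::components(g)$membership

  # renumber components in raster (row-major) order of their first pixel
  rows <- ((fg - 1L) %% h) + 1L
  cols <- ((fg - 1L) %/% h) + 1L
  raster_rank <- (rows - 1L) * w + cols
  first_seen <- tapply(raster_rank, memb, min)
  relabel <- integer(length(first_seen))
  relabel[order(first_seen)] <- seq_along(first_seen)
  out[fg] <- relabel[memb]
  out
}

# Morphology on binary masks via a disc structuring element of the given
# radius (in pixels); radius 0 is the identity.
disc_dilate <- function(mask, radius) {
  if (radius <= 0) return(mask)
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  m <- EBImage::dilate(mask, brush)
  matrix(as.numeric(m > 0), nrow(mask), ncol(mask))
}

disc_erode <- function(mask, radius) {
  if (radius <= 0) return(mask)
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  m <- EBImage::erode(mask, brush)
  matrix(as.numeric(m > 0), nrow(mask), ncol(mask))
}

# Boundary pixels: foreground pixels 4-adjacent to background; pixels
# beyond the image border count as background, so foreground pixels on
# the border are boundary pixels.
boundary_pixels <- function(mask) {
  assert_binary_mask(mask)
  h <- nrow(mask); w <- ncol(mask)
  padded <- matrix(0, h + 2L, w + 2L)
  padded[2:(h + 1L), 2:(w + 1L)] <- mask
  core <- padded[2:(h + 1L), 2:(w + 1L)]
  up    <- padded[1:h, 2:(w + 1L)]
  down  <- padded[3:(h + 2L), 2:(w + 1L)]
  left  <- padded[2:(h + 1L), 1:w]
  right <- padded[2:(h + 1L), 3:(w + 2L)]
  (core == 1) & (up == 0 | down == 0 | left == 0 | right == 0)
}

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}
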