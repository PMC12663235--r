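# Construction of the binary pixel-labeling problem over ambiguous pixels.
#
# The objective being maximized is
#   O_idf - lambda * O_scf
# where O_idf rewards labels consistent with the per-pixel foreground
# probability P (x * P + (1 - x) * (1 - P), summed over ambiguous pixels)
# and O_scf penalizes label changes across 4-neighbor edges, each edge
# weighted by the color similarity S = exp(-||c_u - c_v||_2 / theta).
# Edges wholly inside the agreed region contribute constants and are
# dropped; edges between an ambiguous pixel and a fixed pixel are folded
# into that pixel's unary term.

#' Color similarity between two RGB pixels
#'
#' `exp(-||c1 - c2||_2 / theta)` with the Euclidean norm over the three
#' channels. Equal colors give 1; the similarity decays with the color
#' distance on the scale set by `theta` (25 by default throughout the
#' package, meaningful on the raw 8-bit intensity scale).
#'
#' @param c1,c2 length-3 RGB vectors (or n x 3 matrices, paired by row).
#' @param theta positive similarity scale.
#' @return similarity value(s) in `(0, 1]`.
#' @export
color_similarity <- function(c1, c2, theta = 25) {
  if (theta <= 0) abort("`theta` must be positive.")
  if (is.null(dim(c1))) c1 <- matrix(c1, 1L)
  if (is.null(dim(c2))) c2 <- matrix(c2, 1L)
  d <- sqrt(rowSums((c1 - c2)^2))
  exp(-d / theta)
}

#' Build the pixel labeling problem over ambiguous pixels
#'
#' Creates one binary variable per ambiguous pixel (1 = foreground) with
#' unary gains `(P, 1-P)`, and one edge per 4-neighbor pair (down and
#' right) where at least one endpoint is ambiguous. Edges between two
#' ambiguous pixels become free edges with weight `S`; edges to a fixed
#' (F or B) neighbor are folded into the ambiguous pixel's unary term as
#' a penalty `lambda * S` paid when its label differs from the fixed
#' neighbor's label.
#'
#' @param image H x W x 3 RGB array (0-255).
#' @param partition an `ambiguity_partition`.
#' @param pmap a `probability_map` (or an H x W probability matrix).
#' @param lambda non-negative smoothness trade-off (default 2).
#' @param theta positive color-similarity scale (default 25).
#' @return an object of class `pixel_labeling_problem`.
#' @export
build_problem <- function(image, partition, pmap, lambda = 2, theta = 25) {
  assert_rgb_image(image)
  if (lambda < 0) abort("`lambda` must be non-negative.")
  if (theta <= 0) abort("`theta` must be positive.")
  p_mat <- if (inherits(pmap, "probability_map")) pmap$p else pmap
  h <- dim(image)[1]; w <- dim(image)[2]
  if (h != partition$height || w != partition$width) {
    abort("image and partition dimensions must agree.")
  }
  assert_same_shape(p_mat, partition$a, "pmap", "partition")

  a_lin <- which(partition$a)
  rows <- ((a_lin - 1L) %% h) + 1L
  cols <- ((a_lin - 1L) %/% h) + 1L
  # raster (row-major) variable ordering
  ord <- order(rows, cols)
  a_lin <- a_lin[ord]; rows <- rows[ord]; cols <- cols[ord]
  n <- length(a_lin)

  var_of <- matrix(0L, h, w)
  var_of[a_lin] <- seq_len(n)
  fixed_label <- matrix(NA_real_, h, w)
  fixed_label[partition$f] <- 1
  fixed_label[partition$b] <- 0

  p_amb <- p_mat[a_lin]
  gain1 <- p_amb
  gain0 <- 1 - p_amb
  channels <- matrix(image, h * w, 3L)

  edge_u <- integer(0); edge_v <- integer(0); edge_s <- numeric(0)
  edge_orient <- character(0)
  fold_var <- integer(0); fold_s <- numeric(0); fold_lab <- numeric(0)

  collect <- function(lin_a, lin_b, orient) {
    va <- var_of[lin_a]; vb <- var_of[lin_b]
    s <- color_similarity(channels[lin_a, , drop = FALSE],
                          channels[lin_b, , drop = FALSE], theta)
    both <- va > 0L & vb > 0L
    if (any(both)) {
      edge_u <<- c(edge_u, va[both]); edge_v <<- c(edge_v, vb[both])
      edge_s <<- c(edge_s, s[both])
      edge_orient <<- c(edge_orient, rep(orient, sum(both)))
    }
    a_only <- va > 0L & vb == 0L
    if (any(a_only)) {
      fold_var <<- c(fold_var, va[a_only]); fold_s <<- c(fold_s, s[a_only])
      fold_lab <<- c(fold_lab, fixed_label[lin_b][a_only])
    }
    b_only <- va == 0L & vb > 0L
    if (any(b_only)) {
      fold_var <<- c(fold_var, vb[b_only]); fold_s <<- c(fold_s, s[b_only])
      fold_lab <<- c(fold_lab, fixed_label[lin_a][b_only])
    }
  }

  if (h > 1L) {
    top <- rc_to_lin(rep(1:(h - 1L), w), rep(1:w, each = h - 1L), h)
    collect(top, top + 1L, "vertical")
  }
  if (w > 1L) {
    left <- rc_to_lin(rep(1:h, w - 1L), rep(1:(w - 1L), each = h), h)
    collect(left, left + h, "horizontal")
  }

  structure(
    list(
      n = n, rows = rows, cols = cols, lin = a_lin,
      height = h, width = w,
      p = p_amb, gain1 = gain1, gain0 = gain0,
      edges = tibble(u = edge_u, v = edge_v, s = edge_s,
                     orientation = edge_orient),
      folded = tibble(var = fold_var, s = fold_s, fixed_label = fold_lab),
      lambda = lambda, theta = theta
    ),
    class = "pixel_labeling_problem"
  )
}

#' @export
print.pixel_labeling_problem <- function(x, ...) {
  cat(sprintf(
    "<pixel_labeling_problem> %d variable(s), %d free edge(s), %d folded term(s); lambda = %g, theta = %g\n",
    x$n, nrow(x$edges), nrow(x$folded), x$lambda, x$theta
  ))
  invisible(x)
}

# Objective components for a given 0/1 labeling of the ambiguous pixels.
# o_scf includes both free edges and folded ambiguous-fixed edges so the
# reported objective is comparable across solvers.
objective_components <- function(prob, labels) {
  stopifnot(length(labels) == prob$n)
  o_idf <- sum(ifelse(labels == 1, prob$gain1, prob$gain0))
  cut_free <- 0
  if (nrow(prob$edges) > 0L) {
    cut_free <- sum(prob$edges$s[labels[prob$edges$u] != labels[prob$edges$v]])
  }
  cut_fold <- 0
  if (nrow(prob$folded) > 0L) {
    cut_fold <- sum(prob$folded$s[labels[prob$folded$var] != prob$folded$fixed_label])
  }
  o_scf <- cut_free + cut_fold
  list(o_idf = o_idf, o_scf = o_scf,
       objective = o_idf - prob$lambda * o_scf)
}

#' Recompute the objective of a labeling
#'
#' Evaluates `O_idf - lambda * O_scf` (including folded ambiguous-fixed
#' edge terms) for an explicit 0/1 labeling of the problem's ambiguous
#' pixels. Used to verify solver output.
#'
#' @param prob a `pixel_labeling_problem`.
#' @param labels integer 0/1 vector, one entry per ambiguous pixel.
#' @return the objective value (numeric scalar).
#' @export
labeling_objective <- function(prob, labels) {
  objective_components(prob, labels)$objective
}
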