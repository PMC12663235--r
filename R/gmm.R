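# Patch-local Gaussian mixture intensity model.
#
# Foreground and background RGB intensity distributions are modeled per
# patch as full-covariance Gaussian mixtures fitted by EM on the
# unambiguous pixels only; the two densities are normalized against each
# other to give each pixel a foreground probability.

COV_FLOOR <- 1e-3
EM_MAX_ITER <- 200L
EM_REL_TOL <- 1e-4

# log N(x; mu, Sigma) for all rows of X, via Cholesky
log_dmvnorm <- function(X, mu, sigma) {
  R <- chol(sigma)
  logdet <- 2 * sum(log(diag(R)))
  Z <- sweep(X, 2, mu)
  quad <- rowSums((Z %*% chol2inv(R)) * Z)
  -1.5 * log(2 * pi) - 0.5 * logdet - 0.5 * quad
}

# k-means++-style seeded choice of initial centers
kmeanspp_centers <- function(X, n_centers) {
  n <- nrow(X)
  centers <- matrix(0, n_centers, ncol(X))
  first <- sample.int(n, 1L)
  centers[1L, ] <- X[first, ]
  if (n_centers > 1L) {
    d2 <- rowSums(sweep(X, 2, centers[1L, ])^2)
    for (k in 2:n_centers) {
      if (sum(d2) <= 0) {
        pick <- sample.int(n, 1L)
      } else {
        pick <- sample.int(n, 1L, prob = d2)
      }
      centers[k, ] <- X[pick, ]
      d2 <- pmin(d2, rowSums(sweep(X, 2, centers[k, ])^2))
    }
  }
  centers
}

#' Fit a Gaussian mixture to RGB pixels by EM
#'
#' Fits an N-component full-covariance 3-dimensional Gaussian mixture to a
#' set of RGB pixels with seeded k-means++-style initialization followed by
#' EM. A small floor (`1e-3`) is added to covariance diagonals so nearly
#' constant-color pixel sets remain well-posed. If the pixels contain fewer
#' distinct colors than `n_components`, the component count is reduced
#' accordingly (down to 1). The fit is deterministic given the seed.
#'
#' @param pixels numeric n x 3 matrix of RGB values (0-255 scale).
#' @param n_components number of mixture components N.
#' @param seed integer seed for the initialization stream.
#' @return an object of class `maskrec_gmm`: list with `n_components`,
#'   `weights`, `means` (N x 3), `covariances` (3 x 3 x N).
#' @export
fit_gmm <- function(pixels, n_components = 2L, seed = 0L) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) == 0L) {
    abort("`pixels` is empty; the caller must use its fallback model.",
          class = "maskrec_empty_pixels")
  }
  if (ncol(pixels) != 3L) abort("`pixels` must have 3 columns (RGB).")
  storage.mode(pixels) <- "double"

  n_distinct <- nrow(unique(pixels))
  n_comp <- max(1L, min(as.integer(n_components), n_distinct))

  if (n_comp == 1L) {
    mu <- colMeans(pixels)
    Z <- sweep(pixels, 2, mu)
    sigma <- crossprod(Z) / nrow(Z) + diag(COV_FLOOR, 3)
    return(new_gmm(1L, 1, matrix(mu, 1, 3), array(sigma, c(3, 3, 1))))
  }

  with_seed(seed, {
    centers <- kmeanspp_centers(pixels, n_comp)
    # hard-assignment warm start
    d2 <- sapply(seq_len(n_comp), function(k) {
      rowSums(sweep(pixels, 2, centers[k, ])^2)
    })
    assign0 <- max.col(-d2, ties.method = "first")

    w <- numeric(n_comp); mu <- matrix(0, n_comp, 3)
    sig <- array(0, c(3, 3, n_comp))
    for (k in seq_len(n_comp)) {
      sel <- pixels[assign0 == k, , drop = FALSE]
      if (nrow(sel) == 0L) sel <- centers[k, , drop = FALSE]
      w[k] <- max(nrow(sel), 1) / nrow(pixels)
      mu[k, ] <- colMeans(sel)
      Z <- sweep(sel, 2, mu[k, ])
      sig[, , k] <- crossprod(Z) / max(nrow(Z), 1) + diag(COV_FLOOR, 3)
    }
    w <- w / sum(w)

    ll_prev <- -Inf
    for (iter in seq_len(EM_MAX_ITER)) {
      logp <- sapply(seq_len(n_comp), function(k) {
        log(w[k]) + log_dmvnorm(pixels, mu[k, ], sig[, , k])
      })
      if (n_comp == 1L) logp <- matrix(logp, ncol = 1L)
      mx <- apply(logp, 1, max)
      lse <- mx + log(rowSums(exp(logp - mx)))
      ll <- sum(lse)
      resp <- exp(logp - lse)

      nk <- colSums(resp)
      nk <- pmax(nk, 1e-10)
      w <- nk / sum(nk)
      for (k in seq_len(n_comp)) {
        mu[k, ] <- colSums(pixels * resp[, k]) / nk[k]
        Z <- sweep(pixels, 2, mu[k, ])
        sig[, , k] <- crossprod(Z * sqrt(resp[, k]), Z * sqrt(resp[, k])) / nk[k] +
          diag(COV_FLOOR, 3)
      }
      if (is.finite(ll_prev) &&
          abs(ll - ll_prev) / (abs(ll_prev) + 1e-12) < EM_REL_TOL) break
      ll_prev <- ll
    }
    new_gmm(n_comp, w, mu, sig)
  })
}

new_gmm <- function(n_components, weights, means, covariances) {
  structure(
    list(n_components = n_components, weights = as.numeric(weights),
         means = means, covariances = covariances),
    class = "maskrec_gmm"
  )
}

#' @export
print.maskrec_gmm <- function(x, ...) {
  cat(sprintf("<maskrec_gmm> %d component(s); weights: %s\n",
              x$n_components, paste(signif(x$weights, 3), collapse = ", ")))
  invisible(x)
}

#' Mixture likelihood density of RGB pixels
#'
#' Evaluates the Gaussian-mixture likelihood density
#' \deqn{p'(c) = \sum_n w_n (2\pi)^{-3/2} |\Sigma_n|^{-1/2}
#'   \exp(-\tfrac12 (c-\mu_n)^T \Sigma_n^{-1} (c-\mu_n))}
#' at one or more RGB colors.
#'
#' @param colors a length-3 RGB vector or an n x 3 matrix of colors.
#' @param gmm a `maskrec_gmm` object.
#' @return numeric vector of non-negative densities, one per color.
#' @export
gmm_density <- function(colors, gmm) {
  if (is.null(dim(colors))) colors <- matrix(colors, 1L)
  colors <- as.matrix(colors)
  storage.mode(colors) <- "double"
  dens <- numeric(nrow(colors))
  for (k in seq_len(gmm$n_components)) {
    sigma <- gmm$covariances[, , k]
    R <- tryCatch(chol(sigma), error = function(e) {
      abort("Singular covariance in mixture component; refit with the covariance floor.")
    })
    dens <- dens + gmm$weights[k] * exp(log_dmvnorm(colors, gmm$means[k, ], sigma))
  }
  dens
}

#' Normalized foreground probability of RGB pixels
#'
#' Normalizes the foreground mixture density against the background one:
#' `p = p'(c | G_f) / (p'(c | G_f) + p'(c | G_b))`. The background
#' probability is `1 - p` by construction. If both densities underflow to
#' zero the pixel is uninformative and 0.5 is returned.
#'
#' @param colors length-3 RGB vector or n x 3 matrix.
#' @param gmm_fg,gmm_bg foreground and background `maskrec_gmm` models.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
foreground_probability <- function(colors, gmm_fg, gmm_bg) {
  pf <- gmm_density(colors, gmm_fg)
  pb <- gmm_density(colors, gmm_bg)
  tot <- pf + pb
  p <- ifelse(tot > 0, pf / tot, 0.5)
  pmin(pmax(p, 0), 1)
}

#' Build the merged per-pixel foreground probability map
#'
#' For each patch of the grid, fits a foreground mixture on the patch's
#' F-pixels and a background mixture on its B-pixels, then evaluates the
#' normalized foreground probability for every pixel of the patch.
#' Ambiguous pixels are excluded from fitting but do receive
#' probabilities. Patches lacking F or B pixels fall back to a pair of
#' image-level mixtures fitted on all F and all B pixels; if the whole
#' image lacks one class, those patches receive probability 0.5.
#'
#' @param image H x W x 3 RGB array (0-255 scale).
#' @param partition an `ambiguity_partition` from [partition_pixels()].
#' @param grid a `patch_grid` from [make_patch_grid()].
#' @param n_components mixture components per class (default 2).
#' @param seed integer seed; per-patch fit seeds are derived from it.
#' @return an object of class `probability_map`: list with `p` (H x W
#'   matrix in `[0,1]`) and `provenance` (per-patch `"fitted"` or
#'   `"fallback"` status).
#' @export
build_probability_map <- function(image, partition, grid, n_components = 2L,
                                  seed = 0L) {
  assert_rgb_image(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  if (h != partition$height || w != partition$width ||
      h != grid$height || w != grid$width) {
    abort("image, partition and grid dimensions must agree.")
  }
  channels <- matrix(image, h * w, 3L)

  f_lin <- which(partition$f)
  b_lin <- which(partition$b)
  image_fallback <- NULL
  get_fallback <- function() {
    if (is.null(image_fallback)) {
      if (length(f_lin) == 0L || length(b_lin) == 0L) {
        image_fallback <<- list(degenerate = TRUE)
      } else {
        image_fallback <<- list(
          degenerate = FALSE,
          fg = fit_gmm(channels[f_lin, , drop = FALSE], n_components, seed),
          bg = fit_gmm(channels[b_lin, , drop = FALSE], n_components, seed)
        )
      }
    }
    image_fallback
  }

  p <- matrix(NA_real_, h, w)
  n_patch <- grid$k^2
  provenance <- character(n_patch)
  for (g in 0:(n_patch - 1L)) {
    in_patch <- grid$patch_index == g
    patch_lin <- which(in_patch)
    pf_lin <- patch_lin[partition$f[patch_lin]]
    pb_lin <- patch_lin[partition$b[patch_lin]]

    fit <- NULL
    if (length(pf_lin) > 0L && length(pb_lin) > 0L) {
      fit <- tryCatch(
        list(fg = fit_gmm(channels[pf_lin, , drop = FALSE], n_components, seed + g),
             bg = fit_gmm(channels[pb_lin, , drop = FALSE], n_components, seed + g)),
        error = function(e) NULL
      )
    }
    if (!is.null(fit)) {
      provenance[g + 1L] <- "fitted"
      p[patch_lin] <- foreground_probability(
        channels[patch_lin, , drop = FALSE], fit$fg, fit$bg)
    } else {
      provenance[g + 1L] <- "fallback"
      fb <- get_fallback()
      if (fb$degenerate) {
        p[patch_lin] <- 0.5
      } else {
        p[patch_lin] <- foreground_probability(
          channels[patch_lin, , drop = FALSE], fb$fg, fb$bg)
      }
    }
  }
  structure(
    list(p = p, provenance = provenance, k = grid$k),
    class = "probability_map"
  )
}

#' @export
print.probability_map <- function(x, ...) {
  cat(sprintf(
    "<probability_map> %d x %d, K = %d (%d/%d patches fitted)\n",
    nrow(x$p), ncol(x$p), x$k,
    sum(x$provenance == "fitted"), length(x$provenance)
  ))
  invisible(x)
}
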