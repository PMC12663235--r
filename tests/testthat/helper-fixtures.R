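# Fixtures are built in code; nothing is read from disk.

# Random labeling problem built through build_problem() on a small random
# image/mask pair, so folded ambiguous-fixed terms occur naturally.
random_problem <- function(seed, h = 3, w = 4, lambda = 2, theta = 25,
                           full_ambiguity = FALSE) {
  set.seed(seed)
  img <- array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3))
  if (full_ambiguity) {
    d <- matrix(1, h, w); s <- matrix(0, h, w)
  } else {
    repeat {
      d <- matrix(rbinom(h * w, 1, 0.5), h, w)
      s <- matrix(rbinom(h * w, 1, 0.5), h, w)
      if (any(d != s)) break
    }
  }
  part <- partition_pixels(d, s)
  p <- matrix(runif(h * w), h, w)
  build_problem(img, part, p, lambda = lambda, theta = theta)
}

random_binary_mask <- function(seed, h = 8, w = 8, p = 0.5) {
  set.seed(seed)
  matrix(rbinom(h * w, 1, p), h, w)
}

# flat-colored image helper
flat_image <- function(h, w, rgb = c(128, 128, 128)) {
  array(rep(rgb, each = h * w), c(h, w, 3))
}

# two-color image: foreground pixels (where mask == 1) get fg_rgb
two_color_image <- function(mask, fg_rgb = c(200, 200, 200),
                            bg_rgb = c(50, 50, 50)) {
  h <- nrow(mask); w <- ncol(mask)
  img <- array(0, c(h, w, 3))
  for (ch in 1:3) {
    img[, , ch] <- ifelse(mask == 1, fg_rgb[ch], bg_rgb[ch])
  }
  img
}

# draws from a two-component RGB mixture for recovery tests
draw_mixture <- function(n, mean1, mean2, sd, seed) {
  set.seed(seed)
  n1 <- rbinom(1, n, 0.5)
  rbind(
    matrix(rnorm(n1 * 3, rep(mean1, each = n1), sd), n1, 3),
    matrix(rnorm((n - n1) * 3, rep(mean2, each = n - n1), sd), n - n1, 3)
  )
}
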