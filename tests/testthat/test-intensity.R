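test_that("pixel partition matches the per-pixel definition", {
  # d = [[1,1],[0,0]], s = [[1,0],[0,1]] in (row, col) layout
  d <- matrix(c(1, 1, 0, 0), 2, 2, byrow = TRUE)
  s <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE)
  p <- partition_pixels(d, s)
  expect_equal(p$n_f, 1)
  expect_equal(p$n_b, 1)
  expect_equal(p$n_a, 2)
  expect_true(p$f[1, 1])
  expect_true(p$b[2, 1])

  same <- partition_pixels(d, d)
  expect_equal(same$n_a, 0)

  all_diff <- partition_pixels(matrix(1, 3, 3), matrix(0, 3, 3))
  expect_equal(all_diff$n_a, 9)
  expect_equal(all_diff$n_f, 0)
  expect_equal(all_diff$n_b, 0)

  expect_error(partition_pixels(matrix(1, 2, 2), matrix(1, 3, 3)), "shape|same")
  expect_error(partition_pixels(matrix(2, 2, 2), matrix(1, 2, 2)), "0/1")
})

test_that("partition completeness holds on random mask pairs", {
  for (seed in 1:20) {
    d <- random_binary_mask(seed, 7, 9)
    s <- random_binary_mask(seed + 100, 7, 9)
    p <- partition_pixels(d, s)
    expect_equal(p$n_f + p$n_b + p$n_a, 63)
    expect_false(any(p$f & p$b) || any(p$f & p$a) || any(p$b & p$a))
  }
})

test_that("patch grid covers the image with the remainder rule", {
  g <- make_patch_grid(500, 500, 5)
  sizes <- table(g$patch_index)
  expect_length(sizes, 25)
  expect_true(all(sizes == 100 * 100))

  g1 <- make_patch_grid(10, 10, 1)
  expect_true(all(g1$patch_index == 0))

  g2 <- make_patch_grid(503, 500, 5)
  b <- g2$patch_bounds
  last_row <- b[b$patch >= 20, ]
  expect_true(all(last_row$row_end - last_row$row_start + 1 == 103))
  first_rows <- b[b$patch < 20, ]
  expect_true(all(first_rows$row_end - first_rows$row_start + 1 == 100))

  expect_error(make_patch_grid(10, 10, 0))
  expect_error(make_patch_grid(10, 10, 11))
})

test_that("EM recovers degenerate and well-separated mixtures", {
  one_color <- matrix(rep(c(90, 40, 120), each = 500), 500, 3)
  g <- fit_gmm(one_color, n_components = 2, seed = 1)
  expect_equal(g$n_components, 1)
  expect_equal(as.numeric(g$means[1, ]), c(90, 40, 120), tolerance = 1e-8)

  X <- draw_mixture(1000, c(50, 50, 50), c(200, 200, 200), 5, seed = 7)
  g2 <- fit_gmm(X, n_components = 2, seed = 7)
  mu_sorted <- g2$means[order(g2$means[, 1]), ]
  expect_true(all(abs(mu_sorted[1, ] - 50) < 3))
  expect_true(all(abs(mu_sorted[2, ] - 200) < 3))
  expect_true(all(abs(g2$weights - 0.5) < 0.05))

  g3 <- fit_gmm(X, n_components = 2, seed = 7)
  expect_identical(g2, g3)

  expect_error(fit_gmm(matrix(numeric(0), 0, 3)), class = "maskrec_empty_pixels")
})

test_that("EM fits agree with an independent mixture fitter on separated data", {
  suppressMessages(library(mclust))
  X <- draw_mixture(1500, c(60, 80, 100), c(190, 170, 210), 6, seed = 3)
  ours <- fit_gmm(X, n_components = 2, seed = 3)
  ref <- Mclust(X, G = 2, modelNames = "VVV", verbose = FALSE)
  ref_means <- t(ref$parameters$mean)
  ours_sorted <- ours$means[order(ours$means[, 1]), ]
  ref_sorted <- ref_means[order(ref_means[, 1]), ]
  expect_lt(max(abs(ours_sorted - ref_sorted)), 1)
})

test_that("mixture density matches the closed form", {
  g <- maskrec:::new_gmm(1L, 1, matrix(c(1, 2, 3), 1, 3),
                         array(diag(3), c(3, 3, 1)))
  expect_equal(gmm_density(c(1, 2, 3), g), (2 * pi)^-1.5, tolerance = 1e-9)

  g0 <- maskrec:::new_gmm(1L, 1, matrix(0, 1, 3), array(diag(3), c(3, 3, 1)))
  expect_equal(gmm_density(c(1, 0, 0), g0), (2 * pi)^-1.5 * exp(-0.5),
               tolerance = 1e-9)
  expect_equal(gmm_density(c(1, 0, 0), g0), 0.038511, tolerance = 1e-4)

  # a two-component mixture with identical components collapses
  g2 <- maskrec:::new_gmm(2L, c(0.5, 0.5), matrix(0, 2, 3),
                          array(diag(3), c(3, 3, 2)))
  expect_equal(gmm_density(c(0.3, 0, 0), g2), gmm_density(c(0.3, 0, 0), g0),
               tolerance = 1e-12)
})

test_that("normalized foreground probability behaves per definition", {
  gf <- maskrec:::new_gmm(1L, 1, matrix(200, 1, 3),
                          array(diag(25, 3), c(3, 3, 1)))
  gb <- maskrec:::new_gmm(1L, 1, matrix(50, 1, 3),
                          array(diag(25, 3), c(3, 3, 1)))
  expect_gt(foreground_probability(c(200, 200, 200), gf, gb), 0.999)
  expect_equal(foreground_probability(c(125, 125, 125), gf, gb), 0.5,
               tolerance = 1e-9)
  # underflow on both sides falls back to 0.5
  far <- c(-1e6, 0, 0)
  expect_equal(foreground_probability(far, gf, gb), 0.5)
})

test_that("probability map separates classes and falls back per patch", {
  d <- matrix(0, 10, 10); d[3:5, 3:5] <- 1
  img <- two_color_image(d)
  s <- d
  s[7, 7] <- 1  # ambiguous pixel colored like foreground
  img[7, 7, ] <- c(200, 200, 200)
  part <- partition_pixels(d, s)
  grid <- make_patch_grid(10, 10, 1)
  pm <- build_probability_map(img, part, grid, n_components = 2, seed = 1)
  expect_gt(pm$p[7, 7], 0.99)
  expect_true(all(pm$p >= 0 & pm$p <= 1))

  # indistinguishable classes: the F and B color multisets are identical
  # (mask on row parity, color on column parity), so P stays near 0.5
  rows <- matrix(seq_len(10), 10, 10)
  cols <- matrix(seq_len(10), 10, 10, byrow = TRUE)
  d2 <- matrix(as.numeric(rows %% 2 == 0), 10, 10)
  img2 <- array(ifelse(cols %% 2 == 0, 136, 120), c(10, 10, 3))
  part2 <- partition_pixels(d2, d2)  # no ambiguity, everything fixed
  pm2 <- build_probability_map(img2, part2, grid, n_components = 2, seed = 1)
  expect_true(all(abs(pm2$p - 0.5) < 0.05))

  # patch with no foreground pixels uses the image-level fallback
  d3 <- matrix(0, 10, 10); d3[1:4, 1:4] <- 1
  img3 <- two_color_image(d3)
  part3 <- partition_pixels(d3, d3)
  grid2 <- make_patch_grid(10, 10, 2)
  pm3 <- build_probability_map(img3, part3, grid2, n_components = 2, seed = 1)
  expect_equal(pm3$provenance[1], "fitted")
  expect_equal(pm3$provenance[4], "fallback")  # bottom-right patch: no F pixels
  expect_lt(max(pm3$p[6:10, 6:10]), 0.01)      # fallback still classifies bg
})

test_that("swapping foreground and background roles flips the map", {
  d <- matrix(0, 12, 12); d[4:8, 4:8] <- 1
  set.seed(9)
  img <- two_color_image(d) + array(rnorm(432, 0, 5), c(12, 12, 3))
  img <- pmin(pmax(img, 0), 255)
  s <- d; s[1, 1] <- 1  # one ambiguous pixel
  part <- partition_pixels(d, s)
  part_swapped <- part
  part_swapped$f <- part$b
  part_swapped$b <- part$f
  grid <- make_patch_grid(12, 12, 2)
  pm <- build_probability_map(img, part, grid, seed = 3)
  pm_sw <- build_probability_map(img, part_swapped, grid, seed = 3)
  expect_equal(pm_sw$p, 1 - pm$p, tolerance = 1e-9)
})
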