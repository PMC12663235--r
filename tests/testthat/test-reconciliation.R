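test_that("color similarity follows the exponential-decay form", {
  expect_equal(color_similarity(c(10, 20, 30), c(10, 20, 30), 25), 1)
  expect_equal(color_similarity(c(25, 0, 0), c(0, 0, 0), 25), exp(-1),
               tolerance = 1e-9)
  expect_equal(color_similarity(c(3, 4, 0), c(0, 0, 0), 5), exp(-1),
               tolerance = 1e-9)
  expect_error(color_similarity(c(1, 1, 1), c(0, 0, 0), 0), "positive")
})

test_that("problem construction enumerates variables, edges and folded terms", {
  img <- flat_image(1, 3)
  part <- partition_pixels(matrix(1, 1, 3), matrix(0, 1, 3))
  prob <- build_problem(img, part, matrix(0.5, 1, 3), lambda = 2, theta = 25)
  expect_equal(prob$n, 3)
  expect_equal(nrow(prob$edges), 2)
  expect_equal(prob$edges$s, c(1, 1))
  expect_true(all(prob$edges$orientation == "horizontal"))

  # no ambiguity: zero variables
  same <- partition_pixels(matrix(1, 2, 2), matrix(1, 2, 2))
  prob0 <- build_problem(flat_image(2, 2), same, matrix(0.5, 2, 2))
  expect_equal(prob0$n, 0)
  expect_equal(nrow(prob0$edges), 0)

  # one ambiguous corner of a 2x2: both its 4-neighbor edges fold
  d <- matrix(c(1, 1, 1, 1), 2, 2); s <- matrix(c(0, 1, 1, 1), 2, 2)
  part2 <- partition_pixels(d, s)  # (1,1) ambiguous, rest F
  prob2 <- build_problem(flat_image(2, 2), part2, matrix(0.9, 2, 2))
  expect_equal(prob2$n, 1)
  expect_equal(nrow(prob2$edges), 0)
  expect_equal(nrow(prob2$folded), 2)
  expect_true(all(prob2$folded$fixed_label == 1))
})

test_that("brute force reproduces hand-enumerated optima", {
  img <- flat_image(1, 3)
  part <- partition_pixels(matrix(1, 1, 3), matrix(0, 1, 3))

  prob <- build_problem(img, part, matrix(c(0.9, 0.5, 0.9), 1, 3), lambda = 2)
  lab <- solve_bruteforce(prob)
  expect_equal(lab$labels, c(1L, 1L, 1L))
  expect_equal(lab$objective_value, 2.3, tolerance = 1e-9)
  # the alternative (1,0,1) pays both cut edges: 2.3 - 4.0
  expect_equal(labeling_objective(prob, c(1, 0, 1)), 2.3 - 4.0,
               tolerance = 1e-9)

  prob0 <- build_problem(img, part, matrix(c(0.9, 0.4, 0.9), 1, 3), lambda = 0)
  lab0 <- solve_bruteforce(prob0)
  expect_equal(lab0$labels, c(1L, 0L, 1L))
  expect_equal(lab0$objective_value, 2.4, tolerance = 1e-9)

  empty <- build_problem(img, partition_pixels(matrix(0, 1, 3), matrix(0, 1, 3)),
                         matrix(0.5, 1, 3))
  expect_equal(solve_bruteforce(empty)$objective_value, 0)
  expect_length(solve_bruteforce(empty)$labels, 0)
})

test_that("brute-force ties prefer the background-first labeling", {
  img <- flat_image(1, 2)
  part <- partition_pixels(matrix(1, 1, 2), matrix(0, 1, 2))
  prob <- build_problem(img, part, matrix(0.5, 1, 2), lambda = 0)
  expect_equal(solve_bruteforce(prob)$labels, c(0L, 0L))
})

test_that("all three solvers agree with the brute-force oracle", {
  lambdas <- c(0, 0.5, 2, 5); thetas <- c(5, 25)
  probs <- list(); k <- 0
  for (seed in 1:25) {
    for (lam in lambdas) {
      k <- k + 1
      probs[[k]] <- random_problem(seed * 13 + lam, lambda = lam,
                                   theta = thetas[seed %% 2 + 1])
    }
  }
  ilp <- solve_ilp_batch(probs)
  for (i in seq_along(probs)) {
    bf <- solve_bruteforce(probs[[i]])
    mf <- solve_maxflow(probs[[i]])
    expect_equal(mf$objective_value, bf$objective_value, tolerance = 1e-6)
    expect_equal(ilp[[i]]$objective_value, bf$objective_value, tolerance = 1e-6)
    # objective recomputable from the returned labels
    expect_equal(labeling_objective(probs[[i]], mf$labels),
                 mf$objective_value, tolerance = 1e-9)
  }
})

test_that("ILP and min-cut agree on larger full-ambiguity instances", {
  probs <- lapply(1:10, function(s) {
    random_problem(s, h = 16, w = 16, lambda = 2, theta = 25,
                   full_ambiguity = TRUE)
  })
  ilp <- solve_ilp_batch(probs)
  for (i in seq_along(probs)) {
    mf <- solve_maxflow(probs[[i]])
    expect_equal(ilp[[i]]$objective_value, mf$objective_value,
                 tolerance = 1e-6)
  }
})

test_that("lambda = 0 reduces every solver to probability thresholding", {
  for (seed in 1:5) {
    prob <- random_problem(seed, h = 4, w = 4, lambda = 0)
    want <- as.integer(prob$p > 0.5)  # ties to background
    expect_equal(solve_bruteforce(prob)$labels, want)
    expect_equal(solve_maxflow(prob)$labels, want)
    expect_equal(solve_ilp(prob)$labels, want)
  }
  # explicit tie at P = 0.5
  img <- flat_image(1, 2)
  part <- partition_pixels(matrix(1, 1, 2), matrix(0, 1, 2))
  prob <- build_problem(img, part, matrix(c(0.5, 0.8), 1, 2), lambda = 0)
  expect_equal(solve_maxflow(prob)$labels, c(0L, 1L))
})

test_that("optimal boundary cost is non-increasing in lambda", {
  for (seed in 1:6) {
    scf <- vapply(c(0, 0.5, 1, 2, 5), function(lam) {
      solve_maxflow(random_problem(seed, h = 5, w = 5, lambda = lam))$o_scf
    }, numeric(1))
    expect_true(all(diff(scf) <= 1e-9))
  }
})

test_that("theta limits recover all-similar and threshold behavior", {
  set.seed(42)
  img <- array(sample(0:255, 5 * 5 * 3, replace = TRUE), c(5, 5, 3))
  part <- partition_pixels(matrix(1, 5, 5), matrix(0, 5, 5))
  p <- matrix(runif(25), 5, 5)

  big <- build_problem(img, part, p, lambda = 2, theta = 1e9)
  expect_true(all(big$edges$s > 0.999))

  tiny <- build_problem(img, part, p, lambda = 2, theta = 1e-6)
  expect_true(all(tiny$edges$s < 1e-9))
  want <- as.integer(tiny$p > 0.5)
  expect_equal(solve_maxflow(tiny)$labels, want)
})

test_that("dominant unaries override smoothness", {
  img <- flat_image(4, 4)
  part <- partition_pixels(matrix(1, 4, 4), matrix(0, 4, 4))
  prob <- build_problem(img, part, matrix(1, 4, 4), lambda = 5)
  expect_true(all(solve_maxflow(prob)$labels == 1L))
})

test_that("reconcile preserves agreed pixels and short-circuits on agreement", {
  scene <- generate_scene(synthetic_spec(height = 48, width = 48,
                                         n_cells = 4, seed = 2))
  m <- reconcile(scene$image, scene$mask_d, scene$mask_s, grid_k = 3)
  part <- partition_pixels(scene$mask_d, scene$mask_s)
  expect_true(all(m[part$f] == 1))
  expect_true(all(m[part$b] == 0))

  same <- reconcile(scene$image, scene$mask_d, scene$mask_d)
  expect_equal(unclass(same), scene$mask_d, ignore_attr = TRUE)
  expect_equal(attr(same, "info")$n_ambiguous, 0L)
})

test_that("solved labelings tidy and glance into well-formed tibbles", {
  prob <- random_problem(3, lambda = 2)
  lab <- solve_maxflow(prob)
  td <- tidy(lab)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("row", "col", "p", "label"))
  expect_equal(nrow(td), prob$n)
  gl <- glance(lab)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$solver_name, "maxflow")
  expect_equal(gl$objective_value, lab$objective_value)
})
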