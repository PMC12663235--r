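test_that("small-object removal keeps the boundary case", {
  m <- matrix(0, 10, 10)
  m[2:5, 2:6] <- 1            # 20-pixel component
  expect_equal(remove_small_objects(m, 20), m)

  m19 <- m; m19[5, 6] <- 0    # 19 pixels
  expect_true(all(remove_small_objects(m19, 20) == 0))
  expect_equal(remove_small_objects(m19, 0), m19)

  # mixed sizes: only the small blob goes
  m2 <- m; m2[8, 8] <- 1
  out <- remove_small_objects(m2, 20)
  expect_equal(out[8, 8], 0)
  expect_equal(out[2:5, 2:6], m[2:5, 2:6])
})

test_that("connected-component labeling is 8-connected and raster-ordered", {
  m <- matrix(0, 5, 5)
  m[1, 1] <- 1; m[2, 2] <- 1  # diagonal touch: one component
  lab <- label_components(m)
  expect_equal(max(lab), 1)

  m2 <- matrix(0, 5, 7)
  m2[1:2, 1:2] <- 1; m2[4:5, 5:6] <- 1
  lab2 <- instances_by_connected_components(m2)
  expect_equal(sort(unique(as.vector(lab2))), c(0, 1, 2))
  expect_equal(lab2[1, 1], 1)  # raster-first component gets ID 1
  expect_equal(lab2[4, 5], 2)

  expect_equal(max(instances_by_connected_components(matrix(0, 4, 4))), 0)
  one <- matrix(0, 4, 4); one[2:3, 2:3] <- 1
  expect_equal(max(instances_by_connected_components(one)), 1)
})

test_that("watershed splits touching blobs and respects support", {
  h <- 40; w <- 60; m <- matrix(0, h, w)
  for (i in 1:h) for (j in 1:w) {
    if ((i - 20)^2 + (j - 20)^2 <= 100 || (i - 20)^2 + (j - 37)^2 <= 100) m[i, j] <- 1
  }
  ws <- instances_by_watershed(m)
  expect_equal(max(ws), 2)
  expect_equal((ws > 0) + 0, m)

  convex <- matrix(0, 20, 20); convex[5:15, 5:15] <- 1
  expect_equal(max(instances_by_watershed(convex)), 1)
  expect_equal(max(instances_by_watershed(matrix(0, 5, 5))), 0)
})

test_that("detector-guided conversion transfers, splits and mints IDs", {
  # component equal to detector instance 3 inherits the ID
  sem <- matrix(0, 12, 12); sem[2:4, 2:4] <- 1
  itd <- matrix(0L, 12, 12); itd[2:4, 2:4] <- 3L
  boxes <- tibble::tibble(x_min = 1L, y_min = 1L, x_max = 3L, y_max = 3L,
                          instance_id = 3L)
  out <- convert_to_instances(sem, itd, boxes)
  expect_true(all(out[sem == 1] == 3))

  # component with no detector overlap gets a fresh ID above all existing
  sem2 <- sem; sem2[9:10, 9:10] <- 1
  itd2 <- itd; itd2[6, 6] <- 7L
  sem2[6, 6] <- 1
  out2 <- convert_to_instances(sem2, itd2, boxes)
  expect_true(all(out2[9:10, 9:10] == 8))

  # dumbbell over detector instances 1 and 2: lobes split by k-means
  dumb <- matrix(0, 9, 21)
  dumb[3:7, 2:8] <- 1; dumb[3:7, 14:20] <- 1; dumb[5, 9:13] <- 1
  itd3 <- matrix(0L, 9, 21)
  itd3[4:6, 3:7] <- 1L; itd3[4:6, 15:19] <- 2L
  boxes3 <- tibble::tibble(
    x_min = c(2L, 14L), y_min = c(3L, 3L), x_max = c(6L, 18L),
    y_max = c(5L, 5L), instance_id = c(1L, 2L)
  )
  out3 <- convert_to_instances(dumb, itd3, boxes3)
  expect_true(all(out3[3:7, 2:8] == 1))
  expect_true(all(out3[3:7, 14:20] == 2))
  # no pixel gained or lost
  expect_equal((out3 > 0) + 0, dumb)

  # determinism
  expect_identical(out3, convert_to_instances(dumb, itd3, boxes3))
})

test_that("conversion falls back to centroids when a box is missing", {
  dumb <- matrix(0, 7, 15)
  dumb[2:6, 2:6] <- 1; dumb[2:6, 10:14] <- 1; dumb[4, 7:9] <- 1
  itd <- matrix(0L, 7, 15)
  itd[3:5, 3:5] <- 1L; itd[3:5, 11:13] <- 2L
  boxes <- tibble::tibble(x_min = 2L, y_min = 2L, x_max = 4L, y_max = 4L,
                          instance_id = 1L)  # no box for instance 2
  expect_message(out <- convert_to_instances(dumb, itd, boxes), "centroid")
  expect_true(all(out[2:6, 2:6] == 1))
  expect_true(all(out[2:6, 10:14] == 2))
})

test_that("conversion preserves foreground and never reuses detector IDs", {
  sc <- generate_scene(synthetic_spec(seed = 5))
  rec <- reconcile(sc$image, sc$mask_d, sc$mask_s)
  rec <- remove_small_objects(rec, 20)
  inst <- convert_to_instances(rec, sc$itd_instances, sc$boxes)
  expect_equal((inst > 0) + 0, unclass(rec), ignore_attr = TRUE)
  det_ids <- setdiff(unique(as.vector(sc$itd_instances)), 0L)
  out_ids <- setdiff(unique(as.vector(inst)), 0L)
  fresh <- setdiff(out_ids, det_ids)
  expect_true(all(fresh > max(det_ids)))
})
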