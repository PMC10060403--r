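disc_image <- function(h, w, centers, radius, value = 1) {
  img <- matrix(0, h, w)
  for (k in seq_len(nrow(centers)))
    img <- gridspot:::paint_disc(img, centers[k, 1], centers[k, 2],
                                 radius, value)$image
  img
}

test_that("classical distance-map predictor matches EDT expectations", {
  img <- disc_image(41, 41, rbind(c(20, 20)), 12)
  dm <- predict_distance_map(img)
  expect_lt(abs(max(dm) - 12), 1)
  expect_equal(which.max(dm), which(row(dm) == 21 & col(dm) == 21))
  expect_true(all(predict_distance_map(matrix(0, 9, 9)) == 0))
  # EDT locality: two disjoint discs each equal their single-disc map
  two <- disc_image(41, 81, rbind(c(20, 20), c(60, 20)), 10)
  one <- disc_image(41, 81, rbind(c(20, 20)), 10)
  dm2 <- predict_distance_map(two)
  dm1 <- predict_distance_map(one)
  left <- one > 0.5
  expect_equal(dm2[left], dm1[left])
  # external predictor contract
  expect_error(predict_distance_map(img, external = matrix(0, 2, 2)),
               "shape mismatch")
  neg <- matrix(0, 41, 41); neg[1, 1] <- -1
  expect_error(predict_distance_map(img, external = neg), "negative")
})

test_that("seeded watershed separates objects deterministically", {
  two <- disc_image(41, 81, rbind(c(20, 20), c(60, 20)), 10)
  inst <- watershed_instances(predict_distance_map(two))
  expect_equal(max(inst), 2)
  areas <- tabulate(inst[inst > 0])
  planted <- sum(disc_image(41, 81, rbind(c(20, 20)), 10) > 0.5)
  expect_true(all(abs(areas - planted) / planted <= 0.02))
  # dumbbell: overlapping discs split along the neck
  dumb <- disc_image(41, 61, rbind(c(22, 20), c(38, 20)), 10)
  dinst <- watershed_instances(predict_distance_map(dumb), h = 1,
                               min_seed_distance = 3)
  expect_equal(max(dinst), 2)
  # area conservation: labeled pixels == foreground of the distance map
  dm <- predict_distance_map(dumb)
  expect_equal(sum(dinst > 0), sum(dm > 0))
  expect_equal(max(watershed_instances(matrix(0, 10, 10))), 0)
  expect_error(watershed_instances(dm, h = 0), "h must be")
})

test_that("planted cell counts are recovered exactly over seeds", {
  for (seed in 1:10) {
    sc <- generate_cell_scene(scene_spec(
      rows = 1, cols = 2, pitch_x = 90, pitch_y = 90, spot_radius = 35,
      cells_per_spot = 12, alive_fraction = 0.5, noise_sigma = 0,
      seed = seed))
    for (ch in c("hoechst", "calcein", "pi")) {
      planted <- max(sc$truth_instances[[ch]])
      got <- max(segment_instances(sc$images[[ch]])$instances)
      expect_equal(got, planted,
                   label = sprintf("seed %d channel %s count", seed, ch))
    }
  }
})

test_that("semantic argmax equals the per-pixel brute force", {
  expect_true(all(semantic_argmax(list(matrix(0.2, 4, 4),
                                       matrix(0.8, 4, 4))) == 2))
  # one-hot stack recovers the encoded labels
  set.seed(8)
  enc <- matrix(sample(1:3, 36, TRUE), 6, 6)
  stack <- lapply(1:3, function(k) (enc == k) * 1)
  expect_equal(semantic_argmax(stack), enc)
  # random stack vs. nested-loop argmax with lowest-index ties
  stack <- lapply(1:4, function(k) matrix(sample(seq(0, 1, 0.25), 30, TRUE),
                                          5, 6))
  got <- semantic_argmax(stack)
  for (y in 1:5) for (x in 1:6) {
    v <- vapply(stack, function(s) s[y, x], numeric(1))
    expect_equal(got[y, x], which.max(v))
  }
  expect_error(semantic_argmax(list(matrix(0, 2, 2), matrix(0, 3, 3))),
               "shape mismatch")
  expect_error(semantic_argmax(list(matrix(0, 2, 2))), "at least 2")
})

# Printed feature-table rows (ID, major, minor, eccentricity): the
# eccentricity definition must close over all eight rows to 3 decimals.
table2 <- data.frame(
  id = 1:8,
  major = c(19.394, 20.482, 20.16, 20.054, 18.496, 22.767, 22.412, 21.018),
  minor = c(10.683, 19.893, 19.206, 18.81, 16.962, 9.835, 20.735, 18.486),
  ecc = c(0.835, 0.238, 0.304, 0.347, 0.399, 0.902, 0.38, 0.476))

test_that("eccentricity_from_axes closes over the printed feature table", {
  got <- eccentricity_from_axes(table2$major, table2$minor)
  expect_equal(round(got, 3), table2$ecc)
  expect_equal(eccentricity_from_axes(7, 7), 0)
  expect_error(eccentricity_from_axes(5, 6), "minor")
  expect_error(eccentricity_from_axes(5, 0), "positive")
})

test_that("extract_features measures moment-ellipse geometry", {
  img <- disc_image(61, 61, rbind(c(30, 30)), 14)
  inst <- matrix(0L, 61, 61); inst[img > 0.5] <- 1L
  f <- extract_features(inst, img * 0.5)
  expect_equal(f$area, sum(img > 0.5))
  expect_equal(c(f$x, f$y), c(30, 30), tolerance = 1e-9)
  expect_equal(f$mean_intensity, 0.5)
  expect_lte(f$eccentricity, 0.05)
  expect_lt(abs(f$major_axis - 28) / 28, 0.03)
  expect_lt(abs(f$minor_axis - 28) / 28, 0.03)
  expect_equal(f$eccentricity,
               eccentricity_from_axes(f$major_axis, f$minor_axis),
               tolerance = 1e-6)
  # label-permutation invariance: swapped labels, same value multiset
  two <- disc_image(41, 81, rbind(c(20, 20), c(60, 22)), c(8))
  inst2 <- gridspot:::cpp_label4(two > 0.5)
  swap <- inst2
  swap[inst2 == 1L] <- 2L; swap[inst2 == 2L] <- 1L
  f1 <- extract_features(inst2, two)
  f2 <- extract_features(swap, two)
  expect_equal(f1[order(f1$x), -1], f2[order(f2$x), -1],
               ignore_attr = TRUE)
  expect_equal(nrow(extract_features(matrix(0L, 4, 4))), 0)
})
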