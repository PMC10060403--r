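test_that("preprocess rescales by percentiles and handles degenerate input", {
  m <- matrix(c(rep(0, 50), rep(1, 50)) * 65535, 10, 10) / 65535
  out <- preprocess(m, 1, 99)
  expect_setequal(unique(as.vector(out)), c(0, 1))
  # RGB with equal channels equals the single channel after rescale
  ch <- matrix(seq(0, 1, length.out = 100), 10, 10)
  rgb <- array(rep(ch, 3), c(10, 10, 3))
  expect_equal(preprocess(rgb, 0, 100), preprocess(ch, 0, 100),
               tolerance = 1e-12)
  # ramp 0..255 with p = (0, 100) maps to an exact 0..1 ramp
  ramp <- matrix(0:255, 16, 16) / 255
  expect_equal(preprocess(ramp, 0, 100), (ramp - min(ramp)) / diff(range(ramp)),
               tolerance = 1e-6)
  expect_warning(z <- preprocess(matrix(0.3, 5, 5)), "constant")
  expect_true(all(z == 0))
  expect_error(preprocess(ramp, 50, 10), "p_low")
})

test_that("segment_elements recovers planted discs and honors contracts", {
  sc <- generate_grid_scene(small_grid_spec())
  img <- preprocess(sc$images$grid, 0, 100)
  mask <- segment_elements(img, "otsu")
  truth <- sc$truth_instances$grid > 0
  jac <- sum(mask & truth) / sum(mask | truth)
  expect_gte(jac, 0.99)
  expect_false(any(segment_elements(matrix(0, 8, 8), "otsu")))
  # percentile method: ~10% foreground for 10% bright pixels
  set.seed(4)
  v <- c(runif(900, 0, 0.4), runif(100, 0.8, 1))
  m <- matrix(sample(v), 25, 40)
  frac <- mean(segment_elements(m, "percentile", q = 90))
  expect_lt(abs(frac - 0.10), 0.01)
  expect_error(segment_elements(img, "scores", scores = matrix(0, 2, 2)),
               "expected")
})

test_that("postprocess_elements filters specks and merged components", {
  base <- matrix(0, 80, 200)
  # 22 singles + speck noise
  cx <- seq(15, 190, length.out = 11)
  img <- base
  for (x in cx) for (y in c(20, 60))
    img <- gridspot:::paint_disc(img, x, y, 6, 1)$image
  mask <- img > 0.5
  specks <- mask
  set.seed(1)
  for (k in 1:5) specks[sample(80, 1), sample(200, 1)] <- TRUE
  el <- postprocess_elements(specks, open_radius = 1, area_band = c(0.3, 3))
  expect_equal(nrow(el$centroids), 22)
  # a merged double-area component is removed by a (0.3, 1.5) band
  merged <- gridspot:::paint_disc(img, 100, 40, 6, 1)$image
  merged <- gridspot:::paint_disc(merged, 109, 40, 6, 1)$image  # touching pair
  el2 <- postprocess_elements(merged > 0.5, open_radius = 0,
                              area_band = c(0.3, 1.5))
  expect_equal(nrow(el2$centroids), 22)
  # single component survives (median = own area)
  one <- matrix(FALSE, 10, 10); one[4:6, 4:6] <- TRUE
  expect_equal(nrow(postprocess_elements(one, 0)$centroids), 1)
  expect_error(postprocess_elements(matrix(FALSE, 5, 5)), "failed")
})

lattice_points <- function(rows, cols, pitch, rot_deg) {
  g <- expand.grid(j = 0:(cols - 1), i = 0:(rows - 1))
  th <- rot_deg * pi / 180
  data.frame(x = cos(th) * g$j * pitch - sin(th) * g$i * pitch,
             y = sin(th) * g$j * pitch + cos(th) * g$i * pitch)
}

test_that("estimate_rotation folds neighbor angles into (-45, 45]", {
  expect_lt(abs(estimate_rotation(lattice_points(4, 6, 20, 0))), 1e-9)
  expect_lt(abs(estimate_rotation(lattice_points(4, 6, 20, 5)) - 5), 0.2)
  # 93 degrees is indistinguishable from 3 (mod-90 fold)
  expect_lt(abs(estimate_rotation(lattice_points(4, 6, 20, 93)) - 3), 0.2)
  # fold property on a square-pitch lattice
  r1 <- estimate_rotation(lattice_points(5, 5, 20, 17))
  r2 <- estimate_rotation(lattice_points(5, 5, 20, 17 + 90))
  expect_equal(r1, r2, tolerance = 1e-6)
  expect_error(estimate_rotation(data.frame(x = 1, y = 1)), "at least 2")
})

test_that("fit_grid recovers planted parameters", {
  sc <- generate_grid_scene(small_grid_spec())
  g <- detect_grid(sc$images$grid)
  t <- sc$truth_grid
  expect_equal(g$rows, t$rows)
  expect_equal(g$cols, t$cols)
  expect_lt(sqrt((g$origin_x - t$origin_x)^2 + (g$origin_y - t$origin_y)^2),
            0.5)
  expect_lt(abs(g$pitch_x - t$pitch_x) / t$pitch_x, 0.01)
  expect_lt(abs(g$pitch_y - t$pitch_y) / t$pitch_y, 0.01)
  expect_lt(abs(g$spot_radius - t$spot_radius) / t$spot_radius, 0.02)
})

test_that("fit_grid interpolates a missing spot under expected_shape", {
  sc <- generate_grid_scene(small_grid_spec())
  img <- sc$images$grid
  # erase one interior spot
  ctr <- grid_centers(sc$truth_grid)
  img <- gridspot:::paint_disc(img, ctr$x[9], ctr$y[9], 11, 0.1)$image
  g <- detect_grid(img, expected_shape = c(4, 6))
  expect_equal(g$rows, 4)
  expect_equal(g$cols, 6)
  expect_error(detect_grid(img, expected_shape = c(7, 9)), "irreconcilable")
})

test_that("grid pipeline is noise-robust, rotation-equivariant, idempotent", {
  base <- small_grid_spec(noise_sigma = 0.05, seed = 31)
  g0 <- detect_grid(generate_grid_scene(base)$images$grid)
  for (delta in c(-12, 7)) {
    spd <- small_grid_spec(noise_sigma = 0.05, seed = 31,
                           rotation_deg = delta)
    gd <- detect_grid(generate_grid_scene(spd)$images$grid)
    expect_lt(abs((gd$rotation_deg - g0$rotation_deg) - delta), 0.5)
    expect_lt(abs(gd$pitch_x - g0$pitch_x) / g0$pitch_x, 0.01)
    expect_lt(abs(gd$spot_radius - g0$spot_radius) / g0$spot_radius, 0.01)
  }
  sc <- generate_grid_scene(base)
  expect_identical(detect_grid(sc$images$grid), detect_grid(sc$images$grid))
})

test_that("semi_automated_grid derives parameters deterministically", {
  k <- list(rows = 4, cols = 6, rotation_deg = 0, spot_radius = 5)
  g <- semi_automated_grid(k, clicked_points = rbind(c(10, 10), c(110, 70)))
  expect_equal(g$pitch_x, 20)
  expect_equal(g$pitch_y, 20)
  expect_equal(g$origin_x, 10)
  # full model passes through unchanged
  full <- grid_model(3, 3, 5, 5, 10, 12, 2, 4)
  expect_equal(semi_automated_grid(unclass(full)), full)
  # corner points of a 5-degree rotated lattice recover the rotation
  th <- 5 * pi / 180
  p1 <- c(10, 10)
  p2 <- p1 + 100 * c(cos(th), sin(th))       # (0, cols-1)
  p3 <- p1 + 60 * c(-sin(th), cos(th))       # (rows-1, 0)
  g5 <- semi_automated_grid(list(rows = 4, cols = 6, spot_radius = 5),
                            clicked_points = rbind(p1, p2, p3))
  expect_equal(g5$rotation_deg, 5, tolerance = 1e-6)
  expect_equal(g5$pitch_x, 20, tolerance = 1e-9)
  err <- tryCatch(semi_automated_grid(list(rows = 4)), error = identity)
  expect_match(conditionMessage(err), "pitch_x")
  expect_match(conditionMessage(err), "spot_radius")
})

test_that("extract_rois orders, bounds and separates spot masks", {
  sc <- generate_grid_scene(small_grid_spec())
  img <- sc$images$grid
  rois <- extract_rois(img, sc$truth_grid)
  expect_length(rois, 24)
  expect_equal(c(rois[[1]]$i, rois[[1]]$j), c(0, 0))
  expect_equal(c(rois[[24]]$i, rois[[24]]$j), c(3, 5))
  # disjointness: paint each mask into a counter raster
  cnt <- matrix(0L, nrow(img), ncol(img))
  for (r in rois) {
    sub <- cnt[(r$y0 + 1):r$y1, (r$x0 + 1):r$x1]
    sub[r$mask] <- sub[r$mask] + 1L
    cnt[(r$y0 + 1):r$y1, (r$x0 + 1):r$x1] <- sub
  }
  expect_lte(max(cnt), 1L)
  areas <- vapply(rois, function(r) sum(r$mask), numeric(1))
  expect_lt(abs(sum(areas) - 24 * pi * 10^2) / (24 * pi * 10^2), 0.02)
  bad <- grid_model(4, 6, 500, 500, 32, 32, 0, 10)
  expect_error(extract_rois(img, bad), "outside")
})
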