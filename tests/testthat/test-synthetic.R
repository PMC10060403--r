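test_that("noise-free grid scene plants the stated discs", {
  sc <- generate_grid_scene(small_grid_spec())
  img <- sc$images$grid
  lab <- label_components_oracle(img > 0.5)
  expect_equal(max(lab), 24)
  areas <- tabulate(lab[lab > 0])
  expect_true(all(abs(areas - pi * 10^2) / (pi * 10^2) <= 0.02))
  # planted centers inside bounds
  ctr <- grid_centers(sc$truth_grid)
  expect_true(all(ctr$x >= 0 & ctr$x <= ncol(img) - 1))
  expect_true(all(ctr$y >= 0 & ctr$y <= nrow(img) - 1))
  # truth labels consecutive
  u <- sort(unique(as.vector(sc$truth_instances$grid)))
  expect_identical(u, 0:24)
})

test_that("generators are bit-deterministic in (spec, seed)", {
  for (gen in list(generate_grid_scene, generate_cell_scene)) {
    sp <- small_cell_spec(noise_sigma = 0.05)
    a <- gen(sp); b <- gen(sp)
    expect_identical(a$images, b$images)
    c <- gen(small_cell_spec(noise_sigma = 0.05, seed = 6))
    expect_false(identical(a$images, c$images))
  }
  sp <- scene_spec(rows = 3, cols = 3, seed = 2, noise_sigma = 0.05)
  vm <- matrix(runif(9), 3)
  expect_identical(generate_colorimetric_scene(sp, vm)$rgb,
                   generate_colorimetric_scene(sp, vm)$rgb)
})

test_that("grid scene geometry is rejected when the lattice cannot fit", {
  expect_error(generate_grid_scene(
    scene_spec(rows = 300, cols = 300, pitch_x = 64, pitch_y = 64)),
    "bound")
  expect_error(scene_spec(pitch_x = 15, spot_radius = 10), "pitch")
  expect_error(scene_spec(alive_fraction = 1.5), "alive_fraction")
})

test_that("cell scene plants the stated viability world", {
  # alive_fraction = 1, no faint confounders: PI channel is pure background
  sc <- generate_cell_scene(small_cell_spec(alive_fraction = 1))
  expect_true(all(sc$images$pi == 0))
  # alive_fraction = 0: nothing is calcein-positive-and-pi-negative
  sc0 <- generate_cell_scene(small_cell_spec(alive_fraction = 0))
  expect_false(any(sc0$truth_status$calcein_positive &
                   !sc0$truth_status$pi_positive))
  expect_false(any(sc0$truth_status$alive))
  # count conservation: planted cells == per-spot placements == max label
  sc75 <- generate_cell_scene(small_cell_spec())
  n <- nrow(sc75$truth_status)
  expect_equal(n, 4 * 25)
  expect_equal(max(sc75$truth_instances$hoechst), n)
  expect_equal(as.vector(table(paste(sc75$truth_status$spot_i,
                                     sc75$truth_status$spot_j))),
               rep(25, 4))
  # per-channel truth labels consecutive
  for (ch in names(sc75$truth_instances)) {
    lab <- sc75$truth_instances[[ch]]
    expect_identical(sort(unique(lab[lab > 0])),
                     seq_len(max(lab)))
  }
  # planted status is internally consistent
  expect_identical(sc75$truth_status$alive,
                   sc75$truth_status$calcein_positive &
                     !sc75$truth_status$pi_positive)
})

test_that("impossible cell packing is rejected naming the spot", {
  sp <- scene_spec(rows = 1, cols = 2, pitch_x = 30, pitch_y = 30,
                   spot_radius = 10, cells_per_spot = 40,
                   cell_radius_range = c(4, 4), seed = 1)
  expect_error(generate_cell_scene(sp), "spot \\(0, 0\\)")
})

test_that("colorimetric scene: exact monotone chain gives correlation 1", {
  sp <- scene_spec(rows = 3, cols = 4, spot_radius = 8, seed = 9,
                   noise_sigma = 0)
  vm <- matrix(seq(0, 1, length.out = 12), 3, 4, byrow = TRUE)
  sc <- generate_colorimetric_scene(sp, vm, color_model_channel("R", 0, 1),
                                    noise_sigma = 0)
  scal <- apply_transform(sc$rgb, color_transform("channel", channel = "R"))
  q <- quantify_spots(scal, extract_rois(scal, sc$truth_grid), "mean")
  truth <- vm[cbind(q$i + 1, q$j + 1)]
  expect_equal(cor(q$y_hat, truth), 1, tolerance = 1e-12)
})

test_that("constant value map: spot variance is bounded by noise alone", {
  sp <- scene_spec(rows = 4, cols = 6, spot_radius = 10, seed = 21,
                   noise_sigma = 0)
  vm <- matrix(0.5, 4, 6)
  sigma <- 0.08
  sc <- generate_colorimetric_scene(sp, vm, color_model_channel("R", 0, 1),
                                    noise_sigma = sigma)
  scal <- apply_transform(sc$rgb, color_transform("channel", channel = "R"))
  rois <- extract_rois(scal, sc$truth_grid)
  q <- quantify_spots(scal, rois, "median")
  # noise-only variance of a median over n pixels, estimated empirically
  n_px <- sum(rois[[1]]$mask)
  set.seed(99)
  med_var <- var(replicate(500, median(rnorm(n_px, 0, sigma))))
  expect_lt(var(q$y_hat), 3 * med_var)
})

test_that("value map shape mismatch is rejected", {
  sp <- scene_spec(rows = 3, cols = 4)
  expect_error(generate_colorimetric_scene(sp, matrix(0, 4, 3)),
               "value_map must be 3 x 4")
})
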