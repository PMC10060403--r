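test_that("embed_images produces stable descriptors and passthrough", {
  const <- matrix(0.5, 16, 16)
  checker <- matrix(rep(c(0, 1), 128), 16, 16)
  m <- embed_images(list(a = const, b = const, c = checker))
  expect_identical(m["a", ], m["b", ])
  expect_false(identical(m["a", ], m["c", ]))
  ext <- matrix(rnorm(50), 5, 10)
  got <- embed_images(rep(list(const), 5), external = ext)
  expect_equal(unname(got), ext)
  expect_error(embed_images(list(const), external = matrix(0, 3, 2)),
               "3 rows for 1 images")
  expect_error(embed_images(list()), "at least one")
})

test_that("reduce_pca preserves geometry and matches the eigen oracle", {
  # points on a 3-D line: k = 1 reproduces pairwise distances
  t <- seq(0, 1, length.out = 7)
  line <- cbind(t, 2 * t, -t) + 5
  red <- reduce_pca(line, 1)
  expect_equal(as.matrix(dist(red)), as.matrix(dist(line)),
               tolerance = 1e-9, ignore_attr = TRUE)
  # k = d on full-rank data: distances preserved (pure rotation)
  set.seed(12)
  m <- matrix(rnorm(60), 12, 5)
  expect_equal(as.matrix(dist(reduce_pca(m, 5))), as.matrix(dist(m)),
               tolerance = 1e-9, ignore_attr = TRUE)
  # oracle: projection through eigen-decomposition of the covariance
  k <- 3
  red2 <- reduce_pca(m, k)
  ev <- eigen(cov(m), symmetric = TRUE)$vectors[, 1:k]
  ctr <- scale(m, center = TRUE, scale = FALSE)
  oracle <- ctr %*% ev
  for (c in 1:k)  # sign convention may differ from eigen's
    expect_equal(abs(red2[, c]), abs(oracle[, c]), tolerance = 1e-8,
                 ignore_attr = TRUE)
  expect_error(reduce_pca(m, 10), "too large")
  expect_error(reduce_pca(m[1, , drop = FALSE], 1), "at least 2")
})

test_that("heterogeneity_order is the exhaustive max-min ordering", {
  # three collinear points: medoid first, then the farther extreme
  m <- matrix(c(0, 4, 10), ncol = 1)
  rownames(m) <- c("A", "B", "C")
  ord <- heterogeneity_order(m)
  expect_equal(ord$id, c("B", "C", "A"))
  expect_equal(ord$score[1], 10)  # global max pairwise distance
  # duplicates are never selected before all distinct points
  dup <- rbind(m, m)
  rownames(dup) <- c("A", "B", "C", "A2", "B2", "C2")
  odup <- heterogeneity_order(dup)
  expect_true(all(match(c("A", "B", "C"), odup$id) <=
                    min(match(c("A2", "B2", "C2"), odup$id))))
  expect_equal(nrow(heterogeneity_order(matrix(1, 1, 1))), 1)
  # greedy step vs exhaustive max-min at every step, random cases
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(4:8, 1)
    pts <- matrix(rnorm(2 * n), n)
    rownames(pts) <- sprintf("p%02d", seq_len(n))
    ord <- heterogeneity_order(pts)
    D <- as.matrix(dist(pts))
    sel <- match(ord$id[1], rownames(pts))
    for (step in 2:n) {
      rest <- setdiff(seq_len(n), sel)
      mind <- vapply(rest, function(r) min(D[r, sel]), numeric(1))
      best <- max(mind)
      chosen <- match(ord$id[step], rownames(pts))
      expect_equal(min(D[chosen, sel]), best, tolerance = 1e-12)
      sel <- c(sel, chosen)
    }
  }
})

test_that("preannotate applies classical heuristics and contracts", {
  img <- matrix(c(rep(0.2, 60), rep(0.9, 40)), 10, 10)
  mask <- preannotate(img, "otsu")
  expect_equal(mask, img > 0.5)
  set.seed(2)
  big <- matrix(runif(10000), 100, 100)
  expect_lt(abs(mean(preannotate(big, "percentile", q = 95)) - 0.05), 0.01)
  expect_error(preannotate(img, "external", external = matrix(0, 2, 2)),
               "shape mismatch")
})

test_that("dice follows its definition and conventions", {
  a <- matrix(FALSE, 4, 4); a[1:2, ] <- TRUE
  expect_equal(dice(a, a), 1)
  b <- matrix(FALSE, 4, 4); b[3:4, ] <- TRUE
  expect_equal(dice(a, b), 0)
  # half-overlapping equal-area masks
  c1 <- matrix(FALSE, 4, 4); c1[, 1:2] <- TRUE
  c2 <- matrix(FALSE, 4, 4); c2[, 2:3] <- TRUE
  expect_equal(dice(c1, c2), 0.5)
  expect_equal(dice(c1, c2), dice(c2, c1))
  expect_equal(dice(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), 1)
  expect_error(dice(a, matrix(FALSE, 2, 2)), "differ")
})

test_that("aji_plus equals the exhaustive-assignment oracle", {
  t1 <- matrix(c(1, 1, 0, 2), 2, 2)
  expect_equal(aji_plus(t1, t1), 1)
  expect_equal(aji_plus(t1, matrix(0L, 2, 2)), 0)
  # toy maps vs brute force over all assignments
  for (seed in 1:8) {
    set.seed(seed)
    h <- 6; w <- 6
    truth <- matrix(sample(0:3, h * w, TRUE, prob = c(0.4, 0.2, 0.2, 0.2)),
                    h, w)
    pred <- matrix(sample(0:3, h * w, TRUE, prob = c(0.4, 0.2, 0.2, 0.2)),
                   h, w)
    expect_equal(aji_plus(truth, pred), aji_plus_oracle(truth, pred),
                 tolerance = 1e-12, label = sprintf("seed %d", seed))
  }
  # label-permutation invariance in both arguments
  set.seed(42)
  truth <- matrix(sample(0:3, 36, TRUE), 6, 6)
  pred <- matrix(sample(0:3, 36, TRUE), 6, 6)
  pt <- truth; pt[truth == 1] <- 3L; pt[truth == 3] <- 1L
  pp <- pred; pp[pred == 2] <- 3L; pp[pred == 3] <- 2L
  expect_equal(aji_plus(pt, pp), aji_plus(truth, pred), tolerance = 1e-12)
  expect_lte(aji_plus(truth, pred), 1)
  expect_error(aji_plus(truth, matrix(0L, 2, 2)), "differ")
})
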