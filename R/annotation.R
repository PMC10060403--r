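# Assisted-annotation support: diversity-based sample ordering in a
# reduced feature space, classical pre-annotation heuristics, and the two
# inspection metrics (Dice, AJI+).

# Classical per-image descriptor: 32-bin intensity histogram (density over
# [0, 1]), four intensity moments, and gradient ("edge-density")
# statistics. Stands in for a pretrained embedding network.
default_image_features <- function(image) {
  assert_raster(image)
  v <- as.vector(image)
  hist32 <- tabulate(pmin(pmax(floor(v * 32) + 1L, 1L), 32L), nbins = 32L)
  hist32 <- hist32 / length(v)
  mu <- mean(v); s <- sd(v)
  skew <- if (s > 0) mean((v - mu)^3) / s^3 else 0
  kurt <- if (s > 0) mean((v - mu)^4) / s^4 - 3 else 0
  gx <- image[, -1, drop = FALSE] - image[, -ncol(image), drop = FALSE]
  gy <- image[-1, , drop = FALSE] - image[-nrow(image), , drop = FALSE]
  g <- c(abs(gx), abs(gy))
  c(hist32, mu, s, skew, kurt, mean(g), sd(g), mean(g > 0.1))
}

#' Embed images into a feature matrix
#'
#' One feature row per image. The classical default descriptor
#' concatenates an intensity histogram, image moments and edge-density
#' statistics; an externally computed feature matrix (e.g. from a
#' pretrained network) is accepted unchanged when its row count matches.
#'
#' @param images list of rasters (optionally named; names become ids)
#' @param external optional n x d numeric feature matrix
#' @return matrix with one row per image and rownames as identifiers
#' @export
embed_images <- function(images, external = NULL) {
  if (length(images) < 1) stop("need at least one image", call. = FALSE)
  ids <- names(images)
  if (is.null(ids)) ids <- sprintf("img%03d", seq_along(images))
  if (!is.null(external)) {
    external <- as.matrix(external)
    if (nrow(external) != length(images))
      stop(sprintf("external features have %d rows for %d images",
                   nrow(external), length(images)), call. = FALSE)
    rownames(external) <- ids
    return(external)
  }
  rows <- lapply(images, default_image_features)
  len <- vapply(rows, length, integer(1))
  if (length(unique(len)) != 1)
    stop("inconsistent feature length across images", call. = FALSE)
  m <- do.call(rbind, rows)
  rownames(m) <- ids
  m
}

#' Reduce an embedding to its top principal components
#'
#' Rows are centered and projected on the top-k principal axes. Each
#' axis's sign is fixed so its largest-magnitude loading is positive,
#' making the reduction deterministic.
#'
#' @param m embedding matrix (n x d)
#' @param k target dimension; must satisfy `k <= min(n - 1, d)`
#' @return n x k matrix, rownames preserved
#' @export
reduce_pca <- function(m, k = 10) {
  m <- as.matrix(m)
  n <- nrow(m); d <- ncol(m)
  if (n < 2) stop("PCA needs at least 2 rows", call. = FALSE)
  if (k > min(n - 1, d))
    stop(sprintf("k = %d too large; must be <= min(n - 1, d) = %d",
                 k, min(n - 1, d)), call. = FALSE)
  ctr <- scale(m, center = TRUE, scale = FALSE)
  sv <- svd(ctr, nu = 0, nv = k)
  V <- sv$v
  for (c in seq_len(ncol(V))) {
    piv <- which.max(abs(V[, c]))
    if (V[piv, c] < 0) V[, c] <- -V[, c]
  }
  out <- ctr %*% V
  rownames(out) <- rownames(m)
  out
}

#' Order samples by heterogeneity (farthest-point traversal)
#'
#' Greedy max-min ordering in Euclidean distance: the first sample is the
#' medoid (minimum summed distance to all others; or a given id) and each
#' subsequent sample maximizes the minimum distance to everything already
#' selected, so annotators see dissimilar images first. Ties break by
#' ascending identifier.
#'
#' @param m embedding matrix with rownames as identifiers (see
#'   [reduce_pca()])
#' @param start `"medoid"` or an identifier present in the rownames
#' @return data.frame with columns `id` and `score`; `score` is the
#'   minimum distance to the previously selected samples (for the first
#'   sample, the global maximum pairwise distance)
#' @export
heterogeneity_order <- function(m, start = "medoid") {
  m <- as.matrix(m)
  n <- nrow(m)
  ids <- rownames(m)
  if (is.null(ids)) ids <- sprintf("img%03d", seq_len(n))
  if (n == 1) return(data.frame(id = ids, score = 0))
  D <- as.matrix(dist(m))
  first <- if (identical(start, "medoid")) {
    tot <- rowSums(D)
    which(tot == min(tot))[order(ids[tot == min(tot)])][1]
  } else {
    w <- match(start, ids)
    if (is.na(w)) stop("start id not found: ", start, call. = FALSE)
    w
  }
  selected <- first
  score <- max(D)
  mind <- D[, first]
  for (step in 2:n) {
    mind[selected] <- -Inf
    best <- max(mind)
    cand <- which(mind == best)
    nxt <- cand[order(ids[cand])][1]
    selected <- c(selected, nxt)
    score <- c(score, best)
    mind <- pmin(mind, D[, nxt])
  }
  data.frame(id = ids[selected], score = score)
}

#' Classical pre-annotation of a single-channel image
#'
#' Produces the initial binary mask a user corrects during annotation.
#' Learned predictors enter through `external` only.
#'
#' @param image single-channel raster
#' @param method `"otsu"`, `"percentile"` or `"external"`
#' @param q percentile for `method = "percentile"`
#' @param external external binary mask for `method = "external"`
#' @return logical mask
#' @export
preannotate <- function(image, method = c("otsu", "percentile", "external"),
                        q = 95, external = NULL) {
  method <- match.arg(method)
  if (method == "external") {
    if (is.null(external)) stop("external mask required", call. = FALSE)
    if (!identical(dim(external), dim(image)))
      stop(sprintf("external mask shape mismatch: expected %d x %d, got %d x %d",
                   nrow(image), ncol(image), nrow(external), ncol(external)),
           call. = FALSE)
    return(external > 0)
  }
  segment_elements(image, method, q = q)
}

#' Dice coefficient of two binary masks
#'
#' `2 |A n B| / (|A| + |B|)`; two empty masks score 1 by convention.
#'
#' @param a,b logical masks of identical shape
#' @return score in \[0, 1\]
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("mask shapes differ", call. = FALSE)
  a <- a > 0; b <- b > 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Advanced aggregated Jaccard index (AJI+) of two instance maps
#'
#' Instance-level overlap score: truth and predicted instances are put in
#' an optimal one-to-one correspondence maximizing the summed
#' intersection-over-union (exact assignment), then
#' `score = sum(matched intersections) / (sum(matched unions) +
#' unmatched truth areas + unmatched prediction areas)`. The optimal
#' assignment repairs the over-penalization of the greedy aggregated
#' Jaccard index. Label-permutation invariant in both arguments.
#'
#' @param truth,pred integer instance maps of identical shape (0 =
#'   background)
#' @return score in \[0, 1\]
#' @export
aji_plus <- function(truth, pred) {
  if (!identical(dim(truth), dim(pred)))
    stop("instance map shapes differ", call. = FALSE)
  tl <- sort(unique(truth[truth > 0]))
  pl <- sort(unique(pred[pred > 0]))
  if (length(tl) == 0 && length(pl) == 0) return(1)
  if (length(tl) == 0 || length(pl) == 0) return(0)
  ta <- tabulate(truth[truth > 0], nbins = max(tl))[tl]
  pa <- tabulate(pred[pred > 0], nbins = max(pl))[pl]
  both <- truth > 0 & pred > 0
  inter <- matrix(0, length(tl), length(pl))
  if (any(both)) {
    key <- table(factor(truth[both], levels = tl),
                 factor(pred[both], levels = pl))
    inter <- matrix(as.numeric(key), length(tl), length(pl))
  }
  uni <- outer(ta, pa, "+") - inter
  iou <- inter / uni
  n <- max(length(tl), length(pl))
  cost <- matrix(0, n, n)  # pad with zero-IoU dummies
  cost[seq_along(tl), seq_along(pl)] <- -iou
  assign <- cpp_hungarian(cost)
  num <- 0; den <- 0
  matched_t <- logical(length(tl)); matched_p <- logical(length(pl))
  for (ti in seq_along(tl)) {
    pj <- assign[ti]
    if (pj <= length(pl) && iou[ti, pj] > 0) {
      num <- num + inter[ti, pj]
      den <- den + uni[ti, pj]
      matched_t[ti] <- TRUE; matched_p[pj] <- TRUE
    }
  }
  den <- den + sum(ta[!matched_t]) + sum(pa[!matched_p])
  num / den
}
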