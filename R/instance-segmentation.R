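# Micro-level object detection: Euclidean distance maps, seeded watershed
# and region-feature extraction. The learned distance predictor of the
# original pipeline is replaced by a classical default (Otsu foreground +
# exact EDT); an external predictor can be plugged in via `scores`.

#' Predict a Euclidean distance map
#'
#' Default (classical) predictor: the foreground is found by Otsu's
#' threshold on the normalized image and the exact Euclidean distance to
#' the nearest background pixel is computed inside it. An external
#' predictor (e.g. a trained network) can supply the map directly; it must
#' be non-negative, zero on background, and of matching shape.
#'
#' @param image raster in \[0, 1\]
#' @param external optional externally predicted distance map
#' @return non-negative raster, positive inside objects (class `dmap`)
#' @export
predict_distance_map <- function(image, external = NULL) {
  assert_raster(image)
  if (!is.null(external)) {
    if (!identical(dim(external), dim(image)))
      stop(sprintf("external map shape mismatch: expected %d x %d, got %d x %d",
                   nrow(image), ncol(image), nrow(external), ncol(external)),
           call. = FALSE)
    if (any(external < 0))
      stop("external distance map has negative values", call. = FALSE)
    return(external)
  }
  if (max(image) <= min(image))
    return(matrix(0, nrow(image), ncol(image)))
  fg <- image > otsu_threshold(image)
  cpp_edt(fg)
}

# Seed detection: regional maxima of the h-maxima transform of dmap
# (prominence >= h via grayscale reconstruction), one candidate seed per
# maximum plateau (the plateau pixel of maximal dmap, raster order on
# ties), then a greedy minimum-distance filter in descending dmap order.
find_seeds <- function(dmap, h, min_seed_distance) {
  if (max(dmap) <= 0) return(matrix(0L, nrow(dmap), ncol(dmap)))
  hm <- cpp_reconstruct(dmap - h, dmap)
  tol <- 1e-6
  rm_ <- cpp_reconstruct(hm - tol, hm)
  maxima <- (hm - rm_) >= tol / 2 & dmap > 0
  plat <- cpp_label4(maxima)
  n <- max(plat)
  if (n == 0) return(matrix(0L, nrow(dmap), ncol(dmap)))
  # representative pixel per plateau: maximal dmap, raster order tie-break
  reps <- integer(n); vals <- numeric(n)
  sel <- which(plat > 0)
  o <- sel[order(plat[sel], -dmap[sel], sel)]
  first <- !duplicated(plat[o])
  reps <- o[first]; vals <- dmap[reps]
  hgt <- nrow(dmap)
  px <- (reps - 1) %/% hgt; py <- (reps - 1) %% hgt
  ord <- order(-vals, reps)
  keep <- logical(length(reps))
  for (k in ord) {
    if (!any(keep) ||
        all((px[keep] - px[k])^2 + (py[keep] - py[k])^2 >=
            min_seed_distance^2))
      keep[k] <- TRUE
  }
  seeds <- matrix(0L, nrow(dmap), ncol(dmap))
  kept <- reps[keep]
  seeds[kept] <- seq_along(kept)
  seeds
}

#' Seeded watershed on a distance map
#'
#' Seeds are local maxima of the distance map with prominence at least `h`
#' (via the h-maxima transform) and pairwise distance at least
#' `min_seed_distance`; the watershed floods `-dmap` restricted to
#' `dmap > 0`, one region per seed, with a deterministic FIFO tie-break.
#' Touching objects are split along the neck between their distance-map
#' maxima. Zero seeds yield an empty instance map.
#'
#' @param dmap distance map from [predict_distance_map()]
#' @param h seed prominence in pixels (> 0)
#' @param min_seed_distance minimum seed separation in pixels
#' @return integer instance map, labels 1..N (class contract: 0 =
#'   background)
#' @export
watershed_instances <- function(dmap, h = 1, min_seed_distance = 3) {
  assert_raster(dmap)
  if (h <= 0) stop("seed prominence h must be > 0", call. = FALSE)
  seeds <- find_seeds(dmap, h, min_seed_distance)
  if (max(seeds) == 0) return(matrix(0L, nrow(dmap), ncol(dmap)))
  relabel_consecutive(cpp_watershed(dmap, seeds))
}

#' Per-pixel argmax over a stack of class scores
#'
#' Semantic post-processing: each pixel is assigned the class whose score
#' is highest; ties break toward the lowest class index.
#'
#' @param score_stack list of >= 2 score rasters of identical shape, or a
#'   3-d array with classes along the third dimension
#' @return integer raster of 1-based class indices
#' @export
semantic_argmax <- function(score_stack) {
  if (is.array(score_stack) && length(dim(score_stack)) == 3)
    score_stack <- lapply(seq_len(dim(score_stack)[3]),
                          function(k) score_stack[, , k])
  if (!is.list(score_stack) || length(score_stack) < 2)
    stop("need at least 2 class score rasters", call. = FALSE)
  d <- dim(score_stack[[1]])
  for (k in seq_along(score_stack))
    if (!identical(dim(score_stack[[k]]), d))
      stop(sprintf("score raster %d shape mismatch: expected %d x %d, got %d x %d",
                   k, d[1], d[2], nrow(score_stack[[k]]),
                   ncol(score_stack[[k]])), call. = FALSE)
  best <- matrix(1L, d[1], d[2])
  bestv <- score_stack[[1]]
  for (k in seq_along(score_stack)[-1]) {
    upd <- score_stack[[k]] > bestv  # strict: ties keep the lower index
    best[upd] <- as.integer(k)
    bestv[upd] <- score_stack[[k]][upd]
  }
  best
}

#' Eccentricity of the moment-equivalent ellipse from its axis lengths
#'
#' `sqrt(1 - (minor / major)^2)`: 0 for a circle, approaching 1 for
#' elongated regions.
#'
#' @param major,minor axis lengths in pixels, `0 < minor <= major`
#' @return eccentricity in \[0, 1)
#' @export
eccentricity_from_axes <- function(major, minor) {
  if (any(minor > major))
    stop("minor axis must not exceed major axis", call. = FALSE)
  if (any(minor <= 0)) stop("axis lengths must be positive", call. = FALSE)
  sqrt(1 - (minor / major)^2)
}

#' Extract per-instance region features
#'
#' One record per label: area (pixel count), centroid (mean pixel
#' coordinates, x = column / y = row, 0-based), mean intensity, and the
#' axis lengths of the ellipse with the same normalized second central
#' moments as the region (major = 4 sqrt(lambda_max) for eigenvalues of
#' the pixel-coordinate covariance), from which the eccentricity follows.
#'
#' @param instances integer instance map (0 background)
#' @param intensity intensity raster of the same shape
#' @return data.frame with columns `id`, `area`, `x`, `y`,
#'   `eccentricity`, `mean_intensity`, `major_axis`, `minor_axis`
#' @export
extract_features <- function(instances, intensity = NULL) {
  stopifnot(is.matrix(instances))
  if (is.null(intensity))
    intensity <- matrix(0, nrow(instances), ncol(instances))
  if (!identical(dim(instances), dim(intensity)))
    stop("instance and intensity shapes differ", call. = FALSE)
  st <- label_stats(instances, intensity)
  if (nrow(st) == 0)
    return(data.frame(id = integer(), area = numeric(), x = numeric(),
                      y = numeric(), eccentricity = numeric(),
                      mean_intensity = numeric(), major_axis = numeric(),
                      minor_axis = numeric()))
  sel <- which(instances > 0)
  lab <- instances[sel]
  h <- nrow(instances)
  ys <- (sel - 1) %% h
  xs <- (sel - 1) %/% h
  mx <- st$x[lab]; my <- st$y[lab]
  uxx <- as.vector(rowsum((xs - mx)^2, lab)) / st$area
  uyy <- as.vector(rowsum((ys - my)^2, lab)) / st$area
  uxy <- as.vector(rowsum((xs - mx) * (ys - my), lab)) / st$area
  common <- sqrt(pmax((uxx - uyy)^2 + 4 * uxy^2, 0))
  l1 <- (uxx + uyy + common) / 2
  l2 <- pmax((uxx + uyy - common) / 2, 0)
  major <- 4 * sqrt(l1)
  minor <- 4 * sqrt(l2)
  ecc <- ifelse(major > 0, sqrt(pmax(1 - (minor / major)^2, 0)), 0)
  data.frame(id = st$id, area = st$area, x = st$x, y = st$y,
             eccentricity = ecc, mean_intensity = st$mean_intensity,
             major_axis = major, minor_axis = minor)
}

#' Full instance segmentation of one image or ROI
#'
#' Chains [predict_distance_map()], [watershed_instances()] and
#' [extract_features()].
#'
#' @param image raster in \[0, 1\]
#' @param h,min_seed_distance watershed parameters
#' @param external optional external distance map
#' @return list with `instances` (label raster), `features` (data.frame)
#'   and `dmap`
#' @export
segment_instances <- function(image, h = 1, min_seed_distance = 3,
                              external = NULL) {
  dmap <- predict_distance_map(image, external)
  instances <- watershed_instances(dmap, h, min_seed_distance)
  list(instances = instances,
       features = extract_features(instances, image),
       dmap = dmap)
}
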