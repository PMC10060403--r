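# Macro-level grid detection: preprocess -> element segmentation ->
# post-processing -> rotation estimation -> robust lattice fit. A learned
# element scorer can be plugged in; classical thresholds are the defaults.

#' Pre-process an image for grid detection
#'
#' Multi-channel inputs are reduced to luminance (Rec. 709 weights), then
#' intensities are linearly rescaled so the `p_low` percentile maps to 0
#' and `p_high` to 1, clipped to \[0, 1\]. Percentile normalization makes
#' downstream thresholding robust to exposure differences.
#'
#' @param image numeric raster, or h x w x 3 array
#' @param p_low,p_high percentiles in \[0, 100\], `p_low < p_high`
#' @return raster in \[0, 1\]
#' @export
preprocess <- function(image, p_low = 1, p_high = 99) {
  if (!(p_low >= 0 && p_low < p_high && p_high <= 100))
    stop("require 0 <= p_low < p_high <= 100", call. = FALSE)
  if (length(dim(image)) == 3) image <- luminance(image)
  assert_raster(image)
  q <- quantile(image, c(p_low, p_high) / 100, names = FALSE)
  if (q[2] <= q[1]) {
    warning("constant image: percentile range is empty; returning zeros")
    return(matrix(0, nrow(image), ncol(image)))
  }
  pmin(pmax((image - q[1]) / (q[2] - q[1]), 0), 1)
}

#' Segment candidate grid elements
#'
#' Separates element pixels from background. The default methods are
#' classical thresholds; a learned model can be supplied as a per-pixel
#' score raster in \[0, 1\] via `method = "scores"` (thresholded at
#' `score_threshold`), mirroring a pluggable segmentation network.
#'
#' @param image preprocessed raster in \[0, 1\]
#' @param method `"otsu"`, `"percentile"` or `"scores"`
#' @param q foreground percentile for `method = "percentile"` (pixels above
#'   the q-th percentile are foreground)
#' @param scores external score raster (required for `method = "scores"`)
#' @param score_threshold threshold applied to `scores`
#' @return logical foreground mask
#' @export
segment_elements <- function(image, method = c("otsu", "percentile", "scores"),
                             q = 90, scores = NULL, score_threshold = 0.5) {
  assert_raster(image)
  method <- match.arg(method)
  switch(method,
    otsu = {
      if (max(image) <= min(image))
        matrix(FALSE, nrow(image), ncol(image))
      else image > otsu_threshold(image)
    },
    percentile = image > quantile(image, q / 100, names = FALSE),
    scores = {
      if (is.null(scores))
        stop("method = \"scores\" requires a `scores` raster", call. = FALSE)
      if (!identical(dim(scores), dim(image)))
        stop(sprintf("scores shape mismatch: expected %d x %d, got %d x %d",
                     nrow(image), ncol(image), nrow(scores), ncol(scores)),
             call. = FALSE)
      scores > score_threshold
    })
}

#' Post-process an element mask into a detected element set
#'
#' Morphological opening with a disc smooths the mask and removes specks;
#' connected components are labeled (4-connectivity) and components whose
#' area falls outside `area_band * median(area)` are removed, suppressing
#' debris and merged elements. Surviving components are relabeled 1..N.
#'
#' @param mask logical foreground mask
#' @param open_radius opening disc radius in pixels (0 disables)
#' @param area_band `(low_factor, high_factor)` with
#'   `0 < low < 1 < high`; kept areas lie in `band * median(area)`
#' @return list of class `element_set`: `labels` (integer raster),
#'   `centroids` (data.frame id, x, y, area)
#' @export
postprocess_elements <- function(mask, open_radius = 1,
                                 area_band = c(0.3, 3)) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!(area_band[1] > 0 && area_band[1] < 1 && area_band[2] > 1))
    stop("area_band must satisfy 0 < low < 1 < high", call. = FALSE)
  if (open_radius > 0) mask <- open_disc(mask, open_radius)
  labels <- cpp_label4(mask)
  st <- label_stats(labels)
  if (nrow(st) == 0)
    stop("grid detection failed: no elements survive post-processing",
         call. = FALSE)
  med <- median(st$area)
  keep <- st$area >= area_band[1] * med & st$area <= area_band[2] * med
  if (!any(keep))
    stop("grid detection failed: no elements survive the area filter",
         call. = FALSE)
  labels[!(labels %in% st$id[keep])] <- 0L
  labels <- relabel_consecutive(labels)
  st <- st[keep, , drop = FALSE]
  st$id <- seq_len(nrow(st))
  rownames(st) <- NULL
  structure(list(labels = labels, centroids = st), class = "element_set")
}

# Nearest-neighbor distances and displacement angles among centroids.
nn_displacements <- function(x, y) {
  n <- length(x)
  d <- as.matrix(dist(cbind(x, y)))
  diag(d) <- Inf
  nn <- apply(d, 1, which.min)  # smallest index wins ties (deterministic)
  list(dx = x[nn] - x, dy = y[nn] - y,
       dist = d[cbind(seq_len(n), nn)])
}

# Circular median on the fold period of 90 degrees: the folded angle
# minimizing the summed circular distance to all folded angles; ties go to
# the smallest angle.
circular_median90 <- function(folded) {
  circ <- function(a, b) {
    d <- abs(a - b) %% 90
    pmin(d, 90 - d)
  }
  cost <- vapply(folded, function(a) sum(circ(a, folded)), numeric(1))
  cand <- folded[cost == min(cost)]
  min(cand)
}

#' Estimate grid rotation from element centroids
#'
#' For every centroid the displacement to its nearest neighbour is taken;
#' along a rectangular lattice these displacements point along the grid
#' axes. Each displacement angle is folded modulo 90 degrees into
#' (-45, 45] and the circular median of the folded angles is returned,
#' which is robust to spurious or missing detections. The fold makes
#' rotations differing by 90 degrees indistinguishable (inherent to an
#' unlabeled rectangular lattice).
#'
#' @param centroids data.frame with columns `x`, `y` (or a two-column
#'   matrix)
#' @return rotation in degrees in (-45, 45]
#' @export
estimate_rotation <- function(centroids) {
  if (is.matrix(centroids))
    centroids <- data.frame(x = centroids[, 1], y = centroids[, 2])
  if (nrow(centroids) < 2)
    stop("rotation estimation needs at least 2 centroids", call. = FALSE)
  nn <- nn_displacements(centroids$x, centroids$y)
  ang <- atan2(nn$dy, nn$dx) * 180 / pi
  circular_median90(fold_angle90(ang))
}

# Single-linkage 1-D clustering: split sorted coords at gaps > gap_thr.
# Returns the mean coordinate per cluster, ascending.
cluster_lines <- function(coords, gap_thr) {
  s <- sort(coords)
  grp <- cumsum(c(1, diff(s) > gap_thr))
  as.vector(tapply(s, grp, mean))
}

# Insert interpolated line centers into gaps that are an integer multiple
# of the pitch (within tol), used when expected_shape promises more lines.
interpolate_lines <- function(centers, pitch, tol = 0.1) {
  out <- centers[1]
  for (k in seq_len(length(centers) - 1)) {
    gap <- centers[k + 1] - centers[k]
    m <- round(gap / pitch)
    if (m >= 2 && abs(gap / m - pitch) <= tol * pitch)
      out <- c(out, centers[k] + gap / m * seq_len(m - 1))
    out <- c(out, centers[k + 1])
  }
  out
}

#' Fit a grid model to detected elements
#'
#' Robust lattice estimation: centroids are de-rotated by the estimated
#' rotation, each axis is clustered into grid lines by single-linkage with
#' a gap threshold of half the median nearest-neighbour spacing, the pitch
#' is the median of consecutive line-center differences and the origin is
#' the first line center (rotated back). When `expected_shape` is given,
#' missing interior lines are interpolated when the pitch divides a gap
#' within 10%, and an irreconcilable shape is an error. The spot radius is
#' the median equivalent radius `sqrt(area / pi)` of the elements.
#'
#' @param elements an `element_set` from [postprocess_elements()]
#' @param rotation_deg grid rotation (see [estimate_rotation()])
#' @param expected_shape optional `c(rows, cols)`
#' @return a [grid_model]
#' @export
fit_grid <- function(elements, rotation_deg, expected_shape = NULL) {
  st <- elements$centroids
  if (nrow(st) < 4)
    stop("grid fitting needs at least 4 elements", call. = FALSE)
  R <- rotation_matrix(-rotation_deg)
  uv <- cbind(st$x, st$y) %*% t(R)
  nn <- nn_displacements(st$x, st$y)
  gap_thr <- median(nn$dist) / 2
  lx <- cluster_lines(uv[, 1], gap_thr)
  ly <- cluster_lines(uv[, 2], gap_thr)
  if (length(lx) < 2 || length(ly) < 2)
    stop("grid fitting needs elements spanning >= 2 rows and >= 2 columns",
         call. = FALSE)
  pitch_x <- median(diff(lx))
  pitch_y <- median(diff(ly))
  if (!is.null(expected_shape)) {
    lx <- interpolate_lines(lx, pitch_x)
    ly <- interpolate_lines(ly, pitch_y)
    if (length(ly) != expected_shape[1] || length(lx) != expected_shape[2])
      stop(sprintf(
        "detected shape %d x %d is irreconcilable with expected shape %d x %d",
        length(ly), length(lx), expected_shape[1], expected_shape[2]),
        call. = FALSE)
  }
  Rb <- rotation_matrix(rotation_deg)
  origin <- Rb %*% c(lx[1], ly[1])
  grid_model(rows = length(ly), cols = length(lx),
             origin_x = origin[1], origin_y = origin[2],
             pitch_x = pitch_x, pitch_y = pitch_y,
             rotation_deg = rotation_deg,
             spot_radius = median(sqrt(st$area / pi)))
}

#' Automated grid detection pipeline
#'
#' Convenience wrapper chaining [preprocess()], [segment_elements()],
#' [postprocess_elements()], [estimate_rotation()] and [fit_grid()].
#'
#' @param image raw raster (or RGB array)
#' @param expected_shape optional `c(rows, cols)`
#' @param p_low,p_high normalization percentiles
#' @param method segmentation method, see [segment_elements()]
#' @param open_radius,area_band post-processing, see
#'   [postprocess_elements()]
#' @param ... passed to [segment_elements()]
#' @return a [grid_model]
#' @export
detect_grid <- function(image, expected_shape = NULL, p_low = 1, p_high = 99,
                        method = "otsu", open_radius = 1,
                        area_band = c(0.3, 3), ...) {
  pp <- preprocess(image, p_low, p_high)
  mask <- segment_elements(pp, method, ...)
  el <- postprocess_elements(mask, open_radius, area_band)
  rot <- estimate_rotation(el$centroids)
  fit_grid(el, rot, expected_shape)
}

#' Complete a grid model from partial knowledge and clicked points
#'
#' Semi-automated fallback for imaging conditions where automated
#' detection fails: the user supplies a subset of grid parameters and/or
#' clicked element centers, from which the remaining parameters are
#' derived deterministically. Supported derivations:
#' \itemize{
#'   \item a complete parameter set passes through unchanged;
#'   \item two clicked points, interpreted as the centers of elements
#'     (0, 0) and (rows-1, cols-1), with `rows`, `cols` and `rotation_deg`
#'     known, determine origin and pitch;
#'   \item three clicked points, interpreted as the centers of (0, 0),
#'     (0, cols-1) and (rows-1, 0), with `rows` and `cols` known,
#'     additionally determine the rotation (angle of the first grid row).
#' }
#'
#' @param known named list of known [grid_model] fields
#' @param clicked_points optional matrix/data.frame of clicked element
#'   centers (columns x, y), in the order stated above
#' @return a [grid_model]
#' @export
semi_automated_grid <- function(known = list(), clicked_points = NULL) {
  fields <- c("rows", "cols", "origin_x", "origin_y", "pitch_x", "pitch_y",
              "rotation_deg", "spot_radius")
  bad <- setdiff(names(known), fields)
  if (length(bad))
    stop("unknown grid parameters: ", paste(bad, collapse = ", "),
         call. = FALSE)
  k <- known
  if (!is.null(clicked_points)) {
    cp <- as.matrix(as.data.frame(clicked_points)[, 1:2])
    np <- nrow(cp)
    if (np >= 3 && !is.null(k$rows) && !is.null(k$cols)) {
      e1 <- cp[2, ] - cp[1, ]
      e2 <- cp[3, ] - cp[1, ]
      k$rotation_deg <- fold_angle90(atan2(e1[2], e1[1]) * 180 / pi)
      k$pitch_x <- sqrt(sum(e1^2)) / (k$cols - 1)
      k$pitch_y <- sqrt(sum(e2^2)) / (k$rows - 1)
      k$origin_x <- cp[1, 1]; k$origin_y <- cp[1, 2]
    } else if (np >= 2 && !is.null(k$rows) && !is.null(k$cols) &&
               !is.null(k$rotation_deg)) {
      d <- rotation_matrix(-k$rotation_deg) %*% (cp[2, ] - cp[1, ])
      k$pitch_x <- d[1] / (k$cols - 1)
      k$pitch_y <- d[2] / (k$rows - 1)
      k$origin_x <- cp[1, 1]; k$origin_y <- cp[1, 2]
    }
  }
  missing <- setdiff(fields, names(k))
  if (length(missing))
    stop("grid is underdetermined; missing parameters: ",
         paste(missing, collapse = ", "), call. = FALSE)
  grid_model(k$rows, k$cols, k$origin_x, k$origin_y, k$pitch_x, k$pitch_y,
             k$rotation_deg, k$spot_radius)
}

#' Extract per-spot regions of interest
#'
#' One ROI per grid element, ordered row-major ((0,0) first, column index
#' varying fastest). Each ROI carries a half-open bounding box clipped to
#' the image and the circular spot mask within the box.
#'
#' @param image raster the grid refers to
#' @param grid a [grid_model]; all centers must lie inside the image
#' @return list of `spot_roi` objects with fields `i`, `j`, `x0`, `x1`,
#'   `y0`, `y1` (half-open pixel ranges) and `mask` (logical matrix of the
#'   box shape)
#' @export
extract_rois <- function(image, grid) {
  assert_raster(image)
  h <- nrow(image); w <- ncol(image)
  ctr <- grid_centers(grid)
  out <- vector("list", nrow(ctr))
  r <- grid$spot_radius
  for (k in seq_len(nrow(ctr))) {
    cx <- ctr$x[k]; cy <- ctr$y[k]
    if (cx < 0 || cx > w - 1 || cy < 0 || cy > h - 1)
      stop(sprintf("grid center (%d, %d) lies outside the image",
                   ctr$i[k], ctr$j[k]), call. = FALSE)
    x0 <- max(0L, as.integer(floor(cx - r)))
    x1 <- min(w, as.integer(ceiling(cx + r)) + 1L)
    y0 <- max(0L, as.integer(floor(cy - r)))
    y1 <- min(h, as.integer(ceiling(cy + r)) + 1L)
    xs <- x0:(x1 - 1L); ys <- y0:(y1 - 1L)
    mask <- outer((ys - cy)^2, (xs - cx)^2, "+") <= r^2
    out[[k]] <- structure(list(i = ctr$i[k], j = ctr$j[k],
                               x0 = x0, x1 = x1, y0 = y0, y1 = y1,
                               cx = cx, cy = cy, mask = mask),
                          class = "spot_roi")
  }
  out
}

# Pixel values of `image` under a spot ROI's mask.
roi_pixels <- function(image, roi) {
  image[(roi$y0 + 1L):roi$y1, (roi$x0 + 1L):roi$x1, drop = FALSE][roi$mask]
}
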