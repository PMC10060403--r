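#' @useDynLib gridspot, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median quantile cor sd prcomp isoreg approx dist
#' @importFrom utils write.csv read.csv head packageVersion
NULL

# Pixel convention used everywhere: x = column, y = row, both 0-based at the
# pixel center; a raster is a numeric matrix with nrow = height (y) and
# ncol = width (x). Bounding boxes are half-open.

assert_raster <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("`%s` must be a numeric matrix (h x w raster)", name),
         call. = FALSE)
  invisible(x)
}

#' Offsets of a rasterized disc
#'
#' Integer (dx, dy) offsets whose Euclidean norm is at most `radius`.
#' @param radius disc radius in pixels (>= 0)
#' @return two-column integer matrix of offsets
#' @keywords internal
disc_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r)
  g <- g[g$dx^2 + g$dy^2 <= radius^2 + 1e-9, , drop = FALSE]
  as.matrix(g)
}

# Shift a matrix by (dx, dy) pixels, padding with `fill`.
shift_mat <- function(m, dx, dy, fill) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  ys <- max(1, 1 + dy):min(h, h + dy)
  xs <- max(1, 1 + dx):min(w, w + dx)
  if (length(ys) == 0 || length(xs) == 0) return(out)
  out[ys, xs] <- m[ys - dy, xs - dx, drop = FALSE]
  out
}

# Binary erosion/dilation with a disc structuring element.
erode_disc <- function(mask, radius) {
  if (radius <= 0) return(mask)
  off <- disc_offsets(radius)
  out <- mask
  for (k in seq_len(nrow(off)))
    out <- out & shift_mat(mask, off[k, 1], off[k, 2], FALSE)
  out
}

dilate_disc <- function(mask, radius) {
  if (radius <= 0) return(mask)
  off <- disc_offsets(radius)
  out <- mask
  for (k in seq_len(nrow(off)))
    out <- out | shift_mat(mask, off[k, 1], off[k, 2], FALSE)
  out
}

open_disc <- function(mask, radius) dilate_disc(erode_disc(mask, radius), radius)

#' Otsu threshold of an intensity raster
#'
#' Histogram-based threshold maximizing the between-class variance, the
#' classical parameter-free split into background and foreground.
#'
#' @param image numeric raster, values expected in \[0, 1\]
#' @param n_bins number of histogram bins
#' @return scalar threshold; pixels strictly above it are foreground
#' @export
otsu_threshold <- function(image, n_bins = 256L) {
  assert_raster(image)
  v <- as.vector(image)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(lo)
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  counts <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = n_bins)
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  p <- counts / sum(counts)
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  k <- which.max(sigma_b)  # first maximum: deterministic tie-break
  breaks[k + 1L]
}

# Luminance of an h x w x 3 array (Rec. 709 weights).
luminance <- function(rgb) {
  0.2126 * rgb[, , 1] + 0.7152 * rgb[, , 2] + 0.0722 * rgb[, , 3]
}

# Per-label aggregation over a label raster: returns a data.frame with one
# row per label 1..max, using the shared pixel convention for centroids.
label_stats <- function(labels, intensity = NULL) {
  stopifnot(is.matrix(labels))
  n <- max(labels)
  if (n < 1)
    return(data.frame(id = integer(), area = numeric(),
                      x = numeric(), y = numeric()))
  sel <- which(labels > 0)
  lab <- labels[sel]
  h <- nrow(labels)
  ys <- (sel - 1) %% h          # 0-based row
  xs <- (sel - 1) %/% h         # 0-based col
  area <- tabulate(lab, nbins = n)
  sx <- as.vector(rowsum(xs, lab, reorder = TRUE))
  sy <- as.vector(rowsum(ys, lab, reorder = TRUE))
  out <- data.frame(id = seq_len(n), area = area,
                    x = sx / area, y = sy / area)
  if (!is.null(intensity))
    out$mean_intensity <- as.vector(rowsum(intensity[sel], lab)) / area
  out
}

# Relabel a label raster so the used labels become consecutive 1..N
# (order preserved).
relabel_consecutive <- function(labels) {
  u <- sort(unique(labels[labels > 0]))
  if (length(u) == 0) return(labels)
  map <- integer(max(u))
  map[u] <- seq_along(u)
  out <- labels
  out[out > 0] <- map[out[out > 0]]
  out
}
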