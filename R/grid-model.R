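#' Grid model: parameterization of a rotated rectangular spot lattice
#'
#' Full description of a screening grid (droplet microarray, well plate):
#' element counts, the center of the first element, the pitch along both
#' grid axes, the rotation of the grid axes against the image axes and the
#' spot radius. The center of element (i, j), 0-based row-major, is
#' `origin + R(rotation_deg) \%*\% c(j * pitch_x, i * pitch_y)` with the
#' usual counter-clockwise rotation matrix acting on (x, y) coordinates
#' (x = column, y = row, 0-based pixel centers).
#'
#' @param rows,cols positive integer element counts
#' @param origin_x,origin_y center of element (0, 0) in pixels
#' @param pitch_x,pitch_y center-to-center distances in pixels (> 0)
#' @param rotation_deg grid rotation in degrees, restricted to (-45, 45]
#'   (a rectangular lattice is indistinguishable under 90-degree turns)
#' @param spot_radius element radius in pixels (> 0)
#' @return object of class `grid_model`
#' @export
grid_model <- function(rows, cols, origin_x, origin_y, pitch_x, pitch_y,
                       rotation_deg, spot_radius) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  stopifnot(rows >= 1, cols >= 1)
  if (!(pitch_x > 0 && pitch_y > 0 && spot_radius > 0))
    stop("pitch_x, pitch_y and spot_radius must be positive", call. = FALSE)
  if (!(rotation_deg > -45 && rotation_deg <= 45))
    stop("rotation_deg must lie in (-45, 45]", call. = FALSE)
  structure(list(rows = rows, cols = cols,
                 origin_x = as.numeric(origin_x),
                 origin_y = as.numeric(origin_y),
                 pitch_x = as.numeric(pitch_x),
                 pitch_y = as.numeric(pitch_y),
                 rotation_deg = as.numeric(rotation_deg),
                 spot_radius = as.numeric(spot_radius)),
            class = "grid_model")
}

#' @export
print.grid_model <- function(x, ...) {
  cat(sprintf(
    "grid_model: %d x %d elements\n  origin  (%.2f, %.2f) px\n  pitch   (%.2f, %.2f) px\n  rotation %.3f deg\n  spot radius %.2f px\n",
    x$rows, x$cols, x$origin_x, x$origin_y, x$pitch_x, x$pitch_y,
    x$rotation_deg, x$spot_radius))
  invisible(x)
}

rotation_matrix <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

# Fold an angle (degrees) into (-45, 45] modulo 90.
fold_angle90 <- function(deg) {
  f <- ((deg %% 90) + 90) %% 90
  f[f > 45] <- f[f > 45] - 90
  f
}

#' Element centers of a grid model
#'
#' @param grid a [grid_model]
#' @return data.frame with columns `i`, `j` (0-based indices, row-major
#'   order with `j` varying fastest) and `x`, `y` (pixel centers)
#' @export
grid_centers <- function(grid) {
  stopifnot(inherits(grid, "grid_model"))
  g <- expand.grid(j = seq_len(grid$cols) - 1L, i = seq_len(grid$rows) - 1L)
  R <- rotation_matrix(grid$rotation_deg)
  uv <- cbind(g$j * grid$pitch_x, g$i * grid$pitch_y)
  xy <- uv %*% t(R)
  data.frame(i = g$i, j = g$j,
             x = grid$origin_x + xy[, 1],
             y = grid$origin_y + xy[, 2])
}
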