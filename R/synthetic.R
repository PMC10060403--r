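# Synthetic scene generation. Every generator plants exact ground truth so
# downstream stages can be scored without re-deriving anything from pixels,
# and is bit-reproducible given (spec, seed).

#' Evaluate code with a fixed RNG seed, restoring the caller's RNG state
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Specification of a synthetic scene
#'
#' Parameters of the planted world: lattice geometry, intensity levels,
#' pixel noise and (for cell scenes) per-spot cell placement. Intensities
#' are generated in \[0, 1\]; writers quantize to 16-bit on export.
#'
#' @param rows,cols lattice element counts
#' @param pitch_x,pitch_y lattice pitch in pixels; must exceed
#'   `2 * spot_radius` so spots do not overlap
#' @param origin_x,origin_y optional center of element (0, 0) before
#'   rotation; `NA` (default) centers the lattice in an automatically
#'   sized image
#' @param rotation_deg grid rotation, degrees, counter-clockwise positive,
#'   applied about the image center before noise
#' @param spot_radius spot radius in pixels
#' @param background_level,spot_level background and spot intensities in
#'   \[0, 1\] (grid scenes)
#' @param noise_sigma standard deviation of additive Gaussian pixel noise
#' @param cells_per_spot number of cells planted per spot (cell scenes)
#' @param alive_fraction planted fraction of live cells in \[0, 1\]; the
#'   live count is `round(alive_fraction * n_cells)` so planted fractions
#'   are recovered exactly
#' @param cell_radius_range two-element range of cell radii in pixels
#' @param faint_calcein_prob probability that a planted dead cell also
#'   shows a faint Calcein signal (dying cells can stain faintly for
#'   Calcein while already PI positive); default 0
#' @param margin extra background margin around the outermost spot edge,
#'   pixels
#' @param seed integer RNG seed; identical (spec, seed) gives bit-identical
#'   scenes
#' @return object of class `scene_spec`
#' @export
scene_spec <- function(rows = 4, cols = 6, pitch_x = 32, pitch_y = 32,
                       origin_x = NA, origin_y = NA, rotation_deg = 0,
                       spot_radius = 10, background_level = 0.1,
                       spot_level = 0.8, noise_sigma = 0.02,
                       cells_per_spot = 0, alive_fraction = 1,
                       cell_radius_range = c(3, 4),
                       faint_calcein_prob = 0, margin = 6, seed = 1L) {
  if (!(pitch_x > 2 * spot_radius && pitch_y > 2 * spot_radius))
    stop("pitch must exceed 2 * spot_radius (non-overlapping spots)",
         call. = FALSE)
  if (alive_fraction < 0 || alive_fraction > 1)
    stop("alive_fraction must lie in [0, 1]", call. = FALSE)
  if (cells_per_spot < 0) stop("cells_per_spot must be >= 0", call. = FALSE)
  stopifnot(length(cell_radius_range) == 2,
            cell_radius_range[1] <= cell_radius_range[2],
            cell_radius_range[1] > 0)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 pitch_x = pitch_x, pitch_y = pitch_y,
                 origin_x = origin_x, origin_y = origin_y,
                 rotation_deg = rotation_deg, spot_radius = spot_radius,
                 background_level = background_level, spot_level = spot_level,
                 noise_sigma = noise_sigma,
                 cells_per_spot = as.integer(cells_per_spot),
                 alive_fraction = alive_fraction,
                 cell_radius_range = cell_radius_range,
                 faint_calcein_prob = faint_calcein_prob,
                 margin = margin, seed = as.integer(seed)),
            class = "scene_spec")
}

# Planted lattice geometry: image size, rotated centers and the truth grid.
# Auto-sizing rotates about the image center; a user-supplied origin is
# honored before rotation and bound-checked afterwards.
scene_geometry <- function(spec) {
  Lx <- (spec$cols - 1) * spec$pitch_x
  Ly <- (spec$rows - 1) * spec$pitch_y
  pad <- spec$spot_radius + spec$margin
  th <- abs(spec$rotation_deg) * pi / 180
  if (is.na(spec$origin_x) || is.na(spec$origin_y)) {
    hx <- (cos(th) * Lx + sin(th) * Ly) / 2
    hy <- (sin(th) * Lx + cos(th) * Ly) / 2
    W <- ceiling(2 * (hx + pad)) + 1L
    H <- ceiling(2 * (hy + pad)) + 1L
  } else {
    W <- ceiling(spec$origin_x + Lx + pad) + 1L
    H <- ceiling(spec$origin_y + Ly + pad) + 1L
  }
  if (W > 8192 || H > 8192)
    stop(sprintf(
      "lattice does not fit a representable image: %d x %d exceeds the 8192 px bound",
      H, W), call. = FALSE)
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  if (is.na(spec$origin_x) || is.na(spec$origin_y)) {
    base_x <- cx - Lx / 2; base_y <- cy - Ly / 2
  } else {
    base_x <- spec$origin_x; base_y <- spec$origin_y
  }
  g <- expand.grid(j = seq_len(spec$cols) - 1L, i = seq_len(spec$rows) - 1L)
  ux <- base_x + g$j * spec$pitch_x - cx
  uy <- base_y + g$i * spec$pitch_y - cy
  R <- rotation_matrix(spec$rotation_deg)
  xy <- cbind(ux, uy) %*% t(R)
  centers <- data.frame(i = g$i, j = g$j, x = cx + xy[, 1], y = cy + xy[, 2])
  inside <- centers$x >= 0 & centers$x <= W - 1 &
    centers$y >= 0 & centers$y <= H - 1
  if (!all(inside)) {
    k <- which(!inside)[1]
    stop(sprintf(
      "planted center (%d, %d) falls outside the %d x %d image; violated bound: 0 <= x <= %d, 0 <= y <= %d",
      centers$i[k], centers$j[k], H, W, W - 1, H - 1), call. = FALSE)
  }
  truth <- grid_model(spec$rows, spec$cols, centers$x[1], centers$y[1],
                      spec$pitch_x, spec$pitch_y, spec$rotation_deg,
                      spec$spot_radius)
  list(W = W, H = H, centers = centers, truth = truth)
}

# Paint `value` on the disc of `radius` about (cx, cy); optionally record
# label `lab` in `labels`. Returns list(image, labels).
paint_disc <- function(image, cx, cy, radius, value, labels = NULL, lab = 0L) {
  h <- nrow(image); w <- ncol(image)
  x0 <- max(0L, floor(cx - radius)); x1 <- min(w - 1L, ceiling(cx + radius))
  y0 <- max(0L, floor(cy - radius)); y1 <- min(h - 1L, ceiling(cy + radius))
  xs <- x0:x1; ys <- y0:y1
  dx2 <- (xs - cx)^2; dy2 <- (ys - cy)^2
  m <- outer(dy2, dx2, "+") <= radius^2
  sub <- image[ys + 1L, xs + 1L, drop = FALSE]
  sub[m] <- value
  image[ys + 1L, xs + 1L] <- sub
  if (!is.null(labels)) {
    lsub <- labels[ys + 1L, xs + 1L, drop = FALSE]
    lsub[m] <- lab
    labels[ys + 1L, xs + 1L] <- lsub
  }
  list(image = image, labels = labels)
}

new_scene <- function(images, truth_grid, truth_instances = list(),
                      truth_status = NULL, truth_values = NULL,
                      rgb = NULL, spec = NULL) {
  structure(list(images = images, rgb = rgb, truth_grid = truth_grid,
                 truth_instances = truth_instances,
                 truth_status = truth_status, truth_values = truth_values,
                 spec = spec, seed = spec$seed),
            class = "gridspot_scene")
}

#' @export
print.gridspot_scene <- function(x, ...) {
  ch <- names(x$images)
  cat(sprintf("gridspot_scene: %d x %d grid, channels: %s%s\n",
              x$truth_grid$rows, x$truth_grid$cols,
              if (length(ch)) paste(ch, collapse = ", ") else "none",
              if (!is.null(x$rgb)) " + rgb" else ""))
  invisible(x)
}

#' Generate a synthetic grid scene
#'
#' A single-channel image of `rows x cols` bright discs on a darker
#' background, rotated about the image center, with additive Gaussian pixel
#' noise clipped to \[0, 1\]. The exact planted [grid_model] is recorded as
#' `truth_grid` and the planted discs as a label raster in
#' `truth_instances$grid` (row-major labels 1..N).
#'
#' @param spec a [scene_spec]
#' @return a `gridspot_scene`
#' @export
generate_grid_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  geo <- scene_geometry(spec)
  with_seed(spec$seed, {
    img <- matrix(spec$background_level, geo$H, geo$W)
    labs <- matrix(0L, geo$H, geo$W)
    for (k in seq_len(nrow(geo$centers))) {
      p <- paint_disc(img, geo$centers$x[k], geo$centers$y[k],
                      spec$spot_radius, spec$spot_level, labs, k)
      img <- p$image; labs <- p$labels
    }
    if (spec$noise_sigma > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, spec$noise_sigma),
                          nrow(img))
    img <- pmin(pmax(img, 0), 1)
    new_scene(list(grid = img), geo$truth, list(grid = labs), spec = spec)
  })
}

# Place cells_per_spot non-overlapping cells inside one spot disc.
place_cells_in_spot <- function(spot, spec, retry_budget = 200L) {
  n <- spec$cells_per_spot
  xs <- numeric(0); ys <- numeric(0); rs <- numeric(0)
  rr <- spec$cell_radius_range
  for (k in seq_len(n)) {
    placed <- FALSE
    for (t in seq_len(retry_budget)) {
      r <- stats::runif(1, rr[1], rr[2])
      rho <- (spec$spot_radius - r - 1) * sqrt(stats::runif(1))
      phi <- stats::runif(1, 0, 2 * pi)
      x <- spot$x + rho * cos(phi); y <- spot$y + rho * sin(phi)
      if (length(xs) == 0 ||
          all((xs - x)^2 + (ys - y)^2 >= (rs + r + 2)^2)) {
        xs <- c(xs, x); ys <- c(ys, y); rs <- c(rs, r)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop(sprintf(
        "could not place %d non-overlapping cells in spot (%d, %d) within %d retries",
        n, spot$i, spot$j, retry_budget), call. = FALSE)
  }
  data.frame(x = xs, y = ys, radius = rs)
}

# Gaussian-shaded disc: amp * exp(-d^2 / (2 sigma^2)) for d <= radius, with
# sigma chosen so the profile at the mask edge equals EDGE_FRACTION * amp.
# The hard support keeps planted cells separable by any global threshold.
EDGE_FRACTION <- 0.2

paint_cell <- function(image, cx, cy, radius, amp) {
  sigma <- radius / sqrt(2 * log(1 / EDGE_FRACTION))
  h <- nrow(image); w <- ncol(image)
  x0 <- max(0L, floor(cx - radius)); x1 <- min(w - 1L, ceiling(cx + radius))
  y0 <- max(0L, floor(cy - radius)); y1 <- min(h - 1L, ceiling(cy + radius))
  xs <- x0:x1; ys <- y0:y1
  d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
  prof <- amp * exp(-d2 / (2 * sigma^2))
  prof[d2 > radius^2] <- 0
  image[ys + 1L, xs + 1L] <- pmax(image[ys + 1L, xs + 1L], prof)
  image
}

#' Generate a synthetic three-channel cell scene
#'
#' Emulates a stained live/dead viability acquisition: channels `hoechst`
#' (nuclear stain, every cell), `calcein` (live cells; dead cells join
#' faintly with probability `faint_calcein_prob`) and `pi` (dead cells).
#' Cells are Gaussian-shaded discs placed without overlap inside each spot.
#' `truth_status` records the planted per-cell assignment, and
#' `truth_instances` one label raster per channel (consecutive labels in
#' placement order).
#'
#' @param spec a [scene_spec] with `cells_per_spot >= 1`
#' @return a `gridspot_scene`
#' @export
generate_cell_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  geo <- scene_geometry(spec)
  with_seed(spec$seed, {
    cells <- do.call(rbind, lapply(seq_len(nrow(geo$centers)), function(k) {
      spot <- geo$centers[k, ]
      if (spec$cells_per_spot == 0) return(NULL)
      d <- place_cells_in_spot(spot, spec)
      d$spot_i <- spot$i; d$spot_j <- spot$j
      d
    }))
    n <- if (is.null(cells)) 0L else nrow(cells)
    chans <- list(hoechst = matrix(0, geo$H, geo$W),
                  calcein = matrix(0, geo$H, geo$W),
                  pi = matrix(0, geo$H, geo$W))
    inst <- list(hoechst = matrix(0L, geo$H, geo$W),
                 calcein = matrix(0L, geo$H, geo$W),
                 pi = matrix(0L, geo$H, geo$W))
    status <- NULL
    if (n > 0) {
      n_alive <- round(spec$alive_fraction * n)
      alive <- rep(FALSE, n)
      alive[sample.int(n, n_alive)] <- TRUE
      faint <- !alive & stats::runif(n) < spec$faint_calcein_prob
      amp_h <- stats::runif(n, 0.6, 1.0)
      amp_c <- stats::runif(n, 0.6, 1.0)
      amp_p <- stats::runif(n, 0.6, 1.0)
      status <- data.frame(cell_id = seq_len(n),
                           spot_i = cells$spot_i, spot_j = cells$spot_j,
                           x = cells$x, y = cells$y, radius = cells$radius,
                           hoechst_positive = TRUE,
                           calcein_positive = alive | faint,
                           pi_positive = !alive,
                           alive = alive)
      nxt <- c(hoechst = 0L, calcein = 0L, pi = 0L)
      for (k in seq_len(n)) {
        chans$hoechst <- paint_cell(chans$hoechst, cells$x[k], cells$y[k],
                                    cells$radius[k], amp_h[k])
        nxt["hoechst"] <- nxt["hoechst"] + 1L
        inst$hoechst <- paint_disc(inst$hoechst * 1.0, cells$x[k], cells$y[k],
                                   cells$radius[k], nxt["hoechst"])$image
        if (alive[k] || faint[k]) {
          amp <- if (alive[k]) amp_c[k] else 0.15
          chans$calcein <- paint_cell(chans$calcein, cells$x[k], cells$y[k],
                                      cells$radius[k], amp)
          nxt["calcein"] <- nxt["calcein"] + 1L
          inst$calcein <- paint_disc(inst$calcein * 1.0, cells$x[k], cells$y[k],
                                     cells$radius[k], nxt["calcein"])$image
        }
        if (!alive[k]) {
          chans$pi <- paint_cell(chans$pi, cells$x[k], cells$y[k],
                                 cells$radius[k], amp_p[k])
          nxt["pi"] <- nxt["pi"] + 1L
          inst$pi <- paint_disc(inst$pi * 1.0, cells$x[k], cells$y[k],
                                cells$radius[k], nxt["pi"])$image
        }
      }
      inst <- lapply(inst, function(m) { storage.mode(m) <- "integer"; m })
    }
    if (spec$noise_sigma > 0)
      chans <- lapply(chans, function(m)
        pmin(pmax(m + matrix(stats::rnorm(length(m), 0, spec$noise_sigma),
                             nrow(m)), 0), 1))
    new_scene(chans, geo$truth, inst, truth_status = status, spec = spec)
  })
}

#' Linear single-channel color model
#'
#' Maps a latent value in \[0, 1\] to RGB by moving one channel linearly
#' from `lo` to `hi` while holding the other two at `others`. Monotone in
#' the selected channel by construction.
#'
#' @param channel one of "R", "G", "B"
#' @param lo,hi channel intensity at latent 0 and 1
#' @param others constant intensity of the remaining channels
#' @return function mapping a latent vector to an n x 3 RGB matrix
#' @export
color_model_channel <- function(channel = "R", lo = 0.1, hi = 0.9,
                                others = 0.4) {
  ci <- match(channel, c("R", "G", "B"))
  if (is.na(ci)) stop("channel must be one of R, G, B", call. = FALSE)
  function(latent) {
    out <- matrix(others, length(latent), 3)
    out[, ci] <- lo + (hi - lo) * latent
    out
  }
}

#' Generate a synthetic colorimetric scanner scene
#'
#' An RGB image where each spot's interior color is `color_model(latent)`
#' plus i.i.d. Gaussian pixel noise, on a light-grey background. The latent
#' per-spot values are recorded in `truth_values`.
#'
#' @param spec a [scene_spec]
#' @param value_map `rows x cols` matrix of latent scalars (one per spot)
#' @param color_model function mapping a latent vector to an n x 3 RGB
#'   matrix, monotone in at least one channel; see [color_model_channel()]
#' @param noise_sigma pixel noise standard deviation (defaults to
#'   `spec$noise_sigma`)
#' @return a `gridspot_scene` with the RGB raster in `$rgb`
#' @export
generate_colorimetric_scene <- function(spec, value_map,
                                        color_model = color_model_channel(),
                                        noise_sigma = spec$noise_sigma) {
  stopifnot(inherits(spec, "scene_spec"))
  value_map <- as.matrix(value_map)
  if (!all(dim(value_map) == c(spec$rows, spec$cols)))
    stop(sprintf("value_map must be %d x %d, got %d x %d",
                 spec$rows, spec$cols, nrow(value_map), ncol(value_map)),
         call. = FALSE)
  geo <- scene_geometry(spec)
  with_seed(spec$seed, {
    rgb <- array(0.85, dim = c(geo$H, geo$W, 3))
    labs <- matrix(0L, geo$H, geo$W)
    cols3 <- color_model(as.vector(t(value_map)))  # row-major spot order
    if (!is.matrix(cols3) || ncol(cols3) != 3)
      stop("color_model must return an n x 3 RGB matrix", call. = FALSE)
    for (k in seq_len(nrow(geo$centers))) {
      for (c in 1:3) {
        p <- paint_disc(rgb[, , c], geo$centers$x[k], geo$centers$y[k],
                        spec$spot_radius, cols3[k, c])
        rgb[, , c] <- p$image
      }
      labs <- paint_disc(labs * 1.0, geo$centers$x[k], geo$centers$y[k],
                         spec$spot_radius, k)$image
    }
    if (noise_sigma > 0)
      rgb <- rgb + array(stats::rnorm(length(rgb), 0, noise_sigma), dim(rgb))
    rgb <- pmin(pmax(rgb, 0), 1)
    storage.mode(labs) <- "integer"
    new_scene(list(), geo$truth, list(spots = labs),
              truth_values = value_map, rgb = rgb, spec = spec)
  })
}
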