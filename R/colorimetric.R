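# Colorimetric analysis: scalarize an RGB scanner image, aggregate per
# spot, and calibrate the per-spot metric against known values with a
# monotone map.

#' Construct a color transform
#'
#' A transform converts an RGB pixel into a scalar used to quantify spot
#' color. Registered families:
#' \describe{
#'   \item{luminance}{Rec. 709 luminance 0.2126 R + 0.7152 G + 0.0722 B}
#'   \item{channel}{a single channel, parameter `channel` in R/G/B}
#'   \item{linear}{`w_r R + w_g G + w_b B`, parameter `weights`}
#'   \item{hue}{HSV hue in degrees \[0, 360); 0 for achromatic pixels}
#' }
#'
#' @param name transform family name
#' @param channel channel for `"channel"`
#' @param weights length-3 numeric for `"linear"`
#' @return object of class `color_transform`
#' @export
color_transform <- function(name = c("luminance", "channel", "linear", "hue"),
                            channel = "R", weights = c(1, 0, 0)) {
  registry <- c("luminance", "channel", "linear", "hue")
  if (!is.character(name) || !(name[1] %in% registry))
    stop("unknown transform; registry: ", paste(registry, collapse = ", "),
         call. = FALSE)
  name <- name[1]
  if (name == "channel" && !(channel %in% c("R", "G", "B")))
    stop("channel must be one of R, G, B", call. = FALSE)
  if (name == "linear" && (length(weights) != 3 || any(!is.finite(weights))))
    stop("linear weights must be 3 finite numbers", call. = FALSE)
  structure(list(name = name, channel = channel, weights = weights),
            class = "color_transform")
}

#' Apply a color transform to an RGB raster
#'
#' @param rgb h x w x 3 array (planes R, G, B)
#' @param t a [color_transform] (or a family name passed through)
#' @return scalar raster
#' @export
apply_transform <- function(rgb, t = color_transform("luminance")) {
  if (is.character(t)) t <- color_transform(t)
  if (length(dim(rgb)) != 3 || dim(rgb)[3] != 3)
    stop("rgb must be an h x w x 3 array", call. = FALSE)
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  R <- matrix(rgb[, , 1], h, w)
  G <- matrix(rgb[, , 2], h, w)
  B <- matrix(rgb[, , 3], h, w)
  switch(t$name,
    luminance = 0.2126 * R + 0.7152 * G + 0.0722 * B,
    channel = switch(t$channel, R = R, G = G, B = B),
    linear = t$weights[1] * R + t$weights[2] * G + t$weights[3] * B,
    hue = {
      mx <- pmax(R, G, B); mn <- pmin(R, G, B)
      d <- mx - mn
      hdeg <- matrix(0, nrow(R), ncol(R))
      iR <- d > 0 & mx == R
      iG <- d > 0 & mx == G & !iR
      iB <- d > 0 & mx == B & !iR & !iG
      hdeg[iR] <- 60 * (((G - B)[iR] / d[iR]) %% 6)
      hdeg[iG] <- 60 * ((B - R)[iG] / d[iG] + 2)
      hdeg[iB] <- 60 * ((R - G)[iB] / d[iB] + 4)
      hdeg %% 360
    })
}

#' Quantify spots from a scalar raster
#'
#' Aggregates the scalar raster over each spot ROI's disc mask. Spots
#' whose mask is fully clipped out of the image report a missing value.
#' The median aggregator (default) is robust to spot-edge artifacts.
#'
#' @param scalar scalar raster (see [apply_transform()])
#' @param rois ROI list from [extract_rois()]
#' @param aggregator `"median"` or `"mean"`
#' @return data.frame of class `spot_quantification`: columns `i`, `j`,
#'   `y_hat`; aggregator recorded as an attribute
#' @export
quantify_spots <- function(scalar, rois, aggregator = c("median", "mean")) {
  assert_raster(scalar)
  aggregator <- match.arg(aggregator)
  agg <- if (aggregator == "median") median else mean
  out <- data.frame(
    i = vapply(rois, `[[`, numeric(1), "i"),
    j = vapply(rois, `[[`, numeric(1), "j"),
    y_hat = vapply(rois, function(r) {
      px <- roi_pixels(scalar, r)
      if (length(px) == 0) NA_real_ else agg(px)
    }, numeric(1)))
  attr(out, "aggregator") <- aggregator
  class(out) <- c("spot_quantification", "data.frame")
  out
}

#' Calibrate spot quantifications against known values
#'
#' Pearson correlation between the per-spot metric and the known truth,
#' plus a monotone piecewise-linear map from metric to calibrated value
#' fitted by isotonic regression (direction chosen by the sign of the
#' correlation), so differently scaled metrics can be converted into each
#' other via a calibration measurement.
#'
#' @param q a `spot_quantification` (or data.frame with `i`, `j`,
#'   `y_hat`)
#' @param truth `rows x cols` matrix of known values, or a data.frame
#'   with columns `i`, `j`, `value`
#' @return list of class `calibration_result`: `pearson_r`, `map`
#'   (data.frame `x`, `y` of knots), `n`, `direction`; use
#'   [predict_calibration()] to apply the map
#' @export
calibrate <- function(q, truth) {
  if (is.matrix(truth)) {
    truth <- data.frame(i = rep(seq_len(nrow(truth)) - 1L, each = ncol(truth)),
                        j = rep(seq_len(ncol(truth)) - 1L, nrow(truth)),
                        value = as.vector(t(truth)))
  }
  m <- merge(as.data.frame(q), truth, by = c("i", "j"))
  m <- m[is.finite(m$y_hat) & is.finite(m$value), , drop = FALSE]
  if (nrow(m) < 3)
    stop("calibration needs at least 3 paired non-missing points",
         call. = FALSE)
  if (sd(m$value) == 0 || sd(m$y_hat) == 0)
    stop("calibration requires non-constant metric and truth values",
         call. = FALSE)
  r <- cor(m$y_hat, m$value)
  direction <- if (r >= 0) "increasing" else "decreasing"
  o <- order(m$y_hat)
  x <- m$y_hat[o]
  y <- if (direction == "increasing") m$value[o] else -m$value[o]
  iso <- isoreg(x, y)
  knots <- data.frame(x = x, y = iso$yf)
  if (direction == "decreasing") knots$y <- -knots$y
  knots <- knots[!duplicated(knots$x), , drop = FALSE]
  structure(list(pearson_r = r, map = knots, n = nrow(m),
                 direction = direction),
            class = "calibration_result")
}

#' Apply a fitted calibration map
#'
#' Piecewise-linear interpolation through the monotone knots; inputs
#' beyond the knot range are clamped to the end values.
#'
#' @param cal a `calibration_result`
#' @param y_hat metric values to convert
#' @return calibrated values
#' @export
predict_calibration <- function(cal, y_hat) {
  approx(cal$map$x, cal$map$y, xout = y_hat, rule = 2, ties = "ordered")$y
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("calibration_result: n = %d, pearson r = %.4f, %s map with %d knots\n",
              x$n, x$pearson_r, x$direction, nrow(x$map)))
  invisible(x)
}
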