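# Pipeline configuration and the full-run driver: grid detection -> ROI
# extraction -> per-spot processing (instances / viability / colorimetric),
# with every output written in a re-parseable plain format and a run log
# holding the fully resolved configuration.

default_config <- function() {
  list(
    seed = 1L,
    grid = list(p_low = 1, p_high = 99, method = "otsu", q = 90,
                open_radius = 1, area_band = c(0.3, 3),
                expected_shape = NULL),
    segment = list(h = 1, min_seed_distance = 3),
    viability = list(max_match_distance = NULL),
    colorimetric = list(transform = "luminance", channel = "R",
                        weights = c(1, 0, 0), aggregator = "median")
  )
}

merge_config <- function(defaults, user, path = "") {
  bad <- setdiff(names(user), names(defaults))
  if (length(bad))
    stop("unknown config key(s): ",
         paste0(path, bad, collapse = ", "), call. = FALSE)
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])))
      defaults[[k]] <- merge_config(defaults[[k]], as.list(user[[k]]),
                                    paste0(path, k, "."))
    else defaults[[k]] <- user[[k]]
  }
  defaults
}

#' Build a pipeline configuration
#'
#' Stage parameters for every module, merged over documented defaults.
#' Unknown keys are rejected before any computation. The fully resolved
#' configuration (defaults materialized) is what [run_pipeline()] writes
#' to the run log.
#'
#' @param config named list of overrides, or a path to a JSON config file
#'   with the same structure (namespaces `grid`, `segment`, `viability`,
#'   `colorimetric`, plus `seed`)
#' @return resolved configuration list of class `pipeline_config`
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- merge_config(default_config(), as.list(config))
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

resolve_input <- function(x, scale = TRUE) {
  if (is.character(x)) read_image(x, scale = scale) else x
}

#' Run the full image-processing pipeline
#'
#' Executes grid detection (or loads a supplied grid), extracts per-spot
#' ROIs and runs the per-spot stage selected by the inputs: three staining
#' channels trigger viability analysis, an RGB image triggers colorimetric
#' quantification, and a plain image triggers per-spot instance
#' segmentation with feature export. All outputs are plain CSV/JSON/TIFF,
#' and a `run_log.json` records the resolved configuration, seed, package
#' version, stage timings and any per-stage failures (partial results are
#' kept).
#'
#' @param config a [pipeline_config()] (or override list / JSON path)
#' @param inputs named list: `grid_image` (raster or path) and/or `grid`
#'   (a [grid_model] or grid JSON path); optionally `channels` (named
#'   list/paths `hoechst`, `calcein`, `pi`), `rgb` (array or path),
#'   `truth` (per-spot truth values for calibration)
#' @param out_dir output directory
#' @return list with the computed objects (`grid`, `rois`, and per mode
#'   `features` / `viability` / `quantification`, `calibration`),
#'   invisibly; files under `out_dir`
#' @export
run_pipeline <- function(config, inputs, out_dir) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list(config = unclass(config), seed = config$seed,
              package_version = as.character(packageVersion("gridspot")),
              stages = list(), failures = list())
  t0 <- proc.time()[["elapsed"]]
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    log$stages[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }
  result <- list()

  # --- grid stage
  if (!is.null(inputs[["grid"]])) {
    grid <- if (is.character(inputs[["grid"]])) read_grid_json(inputs[["grid"]])
            else inputs[["grid"]]
  } else {
    gi <- resolve_input(inputs[["grid_image"]])
    g <- config$grid
    grid <- detect_grid(gi, expected_shape = g$expected_shape,
                        p_low = g$p_low, p_high = g$p_high,
                        method = g$method, open_radius = g$open_radius,
                        area_band = g$area_band,
                        q = g$q)
  }
  result$grid <- grid
  write_grid_json(grid, file.path(out_dir, "grid.json"))
  tick("grid")

  ref_image <- if (!is.null(inputs[["channels"]]))
    resolve_input(inputs[["channels"]][[1]])
  else if (!is.null(inputs[["rgb"]])) {
    r <- resolve_input(inputs[["rgb"]]); r[, , 1]
  } else resolve_input(inputs[["grid_image"]])
  rois <- extract_rois(ref_image, grid)
  result$rois <- rois
  write_rois_csv(rois, file.path(out_dir, "rois.csv"))
  tick("rois")

  s <- config$segment
  if (!is.null(inputs[["channels"]])) {
    chans <- lapply(inputs[["channels"]], resolve_input)
    feats <- lapply(chans, function(ch) {
      f <- tryCatch(segment_instances(ch, s$h, s$min_seed_distance)$features,
                    error = function(e) {
                      log$failures[[length(log$failures) + 1]] <<-
                        list(stage = "segment", message = conditionMessage(e))
                      extract_features(matrix(0L, 1, 1))
                    })
      f
    })
    for (ch in names(feats))
      write_features_csv(feats[[ch]],
                         file.path(out_dir, paste0("features_", ch, ".csv")))
    cells <- classify_cells(feats$hoechst, feats$calcein, feats$pi,
                            config$viability$max_match_distance)
    via <- compute_viability(cells, grid)
    result$viability <- via
    result$cells <- cells
    write.csv(as.data.frame(cells), file.path(out_dir, "cell_status.csv"),
              row.names = FALSE)
    write.csv(data.frame(n_total = via$n_total, n_alive = via$n_alive,
                         viability = via$viability),
              file.path(out_dir, "viability.csv"), row.names = FALSE)
    if (!is.null(via$per_spot))
      write.csv(via$per_spot, file.path(out_dir, "per_spot_viability.csv"),
                row.names = FALSE)
    tick("viability")
  } else if (!is.null(inputs[["rgb"]])) {
    rgb <- resolve_input(inputs[["rgb"]])
    cc <- config$colorimetric
    tr <- color_transform(cc$transform, channel = cc$channel,
                          weights = cc$weights)
    scalar <- apply_transform(rgb, tr)
    q <- quantify_spots(scalar, rois, cc$aggregator)
    result$quantification <- q
    write.csv(as.data.frame(q), file.path(out_dir, "quantification.csv"),
              row.names = FALSE)
    qm <- matrix(NA_real_, grid$rows, grid$cols)
    qm[cbind(q$i + 1L, q$j + 1L)] <- q$y_hat
    write.csv(qm, file.path(out_dir, "quantification_matrix.csv"),
              row.names = FALSE)
    if (!is.null(inputs[["truth"]])) {
      cal <- calibrate(q, inputs[["truth"]])
      result$calibration <- cal
      jsonlite::write_json(list(pearson_r = cal$pearson_r, n = cal$n,
                                direction = cal$direction,
                                knots = cal$map),
                           file.path(out_dir, "calibration.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    tick("colorimetric")
  } else {
    img <- preprocess(resolve_input(inputs[["grid_image"]]),
                      config$grid$p_low, config$grid$p_high)
    feats <- list()
    for (roi in rois) {
      sub <- img[(roi$y0 + 1):roi$y1, (roi$x0 + 1):roi$x1, drop = FALSE]
      f <- tryCatch(segment_instances(sub, s$h, s$min_seed_distance)$features,
                    error = function(e) {
                      log$failures[[length(log$failures) + 1]] <<-
                        list(stage = "segment",
                             spot = c(roi$i, roi$j),
                             message = conditionMessage(e))
                      NULL
                    })
      if (!is.null(f) && nrow(f) > 0) {
        f$spot_i <- roi$i; f$spot_j <- roi$j
        f$x <- f$x + roi$x0; f$y <- f$y + roi$y0
        feats[[length(feats) + 1]] <- f
      }
    }
    feats <- if (length(feats)) do.call(rbind, feats) else
      extract_features(matrix(0L, 1, 1))
    result$features <- feats
    write.csv(feats, file.path(out_dir, "spot_features.csv"),
              row.names = FALSE)
    tick("segment")
  }
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(result)
}

#' Render a viability overlay image
#'
#' RGB overlay on the Hoechst channel: instance boundaries drawn per
#' channel (blue = Hoechst, green = Calcein, red = PI) and a green cross
#' on every cell classified alive.
#'
#' @param hoechst Hoechst raster (background of the overlay)
#' @param instances named list of instance maps (`hoechst`, `calcein`,
#'   `pi`), any subset
#' @param cells `cell_status` table from [classify_cells()]
#' @param path output image path (.png or .tif)
#' @return the path, invisibly
#' @export
render_viability_overlay <- function(hoechst, instances, cells, path) {
  h <- nrow(hoechst); w <- ncol(hoechst)
  rgb <- array(rep(pmin(pmax(hoechst, 0), 1), 3), c(h, w, 3))
  cols <- list(hoechst = c(0.3, 0.5, 1), calcein = c(0, 1, 0),
               pi = c(1, 0, 0))
  boundary <- function(lab) {
    b <- matrix(FALSE, h, w)
    for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)))
      b <- b | (lab != shift_mat(lab, sh[1], sh[2], 0L))
    b & lab > 0
  }
  for (ch in intersect(names(instances), names(cols))) {
    b <- boundary(instances[[ch]])
    for (c in 1:3) { p <- rgb[, , c]; p[b] <- cols[[ch]][c]; rgb[, , c] <- p }
  }
  alive <- cells[cells$alive, , drop = FALSE]
  for (k in seq_len(nrow(alive))) {
    x <- round(alive$x[k]) + 1L; y <- round(alive$y[k]) + 1L
    xs <- pmin(pmax((x - 2):(x + 2), 1), w)
    ys <- pmin(pmax((y - 2):(y + 2), 1), h)
    rgb[y, xs, ] <- rep(c(0, 1, 0), each = length(xs))
    rgb[ys, x, ] <- rep(c(0, 1, 0), each = length(ys))
  }
  write_image(rgb, path, bits = 8)
}
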