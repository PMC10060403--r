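# Live/dead viability fusion across the three staining channels. Hoechst
# anchors the total cell count; Calcein marks metabolically active cells
# and PI cells with a ruptured membrane. A cell counts as alive iff it is
# Calcein positive and PI negative.

#' Match instances across two staining channels
#'
#' Nearest-neighbour fusion made concrete as mutual nearest neighbours by
#' centroid distance: candidate pairs where each instance is the other's
#' nearest neighbour, pairs farther apart than `max_match_distance`
#' discarded, the rest accepted greedily in ascending distance with every
#' instance used at most once. Deterministic under input order (ties break
#' toward smaller indices).
#'
#' @param anchor,other feature data.frames with columns `id`, `x`, `y`
#'   (see [extract_features()])
#' @param max_match_distance distance cap in pixels (> 0)
#' @return data.frame with columns `anchor_id`, `other_id`, `distance`
#' @export
match_instances <- function(anchor, other, max_match_distance) {
  if (max_match_distance <= 0)
    stop("max_match_distance must be > 0", call. = FALSE)
  empty <- data.frame(anchor_id = integer(), other_id = integer(),
                      distance = numeric())
  if (nrow(anchor) == 0 || nrow(other) == 0) return(empty)
  d <- outer(anchor$x, other$x, "-")^2 + outer(anchor$y, other$y, "-")^2
  d <- sqrt(d)
  nn_a <- apply(d, 1, which.min)   # ties: smallest index
  nn_o <- apply(d, 2, which.min)
  ai <- which(nn_o[nn_a] == seq_len(nrow(anchor)))
  if (length(ai) == 0) return(empty)
  oi <- nn_a[ai]
  dist_ao <- d[cbind(ai, oi)]
  ok <- dist_ao <= max_match_distance
  ai <- ai[ok]; oi <- oi[ok]; dist_ao <- dist_ao[ok]
  ord <- order(dist_ao, ai, oi)
  used_a <- logical(nrow(anchor)); used_o <- logical(nrow(other))
  keep <- logical(length(ord))
  for (k in ord) {
    if (!used_a[ai[k]] && !used_o[oi[k]]) {
      keep[k] <- TRUE
      used_a[ai[k]] <- TRUE; used_o[oi[k]] <- TRUE
    }
  }
  res <- data.frame(anchor_id = anchor$id[ai[keep]],
                    other_id = other$id[oi[keep]],
                    distance = dist_ao[keep])
  res[order(res$anchor_id), , drop = FALSE]
}

#' Fuse per-channel instances into a per-cell status table
#'
#' Cells are anchored on Hoechst instances (the stain marking every cell).
#' Calcein and PI positivity require a matched instance in the respective
#' channel within `max_match_distance` (default: the median Hoechst
#' equivalent diameter). A cell is alive iff Calcein positive and PI
#' negative; faint-Calcein dying cells (matched in both) and Hoechst-only
#' inactive cells both count as not alive. Calcein/PI instances without a
#' Hoechst match are reported as anomalies, not as cells.
#'
#' @param hoechst,calcein,pi feature data.frames from [extract_features()]
#' @param max_match_distance matching cap in pixels; `NULL` for the
#'   default
#' @return data.frame of class `cell_status` with one row per Hoechst
#'   instance: `cell_id`, `x`, `y`, `hoechst_positive`,
#'   `calcein_positive`, `pi_positive`, `alive`, `calcein_id`, `pi_id`;
#'   unmatched non-anchor instances in `attr(, "anomalies")`
#' @export
classify_cells <- function(hoechst, calcein, pi, max_match_distance = NULL) {
  if (is.null(max_match_distance)) {
    max_match_distance <- if (nrow(hoechst) > 0)
      median(2 * sqrt(hoechst$area / base::pi)) else 1
  }
  mc <- match_instances(hoechst, calcein, max_match_distance)
  mp <- match_instances(hoechst, pi, max_match_distance)
  n <- nrow(hoechst)
  calcein_id <- rep(NA_integer_, n); pi_id <- rep(NA_integer_, n)
  calcein_id[match(mc$anchor_id, hoechst$id)] <- mc$other_id
  pi_id[match(mp$anchor_id, hoechst$id)] <- mp$other_id
  tab <- data.frame(cell_id = hoechst$id, x = hoechst$x, y = hoechst$y,
                    hoechst_positive = rep(TRUE, n),
                    calcein_positive = !is.na(calcein_id),
                    pi_positive = !is.na(pi_id),
                    alive = !is.na(calcein_id) & is.na(pi_id),
                    calcein_id = calcein_id, pi_id = pi_id)
  unmatched <- function(channel, ids, matched) {
    ids <- setdiff(ids, matched)
    data.frame(channel = rep(channel, length(ids)), id = ids)
  }
  anomalies <- rbind(unmatched("calcein", calcein$id, mc$other_id),
                     unmatched("pi", pi$id, mp$other_id))
  attr(tab, "anomalies") <- anomalies
  class(tab) <- c("cell_status", "data.frame")
  tab
}

#' Compute cellular viability from a cell status table
#'
#' Viability = alive cells / total (Hoechst-anchored) cells. With a
#' [grid_model], each cell is assigned to the spot ROI containing its
#' centroid and a per-spot breakdown is added; cells outside every spot go
#' to a discard bucket. An empty table yields an undefined viability
#' (`NA`), not 0.
#'
#' @param table a `cell_status` table from [classify_cells()]
#' @param grid optional [grid_model]
#' @return list of class `viability_result`: `n_total`, `n_alive`,
#'   `viability` (`NA_real_` when `n_total == 0`), and with a grid
#'   `per_spot` (data.frame i, j, n_total, n_alive, viability) plus
#'   `n_discarded`
#' @export
compute_viability <- function(table, grid = NULL) {
  n_total <- nrow(table)
  n_alive <- sum(table$alive)
  res <- list(n_total = n_total, n_alive = n_alive,
              viability = if (n_total > 0) n_alive / n_total else NA_real_)
  if (!is.null(grid) && n_total > 0) {
    ctr <- grid_centers(grid)
    d2 <- outer(table$x, ctr$x, "-")^2 + outer(table$y, ctr$y, "-")^2
    nearest <- apply(d2, 1, which.min)
    inside <- d2[cbind(seq_len(n_total), nearest)] <= grid$spot_radius^2
    spot <- ifelse(inside, nearest, NA_integer_)
    per <- data.frame(i = ctr$i, j = ctr$j, n_total = 0L, n_alive = 0L)
    tt <- tabulate(spot[!is.na(spot)], nbins = nrow(ctr))
    ta <- tabulate(spot[!is.na(spot) & table$alive], nbins = nrow(ctr))
    per$n_total <- tt; per$n_alive <- ta
    per$viability <- ifelse(per$n_total > 0, per$n_alive / per$n_total,
                            NA_real_)
    res$per_spot <- per
    res$n_discarded <- sum(is.na(spot))
  }
  structure(res, class = "viability_result")
}

#' @export
print.viability_result <- function(x, ...) {
  cat(sprintf("viability_result: %d cells, %d alive, viability = %s\n",
              x$n_total, x$n_alive,
              if (is.na(x$viability)) "undefined"
              else sprintf("%.4f", x$viability)))
  if (!is.null(x$per_spot))
    cat(sprintf("  per-spot breakdown over %d spots (%d cells discarded)\n",
                nrow(x$per_spot), x$n_discarded))
  invisible(x)
}

#' End-to-end viability analysis of three staining channels
#'
#' Segments each channel with the instance pipeline, fuses the channels
#' and computes viability.
#'
#' @param hoechst,calcein,pi channel rasters
#' @param grid optional [grid_model] for a per-spot breakdown
#' @param h,min_seed_distance watershed parameters
#' @param max_match_distance matching cap (NULL = default)
#' @return a `viability_result` with the `cell_status` table attached as
#'   `$cells`
#' @export
analyze_viability <- function(hoechst, calcein, pi, grid = NULL,
                              h = 1, min_seed_distance = 3,
                              max_match_distance = NULL) {
  fh <- segment_instances(hoechst, h, min_seed_distance)$features
  fc <- segment_instances(calcein, h, min_seed_distance)$features
  fp <- segment_instances(pi, h, min_seed_distance)$features
  cells <- classify_cells(fh, fc, fp, max_match_distance)
  res <- compute_viability(cells, grid)
  res$cells <- cells
  res
}
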