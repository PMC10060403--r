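# Independent oracles used across the suite. These deliberately reimplement
# (slowly, by enumeration) what the package computes by faster algorithms.

# Pure-R 4-connected component labeling by BFS, independent of the
# package's compiled labeling.
label_components_oracle <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  for (x in seq_len(w)) for (y in seq_len(h)) {
    if (!mask[y, x] || lab[y, x] > 0) next
    nxt <- nxt + 1L
    queue <- list(c(y, x)); lab[y, x] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ny <- p[1] + d[1]; nx <- p[2] + d[2]
        if (ny >= 1 && ny <= h && nx >= 1 && nx <= w &&
            mask[ny, nx] && lab[ny, nx] == 0) {
          lab[ny, nx] <- nxt
          queue[[length(queue) + 1]] <- c(ny, nx)
        }
      }
    }
  }
  lab
}

# All permutations of 1..n (n small).
perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  p <- perms(n - 1)
  out <- do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, matrix(ifelse(p >= k, p + 1, p), nrow(p)))
  }))
  dimnames(out) <- NULL
  out
}

# Exhaustive minimum-total-distance perfect matching between two equal-size
# point sets subject to a distance cap; returns NULL when no perfect
# matching within the cap exists, otherwise list(pairs, cost, unique).
exhaustive_min_matching <- function(a, b, cap) {
  n <- nrow(a)
  d <- sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2)
  pm <- perms(n)
  best <- Inf; best_perm <- NULL; n_best <- 0L
  for (r in seq_len(nrow(pm))) {
    pr <- pm[r, ]
    dd <- d[cbind(seq_len(n), pr)]
    if (any(dd > cap)) next
    tot <- sum(dd)
    if (tot < best - 1e-12) { best <- tot; best_perm <- pr; n_best <- 1L }
    else if (abs(tot - best) <= 1e-12) n_best <- n_best + 1L
  }
  if (is.null(best_perm)) return(NULL)
  list(perm = unname(best_perm), cost = best, unique = n_best == 1L)
}

# Exhaustive AJI+ over all one-to-one label assignments of a toy pair of
# instance maps.
aji_plus_oracle <- function(truth, pred) {
  tl <- sort(unique(truth[truth > 0]))
  pl <- sort(unique(pred[pred > 0]))
  if (length(tl) == 0 && length(pl) == 0) return(1)
  if (length(tl) == 0 || length(pl) == 0) return(0)
  n <- max(length(tl), length(pl))
  inter <- function(t, p) sum(truth == t & pred == p)
  area_t <- vapply(tl, function(t) sum(truth == t), numeric(1))
  area_p <- vapply(pl, function(p) sum(pred == p), numeric(1))
  pm <- perms(n)
  best <- -Inf
  for (r in seq_len(nrow(pm))) {
    num <- 0; den <- 0
    used_t <- logical(length(tl)); used_p <- logical(length(pl))
    for (ti in seq_len(n)) {
      pj <- pm[r, ti]
      if (ti <= length(tl) && pj <= length(pl)) {
        iv <- inter(tl[ti], pl[pj])
        if (iv > 0) {
          num <- num + iv
          den <- den + area_t[ti] + area_p[pj] - iv
          used_t[ti] <- TRUE; used_p[pj] <- TRUE
        }
      }
    }
    den <- den + sum(area_t[!used_t]) + sum(area_p[!used_p])
    sc <- if (den > 0) num / den else 1
    if (sc > best) best <- sc
  }
  best
}

# Small default scenes shared across tests.
small_grid_spec <- function(...) {
  args <- utils::modifyList(
    list(rows = 4, cols = 6, pitch_x = 32, pitch_y = 32,
         spot_radius = 10, noise_sigma = 0, seed = 11),
    list(...))
  do.call(scene_spec, args)
}

small_cell_spec <- function(...) {
  args <- utils::modifyList(
    list(rows = 2, cols = 2, pitch_x = 100, pitch_y = 100,
         spot_radius = 40, cells_per_spot = 25, alive_fraction = 0.75,
         noise_sigma = 0, seed = 5),
    list(...))
  do.call(scene_spec, args)
}
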