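# Independent oracles used across the suite. Each reimplements an operation
# by the most transparent route available (explicit loops, exhaustive
# search, breadth-first traversal) and must stay independent of the package
# code paths it checks.

# Breadth-first flood fill on a logical 3D mask, frontier-at-a-time.
bfs_flood_fill <- function(mask, seed, connectivity) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(a = -1:1, b = -1:1, c = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) {
    offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  }
  visited <- array(FALSE, d)
  if (!mask[seed[1], seed[2], seed[3]]) return(visited)
  frontier <- matrix(seed, ncol = 3)
  visited[frontier] <- TRUE
  while (nrow(frontier) > 0) {
    cand <- do.call(rbind, lapply(seq_len(nrow(offs)), function(i) {
      sweep(frontier, 2, offs[i, ], "+")
    }))
    ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
      cand[, 2] >= 1 & cand[, 2] <= d[2] &
      cand[, 3] >= 1 & cand[, 3] <= d[3]
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand) == 0) break
    keep <- mask[cand] & !visited[cand]
    cand <- unique(cand[keep, , drop = FALSE])
    if (nrow(cand) == 0) break
    visited[cand] <- TRUE
    frontier <- cand
  }
  visited
}

# Pearson r and two-sided t-based p, from explicit sums of products.
brute_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  r <- sxy / sqrt(sxx * syy)
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t_stat), df = n - 2))
}

# Otsu threshold by direct sweep over candidate thresholds.
brute_otsu <- function(img) {
  v <- as.vector(img)
  cands <- sort(unique(v))[-1]
  best_t <- NA_real_
  best_var <- -Inf
  for (t in cands) {
    lo <- v[v < t]; hi <- v[v >= t]
    w0 <- length(lo) / length(v)
    bc <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (bc > best_var) {
      best_var <- bc
      best_t <- t
    }
  }
  best_t
}

# Mean HU over a disc by looping every pixel of the slice.
brute_disc_mean <- function(slice_mat, center, radius) {
  acc <- c()
  for (r in seq_len(nrow(slice_mat))) {
    for (c in seq_len(ncol(slice_mat))) {
      if ((r - center[1])^2 + (c - center[2])^2 < radius^2) {
        acc <- c(acc, slice_mat[r, c])
      }
    }
  }
  mean(acc)
}

# Closed-form noiseless phantom HU at one voxel, recomputed from its index.
phantom_model_hu <- function(spec, i, j, k) {
  n_row <- spec$grid_shape[2]; n_col <- spec$grid_shape[3]
  cr <- (n_row + 1) / 2; cc <- (n_col + 1) / 2
  r <- sqrt(((j - cr) * spec$voxel_size)^2 + ((k - cc) * spec$voxel_size)^2)
  layer <- if (r < spec$lumen_radius) "lumen"
  else if (r < spec$intima_outer_radius) "intima"
  else if (r < spec$media_outer_radius) "media"
  else if (r < spec$adventitia_outer_radius) "adventitia"
  else "background"
  coll <- 0
  if (layer == "media") {
    t_med <- (r - spec$intima_outer_radius) /
      (spec$media_outer_radius - spec$intima_outer_radius)
    g <- spec$media_collagen_gradient
    coll <- g[1] + (g[2] - g[1]) * min(max(t_med, 0), 1)
  }
  unname(spec$layer_mean_hu[[layer]] + spec$hu_per_collagen * coll)
}

# A small noiseless phantom used widely below: media band 10 px thick.
tiny_spec <- function(...) {
  args <- utils::modifyList(
    list(grid_shape = c(6L, 40L, 40L), lumen_radius = 24,
         intima_outer_radius = 36, media_outer_radius = 96,
         adventitia_outer_radius = 108, noise_sigma = 0, blur_sigma = 0),
    list(...))
  do.call(phantom_spec, args)
}

# Disc-shaped tissue mask for synthetic histology sections.
disc_mask <- function(n, radius) {
  ctr <- (n + 1) / 2
  outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, `+`) < radius^2
}
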