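# Independent brute-force oracles used across the suite. These deliberately
# take the slow, direct route (double loops, recursion, closed forms) so they
# share no code path with the implementation they check.

# squared displacements of consecutive-frame pairs by explicit double loop
oracle_pooled_r2 <- function(tracks, min_len = 4) {
  out <- numeric(0)
  for (id in unique(tracks$track_id)) {
    t <- tracks[tracks$track_id == id, ]
    t <- t[order(t$frame), ]
    if (nrow(t) < min_len) next
    for (i in seq_len(nrow(t) - 1)) {
      if (t$frame[i + 1] - t$frame[i] == 1) {
        out <- c(out, (t$x_um[i + 1] - t$x_um[i])^2 +
                   (t$y_um[i + 1] - t$y_um[i])^2)
      }
    }
  }
  out
}

# stack-based flood fill at 4-connectivity from a seed pixel
oracle_flood_fill <- function(mask, seed_r, seed_c) {
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  if (!mask[seed_r, seed_c]) return(out)
  stack <- list(c(seed_r, seed_c))
  while (length(stack)) {
    p <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    r <- p[1]; c <- p[2]
    if (out[r, c]) next
    out[r, c] <- TRUE
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      r2 <- r + d[1]; c2 <- c + d[2]
      if (r2 >= 1 && r2 <= nrow(mask) && c2 >= 1 && c2 <= ncol(mask) &&
          mask[r2, c2] && !out[r2, c2])
        stack[[length(stack) + 1]] <- c(r2, c2)
    }
  }
  out
}

# exhaustive-search Otsu on a fixed histogram: try every cut, compute the
# two class weights/means directly
oracle_otsu <- function(x, nbins = 256) {
  edges <- seq(min(x), max(x), length.out = nbins + 1)
  bin <- findInterval(x, edges, rightmost.closed = TRUE)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  best <- -Inf; best_cut <- NA
  for (k in seq_len(nbins - 1)) {
    lo <- bin <= k; hi <- !lo
    if (!any(lo) || !any(hi)) next
    w0 <- mean(lo); w1 <- mean(hi)
    m0 <- mean(mids[bin[lo]]); m1 <- mean(mids[bin[hi]])
    bcv <- w0 * w1 * (m0 - m1)^2
    if (bcv > best) { best <- bcv; best_cut <- edges[k + 1] }
  }
  best_cut
}

# brute-force read-to-window assignment by scanning every window
oracle_assign <- function(reads, windows) {
  out <- rep(NA_character_, nrow(reads))
  for (i in seq_len(nrow(reads))) {
    pos <- if (reads$strand[i] == "+") reads$end[i] else reads$start[i]
    best_d <- Inf
    for (j in seq_len(nrow(windows))) {
      if (windows$contig[j] != reads$contig[i]) next
      if (windows$strand[j] != reads$strand[i]) next
      if (pos < windows$win_start[j] || pos > windows$win_end[j]) next
      d <- abs(pos - windows$end3[j])
      if (d < best_d) { best_d <- d; out[i] <- windows$gene_id[j] }
    }
  }
  out
}

# Yates-corrected chi-square statistic and p by the textbook closed form
oracle_yates <- function(a, b, c, d) {
  n <- a + b + c + d
  expected <- outer(c(a + b, c + d), c(a + c, b + d)) / n
  obs <- matrix(c(a, c, b, d), 2, 2)
  stat <- sum((abs(obs - expected) - 0.5)^2 / expected)
  list(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

# brute-force convex hull membership: a pixel is in the hull of P iff it is
# not strictly separable from P by any line through two points of P
oracle_hull_pixels <- function(rows, cols, dim_out) {
  pts <- unique(cbind(rows, cols))
  h <- grDevices::chull(pts[, 1], pts[, 2])
  hp <- pts[h, , drop = FALSE]
  out <- matrix(FALSE, dim_out[1], dim_out[2])
  for (r in seq_len(dim_out[1])) for (c in seq_len(dim_out[2])) {
    # point-in-polygon by winding of the hull polygon (with boundary)
    inside <- TRUE
    n <- nrow(hp)
    for (k in seq_len(n)) {
      k2 <- if (k == n) 1 else k + 1
      cr <- (hp[k2, 1] - hp[k, 1]) * (c - hp[k, 2]) -
        (hp[k2, 2] - hp[k, 2]) * (r - hp[k, 1])
      if (cr > 1e-9) { inside <- FALSE; break }
    }
    out[r, c] <- inside
  }
  out
}

# a tiny deterministic trajectory_set builder for focus-detection tests
make_cluster_tracks <- function(n_tracks, n_frames, center_px, pixel_size,
                                spread_px = 1.2, seed = 7) {
  set.seed(seed)
  tr <- do.call(rbind, lapply(seq_len(n_tracks), function(i) {
    data.frame(track_id = i, frame = seq_len(n_frames),
               x_um = (center_px + rnorm(n_frames, 0, spread_px)) * pixel_size,
               y_um = (center_px + rnorm(n_frames, 0, spread_px)) * pixel_size)
  }))
  structure(list(tracks = tr, frame_interval = 0.02), class = "trajectory_set")
}

# internal shape-metric access for oracle comparisons
region_shape_metrics_for_test <- function(lab)
  condensateR:::region_shape_metrics(lab)
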