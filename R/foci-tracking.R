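#' Rasterize localizations into a composite image
#'
#' Sums one count per localization into its containing pixel over all frames,
#' the composite in which stably bound molecules appear as bright foci. The
#' composite is normalized to `[0, 1]` so the blob-detection threshold is
#' scale-free.
#'
#' @param trajectory_set `trajectory_set` or tracks data.frame (x_um, y_um).
#' @param image_shape c(rows, cols) in pixels.
#' @param pixel_size pixel edge, um.
#' @return list: `composite` (matrix in `[0, 1]`), `counts` (raw matrix),
#'   `pixel_size`.
#' @export
rasterize_localizations <- function(trajectory_set, image_shape, pixel_size) {
  tr <- if (inherits(trajectory_set, "trajectory_set"))
    trajectory_set$tracks else trajectory_set
  counts <- matrix(0, image_shape[1], image_shape[2])
  if (!is.null(tr) && nrow(tr) > 0) {
    px <- floor(tr$x_um / pixel_size) + 1L
    py <- floor(tr$y_um / pixel_size) + 1L
    keep <- px >= 1 & px <= image_shape[1] & py >= 1 & py <= image_shape[2]
    tab <- table(factor(px[keep], levels = seq_len(image_shape[1])),
                 factor(py[keep], levels = seq_len(image_shape[2])))
    counts <- matrix(as.numeric(tab), image_shape[1], image_shape[2])
  }
  comp <- if (max(counts) > 0) counts / max(counts) else counts
  list(composite = comp, counts = counts, pixel_size = pixel_size)
}

#' Scale-normalized Laplacian-of-Gaussian blob detection
#'
#' Multiscale LoG: the image is Gaussian-smoothed at each scale, the negated
#' Laplacian response scaled by sigma^2, and blobs are local maxima of the
#' response over space and scale exceeding the threshold. Overlapping
#' detections are pruned keeping the stronger response. Blob radius follows
#' the sqrt(2) * sigma convention.
#'
#' @param image numeric matrix (expected in `[0, 1]`).
#' @param min_sigma,max_sigma scale range, px.
#' @param n_sigma number of scales.
#' @param threshold minimum scale-space response.
#' @return data.frame: row, col, sigma, radius, response.
#' @export
log_blob_detect <- function(image, min_sigma = 3, max_sigma = 5,
                            n_sigma = 5, threshold = 0.1) {
  sigmas <- seq(min_sigma, max_sigma, length.out = n_sigma)
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  nr <- nrow(image); nc <- ncol(image)
  cube <- array(0, c(nr, nc, length(sigmas)))
  for (s in seq_along(sigmas)) {
    sm <- as.matrix(EBImage::gblur(EBImage::Image(image), sigma = sigmas[s]))
    # -sigma^2 * Laplacian: bright blobs give positive response
    cube[, , s] <- -sigmas[s]^2 *
      as.matrix(EBImage::filter2(EBImage::Image(sm), lap))
  }
  hits <- which(cube > threshold, arr.ind = TRUE)
  if (nrow(hits) == 0)
    return(data.frame(row = numeric(0), col = numeric(0), sigma = numeric(0),
                      radius = numeric(0), response = numeric(0)))
  is_peak <- vapply(seq_len(nrow(hits)), function(i) {
    r <- hits[i, 1]; c <- hits[i, 2]; s <- hits[i, 3]
    v <- cube[r, c, s]
    nb <- cube[max(1, r - 1):min(nr, r + 1),
               max(1, c - 1):min(nc, c + 1),
               max(1, s - 1):min(length(sigmas), s + 1)]
    v >= max(nb)
  }, logical(1))
  pk <- hits[is_peak, , drop = FALSE]
  blobs <- data.frame(row = pk[, 1], col = pk[, 2],
                      sigma = sigmas[pk[, 3]],
                      radius = sigmas[pk[, 3]] * sqrt(2),
                      response = cube[pk])
  blobs <- blobs[order(-blobs$response), ]
  keep <- rep(TRUE, nrow(blobs))
  for (i in seq_len(nrow(blobs))) {
    if (!keep[i]) next
    if (i < nrow(blobs)) {
      j <- (i + 1):nrow(blobs)
      d <- sqrt((blobs$row[j] - blobs$row[i])^2 +
                  (blobs$col[j] - blobs$col[i])^2)
      keep[j][d < (blobs$radius[j] + blobs$radius[i]) / 2] <- FALSE
    }
  }
  blobs <- blobs[keep, ]
  rownames(blobs) <- NULL
  blobs
}

## pixel-support regions for blobs: all pixels within the blob radius of its
## center; contested pixels go to the nearest center
blob_regions <- function(blobs, image_shape) {
  lab <- matrix(0L, image_shape[1], image_shape[2])
  if (nrow(blobs) == 0) return(lab)
  best_d <- matrix(Inf, image_shape[1], image_shape[2])
  for (i in seq_len(nrow(blobs))) {
    r0 <- blobs$row[i]; c0 <- blobs$col[i]; rad <- blobs$radius[i]
    rr <- max(1, floor(r0 - rad)):min(image_shape[1], ceiling(r0 + rad))
    cc <- max(1, floor(c0 - rad)):min(image_shape[2], ceiling(c0 + rad))
    for (r in rr) for (c in cc) {
      d <- sqrt((r - r0)^2 + (c - c0)^2)
      if (d <= rad && d < best_d[r, c]) {
        best_d[r, c] <- d
        lab[r, c] <- i
      }
    }
  }
  lab
}

#' Detect stable foci from a trajectory composite
#'
#' Implements the stable-focus pipeline: rasterize all localizations to a
#' composite, blob-detect with the Laplacian of Gaussian (min_sigma = 3,
#' max_sigma = 5, threshold = 0.1), segment each blob to its pixel support,
#' and keep only regions supported by at least `min_tracks` trajectories of at
#' least `min_track_len` frames, each overlapping the region for at least
#' `min_overlap` of its localizations.
#'
#' @param trajectory_set a `trajectory_set`.
#' @param image_shape c(rows, cols), px.
#' @param pixel_size pixel edge, um.
#' @param min_sigma,max_sigma,threshold LoG parameters.
#' @param min_tracks,min_track_len,min_overlap stability filters.
#' @return list of class `focus_region_set`: `label` (pixel-support labelled
#'   matrix of kept regions), `regions` (data.frame: region, row, col, radius,
#'   area_px, n_supporting_tracks), `pixel_size`, `params`.
#' @export
detect_stable_foci <- function(trajectory_set, image_shape, pixel_size,
                               min_sigma = 3, max_sigma = 5, threshold = 0.1,
                               min_tracks = 10, min_track_len = 10,
                               min_overlap = 0.7) {
  ras <- rasterize_localizations(trajectory_set, image_shape, pixel_size)
  blobs <- log_blob_detect(ras$composite, min_sigma, max_sigma,
                           threshold = threshold)
  lab <- blob_regions(blobs, image_shape)
  tr <- trajectory_set$tracks
  kept <- integer(0)
  support <- integer(0)
  if (nrow(blobs) > 0 && !is.null(tr) && nrow(tr) > 0) {
    px <- floor(tr$x_um / pixel_size) + 1L
    py <- floor(tr$y_um / pixel_size) + 1L
    inb <- px >= 1 & px <= image_shape[1] & py >= 1 & py <= image_shape[2]
    reg <- integer(nrow(tr))
    reg[inb] <- lab[cbind(px[inb], py[inb])]
    len_by_track <- tapply(reg, tr$track_id, length)
    for (b in seq_len(nrow(blobs))) {
      ov <- tapply(reg == b, tr$track_id, mean)
      n_support <- sum(len_by_track >= min_track_len & ov >= min_overlap)
      if (n_support >= min_tracks) {
        kept <- c(kept, b)
        support <- c(support, n_support)
      }
    }
  }
  lab_kept <- matrix(0L, image_shape[1], image_shape[2])
  regions <- data.frame(region = integer(0), row = numeric(0),
                        col = numeric(0), radius = numeric(0),
                        area_px = integer(0), n_supporting_tracks = integer(0))
  for (i in seq_along(kept)) {
    lab_kept[lab == kept[i]] <- i
    regions <- rbind(regions, data.frame(
      region = i, row = blobs$row[kept[i]], col = blobs$col[kept[i]],
      radius = blobs$radius[kept[i]], area_px = sum(lab == kept[i]),
      n_supporting_tracks = support[i]))
  }
  structure(list(label = lab_kept, regions = regions, pixel_size = pixel_size,
                 params = list(min_sigma = min_sigma, max_sigma = max_sigma,
                               threshold = threshold, min_tracks = min_tracks,
                               min_track_len = min_track_len,
                               min_overlap = min_overlap)),
            class = "focus_region_set")
}

#' Classify a trajectory by its overlap with stable foci
#'
#' The overlap fraction is the share of the track's localizations whose pixel
#' falls inside any kept focus region. Labels: "In" when the whole track
#' overlaps, "InOut" for 25-99%, "Out" below 25%.
#'
#' @param track one track's data.frame (x_um, y_um).
#' @param regions a `focus_region_set` (empty regions give "Out").
#' @return list of class `overlap_class`: `label`, `overlap_fraction`.
#' @export
classify_trajectory <- function(track, regions) {
  lab <- regions$label
  if (is.null(lab) || max(lab) == 0 || nrow(track) == 0) {
    return(structure(list(label = "Out", overlap_fraction = 0),
                     class = "overlap_class"))
  }
  px <- floor(track$x_um / regions$pixel_size) + 1L
  py <- floor(track$y_um / regions$pixel_size) + 1L
  inb <- px >= 1 & px <= nrow(lab) & py >= 1 & py <= ncol(lab)
  inside <- logical(nrow(track))
  inside[inb] <- lab[cbind(px[inb], py[inb])] > 0L
  f <- mean(inside)
  label <- if (f >= 1) "In" else if (f >= 0.25) "InOut" else "Out"
  structure(list(label = label, overlap_fraction = f),
            class = "overlap_class")
}

#' Classify every trajectory of a set
#'
#' @param trajectory_set a `trajectory_set`.
#' @param regions a `focus_region_set`.
#' @return data.frame: track_id, label, overlap_fraction, n_frames.
#' @export
classify_trajectories <- function(trajectory_set, regions) {
  tr <- trajectory_set$tracks
  ids <- unique(tr$track_id)
  out <- lapply(split(tr, tr$track_id), function(t) {
    cl <- classify_trajectory(t, regions)
    data.frame(track_id = t$track_id[1], label = cl$label,
               overlap_fraction = cl$overlap_fraction, n_frames = nrow(t))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$track_id), ]
}
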