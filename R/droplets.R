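#' Canny edge detection
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression along the
#' quantized gradient direction, and hysteresis thresholding (weak edges are
#' kept only when 8-connected to a strong edge). Thresholds default to
#' automatic: the high threshold from an Otsu split of the nonzero gradient
#' magnitudes, the low threshold at half of it.
#'
#' @param image numeric matrix.
#' @param sigma Gaussian smoothing sd, px.
#' @param low,high hysteresis thresholds on gradient magnitude; NULL = auto.
#' @param min_high floor for the automatic high threshold; on a field with no
#'   true edges the Otsu split of noise gradients falls below this floor and
#'   no edges are reported.
#' @return logical matrix of edge pixels.
#' @export
canny_edges <- function(image, sigma = 1, low = NULL, high = NULL,
                        min_high = 0) {
  sm <- as.matrix(EBImage::gblur(EBImage::Image(image), sigma = sigma))
  # Sobel: kc varies across columns (d/dcol), its transpose across rows
  kc <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  gcol <- as.matrix(EBImage::filter2(EBImage::Image(sm), kc))
  grow <- as.matrix(EBImage::filter2(EBImage::Image(sm), t(kc)))
  gx <- grow; gy <- gcol   # (d/drow, d/dcol)
  mag <- sqrt(gx^2 + gy^2)
  nr <- nrow(mag); nc <- ncol(mag)
  if (is.null(high)) {
    nz <- mag[mag > 1e-12]
    high <- if (length(nz) > 1) otsu_threshold(nz) else Inf
    if (is.na(high)) high <- Inf
    high <- max(high, min_high)
  }
  if (is.null(low)) low <- high / 2
  # non-maximum suppression along the true gradient direction, magnitude
  # sampled by bilinear interpolation one pixel ahead and behind
  pad <- matrix(0, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mag
  safe_mag <- pmax(mag, 1e-30)
  ur <- gx / safe_mag; uc <- gy / safe_mag
  bilinear <- function(dr, dc) {
    r <- as.vector(row(mag) + 1 + dr)   # coordinates in the padded matrix
    c <- as.vector(col(mag) + 1 + dc)
    r0 <- pmin(pmax(floor(r), 1), nr + 1); c0 <- pmin(pmax(floor(c), 1), nc + 1)
    fr <- r - r0; fc <- c - c0
    v <- pad[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
      pad[cbind(r0 + 1, c0)] * fr * (1 - fc) +
      pad[cbind(r0, c0 + 1)] * (1 - fr) * fc +
      pad[cbind(r0 + 1, c0 + 1)] * fr * fc
    matrix(v, nr, nc)
  }
  nms <- mag >= bilinear(ur, uc) & mag >= bilinear(-ur, -uc) & mag > 1e-12
  strong <- nms & mag >= high
  weak <- nms & mag >= low
  if (!any(strong)) return(matrix(FALSE, nr, nc))
  comp <- label_components(weak, connectivity = 8)
  keep_ids <- unique(comp[strong])
  matrix(comp %in% setdiff(keep_ids, 0L), nr, nc)
}

## region shape metrics from a labelled matrix: pixel area, chain-code
## perimeter, moment-based axes/eccentricity, solidity and extent
region_shape_metrics <- function(lab) {
  ids <- seq_len(max(lab))
  out <- lapply(ids, function(k) {
    sel <- lab == k
    idx <- which(sel, arr.ind = TRUE)
    area <- nrow(idx)
    per <- chain_code_perimeter(sel)
    # central second moments (pixel-center convention with 1/12 correction
    # for the unit-square pixel support, matching moment-based axis lengths)
    mr <- mean(idx[, 1]); mc <- mean(idx[, 2])
    mrr <- mean((idx[, 1] - mr)^2) + 1 / 12
    mcc <- mean((idx[, 2] - mc)^2) + 1 / 12
    mrc <- mean((idx[, 1] - mr) * (idx[, 2] - mc))
    tr2 <- (mrr + mcc) / 2
    det <- sqrt(((mrr - mcc) / 2)^2 + mrc^2)
    l1 <- tr2 + det; l2 <- max(tr2 - det, 1e-12)
    major <- 4 * sqrt(l1); minor <- 4 * sqrt(l2)
    ecc <- sqrt(pmax(1 - l2 / l1, 0))
    hull <- rasterize_convex_hull(idx[, 1], idx[, 2], dim(lab))
    solidity <- area / sum(hull)
    bbox <- (diff(range(idx[, 1])) + 1) * (diff(range(idx[, 2])) + 1)
    data.frame(region = k, area_px = area, perimeter = per,
               circularity = 4 * pi * area / per^2,
               major_axis = major, minor_axis = minor,
               axis_ratio = major / minor, eccentricity = ecc,
               solidity = solidity, extent = area / bbox,
               row = mr, col = mc)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(region = integer(0), area_px = integer(0),
                      perimeter = numeric(0), circularity = numeric(0),
                      major_axis = numeric(0), minor_axis = numeric(0),
                      axis_ratio = numeric(0), eccentricity = numeric(0),
                      solidity = numeric(0), extent = numeric(0),
                      row = numeric(0), col = numeric(0))
  res
}

#' Segment droplet candidates in a micrograph
#'
#' The reconstitution pipeline: contrast-limited adaptive histogram
#' equalization, Gaussian blur, Canny edge detection, morphological closing
#' with a disk, filling of enclosed regions, and retention of regions of at
#' least `min_area` pixels. Shape metrics (area, chain-code perimeter,
#' circularity, axis lengths, eccentricity, solidity, extent) are attached to
#' every candidate.
#'
#' @param image single-channel numeric matrix.
#' @param min_area candidate area floor, px.
#' @param blur_sigma Gaussian blur sd, px.
#' @param canny_sigma Canny smoothing sd, px.
#' @param canny_min_high floor for the automatic Canny high threshold on the
#'   contrast-normalized image (separates true droplet edges from
#'   CLAHE-amplified noise gradients).
#' @param clahe_limit CLAHE clip limit (EBImage convention).
#' @param closing_radius disk radius for morphological closing, px.
#' @return list of class `droplet_candidates`: `candidates` (data.frame of
#'   shape metrics), `label` (labelled matrix).
#' @export
segment_droplets <- function(image, min_area = 150, blur_sigma = 2,
                             canny_sigma = 1, canny_min_high = 0.3,
                             clahe_limit = 2, closing_radius = 3) {
  rng <- range(image)
  norm <- if (diff(rng) > 0) (image - rng[1]) / diff(rng) else image * 0
  eq <- tryCatch(
    as.matrix(EBImage::clahe(EBImage::Image(norm), nx = 8, ny = 8,
                             limit = clahe_limit)),
    error = function(e) norm)
  sm <- as.matrix(EBImage::gblur(EBImage::Image(eq), sigma = blur_sigma))
  edges <- canny_edges(sm, sigma = canny_sigma, min_high = canny_min_high)
  brush <- EBImage::makeBrush(2 * closing_radius + 1, shape = "disc")
  closed <- as.matrix(EBImage::closing(EBImage::Image(edges * 1), brush))
  filled <- as.matrix(EBImage::fillHull(EBImage::Image(closed)))
  # droplets are the filled interiors; drop pure edge rings (no interior)
  interior <- filled > 0 & closed == 0
  lab_int <- label_components(interior, connectivity = 4)
  lab <- matrix(0L, nrow(image), ncol(image))
  nkeep <- 0L
  if (max(lab_int) > 0) {
    # re-attach the surrounding edge band to each interior region; several
    # interiors inside one filled component collapse to a single droplet
    full <- label_components(filled > 0, connectivity = 8)
    parents <- unique(unlist(lapply(seq_len(max(lab_int)), function(k)
      unique(full[lab_int == k]))))
    for (parent in setdiff(parents, 0L)) {
      sel <- full == parent
      if (sum(sel) >= min_area) {
        nkeep <- nkeep + 1L
        lab[sel] <- nkeep
      }
    }
  }
  metrics <- region_shape_metrics(lab)
  structure(list(candidates = metrics, label = lab), class = "droplet_candidates")
}

#' Apply the droplet shape filters
#'
#' A candidate passes iff circularity >= 0.4, major/minor axis ratio < 1.4,
#' eccentricity < 0.8, solidity > 0.9, and extent in (0.55, 0.95).
#'
#' @param candidates `droplet_candidates` or its metrics data.frame.
#' @return the metrics data.frame with a logical `accepted` column.
#' @export
filter_droplets <- function(candidates) {
  m <- if (inherits(candidates, "droplet_candidates")) candidates$candidates
  else candidates
  m$accepted <- m$circularity >= 0.4 &
    m$axis_ratio < 1.4 &
    m$eccentricity < 0.8 &
    m$solidity > 0.9 &
    m$extent > 0.55 & m$extent < 0.95
  m
}

#' Summarize accepted droplets of one imaging field
#'
#' @param filtered output of [filter_droplets()].
#' @param condition,field identifiers.
#' @return data.frame: condition, field, n_droplets, total_area_px.
#' @export
summarize_droplet_field <- function(filtered, condition, field) {
  acc <- filtered[filtered$accepted, , drop = FALSE]
  data.frame(condition = condition, field = field,
             n_droplets = nrow(acc), total_area_px = sum(acc$area_px))
}

#' Call phase separation per condition from field summaries
#'
#' Otsu thresholds are computed on the log10(x + 1)-scaled droplet counts and
#' total areas pooled over all imaging fields of all conditions; a condition
#' is called phase-separated iff the median of its fields exceeds either (or
#' both) threshold(s).
#'
#' @param summaries data.frame with condition, n_droplets, total_area_px
#'   (one row per field).
#' @return list of class `phase_diagram`: `calls` (data.frame: condition,
#'   median_log_count, median_log_area, phase_separated), `count_threshold`,
#'   `area_threshold` (log10 scale).
#' @export
call_phase_separation <- function(summaries) {
  lc <- log10(summaries$n_droplets + 1)
  la <- log10(summaries$total_area_px + 1)
  thr_c <- suppressWarnings(otsu_threshold(lc))
  thr_a <- suppressWarnings(otsu_threshold(la))
  if (is.na(thr_c) && is.na(thr_a))
    warning("degenerate field metrics: thresholds undefined, all calls negative")
  agg <- function(x) tapply(x, summaries$condition, stats::median)
  mc <- agg(lc); ma <- agg(la)
  calls <- data.frame(condition = names(mc),
                      median_log_count = as.numeric(mc),
                      median_log_area = as.numeric(ma))
  over_c <- if (is.na(thr_c)) rep(FALSE, nrow(calls)) else
    calls$median_log_count > thr_c
  over_a <- if (is.na(thr_a)) rep(FALSE, nrow(calls)) else
    calls$median_log_area > thr_a
  calls$phase_separated <- over_c | over_a
  rownames(calls) <- NULL
  structure(list(calls = calls, count_threshold = thr_c,
                 area_threshold = thr_a),
            class = "phase_diagram")
}
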