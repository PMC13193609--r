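#' Expand labelled cell masks by dilation and convex hull
#'
#' Each cell mask is dilated by `radius` pixels (Euclidean, via distance
#' transform) and replaced by the convex hull of the dilated support, defining
#' the final cell boundary used for within-cell statistics. Pixels claimed by
#' more than one expanded cell are assigned to the cell whose original
#' centroid is nearest.
#'
#' @param masks labelled integer matrix (0 background, k = cell k).
#' @param radius dilation radius, px.
#' @return list of class `cell_mask_set`: `original` (input), `expanded`
#'   (labelled matrix of final boundaries), `centroids` (data.frame).
#' @export
expand_cell_masks <- function(masks, radius = 4) {
  stopifnot(is.matrix(masks))
  labels <- sort(setdiff(unique(as.vector(masks)), 0L))
  d <- dim(masks)
  cents <- data.frame(cell = labels, row = NA_real_, col = NA_real_)
  claim <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    m <- masks == labels[i]
    idx <- which(m, arr.ind = TRUE)
    cents$row[i] <- mean(idx[, 1]); cents$col[i] <- mean(idx[, 2])
    # Euclidean dilation: distance-to-cell <= radius
    dist_to_cell <- as.matrix(EBImage::distmap(EBImage::Image(1 - m)))
    dil <- dist_to_cell <= radius
    hull_pts <- which(dil, arr.ind = TRUE)
    claim[[i]] <- rasterize_convex_hull(hull_pts[, 1], hull_pts[, 2], d)
  }
  expanded <- matrix(0L, d[1], d[2])
  best <- matrix(Inf, d[1], d[2])
  for (i in seq_along(labels)) {
    idx <- which(claim[[i]])
    rr <- (idx - 1L) %% d[1] + 1L
    cc <- (idx - 1L) %/% d[1] + 1L
    dist_c <- sqrt((rr - cents$row[i])^2 + (cc - cents$col[i])^2)
    take <- dist_c < best[idx]
    expanded[idx[take]] <- labels[i]
    best[idx[take]] <- dist_c[take]
  }
  # guarantee the original mask keeps its own label
  expanded[masks > 0L] <- masks[masks > 0L]
  structure(list(original = masks, expanded = expanded, centroids = cents,
                 radius = radius),
            class = "cell_mask_set")
}

#' Global robust focus-intensity threshold
#'
#' Threshold = median + `k_mad` * MAD of the within-cell pixel intensities,
#' pooled over all cells of the image. The MAD is raw (no normal-consistency
#' constant).
#'
#' @param image intensity matrix.
#' @param cell_masks a `cell_mask_set` or labelled matrix; within-cell pixels
#'   are those of the (expanded, if available) cell boundaries.
#' @param k_mad MAD multiplier.
#' @return scalar threshold.
#' @export
global_focus_threshold <- function(image, cell_masks, k_mad = 3.5) {
  lab <- if (inherits(cell_masks, "cell_mask_set")) cell_masks$expanded
  else cell_masks
  v <- image[lab > 0L]
  if (length(v) == 0) stop("no within-cell pixels")
  med <- stats::median(v)
  mad_raw <- stats::median(abs(v - med))
  med + k_mad * mad_raw
}

#' Call fluorescent foci in segmented cells
#'
#' Focal centers are local maxima (8-neighbourhood; a plateau pixel counts
#' when no neighbour is strictly greater) whose intensity strictly exceeds
#' the global threshold. Supra-threshold pixels are grown into regions by
#' orthogonal (4-)connectivity; a region is a focus iff it contains at least
#' one focal center and at least `min_area` pixels. Each focus is assigned to
#' the cell containing its centroid.
#'
#' @param image intensity matrix.
#' @param cell_masks `cell_mask_set` or labelled matrix.
#' @param threshold global threshold, e.g. from [global_focus_threshold()].
#' @param min_area minimum focus area, px.
#' @return list of class `focus_call_set`: `label` (labelled matrix of kept
#'   foci), `calls` (data.frame: focus, cell, area_px, mean_intensity,
#'   total_intensity, n_centers, row, col), `threshold`.
#' @export
call_foci <- function(image, cell_masks, threshold, min_area = 3) {
  lab_cells <- if (inherits(cell_masks, "cell_mask_set")) cell_masks$expanded
  else cell_masks
  supra <- image > threshold
  nr <- nrow(image); nc <- ncol(image)
  # strict local maxima with plateau handling (8-neighbourhood)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- image
  nbr_max <- matrix(-Inf, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nbr_max <- pmax(nbr_max, pad[2:(nr + 1) + dr, 2:(nc + 1) + dc])
  }
  centers <- supra & (image >= nbr_max)
  comp <- label_components(supra, connectivity = 4)
  keep <- integer(0)
  calls <- NULL
  if (max(comp) > 0) {
    for (k in seq_len(max(comp))) {
      in_k <- comp == k
      area <- sum(in_k)
      ncent <- sum(centers & in_k)
      if (area >= min_area && ncent >= 1) {
        keep <- c(keep, k)
        idx <- which(in_k, arr.ind = TRUE)
        crow <- mean(idx[, 1]); ccol <- mean(idx[, 2])
        cell <- lab_cells[round(crow), round(ccol)]
        calls <- rbind(calls, data.frame(
          focus = length(keep), cell = cell, area_px = area,
          mean_intensity = mean(image[in_k]),
          total_intensity = sum(image[in_k]),
          n_centers = ncent, row = crow, col = ccol))
      }
    }
  }
  lab_foci <- matrix(0L, nr, nc)
  for (i in seq_along(keep)) lab_foci[comp == keep[i]] <- i
  if (is.null(calls))
    calls <- data.frame(focus = integer(0), cell = integer(0),
                        area_px = integer(0), mean_intensity = numeric(0),
                        total_intensity = numeric(0), n_centers = integer(0),
                        row = numeric(0), col = numeric(0))
  structure(list(label = lab_foci, calls = calls, threshold = threshold),
            class = "focus_call_set")
}

#' Per-cell focus-to-background intensity ratio
#'
#' For each cell: mean intensity of the measurement channel over the cell's
#' focus pixels divided by its mean over the cell's non-focus pixels. The
#' measurement channel may differ from the channel in which foci were called
#' (cross-channel ratios). Background pixels are the cell's final (expanded)
#' boundary minus all focus pixels.
#'
#' @param image measurement-channel intensity matrix.
#' @param calls a `focus_call_set` (pixel support of the foci).
#' @param cell_masks `cell_mask_set` or labelled matrix.
#' @param log2_ratio return log2 of the ratio.
#' @return data.frame: cell, focus_mean, background_mean, ratio.
#' @export
focus_background_ratio <- function(image, calls, cell_masks,
                                   log2_ratio = FALSE) {
  lab_cells <- if (inherits(cell_masks, "cell_mask_set")) cell_masks$expanded
  else cell_masks
  foc <- calls$label > 0L
  cells <- sort(setdiff(unique(as.vector(lab_cells)), 0L))
  out <- lapply(cells, function(cl) {
    in_cell <- lab_cells == cl
    fpix <- in_cell & foc
    bpix <- in_cell & !foc
    if (sum(fpix) == 0) return(NULL)
    if (sum(bpix) == 0) stop("cell ", cl, " fully covered by foci")
    r <- mean(image[fpix]) / mean(image[bpix])
    data.frame(cell = cl, focus_mean = mean(image[fpix]),
               background_mean = mean(image[bpix]),
               ratio = if (log2_ratio) log2(r) else r)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(cell = integer(0), focus_mean = numeric(0),
                      background_mean = numeric(0), ratio = numeric(0))
  res
}

#' Per-cell Spearman colocalization with per-field mean
#'
#' Rank correlation of two aligned channels over each cell's pixels; the field
#' summary is the mean correlation across its cells. Cells in which either
#' channel is constant are excluded with a warning.
#'
#' @param channel_a,channel_b aligned intensity matrices.
#' @param cell_masks `cell_mask_set` or labelled matrix.
#' @return list: `per_cell` (data.frame: cell, rho, n_px), `field_mean`.
#' @export
colocalization_spearman <- function(channel_a, channel_b, cell_masks) {
  lab <- if (inherits(cell_masks, "cell_mask_set")) cell_masks$expanded
  else cell_masks
  cells <- sort(setdiff(unique(as.vector(lab)), 0L))
  rows <- lapply(cells, function(cl) {
    sel <- lab == cl
    a <- channel_a[sel]; b <- channel_b[sel]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      warning("cell ", cl, " has a constant channel; excluded")
      return(NULL)
    }
    data.frame(cell = cl, rho = stats::cor(a, b, method = "spearman"),
               n_px = sum(sel))
  })
  per_cell <- do.call(rbind, rows)
  if (is.null(per_cell))
    per_cell <- data.frame(cell = integer(0), rho = numeric(0),
                           n_px = integer(0))
  list(per_cell = per_cell,
       field_mean = if (nrow(per_cell)) mean(per_cell$rho) else NA_real_)
}

#' Fit a one-phase association curve to a FRAP trace
#'
#' `y(t) = baseline + (plateau - baseline) * (1 - exp(-k * t))`, with the
#' trace normalized so the pre-bleach mean is 1 and t = 0 at the bleach frame.
#' Reports the rate, its half-time `ln(2)/k`, the plateau (mobile-fraction
#' proxy) and normal-approximation 95% confidence intervals. Traces that do
#' not recover are flagged.
#'
#' @param time seconds, starting at 0 post-bleach.
#' @param intensity normalized intensities.
#' @return list of class `frap_fit`: `k` (1/s), `t_half` (s), `plateau`,
#'   `baseline`, `ci_k`, `ci_t_half`, `flagged`, `reason`.
#' @export
fit_frap <- function(time, intensity) {
  stopifnot(length(time) == length(intensity), length(time) >= 4)
  dat <- data.frame(t = time, y = intensity)
  y0 <- intensity[which.min(time)]
  pl0 <- max(stats::quantile(intensity, 0.9), y0 + 1e-3)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ b + (p - b) * (1 - exp(-k * t)), data = dat,
                      start = list(b = y0, p = pl0, k = 0.1),
                      lower = c(-Inf, -Inf, 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(k = NA_real_, t_half = NA_real_, plateau = NA_real_,
                          baseline = NA_real_, ci_k = c(NA, NA),
                          ci_t_half = c(NA, NA), flagged = TRUE,
                          reason = "fit did not converge"),
                     class = "frap_fit"))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
    rep(NA_real_, 3))
  k <- unname(cf["k"])
  ci_k <- k + c(-1, 1) * 1.96 * unname(se[3])
  flagged <- FALSE; reason <- NA_character_
  if (k <= 2e-6 || unname(cf["p"]) <= unname(cf["b"]) + 1e-6) {
    flagged <- TRUE
    reason <- "no recovery: rate at lower bound or plateau <= baseline"
  }
  structure(list(k = k, t_half = log(2) / k,
                 plateau = unname(cf["p"]), baseline = unname(cf["b"]),
                 ci_k = ci_k, ci_t_half = rev(log(2) / ci_k),
                 flagged = flagged, reason = reason),
            class = "frap_fit")
}

#' Normalize a FRAP trace to its pre-bleach mean
#'
#' Divides the whole trace by the mean of the pre-bleach frames and returns
#' the post-bleach portion on a timebase starting at 0 (the bleach frame).
#'
#' @param time acquisition times, seconds.
#' @param intensity raw intensities.
#' @param n_prebleach number of pre-bleach frames at the start of the trace.
#' @return data.frame: t (s, from 0), y (normalized).
#' @export
normalize_frap_trace <- function(time, intensity, n_prebleach = 3) {
  stopifnot(length(time) == length(intensity),
            length(time) > n_prebleach + 1)
  pre <- mean(intensity[seq_len(n_prebleach)])
  post <- (n_prebleach + 1):length(time)
  data.frame(t = time[post] - time[post][1], y = intensity[post] / pre)
}

#' Ratio-to-control normalization of per-image condensate counts
#'
#' Normalizes per-image (or per-cell) condensate counts so the control group's
#' mean is 1, the presentation used for P-body counting across treatments.
#'
#' @param counts numeric vector of counts.
#' @param group factor/character of the same length.
#' @param control the control group level.
#' @return data.frame: group, count, normalized.
#' @export
normalize_to_control <- function(counts, group, control) {
  stopifnot(length(counts) == length(group), control %in% group)
  ref <- mean(counts[group == control])
  if (ref == 0) stop("control group has zero mean count")
  data.frame(group = group, count = counts, normalized = counts / ref)
}
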