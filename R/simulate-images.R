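#' Labelled elliptical cell masks on a pixel grid
#'
#' Convenience generator of a labelled mask image: cells are ellipses laid on
#' a regular grid, mimicking segmented rod-shaped bacteria or round mammalian
#' cells depending on the axis lengths.
#'
#' @param dim c(rows, cols) of the grid.
#' @param n_cells_x,n_cells_y grid of cells.
#' @param semi_axes c(a, b) ellipse semi-axes in px (rows, cols).
#' @return integer matrix, 0 = background, k = cell k.
#' @export
make_cell_masks <- function(dim = c(128, 128), n_cells_x = 3, n_cells_y = 3,
                            semi_axes = c(12, 16)) {
  masks <- matrix(0L, dim[1], dim[2])
  cx <- round(seq(0.5, n_cells_x - 0.5, by = 1) / n_cells_x * dim[1])
  cy <- round(seq(0.5, n_cells_y - 0.5, by = 1) / n_cells_y * dim[2])
  rows <- matrix(rep(seq_len(dim[1]), dim[2]), dim[1], dim[2])
  cols <- matrix(rep(seq_len(dim[2]), each = dim[1]), dim[1], dim[2])
  k <- 0L
  for (i in seq_along(cx)) for (j in seq_along(cy)) {
    k <- k + 1L
    inside <- ((rows - cx[i]) / semi_axes[1])^2 +
      ((cols - cy[j]) / semi_axes[2])^2 <= 1
    masks[inside & masks == 0L] <- k
  }
  masks
}

#' Ground truth for a synthetic two-channel cell image
#'
#' Bundles labelled cell masks, planted Gaussian foci, background level and
#' noise. Foci must lie inside a cell; amplitudes must be positive.
#'
#' @param cell_masks labelled integer matrix (0 background).
#' @param focus_truth data.frame with columns `row`, `col`, `radius`
#'   (Gaussian sd, px) and `amplitude`.
#' @param background_level scalar background intensity.
#' @param noise_sigma Gaussian noise sd.
#' @return object of class `synthetic_image_truth`.
#' @export
synthetic_image_truth <- function(cell_masks, focus_truth,
                                  background_level = 100, noise_sigma = 5) {
  stopifnot(is.matrix(cell_masks))
  if (nrow(focus_truth) > 0) {
    stopifnot(all(c("row", "col", "radius", "amplitude") %in% names(focus_truth)))
    if (any(focus_truth$amplitude <= 0)) stop("amplitudes must be positive")
    r <- round(focus_truth$row); c <- round(focus_truth$col)
    if (any(r < 1 | r > nrow(cell_masks) | c < 1 | c > ncol(cell_masks)))
      stop("focus outside image bounds")
    if (any(cell_masks[cbind(r, c)] == 0L))
      stop("every focus center must lie inside a cell mask")
  }
  structure(list(cell_masks = cell_masks, focus_truth = focus_truth,
                 background_level = background_level,
                 noise_sigma = noise_sigma),
            class = "synthetic_image_truth")
}

## additive Gaussian spots on a grid
add_gaussian_spots <- function(img, spots) {
  if (is.null(spots) || nrow(spots) == 0) return(img)
  rows <- matrix(rep(seq_len(nrow(img)), ncol(img)), nrow(img), ncol(img))
  cols <- matrix(rep(seq_len(ncol(img)), each = nrow(img)), nrow(img), ncol(img))
  for (i in seq_len(nrow(spots))) {
    img <- img + spots$amplitude[i] *
      exp(-((rows - spots$row[i])^2 + (cols - spots$col[i])^2) /
            (2 * spots$radius[i]^2))
  }
  img
}

#' Render a synthetic (optionally two-channel) cell image
#'
#' Channel 1 = background + Gaussian spots at the planted foci + i.i.d.
#' Gaussian noise. Channel 2 (for colocalization tests) is either absent, a
#' noisy copy correlated with channel 1, or independent noise over the same
#' background.
#'
#' @param truth a [synthetic_image_truth()].
#' @param seed integer seed.
#' @param channel2 "none", "correlated" or "independent".
#' @param channel2_gain multiplier applied to the (noise-free) channel-1
#'   signal when `channel2 = "correlated"`.
#' @return a matrix (single channel) or list(ch1, ch2).
#' @export
render_cell_image <- function(truth, seed = 1L,
                              channel2 = c("none", "correlated", "independent"),
                              channel2_gain = 0.8) {
  stopifnot(inherits(truth, "synthetic_image_truth"))
  channel2 <- match.arg(channel2)
  set.seed(as.integer(seed))
  d <- dim(truth$cell_masks)
  clean <- add_gaussian_spots(matrix(truth$background_level, d[1], d[2]),
                              truth$focus_truth)
  ch1 <- clean + matrix(stats::rnorm(prod(d), 0, truth$noise_sigma), d[1], d[2])
  if (channel2 == "none") return(ch1)
  ch2 <- if (channel2 == "correlated") {
    channel2_gain * clean +
      matrix(stats::rnorm(prod(d), 0, truth$noise_sigma), d[1], d[2])
  } else {
    truth$background_level +
      matrix(stats::rnorm(prod(d), 0, max(truth$noise_sigma, 1)), d[1], d[2])
  }
  list(ch1 = ch1, ch2 = ch2)
}

#' Render a synthetic in vitro droplet field
#'
#' Rasterizes bright elliptical droplets on a noisy background and returns the
#' per-shape ground truth (pixel area, axis ratio) used to validate the
#' droplet segmentation pipeline.
#'
#' @param shapes data.frame with columns `row`, `col` (center px), `a`, `b`
#'   (semi-axes px, a >= b), optional `theta` (radians, default 0) and
#'   `intensity` (default 1).
#' @param dim c(rows, cols).
#' @param background background level.
#' @param noise_sigma Gaussian noise sd.
#' @param allow_overlap if FALSE (default), overlapping shapes are an error.
#' @param seed integer seed.
#' @return list(image, truth) where truth has shape id, area_px, axis_ratio.
#' @export
render_droplet_field <- function(shapes, dim = c(256, 256), background = 0.1,
                                 noise_sigma = 0.02, allow_overlap = FALSE,
                                 seed = 1L) {
  set.seed(as.integer(seed))
  img <- matrix(background, dim[1], dim[2])
  occupancy <- matrix(0L, dim[1], dim[2])
  truth <- data.frame(shape = integer(0), area_px = integer(0),
                      axis_ratio = numeric(0))
  if (!is.null(shapes) && nrow(shapes) > 0) {
    if (is.null(shapes$theta)) shapes$theta <- 0
    if (is.null(shapes$intensity)) shapes$intensity <- 1
    rows <- matrix(rep(seq_len(dim[1]), dim[2]), dim[1], dim[2])
    cols <- matrix(rep(seq_len(dim[2]), each = dim[1]), dim[1], dim[2])
    for (i in seq_len(nrow(shapes))) {
      s <- shapes[i, ]
      if (s$row - s$a < 1 || s$row + s$a > dim[1] ||
          s$col - s$a < 1 || s$col + s$a > dim[2])
        stop("shape ", i, " outside field bounds")
      dr <- rows - s$row; dc <- cols - s$col
      u <- dr * cos(s$theta) + dc * sin(s$theta)
      v <- -dr * sin(s$theta) + dc * cos(s$theta)
      inside <- (u / s$a)^2 + (v / s$b)^2 <= 1
      if (!allow_overlap && any(occupancy[inside] > 0L))
        stop("shape ", i, " overlaps an earlier shape")
      occupancy[inside] <- occupancy[inside] + 1L
      img[inside] <- background + s$intensity
      truth <- rbind(truth, data.frame(shape = i, area_px = sum(inside),
                                       axis_ratio = s$a / s$b))
    }
  }
  img <- img + matrix(stats::rnorm(prod(dim), 0, noise_sigma), dim[1], dim[2])
  list(image = img, truth = truth)
}
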