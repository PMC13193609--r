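#' Configuration for single-molecule trajectory simulation
#'
#' Defines the ground truth of a three-state single-particle-tracking
#' experiment: a condensate-confined slow state, a nucleoid-like slow state
#' and a freely diffusing fast state. Defaults mirror a typical bacterial
#' PALM acquisition: 20 ms frames (50 Hz), ~30 nm localization precision and
#' a geometric track-length distribution with median 10 frames.
#'
#' @param n_tracks number of trajectories.
#' @param frame_interval frame interval in seconds.
#' @param localization_sigma localization error (sd per coordinate), um.
#' @param state_fractions length-3 probabilities (condensate, nucleoid, free);
#'   must sum to 1.
#' @param diffusion_coeffs length-3 diffusion coefficients um^2/s, strictly
#'   increasing (D1 condensate < D2 nucleoid < D3 free).
#' @param focus_centers list/matrix of (x, y) condensate centers, um.
#' @param focus_radius condensate radius, um.
#' @param median_track_length median of the geometric track-length
#'   distribution, frames.
#' @param field_size c(width, height) of the field, um.
#' @param seed integer seed.
#' @return an object of class `trajectory_sim_config`.
#' @export
trajectory_sim_config <- function(n_tracks = 2000,
                                  frame_interval = 0.02,
                                  localization_sigma = 0.03,
                                  state_fractions = c(0.25, 0.30, 0.45),
                                  diffusion_coeffs = c(0.05, 0.3, 2.0),
                                  focus_centers = list(c(1.2, 1.2), c(3.8, 3.8)),
                                  focus_radius = 0.4,
                                  median_track_length = 10,
                                  field_size = c(5, 5),
                                  seed = 1L) {
  stopifnot(length(state_fractions) == 3, length(diffusion_coeffs) == 3)
  if (abs(sum(state_fractions) - 1) > 1e-12)
    stop("state_fractions must sum to 1")
  if (any(diff(diffusion_coeffs) <= 0))
    stop("diffusion_coeffs must be strictly increasing")
  if (frame_interval <= 0) stop("frame_interval must be positive")
  if (any(field_size <= 0)) stop("field_size must be positive")
  if (state_fractions[1] > 0 && focus_radius <= 0)
    stop("focus_radius must be positive when the condensate fraction is nonzero")
  if (is.matrix(focus_centers))
    focus_centers <- lapply(seq_len(nrow(focus_centers)),
                            function(i) focus_centers[i, ])
  structure(list(
    n_tracks = n_tracks, frame_interval = frame_interval,
    localization_sigma = localization_sigma,
    state_fractions = state_fractions, diffusion_coeffs = diffusion_coeffs,
    focus_centers = focus_centers, focus_radius = focus_radius,
    median_track_length = median_track_length,
    field_size = field_size, seed = as.integer(seed)
  ), class = "trajectory_sim_config")
}

## reflect a point radially back into a circle of radius R about (cx, cy)
reflect_into_circle <- function(x, y, cx, cy, R) {
  dx <- x - cx; dy <- y - cy
  r <- sqrt(dx^2 + dy^2)
  while (r > R && r > 0) {
    r_new <- 2 * R - r
    if (r_new < 0) r_new <- R * stats::runif(1)  # pathological long jump
    x <- cx + dx / r * r_new
    y <- cy + dy / r * r_new
    dx <- x - cx; dy <- y - cy
    r <- sqrt(dx^2 + dy^2)
  }
  c(x, y)
}

#' Simulate single-molecule trajectories from a three-state mixture
#'
#' Each track is assigned a diffusive state by the configured fractions and
#' performs a 2-D Brownian walk with its state's diffusion coefficient
#' (per-coordinate step sd `sqrt(2 D dt)`). Condensate-state tracks start
#' inside a focus and are reflected at the focus boundary; all localizations
#' carry i.i.d. Gaussian localization noise. Track lengths (in frames) are
#' geometric with the configured median.
#'
#' @param config a [trajectory_sim_config()].
#' @return a list of class `trajectory_set` with elements `tracks`
#'   (data.frame: track_id, frame, x_um, y_um), `frame_interval`,
#'   `field_size`, `foci` (centers + radius) and `truth` (data.frame:
#'   track_id, state in 1:3 = condensate/nucleoid/free, n_frames).
#' @export
simulate_trajectories <- function(config) {
  stopifnot(inherits(config, "trajectory_sim_config"))
  set.seed(config$seed)
  n <- config$n_tracks
  empty <- data.frame(track_id = integer(0), frame = integer(0),
                      x_um = numeric(0), y_um = numeric(0))
  if (n == 0) {
    return(structure(list(
      tracks = empty, frame_interval = config$frame_interval,
      field_size = config$field_size,
      foci = list(centers = config$focus_centers, radius = config$focus_radius),
      truth = data.frame(track_id = integer(0), state = integer(0),
                         n_frames = integer(0))
    ), class = "trajectory_set"))
  }
  # geometric track length (support >= 2 frames) with stated median:
  # median of 2 + Geom(p) equals m when p = 1 - 2^(-1/(m - 1))
  p_geo <- 1 - 2^(-1 / max(config$median_track_length - 1, 1))
  states <- sample.int(3, n, replace = TRUE, prob = config$state_fractions)
  lens <- 2L + stats::rgeom(n, p_geo)
  sig_step <- sqrt(2 * config$diffusion_coeffs * config$frame_interval)
  fx <- config$field_size[1]; fy <- config$field_size[2]
  out <- vector("list", n)
  for (i in seq_len(n)) {
    L <- lens[i]; st <- states[i]
    if (st == 1L) {
      fc <- config$focus_centers[[sample.int(length(config$focus_centers), 1)]]
      th <- stats::runif(1, 0, 2 * pi)
      rr <- config$focus_radius * sqrt(stats::runif(1))
      pos <- matrix(NA_real_, L, 2)
      pos[1, ] <- c(fc[1] + rr * cos(th), fc[2] + rr * sin(th))
      for (k in 2:L) {
        step <- stats::rnorm(2, 0, sig_step[1])
        pos[k, ] <- reflect_into_circle(pos[k - 1, 1] + step[1],
                                        pos[k - 1, 2] + step[2],
                                        fc[1], fc[2], config$focus_radius)
      }
    } else {
      pos <- matrix(NA_real_, L, 2)
      pos[1, ] <- c(stats::runif(1, 0, fx), stats::runif(1, 0, fy))
      steps <- matrix(stats::rnorm(2 * (L - 1), 0, sig_step[st]), L - 1, 2)
      pos[-1, ] <- pos[rep(1, L - 1), ] + apply(steps, 2, cumsum)
    }
    obs <- pos + matrix(stats::rnorm(2 * L, 0, config$localization_sigma), L, 2)
    out[[i]] <- data.frame(track_id = i, frame = seq_len(L),
                           x_um = obs[, 1], y_um = obs[, 2])
  }
  structure(list(
    tracks = do.call(rbind, out),
    frame_interval = config$frame_interval,
    field_size = config$field_size,
    foci = list(centers = config$focus_centers, radius = config$focus_radius),
    truth = data.frame(track_id = seq_len(n), state = states, n_frames = lens)
  ), class = "trajectory_set")
}
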