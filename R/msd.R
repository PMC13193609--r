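#' Fit the mean-squared-displacement diffusion model to one track
#'
#' The per-track MSD at lags 1..`max_lag` frames (time-averaged over all pairs
#' at each lag) is fit by ordinary least squares to
#' `MSD(k * tau) = 4 * D * k * tau + 4 * sigma^2`, giving an apparent
#' diffusion coefficient and localization error. Tracks shorter than
#' `min_frames` localizations are rejected.
#'
#' @param track data.frame with columns `frame`, `x_um`, `y_um` (one track).
#' @param frame_interval frame interval tau, seconds.
#' @param max_lag largest lag, frames.
#' @param min_frames minimum number of localizations.
#' @return list of class `diffusion_fit`: `D` (um^2/s, clamped at 0),
#'   `sigma` (um), `n_lags_used`, `residual_norm`, `clamped`, `rejected`,
#'   `reason`.
#' @export
fit_msd <- function(track, frame_interval, max_lag = 5, min_frames = 7) {
  if (nrow(track) < min_frames) {
    return(structure(list(D = NA_real_, sigma = NA_real_, n_lags_used = 0L,
                          residual_norm = NA_real_, clamped = FALSE,
                          rejected = TRUE,
                          reason = sprintf("track has %d < %d frames",
                                           nrow(track), min_frames)),
                     class = "diffusion_fit"))
  }
  o <- order(track$frame)
  x <- track$x_um[o]; y <- track$y_um[o]; fr <- track$frame[o]
  lags <- seq_len(min(max_lag, nrow(track) - 1))
  msd <- vapply(lags, function(k) {
    i <- seq_len(length(x) - k)
    keep <- (fr[i + k] - fr[i]) == k    # only true k-frame gaps
    if (!any(keep)) return(NA_real_)
    mean((x[i + k][keep] - x[i][keep])^2 + (y[i + k][keep] - y[i][keep])^2)
  }, numeric(1))
  ok <- !is.na(msd)
  tlag <- lags[ok] * frame_interval
  fit <- stats::lm.fit(cbind(1, tlag), msd[ok])
  slope <- fit$coefficients[2]; intercept <- fit$coefficients[1]
  clamped <- FALSE
  D <- slope / 4
  if (is.na(D) || D < 0) { D <- 0; clamped <- TRUE }
  sigma <- sqrt(max(intercept, 0) / 4)
  structure(list(D = unname(D), sigma = unname(sigma),
                 n_lags_used = sum(ok),
                 residual_norm = sqrt(sum(fit$residuals^2)),
                 clamped = clamped, rejected = FALSE, reason = NA_character_),
            class = "diffusion_fit")
}

#' Pool squared single-frame displacements across tracks
#'
#' Squared displacements between consecutive-frame localizations, pooled over
#' all tracks with at least `min_len` localizations.
#'
#' @param trajectory_set a `trajectory_set` (or its `tracks` data.frame).
#' @param min_len minimum track length in frames.
#' @return numeric vector of r^2 values (um^2).
#' @export
pooled_squared_displacements <- function(trajectory_set, min_len = 4) {
  tr <- if (inherits(trajectory_set, "trajectory_set"))
    trajectory_set$tracks else trajectory_set
  if (is.null(tr) || nrow(tr) == 0) return(numeric(0))
  out <- lapply(split(tr, tr$track_id), function(t) {
    if (nrow(t) < min_len) return(numeric(0))
    o <- order(t$frame)
    x <- t$x_um[o]; y <- t$y_um[o]; fr <- t$frame[o]
    i <- seq_len(nrow(t) - 1)
    consec <- (fr[i + 1] - fr[i]) == 1
    ((x[i + 1] - x[i])^2 + (y[i + 1] - y[i])^2)[consec]
  })
  unlist(out, use.names = FALSE)
}

#' Empirical CDF of pooled squared displacements
#'
#' `P(r^2)` = number of pooled squared displacements less than or equal to
#' r^2, divided by the pool size: a right-continuous nondecreasing step
#' function reaching 1 at the pool maximum.
#'
#' @param r2_pool numeric vector of squared displacements.
#' @return a function r^2 -> probability.
#' @export
empirical_cdf <- function(r2_pool) {
  if (length(r2_pool) == 0) stop("empty displacement pool")
  stats::ecdf(r2_pool)
}
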