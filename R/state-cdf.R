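#' @rdname fit_three_state
#' @details
#' The mixture CDF of squared displacements over one frame interval is
#' \deqn{P(r^2, \tau) = 1 - \sum_i \alpha_i \exp(-r^2 / (\frac{8}{3} D_i \tau))}
#' with the weights summing to 1. The 8/3 scale (rather than the
#' instantaneous-position value of 4) reflects camera-integrated positions;
#' `msd_factor = 4` selects the instantaneous-sampling convention instead.
#' @keywords internal
state_cdf_model <- function(r2, D, alpha, tau, msd_factor = 8 / 3) {
  stopifnot(length(alpha) == length(D), abs(sum(alpha) - 1) < 1e-9)
  terms <- vapply(seq_along(D), function(i)
    alpha[i] * exp(-r2 / (msd_factor * D[i] * tau)), numeric(length(r2)))
  1 - rowSums(matrix(terms, nrow = length(r2)))
}

## shared machinery: unweighted least squares of the K-state mixture CDF
## against the empirical CDF evaluated at every observed r^2, with a
## stick-breaking parameterization keeping weights in the simplex and
## seeded multi-start to avoid local minima.
fit_state_cdf <- function(r2_pool, tau, k, msd_factor = 8 / 3, n_starts = 3,
                          seed = 1L) {
  stopifnot(tau > 0, k %in% c(2, 3))
  r2 <- sort(r2_pool)
  n <- length(r2)
  if (n < 10) stop("need at least 10 pooled displacements")
  Fhat <- seq_len(n) / n
  dat <- data.frame(r2 = r2, F = Fhat)
  scale0 <- msd_factor * tau
  starts <- list()
  set.seed(as.integer(seed))
  qs <- unname(stats::quantile(r2, c(0.2, 0.5, 0.9)))
  base_D <- pmax(qs / scale0, 1e-6)
  for (s in seq_len(n_starts)) {
    jit <- if (s == 1) rep(1, 3) else exp(stats::rnorm(3, 0, 0.5))
    starts[[s]] <- base_D * jit
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch({
      if (k == 3) {
        minpack.lm::nlsLM(
          F ~ 1 - (p1 * exp(-r2 / (scale0 * D1)) +
                     (1 - p1) * p2 * exp(-r2 / (scale0 * D2)) +
                     (1 - p1) * (1 - p2) * exp(-r2 / (scale0 * D3))),
          data = dat,
          start = list(p1 = 0.33, p2 = 0.5,
                       D1 = st[1], D2 = st[2], D3 = st[3]),
          lower = c(0, 0, 1e-8, 1e-8, 1e-8),
          upper = c(1, 1, Inf, Inf, Inf),
          control = minpack.lm::nls.lm.control(maxiter = 500))
      } else {
        minpack.lm::nlsLM(
          F ~ 1 - (p1 * exp(-r2 / (scale0 * D1)) +
                     (1 - p1) * exp(-r2 / (scale0 * D2))),
          data = dat,
          start = list(p1 = 0.5, D1 = st[1], D2 = st[3]),
          lower = c(0, 1e-8, 1e-8), upper = c(1, Inf, Inf),
          control = minpack.lm::nls.lm.control(maxiter = 500))
      }
    }, error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(cf = stats::coef(fit), rss = rss)
  }
  if (is.null(best)) {
    # fall back to direct sum-of-squares minimization on transformed
    # parameters (logit weights, log D): slower but unconditionally stable
    ss <- function(theta) {
      if (k == 3) {
        p1 <- stats::plogis(theta[1]); p2 <- stats::plogis(theta[2])
        Dv <- exp(theta[3:5])
        pred <- 1 - (p1 * exp(-r2 / (scale0 * Dv[1])) +
                       (1 - p1) * p2 * exp(-r2 / (scale0 * Dv[2])) +
                       (1 - p1) * (1 - p2) * exp(-r2 / (scale0 * Dv[3])))
      } else {
        p1 <- stats::plogis(theta[1])
        Dv <- exp(theta[2:3])
        pred <- 1 - (p1 * exp(-r2 / (scale0 * Dv[1])) +
                       (1 - p1) * exp(-r2 / (scale0 * Dv[2])))
      }
      sum((Fhat - pred)^2)
    }
    for (st in starts) {
      th0 <- if (k == 3) c(0, 0, log(st)) else c(0, log(st[c(1, 3)]))
      opt <- tryCatch(stats::optim(th0, ss, method = "Nelder-Mead",
                                   control = list(maxit = 5000)),
                      error = function(e) NULL)
      if (is.null(opt)) next
      if (is.null(best) || opt$value < best$rss) {
        th <- opt$par
        cf <- if (k == 3)
          c(p1 = stats::plogis(th[1]), p2 = stats::plogis(th[2]),
            D1 = exp(th[3]), D2 = exp(th[4]), D3 = exp(th[5]))
        else c(p1 = stats::plogis(th[1]), D1 = exp(th[2]), D2 = exp(th[3]))
        best <- list(cf = cf, rss = opt$value)
      }
    }
  }
  if (is.null(best)) stop("state CDF fit did not converge from any start")
  cf <- best$cf
  if (k == 3) {
    alpha <- c(cf["p1"], (1 - cf["p1"]) * cf["p2"],
               (1 - cf["p1"]) * (1 - cf["p2"]))
    D <- c(cf["D1"], cf["D2"], cf["D3"])
  } else {
    alpha <- c(cf["p1"], 1 - cf["p1"])
    D <- c(cf["D1"], cf["D2"])
  }
  # canonical increasing-D order; ties broken by larger weight first
  o <- order(D, -alpha)
  D <- unname(D[o]); alpha <- unname(alpha[o])
  degenerate <- any(abs(diff(D)) / pmax(D[-length(D)], 1e-12) < 0.05)
  list(D = D, alpha = alpha, residual = best$rss, n = n,
       degenerate = degenerate, msd_factor = msd_factor)
}

#' Fit the three-state squared-displacement mixture CDF
#'
#' Decomposes a pool of single-frame squared displacements into three
#' diffusive states by unweighted nonlinear least squares of the analytic
#' mixture CDF against the empirical CDF at every observed r^2. Weights are
#' constrained to the simplex, diffusion coefficients to be nonnegative, and
#' states are reported in increasing-D order.
#'
#' @param r2_pool numeric vector of squared displacements (um^2); at least
#'   ~100 recommended.
#' @param tau frame interval, seconds.
#' @param msd_factor scale of the per-state exponential: 8/3 (default,
#'   camera-integrated) or 4 (instantaneous positions).
#' @param n_starts number of seeded optimizer starts.
#' @param seed integer seed for the start jitter.
#' @return object of class `three_state_fit` with `D1`, `D2`, `D3`,
#'   `alpha1`, `alpha2`, `alpha3`, `residual` (sum of squares), `n`,
#'   `degenerate` (two D within 5%).
#' @export
fit_three_state <- function(r2_pool, tau, msd_factor = 8 / 3, n_starts = 3,
                            seed = 1L) {
  f <- fit_state_cdf(r2_pool, tau, 3, msd_factor, n_starts, seed)
  structure(list(D1 = f$D[1], D2 = f$D[2], D3 = f$D[3],
                 alpha1 = f$alpha[1], alpha2 = f$alpha[2],
                 alpha3 = f$alpha[3],
                 residual = f$residual, n = f$n, degenerate = f$degenerate,
                 msd_factor = msd_factor),
            class = "three_state_fit")
}

#' Fit the two-state squared-displacement mixture CDF
#'
#' Same analysis as [fit_three_state()] with two components. A fitted weight
#' at the simplex boundary (alpha > 0.99 or < 0.01) is flagged: the second
#' state is then unidentifiable.
#'
#' @inheritParams fit_three_state
#' @return object of class `two_state_fit` with `D1`, `D2`, `alpha`
#'   (weight of the slower state), `residual`, `n`, `degenerate`,
#'   `boundary` flags.
#' @export
fit_two_state <- function(r2_pool, tau, msd_factor = 8 / 3, n_starts = 3,
                          seed = 1L) {
  f <- fit_state_cdf(r2_pool, tau, 2, msd_factor, n_starts, seed)
  structure(list(D1 = f$D[1], D2 = f$D[2], alpha = f$alpha[1],
                 residual = f$residual, n = f$n, degenerate = f$degenerate,
                 boundary = f$alpha[1] > 0.99 || f$alpha[1] < 0.01,
                 msd_factor = msd_factor),
            class = "two_state_fit")
}

#' Partition molecules into condensate, nucleoid and free fractions
#'
#' Combines the three-state fit on all displacements with the three-state fit
#' on the focus-overlapping ("In" + "In/out") displacement subset:
#' `F_condensate = (n_in + n_inout) / n_total * (alpha1 + alpha2)` of the
#' subset fit, `F_free = alpha3` of the full fit, and
#' `F_nucleoid = 1 - F_free - F_condensate`. All three are shares of the
#' analysed displacements. A warning is raised when the full fit's fastest
#' state is not consistent with free diffusion (D3 <= 1 um^2/s).
#'
#' @param full_fit `three_state_fit` on all pooled displacements.
#' @param subset_fit `three_state_fit` on the In + In/out displacement pool.
#' @param n_in,n_inout,n_total displacement counts (In, In/out, all).
#' @return list of class `state_fractions`: `F_condensate`, `F_nucleoid`,
#'   `F_free` (sum to 1 within 1e-9).
#' @export
compute_state_fractions <- function(full_fit, subset_fit, n_in, n_inout,
                                    n_total) {
  if (n_total <= 0) stop("n_total must be positive")
  if (!is.null(full_fit$D3) && full_fit$D3 <= 1)
    warning("full-fit D3 <= 1 um^2/s: fastest state may not be free diffusion")
  w <- if (is.null(subset_fit)) 0 else subset_fit$alpha1 + subset_fit$alpha2
  f_cond <- (n_in + n_inout) / n_total * w
  f_free <- full_fit$alpha3
  f_nuc <- 1 - f_free - f_cond
  if (f_nuc < -1e-9)
    stop("inconsistent fits: negative nucleoid fraction (", signif(f_nuc, 3), ")")
  f_nuc <- max(f_nuc, 0)
  structure(list(F_condensate = f_cond, F_nucleoid = f_nuc, F_free = f_free),
            class = "state_fractions")
}
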