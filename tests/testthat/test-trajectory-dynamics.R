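test_that("fit_msd equals the closed-form MSD regression and rejects short tracks", {
  tau <- 0.02
  set.seed(1)
  short <- data.frame(frame = 1:6, x_um = rnorm(6), y_um = rnorm(6))
  r <- fit_msd(short, tau)
  expect_true(r$rejected)
  expect_match(r$reason, "6 < 7")
  # on any track, the fit must equal an independent double-loop MSD plus a
  # closed-form simple linear regression
  for (s in 1:5) {
    set.seed(100 + s)
    n <- sample(8:25, 1)
    tr <- data.frame(frame = seq_len(n),
                     x_um = cumsum(rnorm(n, 0, 0.1)),
                     y_um = cumsum(rnorm(n, 0, 0.1)))
    f <- fit_msd(tr, tau)
    msd <- sapply(1:5, function(k) {
      v <- c()
      for (i in seq_len(n - k))
        v <- c(v, (tr$x_um[i + k] - tr$x_um[i])^2 +
                 (tr$y_um[i + k] - tr$y_um[i])^2)
      mean(v)
    })
    tk <- (1:5) * tau
    slope <- sum((tk - mean(tk)) * (msd - mean(msd))) /
      sum((tk - mean(tk))^2)
    intercept <- mean(msd) - slope * mean(tk)
    expect_equal(f$D, max(slope / 4, 0), tolerance = 1e-8)
    expect_equal(f$sigma, sqrt(max(intercept, 0) / 4), tolerance = 1e-8)
  }
  # a period-5 oscillation has MSD falling back to 0 at lag 5: negative
  # slope, so D is clamped at zero and flagged
  i <- 1:20
  osc <- data.frame(frame = i, x_um = 0.1 * sin(2 * pi * i / 5),
                    y_um = 0.1 * cos(2 * pi * i / 5))
  fo <- fit_msd(osc, tau)
  expect_equal(fo$D, 0)
  expect_true(fo$clamped)
})

test_that("fit_msd recovers D on simulated Brownian tracks", {
  set.seed(42)
  tau <- 0.02; D <- 0.5; sig <- 0.03
  fits <- replicate(100, {
    n <- 20
    x <- cumsum(c(0, rnorm(n - 1, 0, sqrt(2 * D * tau)))) + rnorm(n, 0, sig)
    y <- cumsum(c(0, rnorm(n - 1, 0, sqrt(2 * D * tau)))) + rnorm(n, 0, sig)
    fit_msd(data.frame(frame = 1:n, x_um = x, y_um = y), tau)$D
  })
  expect_lt(abs(mean(fits) - D) / D, 0.2)
})

test_that("pooled displacements equal the brute-force enumeration", {
  # single 4-frame track gives exactly 3 values
  one <- data.frame(track_id = 1, frame = 1:4, x_um = c(0, 1, 1, 2),
                    y_um = c(0, 0, 1, 1))
  expect_length(pooled_squared_displacements(one), 3)
  # 3-frame tracks contribute nothing
  three <- data.frame(track_id = rep(1:2, each = 3), frame = rep(1:3, 2),
                      x_um = rnorm(6), y_um = rnorm(6))
  expect_length(pooled_squared_displacements(three), 0)
  set.seed(8)
  tr <- do.call(rbind, lapply(1:12, function(i) {
    n <- sample(3:12, 1)
    data.frame(track_id = i, frame = sort(sample(1:20, n)),
               x_um = rnorm(n), y_um = rnorm(n))
  }))
  got <- sort(pooled_squared_displacements(tr))
  want <- sort(oracle_pooled_r2(tr))
  expect_equal(got, want)
})

test_that("empirical CDF matches direct counting", {
  expect_error(empirical_cdf(numeric(0)), "empty")
  f1 <- empirical_cdf(2.5)
  expect_equal(f1(2.4), 0)
  expect_equal(f1(2.5), 1)
  set.seed(3)
  pool <- rexp(400)
  f <- empirical_cdf(pool)
  expect_equal(f(max(pool)), 1)
  qs <- runif(50, 0, max(pool))
  direct <- vapply(qs, function(q) mean(pool <= q), numeric(1))
  expect_equal(f(qs), direct)
})

test_that("three-state CDF fit recovers model-generated parameters", {
  tau <- 0.02
  D <- c(0.05, 0.3, 2.0); al <- c(0.3, 0.3, 0.4)
  set.seed(42)
  comp <- sample(1:3, 5000, replace = TRUE, prob = al)
  r2 <- rexp(5000, rate = 1 / ((8 / 3) * D[comp] * tau))
  f <- fit_three_state(r2, tau, seed = 1)
  expect_lt(abs(f$alpha1 - al[1]), 0.05)
  expect_lt(abs(f$alpha2 - al[2]), 0.05)
  expect_lt(abs(f$alpha3 - al[3]), 0.05)
  expect_lt(abs(f$D1 - D[1]) / D[1], 0.2)
  expect_lt(abs(f$D2 - D[2]) / D[2], 0.2)
  expect_lt(abs(f$D3 - D[3]) / D[3], 0.2)
  expect_true(f$D1 <= f$D2 && f$D2 <= f$D3)
  expect_equal(f$alpha1 + f$alpha2 + f$alpha3, 1, tolerance = 1e-9)
})

test_that("single-state input drives extra mixture weights to zero", {
  tau <- 0.02
  set.seed(7)
  r2 <- rexp(6000, rate = 1 / ((8 / 3) * 2.0 * tau))
  f3 <- fit_three_state(r2, tau, seed = 2)
  # the two slow states should carry (almost) no weight, or collapse onto
  # the fast state; total non-fast weight stays small
  slow_weight <- sum(c(f3$alpha1, f3$alpha2)[c(f3$D1, f3$D2) < 0.5 * f3$D3])
  expect_lt(slow_weight, 0.05)
  f2 <- fit_two_state(r2, tau, seed = 2)
  expect_true(f2$boundary || f2$degenerate)
})

test_that("two-state CDF fit recovers simulated mixtures", {
  tau <- 0.02
  set.seed(12)
  comp <- sample(1:2, 5000, replace = TRUE, prob = c(0.6, 0.4))
  r2 <- rexp(5000, rate = 1 / ((8 / 3) * c(0.05, 0.3)[comp] * tau))
  f <- fit_two_state(r2, tau, seed = 1)
  expect_lt(abs(f$alpha - 0.6), 0.05)
  expect_lt(abs(f$D1 - 0.05) / 0.05, 0.25)
  expect_lt(abs(f$D2 - 0.3) / 0.3, 0.25)
  # three-state fit on two-state data leaves the third state under 0.05
  f3 <- fit_three_state(r2, tau, seed = 1)
  expect_lt(min(f3$alpha1, f3$alpha2, f3$alpha3), 0.05)
})

test_that("state fractions follow the published accounting", {
  full <- structure(list(alpha1 = 0.4, alpha2 = 0.3, alpha3 = 0.30,
                         D1 = 0.05, D2 = 0.3, D3 = 2),
                    class = "three_state_fit")
  sub <- structure(list(alpha1 = 0.5, alpha2 = 0.3, alpha3 = 0.2,
                        D1 = 0.05, D2 = 0.3, D3 = 2),
                   class = "three_state_fit")
  fr <- compute_state_fractions(full, sub, n_in = 400, n_inout = 200,
                                n_total = 1000)
  expect_equal(fr$F_condensate, 0.6 * 0.8)
  expect_equal(fr$F_free, 0.30)
  expect_equal(fr$F_nucleoid, 1 - 0.48 - 0.30)
  expect_equal(fr$F_condensate + fr$F_nucleoid + fr$F_free, 1,
               tolerance = 1e-9)
  # no focus-overlapping steps
  fr0 <- compute_state_fractions(full, NULL, 0, 0, 1000)
  expect_equal(fr0$F_condensate, 0)
  expect_equal(fr0$F_nucleoid, 1 - full$alpha3)
  # all steps in foci, pure condensate subset, no free state
  full2 <- structure(list(alpha1 = 0.6, alpha2 = 0.4, alpha3 = 0,
                          D1 = 0.05, D2 = 0.3, D3 = 2),
                     class = "three_state_fit")
  sub2 <- structure(list(alpha1 = 0.6, alpha2 = 0.4, alpha3 = 0,
                         D1 = 0.05, D2 = 0.3, D3 = 2),
                    class = "three_state_fit")
  fr2 <- compute_state_fractions(full2, sub2, 1000, 0, 1000)
  expect_equal(fr2$F_condensate, 1)
  expect_equal(fr2$F_nucleoid, 0)
  expect_error(compute_state_fractions(full, sub, 1, 1, 0), "n_total")
  # slow fastest state earns a warning
  slow <- structure(list(alpha1 = 0.4, alpha2 = 0.3, alpha3 = 0.3,
                         D1 = 0.01, D2 = 0.1, D3 = 0.8),
                    class = "three_state_fit")
  expect_warning(compute_state_fractions(slow, sub, 0, 0, 10), "D3")
})

test_that("stable-focus detection applies the trajectory filters", {
  px <- 0.049
  ts12 <- make_cluster_tracks(12, 15, center_px = 30, pixel_size = px)
  foci <- detect_stable_foci(ts12, c(64, 64), px)
  expect_equal(nrow(foci$regions), 1)
  expect_equal(foci$regions$n_supporting_tracks, 12)
  # the cluster center lies inside the kept region
  expect_true(foci$label[30, 30] > 0)
  ts5 <- make_cluster_tracks(5, 15, center_px = 30, pixel_size = px)
  expect_equal(nrow(detect_stable_foci(ts5, c(64, 64), px)$regions), 0)
  # 12 tracks of only 8 frames fail the track-length filter
  ts_short <- make_cluster_tracks(12, 8, center_px = 30, pixel_size = px)
  expect_equal(nrow(detect_stable_foci(ts_short, c(64, 64), px)$regions), 0)
  empty <- structure(list(tracks = data.frame(track_id = integer(0),
                                              frame = integer(0),
                                              x_um = numeric(0),
                                              y_um = numeric(0)),
                          frame_interval = 0.02),
                     class = "trajectory_set")
  expect_equal(nrow(detect_stable_foci(empty, c(64, 64), px)$regions), 0)
})

test_that("overlap classification matches point-in-region brute force", {
  px <- 0.049
  ts <- make_cluster_tracks(12, 15, center_px = 30, pixel_size = px)
  foci <- detect_stable_foci(ts, c(64, 64), px)
  # fully inside
  inside <- data.frame(frame = 1:10, x_um = rep(30 * px, 10),
                       y_um = rep(30 * px, 10))
  ci <- classify_trajectory(inside, foci)
  expect_equal(ci$label, "In")
  expect_equal(ci$overlap_fraction, 1.0)
  # half inside
  half <- data.frame(frame = 1:10,
                     x_um = c(rep(30 * px, 5), rep(55 * px, 5)),
                     y_um = rep(30 * px, 10))
  ch <- classify_trajectory(half, foci)
  expect_equal(ch$label, "InOut")
  expect_equal(ch$overlap_fraction, 0.5)
  # fully outside
  out <- data.frame(frame = 1:10, x_um = rep(55 * px, 10),
                    y_um = rep(55 * px, 10))
  co <- classify_trajectory(out, foci)
  expect_equal(co$label, "Out")
  expect_equal(co$overlap_fraction, 0)
  # random tracks: fraction equals brute-force pixel lookup
  set.seed(6)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    t <- data.frame(frame = seq_len(n),
                    x_um = runif(n, 0, 64 * px), y_um = runif(n, 0, 64 * px))
    cl <- classify_trajectory(t, foci)
    inb <- floor(t$x_um / px) + 1
    jnb <- floor(t$y_um / px) + 1
    ok <- inb >= 1 & inb <= 64 & jnb >= 1 & jnb <= 64
    brute <- mean(ok & foci$label[cbind(pmin(pmax(inb, 1), 64),
                                        pmin(pmax(jnb, 1), 64))] > 0)
    expect_equal(cl$overlap_fraction, brute)
  }
  # no regions at all
  none <- detect_stable_foci(make_cluster_tracks(2, 15, 30, px),
                             c(64, 64), px)
  expect_equal(classify_trajectory(inside, none)$label, "Out")
})
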