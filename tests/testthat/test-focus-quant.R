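test_that("mask expansion matches a brute-force dilation + hull oracle", {
  # two far-apart square cells stay disjoint after expansion
  m <- matrix(0L, 60, 60)
  m[10:15, 10:15] <- 1L
  m[40:45, 40:45] <- 2L
  cm <- expand_cell_masks(m)
  expect_true(all(cm$expanded[m == 1L] == 1L))
  expect_true(all(cm$expanded[m == 2L] == 2L))
  e1 <- cm$expanded == 1L; e2 <- cm$expanded == 2L
  expect_equal(sum(e1 & e2), 0)
  # convex input: expanded support equals brute-force hull of the brute-force
  # Euclidean dilation
  idx <- which(m == 1L, arr.ind = TRUE)
  all_px <- expand.grid(r = 1:60, c = 1:60)
  d2 <- vapply(seq_len(nrow(all_px)), function(i)
    min((all_px$r[i] - idx[, 1])^2 + (all_px$c[i] - idx[, 2])^2), numeric(1))
  dil <- matrix(FALSE, 60, 60)
  dil[cbind(all_px$r, all_px$c)] <- d2 <= 16
  dil_idx <- which(dil, arr.ind = TRUE)
  want <- oracle_hull_pixels(dil_idx[, 1], dil_idx[, 2], c(60, 60))
  expect_equal(unname(e1), unname(want))
  # single-pixel mask
  m2 <- matrix(0L, 20, 20); m2[10, 10] <- 1L
  cm2 <- expand_cell_masks(m2)
  got2 <- cm2$expanded == 1L
  d2b <- outer(1:20, rep(1, 20)) # placeholder
  brute <- matrix(FALSE, 20, 20)
  for (r in 1:20) for (c in 1:20)
    brute[r, c] <- (r - 10)^2 + (c - 10)^2 <= 16
  bi <- which(brute, arr.ind = TRUE)
  want2 <- oracle_hull_pixels(bi[, 1], bi[, 2], c(20, 20))
  expect_equal(unname(got2), unname(want2))
})

test_that("the global focus threshold is median + 3.5 raw MAD", {
  m <- matrix(0L, 5, 5); m[1, 1:5] <- 1L
  img <- matrix(0, 5, 5); img[1, 1:5] <- c(0, 1, 2, 3, 4)
  cm <- structure(list(expanded = m), class = "cell_mask_set")
  expect_equal(global_focus_threshold(img, cm), 2 + 3.5 * 1)
  const <- matrix(7, 5, 5)
  expect_equal(global_focus_threshold(const, m), 7)
  # translation equivariance
  expect_equal(global_focus_threshold(img + 11, cm),
               global_focus_threshold(img, cm) + 11)
  expect_error(global_focus_threshold(img, matrix(0L, 5, 5)), "within-cell")
})

test_that("focus calling follows the center/growth/area rules", {
  masks <- matrix(1L, 32, 32)
  img <- matrix(10, 32, 32)
  # 2-pixel supra-threshold blob: discarded
  img[10, 10:11] <- 100
  calls <- call_foci(img, masks, threshold = 50)
  expect_equal(nrow(calls$calls), 0)
  # nothing above threshold
  expect_equal(nrow(call_foci(matrix(1, 8, 8), matrix(1L, 8, 8), 5)$calls), 0)
  # a rendered Gaussian spot: exactly one call whose support equals the
  # flood-fill oracle from the peak
  masks2 <- make_cell_masks(c(64, 64), 1, 1, semi_axes = c(25, 25))
  truth <- synthetic_image_truth(masks2,
                                 data.frame(row = 32, col = 32, radius = 2.5,
                                            amplitude = 80),
                                 background_level = 100, noise_sigma = 4)
  img2 <- render_cell_image(truth, seed = 3)
  cm <- expand_cell_masks(masks2)
  thr <- global_focus_threshold(img2, cm)
  fc <- call_foci(img2, cm, thr)
  expect_equal(nrow(fc$calls), 1)
  peak <- which(img2 == max(img2), arr.ind = TRUE)
  want <- oracle_flood_fill(img2 > thr, peak[1, 1], peak[1, 2])
  expect_equal(unname(fc$label > 0), unname(want))
  # every call pixel is supra-threshold
  expect_true(all(img2[fc$label > 0] > thr))
})

test_that("focus calling is invariant to adding a constant end-to-end", {
  masks <- make_cell_masks(c(64, 64), 2, 2, semi_axes = c(12, 12))
  set.seed(4)
  truth <- synthetic_image_truth(masks,
                                 data.frame(row = c(16, 48), col = c(16, 48),
                                            radius = 2, amplitude = 60),
                                 background_level = 100, noise_sigma = 5)
  img <- render_cell_image(truth, seed = 4)
  cm <- expand_cell_masks(masks)
  c1 <- call_foci(img, cm, global_focus_threshold(img, cm))
  c2 <- call_foci(img + 123, cm, global_focus_threshold(img + 123, cm))
  expect_equal(c1$label, c2$label)
  expect_equal(c1$calls$area_px, c2$calls$area_px)
})

test_that("focus/background ratios equal masked means", {
  masks <- matrix(1L, 16, 16)
  img <- matrix(2, 16, 16)
  lab <- matrix(0L, 16, 16); lab[8:9, 8:9] <- 1L
  calls <- structure(list(label = lab), class = "focus_call_set")
  # focus pixels equal background: ratio 1, log2 0
  r1 <- focus_background_ratio(img, calls, masks)
  expect_equal(r1$ratio, 1)
  expect_equal(focus_background_ratio(img, calls, masks,
                                      log2_ratio = TRUE)$ratio, 0)
  # focus mean 4x background: log2 = 2
  img2 <- img; img2[lab == 1L] <- 8
  expect_equal(focus_background_ratio(img2, calls, masks,
                                      log2_ratio = TRUE)$ratio, 2)
  # random image matches direct masked means
  set.seed(5)
  img3 <- matrix(runif(256, 1, 9), 16, 16)
  r3 <- focus_background_ratio(img3, calls, masks)
  want <- mean(img3[lab == 1L]) / mean(img3[lab == 0L])
  expect_equal(r3$ratio, want)
  # fully covered cell errors
  full <- structure(list(label = matrix(1L, 16, 16)),
                    class = "focus_call_set")
  expect_error(focus_background_ratio(img, full, masks), "covered")
})

test_that("Spearman colocalization behaves at its limits and under the null", {
  masks <- make_cell_masks(c(72, 72), 2, 2, semi_axes = c(14, 14))
  set.seed(6)
  a <- matrix(runif(72 * 72), 72, 72)
  res_mono <- colocalization_spearman(a, exp(a), masks)
  expect_true(all(res_mono$per_cell$rho == 1))
  expect_equal(res_mono$field_mean, 1)
  res_neg <- colocalization_spearman(a, -a, masks)
  expect_true(all(res_neg$per_cell$rho == -1))
  b <- matrix(runif(72 * 72), 72, 72)
  res_null <- colocalization_spearman(a, b, masks)
  expect_true(all(res_null$per_cell$n_px >= 500))
  expect_lt(abs(res_null$field_mean), 0.1)
  ws <- testthat::capture_warnings(
    res_const <- colocalization_spearman(matrix(1, 72, 72), b, masks))
  expect_true(length(ws) >= 1 && all(grepl("constant", ws)))
  expect_equal(nrow(res_const$per_cell), 0)
})

test_that("FRAP fitting recovers the one-phase association curve", {
  t <- seq(0, 115, by = 5)
  y <- 0.25 + (0.85 - 0.25) * (1 - exp(-log(2) / 8.8 * t))
  f <- fit_frap(t, y)
  expect_equal(f$t_half, 8.8, tolerance = 1e-4)
  expect_equal(f$plateau, 0.85, tolerance = 1e-4)
  expect_false(f$flagged)
  expect_true(f$ci_t_half[1] <= 8.8 && 8.8 <= f$ci_t_half[2])
  flat <- fit_frap(t, rep(0.3, length(t)))
  expect_true(flat$flagged)
  # noisy recovery: sd 0.02, 24 timepoints, many seeded repeats
  errs <- vapply(1:60, function(s) {
    set.seed(s)
    yn <- y + rnorm(length(y), 0, 0.02)
    abs(fit_frap(t, yn)$t_half - 8.8) / 8.8
  }, numeric(1))
  expect_lt(stats::median(errs), 0.15)
  expect_gt(mean(errs < 0.15), 0.8)
})

test_that("FRAP normalization uses the pre-bleach mean and zero timebase", {
  time <- seq(0, 130, by = 5)
  intensity <- c(rep(2, 3), 0.5 * 2, 2 * (0.6 + 0.2 * seq_len(23) / 23))
  tr <- normalize_frap_trace(time, intensity, n_prebleach = 3)
  expect_equal(tr$t[1], 0)
  expect_equal(tr$y[1], 0.5)
  expect_equal(nrow(tr), length(time) - 3)
})

test_that("count normalization to a control group scales its mean to 1", {
  out <- normalize_to_control(c(4, 6, 10, 12), rep(c("ctrl", "trt"), each = 2),
                              "ctrl")
  expect_equal(mean(out$normalized[out$group == "ctrl"]), 1)
  expect_equal(out$normalized[3], 2)
  expect_error(normalize_to_control(c(0, 0), c("ctrl", "t"), "ctrl"), "zero")
})
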