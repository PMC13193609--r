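test_that("trajectory simulation honours config invariants and errors", {
  expect_error(trajectory_sim_config(state_fractions = c(0.5, 0.5, 0.1)),
               "sum to 1")
  expect_error(trajectory_sim_config(diffusion_coeffs = c(1, 0.5, 2)),
               "increasing")
  expect_error(trajectory_sim_config(frame_interval = 0), "positive")
  expect_error(trajectory_sim_config(state_fractions = c(0.5, 0.2, 0.3),
                                     focus_radius = 0),
               "focus_radius")
  empty <- simulate_trajectories(trajectory_sim_config(n_tracks = 0))
  expect_s3_class(empty, "trajectory_set")
  expect_equal(nrow(empty$tracks), 0)
})

test_that("condensate-only tracks stay within the focus boundary", {
  cfg <- trajectory_sim_config(n_tracks = 40,
                               state_fractions = c(1, 0, 0),
                               focus_centers = list(c(2.5, 2.5)),
                               focus_radius = 0.3, seed = 5)
  ts <- simulate_trajectories(cfg)
  expect_true(all(ts$truth$state == 1))
  r <- sqrt((ts$tracks$x_um - 2.5)^2 + (ts$tracks$y_um - 2.5)^2)
  expect_true(all(r <= 0.3 + 3 * cfg$localization_sigma))
})

test_that("free-state displacements follow the Brownian moments", {
  cfg <- trajectory_sim_config(n_tracks = 400, state_fractions = c(0, 0, 1),
                               diffusion_coeffs = c(0.05, 0.3, 2.0),
                               localization_sigma = 0, seed = 3)
  ts <- simulate_trajectories(cfg)
  pool <- pooled_squared_displacements(ts)
  expect_gt(length(pool), 1e4 / 3)
  expected <- 4 * 2.0 * 0.02
  se <- stats::sd(pool) / sqrt(length(pool))
  expect_lt(abs(mean(pool) - expected), 4 * se)
  # step lengths per coordinate are Gaussian => r^2 exponential (Rayleigh r)
  ks <- stats::ks.test(pool, "pexp", rate = 1 / expected)
  expect_gt(ks$p.value, 0.01)
})

test_that("trajectory generator is deterministic given the seed", {
  cfg <- trajectory_sim_config(n_tracks = 50, seed = 11)
  expect_identical(simulate_trajectories(cfg), simulate_trajectories(cfg))
})

test_that("rendered cell images match the planted truth", {
  masks <- make_cell_masks(c(64, 64), 2, 2)
  flat <- synthetic_image_truth(masks, data.frame(row = numeric(0),
                                                  col = numeric(0),
                                                  radius = numeric(0),
                                                  amplitude = numeric(0)),
                                background_level = 50, noise_sigma = 0)
  img <- render_cell_image(flat, seed = 1)
  expect_true(all(img == 50))
  truth <- synthetic_image_truth(masks,
                                 data.frame(row = 16, col = 16, radius = 2,
                                            amplitude = 40),
                                 background_level = 50, noise_sigma = 3)
  img2 <- render_cell_image(truth, seed = 2)
  peak <- which(img2 == max(img2), arr.ind = TRUE)
  expect_lte(max(abs(peak - c(16, 16))), 1)
  expect_identical(render_cell_image(truth, seed = 2),
                   render_cell_image(truth, seed = 2))
  expect_error(synthetic_image_truth(masks,
                                     data.frame(row = 1, col = 1, radius = 2,
                                                amplitude = 10)),
               "inside a cell")
  expect_error(synthetic_image_truth(masks,
                                     data.frame(row = 16, col = 16, radius = 2,
                                                amplitude = -1)),
               "positive")
})

test_that("droplet fields carry pixel-accurate shape truth", {
  empty <- render_droplet_field(NULL, dim = c(64, 64), seed = 1)
  expect_equal(nrow(empty$truth), 0)
  fld <- render_droplet_field(data.frame(row = 32, col = 32, a = 10, b = 10),
                              dim = c(64, 64), seed = 2)
  expect_lt(abs(fld$truth$area_px - pi * 100) / (pi * 100), 0.05)
  ell <- render_droplet_field(data.frame(row = 40, col = 40, a = 20, b = 10),
                              dim = c(96, 96), seed = 2)
  expect_equal(ell$truth$axis_ratio, 2.0)
  expect_error(
    render_droplet_field(data.frame(row = c(32, 34), col = c(32, 34),
                                    a = c(10, 10), b = c(10, 10)),
                         dim = c(64, 64), seed = 1),
    "overlaps")
})

test_that("decay count simulation matches its expectations", {
  cfg <- decay_sim_config(n_genes = 20, seed = 4)
  s1 <- simulate_decay_counts(cfg)
  expect_identical(s1$counts, simulate_decay_counts(cfg)$counts)
  expect_true(all(startsWith(
    rownames(s1$counts)[21:nrow(s1$counts)], "ERCC-")))
  # no-decay genes have equal expected (library-corrected) counts over time
  cfg2 <- decay_sim_config(n_genes = 30, prop_stable = 1,
                           library_size_factors = rep(1, 12), seed = 5)
  s2 <- simulate_decay_counts(cfg2)
  tp_means <- sapply(split(seq_len(12), s2$samples$timepoint_min),
                     function(ix) mean(s2$counts[1:30, ix]))
  expect_lt(diff(range(tp_means)) / mean(tp_means), 0.05)
  # empirical Poisson mean at t = 30 for b = 30: a * exp(-1)
  cfg3 <- decay_sim_config(n_genes = 1, a_range = c(1000, 1000),
                           b_range = c(30, 30), n_replicates = 50,
                           library_size_factors = rep(1, 200), seed = 6)
  s3 <- simulate_decay_counts(cfg3)
  at30 <- s3$counts[1, s3$samples$timepoint_min == 30]
  mu <- 1000 * exp(-1)
  expect_lt(abs(mean(at30) - mu), 3 * stats::sd(at30) / sqrt(length(at30)))
  expect_error(decay_sim_config(timepoints = numeric(0)), "nonempty")
})

test_that("summed depth-corrected counts decrease in time when all b finite", {
  cfg <- decay_sim_config(n_genes = 60, b_range = c(10, 50), seed = 8)
  sim <- simulate_decay_counts(cfg)
  depth_corr <- sweep(sim$counts[1:60, ], 2, cfg$library_size_factors, `/`)
  tot <- tapply(colSums(depth_corr), sim$samples$timepoint_min, mean)
  expect_true(all(diff(tot[order(as.numeric(names(tot)))]) < 0))
})

test_that("poly(A) read simulation places reads and tails correctly", {
  cfg <- polya_sim_config(n_genes = 4, reads_per_gene = 30, seed = 9)
  sim <- simulate_polya_reads(cfg)
  w <- gene_windows(sim$annotation)
  # every read interval inside its gene's 3' window, matching strand
  for (g in seq_len(4)) {
    rd <- sim$reads[startsWith(sim$reads$read_id, sim$annotation$gene_id[g]), ]
    expect_true(all(rd$start >= w$win_start[g] & rd$end <= w$win_end[g]))
    expect_true(all(rd$strand == sim$annotation$strand[g]))
  }
  # full zero inflation: all runs empty
  cfg0 <- polya_sim_config(n_genes = 2, zero_inflation = 1,
                           reads_per_gene = 20, seed = 2)
  sim0 <- simulate_polya_reads(cfg0)
  expect_true(all(sim0$reads$tail_true == 0))
  expect_true(all(!startsWith(sim0$reads$sequence, "T")))
  # ZINB mean identity: mean run ~ (1 - pi) * mu
  cfg1 <- polya_sim_config(n_genes = 1, condition_means = c(6, 6, 6, 6),
                           zero_inflation = 0.3, reads_per_gene = 700,
                           seed = 3)
  sim1 <- simulate_polya_reads(cfg1)
  tails <- sim1$reads$tail_true
  expect_gt(length(tails), 1e4 - 1)
  se <- stats::sd(tails) / sqrt(length(tails))
  expect_lt(abs(mean(tails) - 0.7 * 6), 3 * se)
  expect_error(polya_sim_config(zero_inflation = 1.2), "zero_inflation")
  expect_error(polya_sim_config(overdispersion = 0), "overdispersion")
})
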