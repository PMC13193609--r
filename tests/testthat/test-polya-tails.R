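test_that("terminal-A counting follows the maximal-run rule", {
  expect_equal(count_terminal_As("GCATTTT"), 0L)
  expect_equal(count_terminal_As("TTTTGACCA"), 4L)
  expect_equal(count_terminal_As(strrep("T", 25)), 25L)
  # matches a regex-run oracle and ignores inner T content
  set.seed(2)
  for (i in 1:30) {
    run <- sample(0:12, 1)
    inner <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
                   collapse = "")
    seq <- paste0(strrep("T", run), "G", inner)
    expect_equal(count_terminal_As(seq), run)
    # counting twice changes nothing (idempotent on the same string)
    expect_equal(count_terminal_As(seq), count_terminal_As(seq))
  }
  # total mode counts every T
  expect_equal(count_terminal_As("TTGTT", mode = "total"), 4L)
  expect_equal(count_terminal_As("GATTTT", terminus = "end"), 4L)
})

test_that("3' windows are strand-aware and 301 bases long", {
  ann <- data.frame(gene_id = c("p", "m"), contig = "chr",
                    start = c(1000, 1000), end = c(1900, 1900),
                    strand = c("+", "-"))
  w <- gene_windows(ann)
  expect_equal(w$win_end - w$win_start + 1, c(301, 301))
  expect_equal(w$end3, c(1900, 1000))
  expect_equal(w$win_start[1], 1850)  # 50 before the + 3' end
  expect_equal(w$win_end[1], 2150)    # 250 after
  expect_equal(w$win_start[2], 750)   # 250 after on the - strand
  expect_equal(w$win_end[2], 1050)
})

test_that("read assignment equals the brute-force interval scan", {
  ann <- data.frame(gene_id = c("g1", "g2"), contig = "chr",
                    start = c(1000, 1300), end = c(1400, 1600),
                    strand = c("+", "+"))
  w <- gene_windows(ann)  # windows: g1 [1350, 1650], g2 [1550, 1850]
  reads <- data.frame(
    contig = "chr",
    start = c(1390, 1622, 1390, 1531, 100),
    end = c(1400, 1651, 1400, 1560, 130),
    strand = c("+", "+", "-", "+", "+"))
  got <- assign_read_to_gene(reads, w)
  expect_equal(got[1], "g1")      # right at the 3' end
  expect_equal(got[2], "g2")      # past g1's window but inside g2's
  expect_true(is.na(got[3]))      # opposite strand
  expect_equal(got[4], "g2")      # in both windows: nearest 3' end wins
  expect_true(is.na(got[5]))      # far away
  # 251 bases past the 3' end: outside the window of an isolated gene
  w1 <- w[w$gene_id == "g1", ]
  at250 <- data.frame(contig = "chr", start = 1620, end = 1650, strand = "+")
  at251 <- data.frame(contig = "chr", start = 1622, end = 1651, strand = "+")
  expect_equal(assign_read_to_gene(at250, w1), "g1")
  expect_true(is.na(assign_read_to_gene(at251, w1)))
  # randomized reads against the oracle
  set.seed(11)
  cfg <- polya_sim_config(n_genes = 12, reads_per_gene = 12, seed = 11)
  sim <- simulate_polya_reads(cfg)
  w2 <- gene_windows(sim$annotation)
  rnd <- sim$reads[sample(nrow(sim$reads), 400), ]
  # jitter a third of them off-window
  ji <- sample(nrow(rnd), 130)
  rnd$start[ji] <- rnd$start[ji] + sample(c(-4000, 4000), 130, replace = TRUE)
  rnd$end[ji] <- rnd$end[ji] + (rnd$start[ji] - (rnd$end[ji] - 29) + 29) * 0
  rnd$end[ji] <- rnd$start[ji] + 29
  expect_equal(assign_read_to_gene(rnd, w2), oracle_assign(rnd, w2))
})

test_that("ZINB fitting matches the plain NB limit when inflation is absent", {
  skip_if_not_installed("MASS")
  set.seed(5)
  cond <- rep(c("a", "b", "c", "d"), each = 1500)
  mu <- c(a = 5, b = 8, c = 5, d = 3)
  y <- stats::rnbinom(6000, mu = mu[cond], size = 4)
  f <- fit_gene_zinb(y, cond)
  expect_lte(f$zero_inflation, 0.05)
  nb <- MASS::glm.nb(y ~ 0 + factor(cond))
  mu_nb <- exp(stats::coef(nb))
  expect_true(all(abs(f$mu - mu_nb) / mu_nb < 0.05))
})

test_that("ZINB fitting recovers planted parameters and honours the cap", {
  set.seed(6)
  cond <- rep(c("a", "b", "c", "d"), each = 2500)
  mu <- c(a = 6, b = 6, c = 6, d = 3)
  pi0 <- 0.3
  y <- ifelse(stats::runif(10000) < pi0, 0L,
              stats::rnbinom(10000, mu = mu[cond], size = 5))
  f <- fit_gene_zinb(y, cond)
  expect_true(all(abs(f$mu - mu) / mu < 0.10))
  expect_lt(abs(f$zero_inflation - pi0), 0.05)
  expect_lte(f$iterations, 500)
  expect_true(f$converged)
  # all-zero gene: inflation 1, flagged
  f0 <- fit_gene_zinb(rep(0L, 40), rep(c("a", "b", "c", "d"), 10))
  expect_equal(f0$zero_inflation, 1)
  expect_true(f0$flagged)
})

test_that("tail-length contrasts are calibrated and detect planted shifts", {
  # identical conditions: deltas near 0, p roughly uniform
  set.seed(7)
  n_genes <- 25
  obs <- do.call(rbind, lapply(seq_len(n_genes), function(g) {
    cond <- rep(c("a", "b", "c", "d"), each = 400)
    y <- ifelse(stats::runif(1600) < 0.2, 0L,
                stats::rnbinom(1600, mu = 6, size = 5))
    data.frame(gene_id = sprintf("g%02d", g), sample = cond,
               condition = cond, tail_length = y)
  }))
  fits <- fit_all_zinb(obs)
  cmp <- compare_tail_lengths(fits, "a", "b")
  expect_lt(abs(stats::median(cmp$contrasts$delta_mean)), 0.3)
  expect_gt(stats::ks.test(cmp$contrasts$p_value, "punif")$p.value, 0.01)
  # planted -2 base shift in condition d
  obs2 <- do.call(rbind, lapply(seq_len(n_genes), function(g) {
    cond <- rep(c("a", "b", "c", "d"), each = 400)
    mu <- ifelse(cond == "d", 4, 6)
    y <- ifelse(stats::runif(1600) < 0.2, 0L,
                stats::rnbinom(1600, mu = mu, size = 5))
    data.frame(gene_id = sprintf("g%02d", g), sample = cond,
               condition = cond, tail_length = y)
  }))
  fits2 <- fit_all_zinb(obs2)
  cmp2 <- compare_tail_lengths(fits2, "d", "a")
  expect_lt(abs(stats::median(cmp2$contrasts$delta_mean) - (-2)), 0.5)
  # cumulative curves are proper CDFs
  cdf <- compare_tail_lengths(fits2, "a", "b")$cumulative("d")
  grid <- seq(0, 12, by = 0.5)
  expect_true(all(diff(cdf(grid)) >= 0))
  expect_equal(cdf(100), 1)
})

test_that("the full poly(A) pipeline recovers planted condition means", {
  cfg <- polya_sim_config(n_genes = 3, condition_means = c(6, 6, 6, 3),
                          zero_inflation = 0.3, reads_per_gene = 150,
                          seed = 21)
  sim <- simulate_polya_reads(cfg)
  obs <- tail_observations(sim$reads, sim$annotation)
  fits <- fit_all_zinb(obs)
  expect_length(fits, 3)
  err <- vapply(fits, function(f) {
    mu_hat <- f$mu[c("WT.Nplus", "WT.N24", "dppk.Nplus", "dppk.N24")]
    max(abs(mu_hat - c(6, 6, 6, 3)) / c(6, 6, 6, 3))
  }, numeric(1))
  expect_true(stats::median(err) < 0.15)
})
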