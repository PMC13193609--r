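#' Equally populated quantile bins of effect sizes
#'
#' Rank-based binning into `n_bins` equally populated bins (sizes differing by
#' at most one); ties are broken by stable input order. Bin 1 holds the
#' smallest values.
#'
#' @param values numeric vector (per-gene effect sizes).
#' @param n_bins number of bins (default quintiles).
#' @return integer vector of bin labels in 1..n_bins.
#' @export
quintile_bins <- function(values, n_bins = 5) {
  n <- length(values)
  if (n < n_bins) stop("fewer values than bins")
  if (length(unique(values)) == 1)
    warning("all values equal: bins assigned by stable input order")
  o <- order(values)                      # stable for ties
  sizes <- rep(n %/% n_bins, n_bins)
  extra <- n %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bins <- integer(n)
  bins[o] <- rep(seq_len(n_bins), times = sizes)
  bins
}

#' Odds-ratio enrichment of a term within a bin
#'
#' 2x2 table of term x bin membership over the universe; the odds ratio uses
#' the small-sample correction (+0.5 to every cell) and the p-value is the
#' Yates continuity-corrected chi-square. The 95% CI is on the corrected
#' log odds ratio (Woolf with +0.5).
#'
#' @param term_members,bin_members,universe character/id vectors; members must
#'   lie within the universe.
#' @return list of class `odds_ratio_result`: `table` (2x2), `odds_ratio`,
#'   `log2_odds_ratio`, `ci` (ratio scale), `p_value`.
#' @export
term_odds_ratio <- function(term_members, bin_members, universe) {
  if (length(universe) == 0) stop("empty universe")
  universe <- unique(universe)
  term_members <- intersect(unique(term_members), universe)
  bin_members <- intersect(unique(bin_members), universe)
  a <- length(intersect(term_members, bin_members))
  b <- length(setdiff(bin_members, term_members))
  c <- length(setdiff(term_members, bin_members))
  d <- length(universe) - a - b - c
  tab <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE,
                dimnames = list(bin = c("in", "out"),
                                term = c("in", "out")))
  or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  se <- sqrt(1 / (a + 0.5) + 1 / (b + 0.5) + 1 / (c + 0.5) + 1 / (d + 0.5))
  ci <- exp(log(or) + c(-1, 1) * 1.96 * se)
  p <- tryCatch(
    suppressWarnings(stats::chisq.test(tab, correct = TRUE)$p.value),
    error = function(e) NA_real_)
  structure(list(table = tab, odds_ratio = or, log2_odds_ratio = log2(or),
                 ci = ci, p_value = p),
            class = "odds_ratio_result")
}

#' Permutation test for annotation-set overlaps
#'
#' Observed overlap sizes of a query set with each reference set (and their
#' joint overlap) are compared against a null in which same-size sets are
#' drawn uniformly from the universe; the optional `annotate` function maps a
#' drawn element set to the label space in which overlaps are counted (e.g.
#' proteins to GO terms). p = (1 + #{null >= observed}) / (n_perm + 1), so it
#' never returns 0.
#'
#' @param query_set elements of the query (pre-annotation space).
#' @param reference_sets named list of sets in the overlap (label) space.
#' @param universe pool the null redraws from.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param annotate function mapping an element vector to label space
#'   (default identity).
#' @param tie_break "conservative" (default; ties with the observed overlap
#'   count toward the tail, so p never understates significance) or
#'   "randomized" (ties split uniformly, giving an exactly uniform p under
#'   the null — the right instrument for calibration checks).
#' @return list of class `permutation_result`: `observed` (named overlap
#'   sizes incl. `joint`), `p` (named), `n_perm`, `seed`.
#' @export
overlap_permutation_test <- function(query_set, reference_sets, universe,
                                     n_perm = 1000, seed = 1L,
                                     annotate = identity,
                                     tie_break = c("conservative",
                                                   "randomized")) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  tie_break <- match.arg(tie_break)
  query_set <- unique(query_set)
  if (length(query_set) > length(unique(universe)))
    stop("query larger than universe")
  overlaps <- function(labels) {
    two <- vapply(reference_sets, function(r)
      length(intersect(labels, r)), numeric(1))
    joint <- length(Reduce(intersect, c(list(labels), reference_sets)))
    c(two, joint = joint)
  }
  obs <- overlaps(annotate(query_set))
  set.seed(as.integer(seed))
  gt <- numeric(length(obs))
  eq <- numeric(length(obs))
  for (i in seq_len(n_perm)) {
    ov <- overlaps(annotate(sample(universe, length(query_set))))
    gt <- gt + (ov > obs)
    eq <- eq + (ov == obs)
  }
  p <- if (tie_break == "conservative") {
    (1 + gt + eq) / (n_perm + 1)
  } else {
    (stats::runif(length(obs)) * (1 + eq) + gt) / (n_perm + 1)
  }
  structure(list(observed = obs, p = p, n_perm = n_perm,
                 seed = as.integer(seed), tie_break = tie_break),
            class = "permutation_result")
}

#' One-sample proportion test
#'
#' z = (k/n - p0) / sqrt(p0 (1 - p0) / n) with a two-sided normal p-value;
#' `method = "binomial"` gives the exact binomial p instead. The fold
#' enrichment (k/n) / p0 is reported alongside.
#'
#' @param k successes.
#' @param n trials.
#' @param p0 null proportion in (0, 1).
#' @param method "normal" or "binomial".
#' @return list: `z`, `p_value`, `estimate` (k/n), `fold_enrichment`.
#' @export
proportion_test <- function(k, n, p0, method = c("normal", "binomial")) {
  method <- match.arg(method)
  if (n <= 0) stop("n must be positive")
  stopifnot(k >= 0, k <= n, p0 > 0, p0 < 1)
  est <- k / n
  z <- (est - p0) / sqrt(p0 * (1 - p0) / n)
  p <- if (method == "normal") 2 * stats::pnorm(-abs(z))
  else stats::binom.test(k, n, p0)$p.value
  list(z = z, p_value = p, estimate = est, fold_enrichment = est / p0)
}
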