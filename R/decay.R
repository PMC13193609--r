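#' Spike-in normalization of a rifampicin-chase count matrix
#'
#' Per sample, counts are converted to relative abundances (divided by the
#' sample total) and then rescaled by the median relative abundance of the
#' qualifying spike-in transcripts (relative abundance > `min_spike_rel`),
#' yielding a per-cell abundance estimate robust to library-size and global
#' RNA-content changes. Spike-in rows are carried through, normalized the same
#' way, which makes the operation idempotent.
#'
#' @param counts nonnegative matrix, genes + spike-ins x samples.
#' @param spike_rows logical vector per row, or NULL to flag rows whose name
#'   starts with `spike_prefix`.
#' @param spike_prefix row-name prefix marking spike-ins.
#' @param min_spike_rel relative-abundance floor for a spike-in to enter the
#'   median.
#' @return list of class `normalized_abundances`: `abundances` (matrix, all
#'   rows), `spike_rows`, `factors` (per-sample median qualifying spike-in
#'   relative abundance).
#' @export
normalize_counts <- function(counts, spike_rows = NULL,
                             spike_prefix = "ERCC-", min_spike_rel = 5e-4) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  if (is.null(spike_rows))
    spike_rows <- startsWith(rownames(counts), spike_prefix)
  if (!any(spike_rows)) stop("no spike-in rows found")
  totals <- colSums(counts)
  if (any(totals <= 0)) stop("sample with zero total count")
  rel <- sweep(counts, 2, totals, `/`)
  factors <- vapply(seq_len(ncol(rel)), function(s) {
    v <- rel[spike_rows, s]
    v <- v[v > min_spike_rel]
    if (length(v) == 0)
      stop("sample ", colnames(counts)[s] %||% s,
           " has no qualifying spike-in (relative abundance > ",
           min_spike_rel, ")")
    stats::median(v)
  }, numeric(1))
  structure(list(abundances = sweep(rel, 2, factors, `/`),
                 spike_rows = spike_rows, factors = factors),
            class = "normalized_abundances")
}

#' Fit an exponential decay to one gene's abundance series
#'
#' Bounded nonlinear least squares of `y = a * exp(-t / b)` with both
#' parameters constrained nonnegative and initialized at a = 0.001, b = 20
#' (minutes). The p-value of the decay constant comes from its t statistic
#' (estimate / standard error, df = n - 2).
#'
#' @param t timepoints, minutes.
#' @param y normalized abundances (replicate-level observations).
#' @return list of class `decay_fit`: `a`, `b` (minutes), `r_squared`,
#'   `p_value` (for b), `converged`.
#' @export
fit_decay <- function(t, y) {
  stopifnot(length(t) == length(y))
  bad <- structure(list(a = NA_real_, b = NA_real_, r_squared = NA_real_,
                        p_value = NA_real_, converged = FALSE),
                   class = "decay_fit")
  if (length(unique(t)) < 3 || all(y == 0)) return(bad)
  dat <- data.frame(t = t, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-t / b), data = dat,
                      start = list(a = 0.001, b = 20),
                      lower = c(0, 0), upper = c(Inf, Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 1000)),
    error = function(e) NULL)
  if (is.null(fit)) return(bad)
  cf <- stats::coef(fit)
  res <- stats::residuals(fit)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else NA_real_
  p <- tryCatch({
    sm <- summary(fit)
    unname(sm$coefficients["b", "Pr(>|t|)"])
  }, error = function(e) NA_real_)
  structure(list(a = unname(cf["a"]), b = unname(cf["b"]), r_squared = r2,
                 p_value = p, converged = TRUE),
            class = "decay_fit")
}

#' Fit exponential decays for every gene of a normalized matrix
#'
#' Replicate-level observations enter the fit directly (preserving degrees of
#' freedom for the decay-constant t statistic). Genes with all-zero abundance
#' are skipped.
#'
#' @param norm a `normalized_abundances` (or abundance matrix).
#' @param samples data.frame with `sample` and `timepoint_min` matching
#'   columns.
#' @return data.frame: gene, a, b, r_squared, p_value, q_value (BH across
#'   fitted genes), converged.
#' @export
fit_decay_matrix <- function(norm, samples) {
  ab <- if (inherits(norm, "normalized_abundances")) {
    norm$abundances[!norm$spike_rows, , drop = FALSE]
  } else norm
  stopifnot(ncol(ab) == nrow(samples))
  tp <- samples$timepoint_min
  rows <- lapply(seq_len(nrow(ab)), function(i) {
    f <- fit_decay(tp, ab[i, ])
    data.frame(gene = rownames(ab)[i] %||% as.character(i),
               a = f$a, b = f$b, r_squared = f$r_squared,
               p_value = f$p_value, converged = f$converged)
  })
  res <- do.call(rbind, rows)
  res$q_value <- NA_real_
  ok <- res$converged & !is.na(res$p_value)
  res$q_value[ok] <- stats::p.adjust(res$p_value[ok], method = "BH")
  res
}

#' Filter decay fits and classify genotype stability changes
#'
#' Keeps genes whose fits are confident in both genotypes (q < `max_q` and
#' R^2 > `min_r2`) and classifies each by the decay-constant pair:
#' stable-vs-unstable when tau exceeds 65 min in one genotype and is below
#' 55 min in the other; directional (`WT_gt_mut` / `mut_gt_WT`) when both are
#' below 65 min and one exceeds the other by at least 10 min; otherwise
#' unclassified. Decay constants are additionally flagged "measurable" when
#' inside the 5-65 min window.
#'
#' @param fits_wt,fits_mut data.frames from [fit_decay_matrix()].
#' @param max_q,min_r2 fit-confidence filters.
#' @param stable_hi,stable_lo,directional_margin classification thresholds,
#'   minutes.
#' @return data.frame: gene, b_wt, b_mut, kept, category, measurable_wt,
#'   measurable_mut.
#' @export
filter_and_classify <- function(fits_wt, fits_mut, max_q = 0.1, min_r2 = 0.5,
                                stable_hi = 65, stable_lo = 55,
                                directional_margin = 10) {
  genes <- union(fits_wt$gene, fits_mut$gene)
  iw <- match(genes, fits_wt$gene)
  im <- match(genes, fits_mut$gene)
  b_wt <- fits_wt$b[iw]; b_mut <- fits_mut$b[im]
  ok_wt <- !is.na(iw) & fits_wt$converged[iw] &
    !is.na(fits_wt$q_value[iw]) & fits_wt$q_value[iw] < max_q &
    !is.na(fits_wt$r_squared[iw]) & fits_wt$r_squared[iw] > min_r2
  ok_mut <- !is.na(im) & fits_mut$converged[im] &
    !is.na(fits_mut$q_value[im]) & fits_mut$q_value[im] < max_q &
    !is.na(fits_mut$r_squared[im]) & fits_mut$r_squared[im] > min_r2
  kept <- ok_wt & ok_mut
  category <- rep("unclassified", length(genes))
  category[!(!is.na(iw) & !is.na(im))] <- "unclassified"
  cl <- classify_stability(b_wt, b_mut, stable_hi, stable_lo,
                           directional_margin)
  category[kept] <- cl[kept]
  data.frame(gene = genes, b_wt = b_wt, b_mut = b_mut, kept = kept,
             category = category,
             measurable_wt = !is.na(b_wt) & b_wt >= 5 & b_wt <= 65,
             measurable_mut = !is.na(b_mut) & b_mut >= 5 & b_mut <= 65)
}

#' Stability category from a pair of decay constants
#'
#' Pure rule: `stable_vs_unstable_WT` when tau_WT > 65 and tau_mut < 55 min
#' (and the mirror category for the mutant); `WT_gt_mut` / `mut_gt_WT` when
#' both are < 65 min and one exceeds the other by >= 10 min; else
#' `unclassified`.
#'
#' @param b_wt,b_mut decay constants, minutes (vectorized).
#' @param stable_hi,stable_lo,directional_margin thresholds, minutes.
#' @return character vector of categories.
#' @export
classify_stability <- function(b_wt, b_mut, stable_hi = 65, stable_lo = 55,
                               directional_margin = 10) {
  out <- rep("unclassified", length(b_wt))
  ok <- !is.na(b_wt) & !is.na(b_mut)
  sw <- ok & b_wt > stable_hi & b_mut < stable_lo
  sm <- ok & b_mut > stable_hi & b_wt < stable_lo
  both <- ok & b_wt < stable_hi & b_mut < stable_hi
  wg <- both & (b_wt - b_mut) >= directional_margin
  mg <- both & (b_mut - b_wt) >= directional_margin
  out[sw] <- "stable_vs_unstable_WT"
  out[sm] <- "stable_vs_unstable_mut"
  out[wg] <- "WT_gt_mut"
  out[mg] <- "mut_gt_WT"
  out
}

#' Compare half-life distributions between genotypes
#'
#' Median shift of the mutant relative to the wild type, as a percentage, with
#' a two-sided (unpaired) Wilcoxon rank-sum p-value. Also usable for
#' comparing a gene subset's half-life changes against the complement.
#'
#' @param tau_wt,tau_mut numeric vectors (decay constants or half-lives).
#' @return list: `median_shift_pct` = 100 * (median(mut) - median(WT)) /
#'   median(WT), `p_value`, `n_wt`, `n_mut`.
#' @export
compare_half_lives <- function(tau_wt, tau_mut) {
  if (length(tau_wt) < 3 || length(tau_mut) < 3)
    stop("need at least 3 values per group")
  shift <- 100 * (stats::median(tau_mut) - stats::median(tau_wt)) /
    stats::median(tau_wt)
  p <- stats::wilcox.test(tau_mut, tau_wt, exact = FALSE)$p.value
  list(median_shift_pct = shift, p_value = p,
       n_wt = length(tau_wt), n_mut = length(tau_mut))
}
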