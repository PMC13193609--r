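#' Configuration for a rifampicin-chase count simulation
#'
#' Ground truth for a transcription-shutoff time course: per-gene abundances
#' decay as `a * exp(-t / b)`, spike-in transcripts stay constant, and every
#' sample carries its own library-size factor. Defaults follow a 4-timepoint
#' chase (0/10/30/60 min) with 3 replicates.
#'
#' @param n_genes number of genomic features.
#' @param a_range interval for baseline expected counts at t = 0.
#' @param b_range interval (minutes) for decay constants; genes may instead be
#'   marked non-decaying via `prop_stable`.
#' @param prop_stable fraction of genes flagged no-decay (b = Inf).
#' @param timepoints minutes, nonnegative increasing.
#' @param n_replicates replicates per timepoint.
#' @param library_size_factors per-sample positive factors, length
#'   `length(timepoints) * n_replicates`, or NULL for lognormal variation.
#' @param ercc_abundances fixed expected counts of the spike-in rows.
#' @param overdispersion NULL for Poisson sampling (default) or a positive
#'   negative-binomial size parameter.
#' @param a_values,b_values optional explicit per-gene parameters (override
#'   the ranges); useful for paired-genotype designs.
#' @param seed integer seed.
#' @return object of class `decay_sim_config`.
#' @export
decay_sim_config <- function(n_genes = 200,
                             a_range = c(200, 2000),
                             b_range = c(10, 60),
                             a_values = NULL,
                             b_values = NULL,
                             prop_stable = 0,
                             timepoints = c(0, 10, 30, 60),
                             n_replicates = 3,
                             library_size_factors = NULL,
                             ercc_abundances = round(exp(seq(log(300),
                                                             log(8000),
                                                             length.out = 20))),
                             overdispersion = NULL,
                             seed = 1L) {
  if (length(timepoints) == 0) stop("timepoints must be nonempty")
  if (any(timepoints < 0) || any(diff(timepoints) <= 0))
    stop("timepoints must be nonnegative and increasing")
  n_samples <- length(timepoints) * n_replicates
  if (is.null(library_size_factors)) {
    set.seed(as.integer(seed) + 1L)
    library_size_factors <- exp(stats::rnorm(n_samples, 0, 0.15))
  }
  if (any(library_size_factors <= 0)) stop("library_size_factors must be > 0")
  if (length(library_size_factors) != n_samples)
    stop("need one library size factor per sample")
  if (!is.null(a_values)) stopifnot(length(a_values) == n_genes,
                                    all(a_values >= 0))
  if (!is.null(b_values)) stopifnot(length(b_values) == n_genes,
                                    all(b_values > 0))
  structure(list(n_genes = n_genes, a_range = a_range, b_range = b_range,
                 a_values = a_values, b_values = b_values,
                 prop_stable = prop_stable, timepoints = timepoints,
                 n_replicates = n_replicates,
                 library_size_factors = library_size_factors,
                 ercc_abundances = ercc_abundances,
                 overdispersion = overdispersion,
                 seed = as.integer(seed)),
            class = "decay_sim_config")
}

#' Simulate a rifampicin-chase count matrix with spike-ins
#'
#' Expected gene counts are `a * exp(-t / b) * library_factor`, sampled with
#' Poisson noise (or negative binomial when overdispersion is set); spike-in
#' rows (`ERCC-...`) have time-invariant expectations scaled only by the
#' library factor.
#'
#' @param config a [decay_sim_config()].
#' @return list with `counts` (matrix, genes + spike-ins x samples),
#'   `samples` (data.frame: sample, timepoint_min, replicate), and `truth`
#'   (data.frame: gene, a, b; b = Inf for no-decay genes).
#' @export
simulate_decay_counts <- function(config) {
  stopifnot(inherits(config, "decay_sim_config"))
  set.seed(config$seed)
  tp <- rep(config$timepoints, each = config$n_replicates)
  rep_id <- rep(seq_len(config$n_replicates), times = length(config$timepoints))
  n_s <- length(tp)
  a <- config$a_values %||%
    stats::runif(config$n_genes, config$a_range[1], config$a_range[2])
  b <- config$b_values %||%
    stats::runif(config$n_genes, config$b_range[1], config$b_range[2])
  stable <- stats::runif(config$n_genes) < config$prop_stable
  b[stable] <- Inf
  mu_gene <- outer(a, rep(1, n_s)) * exp(-outer(1 / b, tp))
  mu_gene <- sweep(mu_gene, 2, config$library_size_factors, `*`)
  mu_ercc <- outer(config$ercc_abundances, config$library_size_factors)
  mu <- rbind(mu_gene, mu_ercc)
  counts <- if (is.null(config$overdispersion)) {
    matrix(stats::rpois(length(mu), mu), nrow(mu), ncol(mu))
  } else {
    matrix(stats::rnbinom(length(mu), mu = mu, size = config$overdispersion),
           nrow(mu), ncol(mu))
  }
  gene_ids <- sprintf("gene%04d", seq_len(config$n_genes))
  ercc_ids <- sprintf("ERCC-%05d", seq_along(config$ercc_abundances))
  rownames(counts) <- c(gene_ids, ercc_ids)
  colnames(counts) <- sprintf("t%03d_r%d", tp, rep_id)
  list(counts = counts,
       samples = data.frame(sample = colnames(counts), timepoint_min = tp,
                            replicate = rep_id),
       truth = data.frame(gene = gene_ids, a = a, b = b))
}
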