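#' Configuration for untemplated poly(A) tail-read simulation
#'
#' Ground truth for a 3'-tail sequencing experiment over a 2x2 design
#' (genotype x nitrogen status, four replicates each): per gene and condition,
#' the length of the untemplated tail follows a zero-inflated negative
#' binomial with shared inflation and overdispersion.
#'
#' @param n_genes number of genes.
#' @param condition_means n_genes x 4 matrix (or length-4 vector recycled to
#'   all genes) of negative-binomial mean tail lengths per condition, in the
#'   order WT.Nplus, WT.N24, dppk.Nplus, dppk.N24.
#' @param zero_inflation probability in `[0, 1]` of a structurally absent tail.
#' @param overdispersion positive NB size parameter (larger = closer to
#'   Poisson).
#' @param reads_per_gene reads per gene per sample.
#' @param n_replicates replicates per condition.
#' @param gene_annotation data.frame with gene_id, contig, start, end
#'   (1-based inclusive), strand; NULL for an auto-generated single-contig
#'   annotation.
#' @param contig_length length of the contig(s), bases.
#' @param read_template_length templated (genome-matching) bases per read.
#' @param seed integer seed.
#' @return object of class `polya_sim_config`.
#' @export
polya_sim_config <- function(n_genes = 50,
                             condition_means = c(6, 8, 6, 5),
                             zero_inflation = 0.3,
                             overdispersion = 5,
                             reads_per_gene = 200,
                             n_replicates = 4,
                             gene_annotation = NULL,
                             contig_length = NULL,
                             read_template_length = 30,
                             seed = 1L) {
  if (zero_inflation < 0 || zero_inflation > 1)
    stop("zero_inflation must be in [0, 1]")
  if (overdispersion <= 0) stop("overdispersion must be positive")
  if (is.null(dim(condition_means)))
    condition_means <- matrix(rep(condition_means, each = n_genes), n_genes, 4)
  stopifnot(ncol(condition_means) == 4, nrow(condition_means) == n_genes)
  if (is.null(gene_annotation)) {
    gene_len <- 900L
    spacing <- 1500L
    start <- 1000L + (seq_len(n_genes) - 1L) * spacing
    gene_annotation <- data.frame(
      gene_id = sprintf("gene%04d", seq_len(n_genes)),
      contig = "chr",
      start = start, end = start + gene_len - 1L,
      strand = rep(c("+", "-"), length.out = n_genes),
      stringsAsFactors = FALSE
    )
  }
  if (!all(gene_annotation$strand %in% c("+", "-")))
    stop("annotation strands must be '+' or '-'")
  if (is.null(contig_length))
    contig_length <- max(gene_annotation$end) + 1000L
  structure(list(n_genes = n_genes, condition_means = condition_means,
                 zero_inflation = zero_inflation,
                 overdispersion = overdispersion,
                 reads_per_gene = reads_per_gene,
                 n_replicates = n_replicates,
                 gene_annotation = gene_annotation,
                 contig_length = contig_length,
                 read_template_length = read_template_length,
                 seed = as.integer(seed)),
            class = "polya_sim_config")
}

## 3' window of a gene in genome coordinates (1-based inclusive):
## 50 bases before to 250 bases after the 3' end, in transcription direction.
gene_3p_window <- function(start, end, strand,
                           upstream = 50L, downstream = 250L) {
  if (strand == "+") c(end - upstream, end + downstream)
  else c(start - downstream, start + upstream)
}

#' Simulate 3'-tail sequencing reads with untemplated terminal runs
#'
#' Each read is placed (fully) inside its gene's 3' window on the gene's
#' strand and carries a leading run of 'T' bases whose length is drawn from
#' the gene x condition zero-inflated negative binomial; the first templated
#' base after the run is never 'T', so the run length is exactly the planted
#' tail length.
#'
#' @param config a [polya_sim_config()].
#' @return list with `reads` (data.frame: read_id, sample, condition,
#'   replicate, contig, start, end, strand, sequence, tail_true),
#'   `annotation` and `truth` (condition_means, zero_inflation,
#'   overdispersion).
#' @export
simulate_polya_reads <- function(config) {
  stopifnot(inherits(config, "polya_sim_config"))
  set.seed(config$seed)
  ann <- config$gene_annotation
  conditions <- c("WT.Nplus", "WT.N24", "dppk.Nplus", "dppk.N24")
  tmpl_len <- config$read_template_length
  out <- vector("list", config$n_genes * 4 * config$n_replicates)
  ix <- 0L
  for (g in seq_len(config$n_genes)) {
    w <- gene_3p_window(ann$start[g], ann$end[g], ann$strand[g])
    if (w[1] < 1 || w[2] > config$contig_length)
      stop("3' window of ", ann$gene_id[g], " lies outside the contig")
    for (ci in 1:4) for (r in seq_len(config$n_replicates)) {
      n <- config$reads_per_gene
      tail_len <- ifelse(
        stats::runif(n) < config$zero_inflation, 0L,
        stats::rnbinom(n, mu = config$condition_means[g, ci],
                       size = config$overdispersion))
      # place the templated interval fully inside the window
      if (ann$strand[g] == "+") {
        p_end <- sample(seq.int(w[1] + tmpl_len - 1L, w[2]), n, replace = TRUE)
        p_start <- p_end - tmpl_len + 1L
      } else {
        p_start <- sample(seq.int(w[1], w[2] - tmpl_len + 1L), n, replace = TRUE)
        p_end <- p_start + tmpl_len - 1L
      }
      first <- sample(c("A", "C", "G"), n, replace = TRUE)
      rest <- vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), tmpl_len - 1L, replace = TRUE),
              collapse = ""), character(1))
      ix <- ix + 1L
      out[[ix]] <- data.frame(
        read_id = sprintf("%s_%s_r%d_%04d", ann$gene_id[g], conditions[ci],
                          r, seq_len(n)),
        sample = sprintf("%s_r%d", conditions[ci], r),
        condition = conditions[ci], replicate = r,
        contig = ann$contig[g], start = p_start, end = p_end,
        strand = ann$strand[g],
        sequence = paste0(strrep("T", tail_len), first, rest),
        tail_true = as.integer(tail_len),
        stringsAsFactors = FALSE
      )
    }
  }
  list(reads = do.call(rbind, out[seq_len(ix)]),
       annotation = ann,
       truth = list(condition_means = config$condition_means,
                    zero_inflation = config$zero_inflation,
                    overdispersion = config$overdispersion,
                    conditions = conditions))
}
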