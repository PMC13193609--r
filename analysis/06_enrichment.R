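#!/usr/bin/env Rscript
# Set-level enrichment statistics on synthetic annotations.
#
# Builds a gene universe with per-gene stability changes in which one
# functional term is planted in the top quintile, computes quintile x term
# odds ratios (small-sample + Yates correction), runs the overlap
# permutation test between a planted protein set and reference condensate
# annotations, and the one-sample proportion test on a planted pulldown
# overlap. Tables land in results/enrichment/.

suppressMessages(library(condensateR))
seed <- 1L
out <- "results/enrichment"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

set.seed(seed)
n <- 1000
genes <- sprintf("gene%04d", seq_len(n))
# planted effect: members of term T1 sit high, T2 is null
t1 <- sample(genes, 60)
t2 <- sample(genes, 60)
effect <- rnorm(n)
effect[genes %in% t1] <- effect[genes %in% t1] + 2.2
bins <- quintile_bins(effect)
terms <- rbind(data.frame(term_id = "T1_planted", gene_id = t1),
               data.frame(term_id = "T2_null", gene_id = t2))

res <- do.call(rbind, lapply(split(terms$gene_id, terms$term_id),
                             function(members) NULL))
rows <- list()
for (tm in unique(terms$term_id)) {
  members <- terms$gene_id[terms$term_id == tm]
  for (bn in 1:5) {
    orr <- term_odds_ratio(members, genes[bins == bn], genes)
    rows[[length(rows) + 1]] <- data.frame(
      term_id = tm, quintile = bn, odds_ratio = orr$odds_ratio,
      log2_odds_ratio = orr$log2_odds_ratio, ci_low = orr$ci[1],
      ci_high = orr$ci[2], p_value = orr$p_value)
  }
}
enr <- do.call(rbind, rows)
enr$q_value <- p.adjust(enr$p_value, "BH")
write.table(enr, file.path(out, "quintile_odds_ratios.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
top <- enr[enr$term_id == "T1_planted" & enr$quintile == 5, ]
cat(sprintf("Planted term, top quintile: log2 OR = %.2f (q = %.2g)\n",
            top$log2_odds_ratio, top$q_value))
cat(sprintf("Null term |log2 OR| range: %.2f-%.2f\n",
            min(abs(enr$log2_odds_ratio[enr$term_id == "T2_null"])),
            max(abs(enr$log2_odds_ratio[enr$term_id == "T2_null"]))))

# overlap permutation test: planted condensate proteome vs two references
universe <- sprintf("prot%04d", seq_len(1500))
ref_pbody <- sample(universe, 200)
ref_sg <- sample(universe, 180)
query <- unique(c(sample(ref_pbody, 70), sample(universe, 50)))
perm <- overlap_permutation_test(query, list(pbody = ref_pbody, sg = ref_sg),
                                 universe, n_perm = 1000, seed = seed)
cat("Observed overlaps:", paste(names(perm$observed), perm$observed,
                                collapse = ", "), "\n")
cat("Permutation p:", paste(names(perm$p), signif(perm$p, 3),
                            collapse = ", "), "\n")
write.table(data.frame(set = names(perm$observed),
                       observed = perm$observed, p = perm$p),
            file.path(out, "overlap_permutation.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# the pulldown proportion test on a planted 45%-of-76 vs 8% background
pt <- proportion_test(34, 76, 0.08)
cat(sprintf("Proportion test: %.0f%% of 76 vs 8%% background -> %.1f-fold, z = %.1f, p = %.2g\n",
            100 * pt$estimate, pt$fold_enrichment, pt$z, pt$p_value))
write.table(data.frame(k = 34, n = 76, p0 = 0.08, z = pt$z,
                       p_value = pt$p_value,
                       fold_enrichment = pt$fold_enrichment),
            file.path(out, "proportion_test.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
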