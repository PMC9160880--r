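#!/usr/bin/env Rscript
# Gene-set transcriptome statistics on the simulated expression table:
# per-sample normalization to a mean signal of 500, one-sided
# Mann-Whitney shift tests per gene set (dual CMP/AbrB members
# excluded), volcano DE classification (|log2FC| >= 1, p < 0.05) and the
# 1.5-fold-change classification.

suppressPackageStartupMessages(library(emuflux))

sim <- file.path("results", "simulated")
sig <- utils::read.delim(file.path(sim, "expression.tsv"),
                         check.names = FALSE)
m <- as.matrix(sig[, -1]); rownames(m) <- sig$gene_id
sets_tab <- utils::read.delim(file.path(sim, "gene_sets.tsv"))
sets <- split(sets_tab$gene_id, sets_tab$set_id)
cond <- stats::setNames(substr(colnames(m), 1, 1), colnames(m))
tb <- normalize_signals(expression_table(m, cond, sets))
cat(sprintf("normalized %d genes x %d samples (mean signal %.0f)\n",
            nrow(tb$signals), ncol(tb$signals), mean(colMeans(tb$signals))))

# in this scenario condition B carries the AbrB induction / CMP repression
dirs <- c(AbrB = "greater", CMP = "less", amino = "less",
          purine = "less", pyrimidine = "less")
set_rows <- do.call(rbind, lapply(names(dirs), function(s) {
  ss <- set_summary(tb, s, "A", "B", direction = dirs[[s]])
  data.frame(set = s, n = ss$n, excluded = ss$n_excluded,
             direction = dirs[[s]], p_value = ss$p_value,
             median_log2_shift = ss$median_diff,
             frac_up = ss$frac_up, frac_down = ss$frac_down)
}))
print(set_rows, digits = 3)
utils::write.table(format(set_rows, digits = 4),
                   file.path("results", "set_summaries.tsv"),
                   sep = "\t", row.names = FALSE, quote = FALSE)

de <- de_table(tb, "A", "B")
de$fold_class <- classify_fold_cutoff(2^de$log2fc)
cat(sprintf("\nvolcano: %d up, %d down of %d genes (%s)\n",
            sum(de$class == "up"), sum(de$class == "down"), nrow(de),
            attr(de, "method")))
cat(sprintf("1.5-fold cutoff: %d up, %d down\n",
            sum(de$fold_class == "up"), sum(de$fold_class == "down")))
utils::write.table(format(de, digits = 4),
                   file.path("results", "de_genes.tsv"),
                   sep = "\t", row.names = FALSE, quote = FALSE)
cat("wrote results/set_summaries.tsv, results/de_genes.tsv\n")
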