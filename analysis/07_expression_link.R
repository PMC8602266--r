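#!/usr/bin/env Rscript
# Stage 7: clone size and gene expression.
#
# Cells are matched to clonotypes by barcode; expression is
# log-normalized to counts-per-10k. Outputs: Spearman correlation of
# every gene with clone size (all cells and per condition), rank-sum
# differential expression between conditions (Bonferroni; display
# filter adjusted p < 0.01 and |log2FC| > 0.2), per-clonotype average
# raw counts, and a module score over the planted condition-shifted
# genes (binned-control construction). The planted size-correlated
# genes top the correlation ranking with the planted signs.

library(pairtcr)

cmap <- synth_condition_map(synth_config(seed = 1L))
cs <- read_clonotypes_tsv("results/clonotypes.tsv", cmap)
cs$cells <- read.delim("results/paired_cells.tsv", stringsAsFactors = FALSE)
ex <- read_expression_mtx("results/inputs/expression")
truth <- jsonlite::read_json("results/inputs/ground_truth.json",
                             simplifyVector = TRUE)

expr <- normalize_log1p_cp10k(ex$counts)
cells <- attach_clonotypes(ex$meta, cs)
cat(sprintf("cells matched to clonotypes: %.1f%%\n",
            100 * mean(attr(cells, "matched_fraction"))))

corr <- clone_size_correlation(expr, cells)
corr_cond <- clone_size_correlation(expr, cells, stratify_by = "condition")
write.table(rbind(corr, corr_cond), "results/clone_size_correlation.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
gt <- truth$gene_truth
top <- merge(corr, gt, by = "gene")
planted <- top[top$sign != 0, ]
cat("planted size-correlated genes with correct rho sign:",
    sum(sign(planted$rho) == planted$sign), "of", nrow(planted), "\n")
cat("strongest correlations:",
    paste(head(corr$gene, 3), collapse = ", "), "(positive);",
    paste(tail(corr$gene, 3), collapse = ", "), "(negative)\n")

conds <- sort(unique(cells$condition))
de <- differential_expression(expr,
                              cells$barcode[cells$condition == conds[1]],
                              cells$barcode[cells$condition == conds[2]])
de$display_hit <- de$p_adjusted < 0.01 & abs(de$log2fc) > 0.2
write.table(de, "results/differential_expression.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("DE display hits (", conds[2], " over ", conds[1], "): ",
    sum(de$display_hit), " genes; planted condition-shifted among them: ",
    sum(de$gene[de$display_hit] %in% gt$gene[gt$condition_shifted]),
    " of ", sum(gt$condition_shifted), "\n", sep = "")

avg <- average_expression_by(ex$counts, cells, "clonotype_id")
write.table(data.frame(clonotype_id = rownames(avg$mean_counts),
                       size = avg$entity_size, avg$mean_counts,
                       check.names = FALSE),
            "results/avg_expression_by_clonotype.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

shifted <- gt$gene[gt$condition_shifted]
ms <- module_score(expr, shifted, seed = 1)
score_by_cond <- tapply(ms[cells$barcode], cells$condition, mean)
write.table(data.frame(barcode = names(ms), score = as.numeric(ms)),
            "results/condition_module_scores.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("condition-shifted module score: AU =",
    round(score_by_cond["AU"], 3), ", WT =",
    round(score_by_cond["WT"], 3), "\n")
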