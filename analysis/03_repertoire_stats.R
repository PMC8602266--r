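#!/usr/bin/env Rscript
# Stage 3: repertoire statistics.
#
# Per-sample Shannon diversity and rarefaction, public clonotypes and
# their condition sharing, Bray-Curtis + NMDS ordination of samples
# over public-clonotype counts, the sample-clonotype network of
# expanded clones (> 10 cells), and clonotype expansion labels between
# conditions (|log2FC| > 3, clone size > 10, pseudocount 1).

library(pairtcr)

cmap <- synth_condition_map(synth_config(seed = 1L))
cs <- read_clonotypes_tsv("results/clonotypes.tsv", cmap)

per_sample <- data.frame(
  sample_id = colnames(cs$counts),
  condition = unname(cmap[colnames(cs$counts)]),
  n_cells = colSums(cs$counts),
  n_clonotypes = colSums(cs$counts > 0),
  shannon = apply(cs$counts, 2, function(x) shannon_diversity(x[x > 0])),
  geometric_mean_size = apply(cs$counts, 2, function(x)
    geometric_mean_clone_size(x[x > 0])))
write.table(per_sample, "results/per_sample_stats.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

rar <- do.call(rbind, lapply(colnames(cs$counts), function(s) {
  x <- cs$counts[, s]
  cbind(sample_id = s, rarefaction_curve(x[x > 0], step = 20))
}))
write.table(rar, "results/rarefaction.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

pub <- public_clonotypes(cs$counts, cmap)
write.table(pub, "results/public_clonotypes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

pubm <- t(cs$counts[pub$clonotype_id, , drop = FALSE])
ord <- nmds(bray_curtis(pubm), k = 2, seed = 1, n_restarts = 50)
write.table(data.frame(sample_id = rownames(ord$coordinates),
                       ord$coordinates, stress = ord$stress),
            "results/nmds_public.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

net <- sample_clonotype_network(cs, min_size = 10)
write.table(net$edges, "results/network_edges.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cond <- repertoire_matrix(cs, "condition")
lab <- expansion_labels(cond[, "AU"], cond[, "WT"],
                        entity_id = rownames(cond),
                        log2fc_threshold = 3, size_floor = 10,
                        labels = c("AU", "WT"))
write.table(lab, "results/clonotype_expansion.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("mean Shannon diversity:", round(mean(per_sample$shannon), 3), "\n")
cat("public clonotypes:", nrow(pub),
    "| shared between conditions:", sum(pub$condition_shared), "\n")
cat("NMDS stress:", round(ord$stress, 4),
    if (ord$converged_flag) "(< 0.1)" else "(>= 0.1: interpret with care)", "\n")
cat("network: ", nrow(net$edges), "edges over",
    length(unique(net$edges$clonotype_id)), "expanded clonotypes\n")
cat("condition-enriched clonotypes:", sum(lab$label != "shared"), "\n")
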