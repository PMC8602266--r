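#!/usr/bin/env Rscript
# Stage 2: contig QC and clonotype calling.
#
# Reads the per-sample 10x-dialect contig tables, keeps full-length
# productive chains, keeps cells with one TRA and one TRB (highest-UMI
# contig per chain), and calls clonotypes as identity classes of the
# paired CDR3 alpha/beta amino-acid sequences. Typical output here:
# ~95% of cells survive pairing (the 5% decoys are discarded), ~3,000
# clonotypes, heavy-tailed clone sizes.

library(pairtcr)

inputs <- "results/inputs"
paths <- list.files(file.path(inputs, "contigs"), full.names = TRUE)
names(paths) <- sub("_contigs$", "", tools::file_path_sans_ext(basename(paths)))
cmap <- synth_condition_map(synth_config(seed = 1L))

contigs <- read_contig_set(paths, "tenx_csv")
cells <- filter_productive_paired(contigs)
cs <- call_clonotypes(cells, cmap)

write_clonotypes_tsv(cs, "results/clonotypes.tsv")
write.table(cs$cells, "results/paired_cells.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

n_barcodes <- length(unique(paste(contigs$sample_id, contigs$barcode)))
cat("contig rows:", nrow(contigs), "\n")
cat("cells with paired productive chains:", nrow(cells), "of", n_barcodes,
    sprintf("(%.1f%%)\n", 100 * nrow(cells) / n_barcodes))
cat("clonotypes:", nrow(cs$clonotypes), "\n")
cat("largest clone:", max(cs$clonotypes$size), "cells;",
    "singletons:", sum(cs$clonotypes$size == 1), "\n")
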