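#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Emulated design: 5 wild-type (WT) and 5 autoimmune (AU) chimeras, 300
# clonotypes per sample with Zipf clone sizes, 8 public clonotypes
# emitted in both conditions, 5 planted CDR3beta motifs (carrier
# fraction 0.05, V-gene bias 0.8), an expression panel with
# size-correlated and condition-shifted genes, a CDR3beta-antigen
# reference database carrying the planted motifs, and a toy proteome
# with planted 9-mer target peptides. Everything is written as
# plain-text files under results/inputs so later stages exercise the
# package's readers.

library(pairtcr)

seed <- 1L
out <- "results/inputs"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- synth_config(seed = seed)
rep_data <- generate_repertoire(cfg)
paths <- write_contigs_csv(rep_data$contigs, file.path(out, "contigs"))

ex <- generate_expression(rep_data$cells, cfg)
write_expression_mtx(ex$counts, ex$meta, file.path(out, "expression"))

bg <- synth_background_repertoire(5000, cfg)
write.table(bg, file.path(out, "reference_repertoire.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_reference_tsv(generate_reference_db(cfg, repertoire = rep_data),
                    file.path(out, "reference_db.tsv"))
pr <- generate_proteome(cfg)
write_proteome_fasta(pr$proteome, file.path(out, "proteome.fasta"))
jsonlite::write_json(list(motifs = rep_data$truth$motifs,
                          public_keys = rep_data$truth$public_keys,
                          placements = pr$placements,
                          gene_truth = ex$gene_truth),
                     file.path(out, "ground_truth.json"),
                     auto_unbox = TRUE, pretty = TRUE)

cat("samples:", length(paths), "\n")
cat("paired cells:", nrow(rep_data$cells), "\n")
cat("planted motifs:", paste(names(rep_data$truth$motifs), collapse = ", "), "\n")
cat("public clonotypes:", length(rep_data$truth$public_keys), "\n")
cat("expression:", nrow(ex$counts), "genes x", ncol(ex$counts), "cells\n")
cat("proteome:", length(pr$proteome), "proteins,",
    nrow(pr$placements), "planted peptide placements\n")
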