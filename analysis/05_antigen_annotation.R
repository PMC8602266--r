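#!/usr/bin/env Rscript
# Stage 5: antigen annotation from the CDR3beta reference database.
#
# The raw database (with deliberate duplicate and non-amino-acid noise
# rows) is compiled to the unified schema, clonotypes are annotated by
# exact CDR3beta match (a few percent of unique CDR3betas, as with real
# databases), and specificity groups inherit peptide/antigen/disease
# annotations from database groups sharing the same seed motif.

library(pairtcr)

cmap <- synth_condition_map(synth_config(seed = 1L))
cs <- read_clonotypes_tsv("results/clonotypes.tsv", cmap)
cs$cells <- read.delim("results/paired_cells.tsv", stringsAsFactors = FALSE)

db_raw <- read_reference_tsv("results/inputs/reference_db.tsv")
db <- compile_reference(db_raw)
cat("database rows:", nrow(db_raw), "raw ->", nrow(db), "clean\n")

em <- exact_match(cs, db)
write.table(em$annotations, "results/exact_match_annotations.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("exact CDR3beta match: %.2f%% of unique CDR3betas (%d annotations)\n",
            100 * em$matched_fraction, nrow(em$annotations)))

bg <- read.delim("results/inputs/reference_repertoire.tsv",
                 stringsAsFactors = FALSE)
ref <- reference_repertoire(bg$cdr3b, bg$v_gene)
groups <- read.delim("results/specificity_groups.tsv",
                     stringsAsFactors = FALSE)
dbg <- db_specificity_groups(db, ref)
tr <- motif_transfer(groups, dbg)
write.table(tr, "results/annotated_groups.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

ann <- tr[tr$annotated & tr$passes_filter, ]
cat(sprintf("annotated specificity groups: %d of %d passing (%.0f%% of all)\n",
            nrow(ann), sum(tr$passes_filter),
            100 * attr(tr, "annotated_fraction")))
cat("predicted disease classes:",
    paste(unique(unlist(strsplit(ann$pred_disease_class, ";"))),
          collapse = ", "), "\n")
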