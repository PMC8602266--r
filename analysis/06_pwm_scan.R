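#!/usr/bin/env Rscript
# Stage 6: profile-based antigen search.
#
# For each condition, 9-mer peptides annotated to expanded clonotypes
# (clone size > 3, log2FC sign toward the condition) are weighted by
# clone size x linear fold enrichment and pooled into a position-weight
# matrix of amino-acid enrichment ratios; the PWM scores every
# 9-residue window of the proteome. Empirical p = share of windows
# scoring at least as high; Bonferroni over all windows. The planted
# target peptides surface as the top-scoring windows.

library(pairtcr)

cmap <- synth_condition_map(synth_config(seed = 1L))
cs <- read_clonotypes_tsv("results/clonotypes.tsv", cmap)
ann <- read.delim("results/exact_match_annotations.tsv",
                  stringsAsFactors = FALSE)
lab <- read.delim("results/clonotype_expansion.tsv", stringsAsFactors = FALSE)
proteome <- read_proteome_fasta("results/inputs/proteome.fasta")
bgfreq <- proteome_background(proteome)

for (side in c("A", "B")) {
  cond_name <- if (side == "A") "AU" else "WT"  # labels used in stage 3
  wp <- select_weighted_peptides(ann, lab, condition = side,
                                 min_clone_size = 3)
  if (nrow(wp) == 0) { cat(cond_name, ": no training peptides\n"); next }
  pwm <- build_pwm(wp$peptide, wp$weight, background = bgfreq)
  sc <- scan_proteome(pwm, proteome)
  out <- paste0("results/pwm_hits_", cond_name, ".tsv")
  write.table(sc$hits, out, sep = "\t", quote = FALSE, row.names = FALSE)
  sig <- sc$hits[sc$hits$p < 0.001, ]
  cat(cond_name, ": ", nrow(wp), " training peptides, ",
      sc$n_windows, " windows scanned, ",
      nrow(sig), " hits at empirical p < 0.001 (",
      length(unique(sig$peptide)), " unique peptides, ",
      length(unique(sig$protein_id)), " proteins)\n", sep = "")
  cat("  top hit: ", sc$hits$peptide[1], " in ", sc$hits$protein_id[1],
      " at p = ", signif(sc$hits$p[1], 3), "\n", sep = "")
  # Composition null (random 9-mers from background frequencies) allows
  # a meaningful Bonferroni count.
  scc <- scan_proteome(pwm, proteome, p_mode = "composition_null",
                       null_seed = 1)
  cat("  composition null: ", sum(scc$hits$p_bonferroni < 0.05),
      " Bonferroni-significant hits\n", sep = "")
}
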