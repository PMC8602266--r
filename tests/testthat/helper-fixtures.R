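# Shared fixture builders and independent oracles.

# One contig row in the reader schema.
contig_row <- function(sample_id = "S1", barcode, chain, cdr3, v = "TRBV1",
                       j = "TRBJ1-1", full_length = TRUE, productive = TRUE,
                       umis = 1L) {
  data.frame(sample_id = sample_id, barcode = barcode, chain = chain,
             cdr3_aa = cdr3, cdr3_nt = "", v_gene = v, j_gene = j,
             full_length = full_length, productive = productive,
             umis = as.integer(umis), stringsAsFactors = FALSE)
}

# Paired-cell rows ready for call_clonotypes().
cell_row <- function(sample_id, barcode, cdr3a, cdr3b, trbv = "TRBV1",
                     trav = "TRAV1", traj = "TRAJ1", trbj = "TRBJ1-1") {
  data.frame(sample_id = sample_id, barcode = barcode,
             cdr3a_aa = cdr3a, trav = trav, traj = traj,
             cdr3b_aa = cdr3b, trbv = trbv, trbj = trbj,
             stringsAsFactors = FALSE)
}

# A clonotype_set with given (sample, cdr3a, cdr3b[, trbv]) cell rows.
make_cs <- function(cells, condition_map = NULL) {
  if (is.null(condition_map)) {
    s <- unique(cells$sample_id)
    condition_map <- stats::setNames(rep(c("A", "B"), length.out = length(s)), s)
  }
  call_clonotypes(cells, condition_map)
}

# Independent oracle: one-sided hypergeometric tail P(X >= a) for the
# 2x2 table [a, b; c, d], by direct choose() enumeration.
hyper_tail_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(k, m)
  pmf <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
  sum(pmf[xs >= a])
}

# Independent oracle: Monte-Carlo expected richness of an m-cell
# subsample of a count vector; returns mean and standard error.
mc_rarefaction_oracle <- function(counts, m, reps = 1e5) {
  clone_of <- rep.int(seq_along(counts), counts)
  N <- sum(counts)
  obs <- vapply(seq_len(reps), function(i)
    length(unique(clone_of[sample.int(N, m)])), numeric(1))
  list(mean = mean(obs), se = stats::sd(obs) / sqrt(reps))
}

# Tiny synthetic config for fast end-to-end runs; overrides win.
small_synth_config <- function(seed = 1, ...) {
  defaults <- list(clones_per_sample = 80, n_genes = 60,
                   n_size_correlated_genes = 8, n_condition_genes = 4,
                   db_background_entries = 60, db_entries_per_motif = 15,
                   proteome_n_proteins = 20, protein_length = 120,
                   seed = seed)
  do.call(synth_config, utils::modifyList(defaults, list(...)))
}
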