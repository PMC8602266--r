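# GLIPH-style specificity grouping: clonotypes are clustered into
# predicted antigen-specificity groups by shared local CDR3beta motifs
# (k-mers of the trimmed interior, Fisher-enriched against a reference
# repertoire) and by global similarity (single conservative substitution
# among equal-length CDR3betas). Groups are then tested for V-gene bias
# and CDR3-length concentration and filtered on a composite final score.

.pkg_env <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.pkg_env$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_env$BLOSUM62 <- e$BLOSUM62
  }
  .pkg_env$BLOSUM62
}

cdr3_interior <- function(cdr3, trim = c(3, 2)) {
  L <- nchar(cdr3)
  out <- substr(cdr3, trim[1] + 1L, L - trim[2])
  out[L - trim[1] - trim[2] < 1] <- ""
  out
}

#' Extract local CDR3beta motifs (interior k-mers)
#'
#' Enumerates k-mers of the CDR3beta interior after trimming the first 3
#' and last 2 residues (the conserved ends contribute no specificity
#' signal). Raw counts accumulate over input occurrences; unique counts
#' are over distinct CDR3beta strings.
#'
#' @param cdr3b Character vector of CDR3beta sequences (one per
#'   clonotype; duplicates allowed and counted in `count`).
#' @param sample_id Optional sample ids parallel to `cdr3b`, for
#'   per-motif sample presence.
#' @param k Integer k-mer sizes (default 2, 3, 4).
#' @param trim Length-2 integer: residues dropped from the N and C
#'   terminus before k-mer extraction.
#' @return Data frame `motif`, `k`, `count` (raw occurrences),
#'   `n_cdr3` (distinct CDR3betas containing the motif), `n_samples`.
#' @export
extract_motifs <- function(cdr3b, sample_id = NULL, k = c(2, 3, 4),
                           trim = c(3, 2)) {
  if (any(trim < 0) || sum(trim) < 0) stop("trim must be non-negative")
  interior <- cdr3_interior(cdr3b, trim)
  if (is.null(sample_id)) sample_id <- rep("all", length(cdr3b))
  per_seq <- list()
  for (kk in k) {
    L <- nchar(interior)
    max_start <- L - kk + 1L
    idx <- which(max_start >= 1L)
    if (length(idx) == 0) next
    starts <- sequence(max_start[idx])
    seq_i <- rep(idx, max_start[idx])
    per_seq[[as.character(kk)]] <- data.frame(
      seq_i = seq_i, k = kk,
      motif = substr(interior[seq_i], starts, starts + kk - 1L),
      stringsAsFactors = FALSE)
  }
  if (length(per_seq) == 0)
    return(data.frame(motif = character(0), k = integer(0), count = integer(0),
                      n_cdr3 = integer(0), n_samples = integer(0)))
  all_km <- do.call(rbind, per_seq)
  # Raw occurrence count (one per sequence occurrence, positions collapsed
  # within a sequence count once each position).
  count <- table(all_km$motif)
  # Unique-CDR3 and sample presence: collapse to (motif, cdr3) / (motif, sample).
  seq_motif <- unique(data.frame(motif = all_km$motif,
                                 cdr3 = cdr3b[all_km$seq_i],
                                 stringsAsFactors = FALSE))
  n_cdr3 <- table(seq_motif$motif)
  samp_motif <- unique(data.frame(motif = all_km$motif,
                                  s = sample_id[all_km$seq_i],
                                  stringsAsFactors = FALSE))
  n_samp <- table(samp_motif$motif)
  motifs <- sort(unique(all_km$motif))
  out <- data.frame(motif = motifs,
                    k = nchar(motifs),
                    count = as.integer(count[motifs]),
                    n_cdr3 = as.integer(n_cdr3[motifs]),
                    n_samples = as.integer(n_samp[motifs]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Build a reference repertoire for motif enrichment
#'
#' Precomputes per-motif unique-CDR3 background counts from a reference
#' set of CDR3beta sequences (e.g. a naive CD4 repertoire, or the
#' synthetic generator's motif-free background).
#'
#' @param cdr3b Reference CDR3beta sequences.
#' @param v_gene Optional parallel V genes.
#' @param k,trim As in [extract_motifs()].
#' @return Object of class `reference_repertoire`.
#' @export
reference_repertoire <- function(cdr3b, v_gene = NULL, k = c(2, 3, 4),
                                 trim = c(3, 2)) {
  if (length(cdr3b) == 0) stop("reference repertoire must be nonempty")
  uniq <- unique(cdr3b)
  motifs <- extract_motifs(uniq, k = k, trim = trim)
  bg <- setNames(motifs$n_cdr3, motifs$motif)
  structure(list(n_unique = length(uniq), motif_n_cdr3 = bg,
                 cdr3b = uniq, v_gene = v_gene, k = k, trim = trim),
            class = "reference_repertoire")
}

#' Fisher-exact motif enrichment against a reference repertoire
#'
#' One-sided (greater) Fisher exact p for each query motif from the 2x2
#' table of unique-CDR3 presence/absence in query vs reference. An
#' optional non-templated-encoding bonus doubles a motif's enrichment
#' weight (flagged, not altering p); it requires nucleotide-level
#' germline annotation and is off by default.
#'
#' @param query_motifs Motif table from [extract_motifs()] on the query.
#' @param n_query_unique Number of distinct query CDR3betas.
#' @param reference A [reference_repertoire()].
#' @param k_test k-mer sizes to test (default 3 and 4; 2-mers are too
#'   degenerate to be informative).
#' @param nt_bonus Optional character vector of motifs receiving the
#'   non-templated bonus.
#' @return Data frame of motif hits: `motif`, `k`, `n_cdr3_query`,
#'   `n_samples`, `n_cdr3_ref`, `fisher_p` (raw one-sided p),
#'   `p_adjusted` (Bonferroni over all tested motifs; the motif component
#'   of the group final score), `weight`, `weight_flag`.
#' @export
motif_enrichment <- function(query_motifs, n_query_unique, reference,
                             k_test = c(3, 4), nt_bonus = NULL) {
  hits <- query_motifs[query_motifs$k %in% k_test, , drop = FALSE]
  if (nrow(hits) == 0)
    return(data.frame(motif = character(0), k = integer(0),
                      n_cdr3_query = integer(0), n_samples = integer(0),
                      n_cdr3_ref = integer(0), fisher_p = numeric(0),
                      weight = numeric(0), weight_flag = logical(0)))
  ref_n <- reference$motif_n_cdr3[hits$motif]
  ref_n[is.na(ref_n)] <- 0L
  a <- hits$n_cdr3
  c_ <- as.integer(ref_n)
  p <- fisher_p_greater(a, n_query_unique - a, c_, reference$n_unique - c_)
  flag <- hits$motif %in% nt_bonus
  out <- data.frame(motif = hits$motif, k = hits$k,
                    n_cdr3_query = a, n_samples = hits$n_samples,
                    n_cdr3_ref = c_, fisher_p = p,
                    # Bonferroni over the motifs tested: the motif component
                    # entering the final score must be calibrated against the
                    # tens of thousands of k-mers scanned per repertoire.
                    p_adjusted = pmin(1, p * nrow(hits)),
                    weight = ifelse(flag, 2, 1) * a,
                    weight_flag = flag, stringsAsFactors = FALSE)
  out[order(out$fisher_p, out$motif), ]
}

#' Global similarity clusters of CDR3beta sequences
#'
#' Graph on CDR3beta strings of equal length with an edge when the
#' Hamming distance is at most 1 and the single substituted position, if
#' any, scores non-negatively under BLOSUM62. Clusters are connected
#' components representing at least two input sequences (a CDR3beta
#' shared verbatim by two clonotypes qualifies on its own).
#'
#' @param cdr3b Character vector, one entry per clonotype.
#' @return List of character vectors, each the distinct CDR3betas of a
#'   cluster, named by their lexicographically smallest member.
#' @export
global_clusters <- function(cdr3b) {
  if (length(cdr3b) == 0) return(list())
  mult <- table(cdr3b)
  uniq <- names(mult)
  B <- blosum62()
  edges_from <- character(0)
  edges_to <- character(0)
  for (sub_seqs in split(uniq, nchar(uniq))) {
    n <- length(sub_seqs)
    if (n < 2) next
    L <- nchar(sub_seqs[1])
    chars <- do.call(rbind, strsplit(sub_seqs, ""))
    for (p in seq_len(L)) {
      masked <- paste0(substr(sub_seqs, 1, p - 1L), "\r",
                       substr(sub_seqs, p + 1L, L))
      for (grp in split(seq_len(n), masked)) {
        if (length(grp) < 2) next
        prs <- utils::combn(grp, 2)
        for (j in seq_len(ncol(prs))) {
          a <- chars[prs[1, j], p]; b <- chars[prs[2, j], p]
          if (a %in% rownames(B) && b %in% colnames(B) && B[a, b] >= 0) {
            edges_from <- c(edges_from, sub_seqs[prs[1, j]])
            edges_to <- c(edges_to, sub_seqs[prs[2, j]])
          }
        }
      }
    }
  }
  comps <- list()
  if (length(edges_from) > 0) {
    g <- igraph::graph_from_data_frame(
      unique(data.frame(from = edges_from, to = edges_to,
                        stringsAsFactors = FALSE)), directed = FALSE)
    mem <- igraph::components(g)$membership
    comps <- split(names(mem), mem)
  }
  # Singleton components from verbatim-duplicated CDR3betas.
  in_comp <- unlist(comps, use.names = FALSE)
  dups <- setdiff(uniq[mult >= 2], in_comp)
  comps <- c(comps, as.list(dups))
  # Keep clusters representing >= 2 input sequences.
  keep <- vapply(comps, function(s) sum(mult[s]) >= 2, logical(1))
  comps <- lapply(comps[keep], function(s) sort(unname(s)))
  names(comps) <- vapply(comps, `[`, character(1), 1)
  comps[order(names(comps))]
}

#' V-gene bias of a specificity group
#'
#' One-sided Fisher exact p for over-representation of the group's modal
#' TRBV gene among its member clonotypes relative to the full repertoire
#' (members included).
#'
#' @param member_v TRBV genes of member clonotypes.
#' @param repertoire_v TRBV genes of all repertoire clonotypes.
#' @return List `p`, `modal_v`.
#' @export
vgene_bias <- function(member_v, repertoire_v) {
  g <- modal_value(member_v)
  a <- sum(member_v == g)
  n_mem <- length(member_v)
  K <- sum(repertoire_v == g)
  N <- length(repertoire_v)
  list(p = fisher_p_greater(a, n_mem - a, K - a, (N - K) - (n_mem - a)),
       modal_v = g)
}

# CDR3beta-length concentration of a group vs the repertoire, same
# construction as the V-gene bias test on the modal member length.
length_concentration <- function(member_len, repertoire_len) {
  g <- modal_value(member_len)
  a <- sum(member_len == g)
  n_mem <- length(member_len)
  K <- sum(repertoire_len == g)
  N <- length(repertoire_len)
  list(p = fisher_p_greater(a, n_mem - a, K - a, (N - K) - (n_mem - a)),
       modal_len = as.integer(g))
}

#' Composite final score of a specificity group
#'
#' Product of the motif, V-gene bias and length-concentration
#' probabilities; smaller is more significant, filtered at 1e-5.
#' @param motif_p,vgene_p,length_p Component probabilities.
#' @return Final score.
#' @export
final_score <- function(motif_p, vgene_p, length_p) {
  motif_p * vgene_p * length_p
}

#' Assemble specificity groups from motif hits and global clusters
#'
#' One group per motif hit with raw `fisher_p < p_motif` (members:
#' clonotypes whose trimmed CDR3beta interior contains the motif) and one
#' per global cluster (motif component set to 1). The final score uses
#' the Bonferroni-adjusted motif component, so candidate groups are
#' listed permissively while the pass filter stays calibrated against
#' the number of motifs scanned. Clonotypes may belong to multiple
#' groups. Per-group statistics: unique clonotypes, samples with member
#' cells, per-condition cell counts, V-gene bias p, length p, final
#' score, and an expansion label on the per-condition cell counts.
#'
#' @param hits Motif hits from [motif_enrichment()].
#' @param clusters Global clusters from [global_clusters()].
#' @param cs A `clonotype_set`.
#' @param p_motif Motif significance threshold for seeding a group.
#' @param trim Trimming convention used for containment (must match
#'   extraction).
#' @param enrich_log2fc,enrich_floor,enrich_pseudocount Expansion-label
#'   parameters applied to per-condition cell counts (defaults 2.5, 10,
#'   1: the specificity-group expansion display convention).
#' @return List with `groups` (one row per group) and `members`
#'   (`group_id`, `clonotype_id`).
#' @export
assemble_groups <- function(hits, clusters, cs, p_motif = 1e-3,
                            trim = c(3, 2), enrich_log2fc = 2.5,
                            enrich_floor = 10, enrich_pseudocount = 1) {
  clo <- cs$clonotypes
  interior <- cdr3_interior(clo$cdr3b_aa, trim)
  rep_v <- clo$trbv
  rep_len <- nchar(clo$cdr3b_aa)
  cond_mat <- repertoire_matrix(cs, "condition")
  conds <- colnames(cond_mat)
  sig <- hits[hits$fisher_p < p_motif, , drop = FALSE]

  seed_list <- c(
    lapply(seq_len(nrow(sig)), function(i) {
      list(type = "motif", seed = sig$motif[i], motif_p = sig$fisher_p[i],
           motif_p_adj = sig$p_adjusted[i],
           members = which(grepl(sig$motif[i], interior, fixed = TRUE)))
    }),
    lapply(clusters, function(seqs) {
      list(type = "global", seed = seqs[1], motif_p = 1, motif_p_adj = 1,
           members = which(clo$cdr3b_aa %in% seqs))
    }))
  seed_list <- Filter(function(s) length(s$members) > 0, seed_list)
  if (length(seed_list) == 0)
    return(list(groups = data.frame(), members = data.frame()))

  rows <- vector("list", length(seed_list))
  members <- vector("list", length(seed_list))
  for (i in seq_along(seed_list)) {
    s <- seed_list[[i]]
    m <- s$members
    gid <- sprintf("SG%05d_%s", i, s$seed)
    vb <- vgene_bias(rep_v[m], rep_v)
    lc <- length_concentration(rep_len[m], rep_len)
    fs <- final_score(s$motif_p_adj, vb$p, lc$p)
    samp_counts <- colSums(cs$counts[m, , drop = FALSE] > 0)
    cond_cells <- colSums(cond_mat[m, , drop = FALSE])
    row <- data.frame(group_id = gid, seed = s$seed, seed_type = s$type,
                      n_unique_clonotypes = length(m),
                      n_samples = as.integer(sum(samp_counts > 0)),
                      n_cells = as.integer(sum(cond_cells)),
                      motif_p = s$motif_p, motif_p_adj = s$motif_p_adj,
                      vgene_bias_p = vb$p,
                      modal_v = vb$modal_v, length_p = lc$p,
                      final_score = fs, stringsAsFactors = FALSE)
    for (cn in conds) row[[paste0("cells_", cn)]] <- as.integer(cond_cells[cn])
    rows[[i]] <- row
    members[[i]] <- data.frame(group_id = gid,
                               clonotype_id = clo$clonotype_id[m],
                               stringsAsFactors = FALSE)
  }
  groups <- do.call(rbind, rows)
  if (length(conds) == 2) {
    el <- expansion_labels(groups[[paste0("cells_", conds[1])]],
                           groups[[paste0("cells_", conds[2])]],
                           entity_id = groups$group_id,
                           log2fc_threshold = enrich_log2fc,
                           size_floor = enrich_floor,
                           pseudocount = enrich_pseudocount,
                           labels = conds)
    groups$log2fc <- el$log2fc
    groups$enrichment <- el$label
  }
  rownames(groups) <- NULL
  list(groups = groups, members = do.call(rbind, members))
}

#' Filter specificity groups on the high-fidelity criteria
#'
#' A group passes when it has at least `min_clonotypes` unique clonotypes
#' from at least `min_samples` samples, significant V-gene bias
#' (`vgene_bias_p < max_vgene_p`) and a significant final score
#' (`final_score < max_final`). Defaults are the published criteria
#' (4 clonotypes, 3 samples, 0.05, 1e-5); a stricter 4-sample variant is
#' reachable via `min_samples`.
#'
#' @param groups Group table from [assemble_groups()].
#' @param min_clonotypes,min_samples,max_vgene_p,max_final Thresholds.
#' @return `groups` with a `passes_filter` column.
#' @export
filter_groups <- function(groups, min_clonotypes = 4, min_samples = 3,
                          max_vgene_p = 0.05, max_final = 1e-5) {
  if (nrow(groups) == 0) {
    groups$passes_filter <- logical(0)
    return(groups)
  }
  groups$passes_filter <- groups$n_unique_clonotypes >= min_clonotypes &
    groups$n_samples >= min_samples &
    groups$vgene_bias_p < max_vgene_p &
    groups$final_score < max_final
  groups
}

#' Full specificity-grouping pipeline for a clonotype set
#'
#' Extracts motifs, tests enrichment against the reference, builds global
#' clusters, assembles and filters groups.
#'
#' @param cs A `clonotype_set`.
#' @param reference A [reference_repertoire()].
#' @param k_extract,k_test,trim Motif extraction/testing parameters.
#' @param p_motif Motif seeding threshold.
#' @param min_clonotypes,min_samples,max_vgene_p,max_final Filter
#'   thresholds.
#' @param enrich_log2fc,enrich_floor Expansion-label parameters.
#' @return List `groups`, `members`, `hits` (all tested motifs).
#' @export
specificity_groups <- function(cs, reference, k_extract = c(2, 3, 4),
                               k_test = c(3, 4), trim = c(3, 2),
                               p_motif = 1e-3, min_clonotypes = 4,
                               min_samples = 3, max_vgene_p = 0.05,
                               max_final = 1e-5, enrich_log2fc = 2.5,
                               enrich_floor = 10) {
  clo <- cs$clonotypes
  # Representative sample per clonotype: motif-level n_samples is a coarse
  # summary; the filter uses the exact group-level count recomputed in
  # assemble_groups() from the clonotype x sample matrix.
  rep_sample <- apply(cs$counts > 0, 1, function(p) colnames(cs$counts)[p][1])
  motifs <- extract_motifs(clo$cdr3b_aa, sample_id = rep_sample,
                           k = k_extract, trim = trim)
  hits <- motif_enrichment(motifs, n_query_unique = length(unique(clo$cdr3b_aa)),
                           reference = reference, k_test = k_test)
  clusters <- global_clusters(clo$cdr3b_aa)
  asm <- assemble_groups(hits, clusters, cs, p_motif = p_motif, trim = trim,
                         enrich_log2fc = enrich_log2fc,
                         enrich_floor = enrich_floor)
  if (nrow(asm$groups) > 0)
    asm$groups <- filter_groups(asm$groups, min_clonotypes, min_samples,
                                max_vgene_p, max_final)
  list(groups = asm$groups, members = asm$members, hits = hits)
}
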