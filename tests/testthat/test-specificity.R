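# Motif extraction, Fisher enrichment, global clustering, group
# assembly, V-gene bias, final score, filtering.

test_that("interior k-mer extraction respects the trimming convention", {
  m <- extract_motifs("CASSQETQYF", k = 3)
  expect_setequal(m$motif, c("SQE", "QET", "ETQ"))
  # Length-6 CDR3 leaves a 1-residue interior: no k >= 2 motifs.
  short <- extract_motifs("CASSYF", k = c(2, 3, 4))
  expect_equal(nrow(short), 0)
  # Duplicates double the raw count but not the unique-CDR3 count.
  dup <- extract_motifs(c("CASSQETQYF", "CASSQETQYF"), k = 3)
  expect_equal(dup$count[dup$motif == "QET"], 2L)
  expect_equal(dup$n_cdr3[dup$motif == "QET"], 1L)
})

test_that("Fisher motif p equals brute-force hypergeometric enumeration", {
  # Query: 3 of 4 CDR3s carry the motif; reference: 2 of 6.
  expect_equal(fisher_p_greater(3, 1, 2, 4), hyper_tail_oracle(3, 1, 2, 4),
               tolerance = 1e-12)
  # Cross-check against fisher.test's one-sided p as well.
  ft <- stats::fisher.test(matrix(c(3, 1, 2, 4), 2, byrow = TRUE),
                           alternative = "greater")$p.value
  expect_equal(fisher_p_greater(3, 1, 2, 4), ft, tolerance = 1e-12)
  # A motif absent from the query has p = 1.
  expect_equal(fisher_p_greater(0, 10, 3, 7), 1)
})

test_that("motif enrichment tables are built on unique-CDR3 counts", {
  ref <- reference_repertoire(c("CASSAQETQAAF", "CASSGGGGGGGF",
                                "CASSHHHHHHHF", "CASSKKKKKKKF"))
  q <- c("CASSWQETQWWF", "CASSYQETQYYF", "CASSPQETQPPF")
  motifs <- extract_motifs(q, k = c(3, 4))
  hits <- motif_enrichment(motifs, n_query_unique = length(unique(q)),
                           reference = ref, k_test = c(3, 4))
  h <- hits[hits$motif == "QETQ", ]
  expect_equal(h$n_cdr3_query, 3L)
  expect_equal(h$n_cdr3_ref, 1L)
  expect_equal(h$fisher_p, hyper_tail_oracle(3, 0, 1, 3), tolerance = 1e-12)
  expect_equal(h$p_adjusted, min(1, h$fisher_p * nrow(hits)))
})

test_that("null Fisher motif p-values are conservative (super-uniform)", {
  cfg <- synth_config(seed = 21, planted_motifs = default_planted_motifs()[0, ],
                      clones_per_sample = 150)
  rep <- generate_repertoire(cfg)
  bg <- synth_background_repertoire(3000, cfg)
  ref <- reference_repertoire(bg$cdr3b)
  q <- unique(rep$clonotypes$cdr3b)
  hits <- motif_enrichment(extract_motifs(q, k = 3), length(q), ref,
                           k_test = 3)
  for (alpha in c(0.001, 0.01, 0.05, 0.25)) {
    frac <- mean(hits$fisher_p <= alpha)
    expect_lte(frac, 1.5 * alpha + 3 * sqrt(alpha / nrow(hits)))
  }
})

test_that("global clusters require one conservative substitution at equal length", {
  cl <- global_clusters(c("CASSLG", "CASSIG"))   # L<->I: BLOSUM62 +2
  expect_length(cl, 1)
  expect_setequal(cl[[1]], c("CASSIG", "CASSLG"))
  expect_length(global_clusters(c("CASSLG", "CASSPG")), 0)  # L<->P: -3
  dup <- global_clusters(c("CASSLG", "CASSLG"))  # verbatim duplicates
  expect_length(dup, 1)
  expect_equal(dup[[1]], "CASSLG")
  # Different lengths never cluster.
  expect_length(global_clusters(c("CASSLG", "CASSLLG")), 0)
})

test_that("V-gene bias p matches the hypergeometric oracle at boundaries", {
  member_v <- rep("TRBV5", 6)
  repertoire_v <- c(rep("TRBV5", 60), rep("TRBVx", 540))
  vb <- vgene_bias(member_v, repertoire_v)
  expect_equal(vb$p, hyper_tail_oracle(6, 0, 54, 540), tolerance = 1e-12)
  expect_equal(vb$modal_v, "TRBV5")
  # Group usage at repertoire proportions: no evidence of bias.
  rep_v <- rep(c("TRBV1", "TRBV2"), c(50, 50))
  expect_gte(vgene_bias(c("TRBV1", "TRBV2"), rep_v)$p, 0.5)
  # Single-member group: p is the modal-gene marginal frequency.
  expect_equal(vgene_bias("TRBV1", rep_v)$p, 0.5, tolerance = 1e-12)
})

test_that("final score multiplies components commutatively", {
  expect_equal(final_score(1, 1, 1), 1)
  expect_equal(final_score(1e-4, 0.03, 0.5), 1.5e-6)
  expect_equal(final_score(0.5, 1e-4, 0.03), final_score(1e-4, 0.03, 0.5))
})

test_that("groups are assembled per significant motif with multi-membership", {
  # 5 carrier clonotypes over 4 samples; one clonotype carries two motifs.
  cells <- rbind(
    cell_row("S1", "b1", "CAAAAF", "CASSWQETQWWF", trbv = "TRBV5"),
    cell_row("S2", "b2", "CAAACF", "CASSYQETQYYF", trbv = "TRBV5"),
    cell_row("S3", "b3", "CAAADF", "CASSPQETQPPF", trbv = "TRBV5"),
    cell_row("S4", "b4", "CAAAEF", "CASSGTNWQETQWF", trbv = "TRBV5"),
    cell_row("S1", "b5", "CAAAGF", "CASSHQETQHHF", trbv = "TRBV5"),
    cell_row("S2", "b6", "CAAAHF", "CASSKKKKKKKF", trbv = "TRBV9"))
  cs <- make_cs(cells, c(S1 = "A", S2 = "A", S3 = "B", S4 = "B"))
  ref <- reference_repertoire(
    paste0("CASS", c("AAAAAAA", "GGGGGGG", "HHHHHHH", "LLLLLLL", "MMMMMMM",
                     "NNNNNNN", "PPPPPPP", "RRRRRRR"), "F"))
  sg <- specificity_groups(cs, ref, p_motif = 1)
  g <- sg$groups[sg$groups$seed == "QETQ", ]
  expect_equal(g$n_unique_clonotypes, 5L)
  expect_equal(g$n_samples, 4L)
  # The clonotype carrying QETQ and GTN appears in both motif groups.
  both <- sg$members$clonotype_id[sg$members$group_id %in%
    sg$groups$group_id[sg$groups$seed %in% c("QETQ", "GTN")]]
  ct <- cs$cells$clonotype_id[cs$cells$barcode == "b4"]
  expect_gte(sum(both == ct), 2)
})

test_that("no significant motifs and no clusters yield an empty group list", {
  asm <- assemble_groups(
    hits = data.frame(motif = character(0), k = integer(0),
                      n_cdr3_query = integer(0), n_samples = integer(0),
                      n_cdr3_ref = integer(0), fisher_p = numeric(0),
                      p_adjusted = numeric(0), weight = numeric(0),
                      weight_flag = logical(0)),
    clusters = list(),
    cs = make_cs(cell_row("S1", "b1", "CAAAAF", "CSSSSF"), c(S1 = "A")))
  expect_equal(nrow(asm$groups), 0)
})

test_that("the group filter enforces clonotype, sample and score criteria", {
  g <- data.frame(group_id = c("g1", "g2", "g3"),
                  n_unique_clonotypes = c(3L, 5L, 5L),
                  n_samples = c(5L, 2L, 4L),
                  vgene_bias_p = c(1e-6, 1e-6, 1e-3),
                  final_score = c(1e-9, 1e-9, 1e-7))
  out <- filter_groups(g)
  expect_equal(out$passes_filter, c(FALSE, FALSE, TRUE))  # g1: too few clonotypes; g2: too few samples
  vac <- filter_groups(g, min_clonotypes = 1, min_samples = 1,
                       max_vgene_p = 1, max_final = 1)
  expect_true(all(vac$passes_filter))
  # Methods-style stricter sample floor.
  expect_false(filter_groups(g, min_samples = 5)$passes_filter[3])
})

test_that("adding an unrelated clonotype preserves existing groups and members", {
  base_cells <- rbind(
    cell_row("S1", "b1", "CAAAAF", "CASSWQETQWWF", trbv = "TRBV5"),
    cell_row("S2", "b2", "CAAACF", "CASSYQETQYYF", trbv = "TRBV5"),
    cell_row("S3", "b3", "CAAADF", "CASSPQETQPPF", trbv = "TRBV5"),
    cell_row("S4", "b4", "CAAAEF", "CASSRQETQMMF", trbv = "TRBV5"))
  extra <- cell_row("S1", "b9", "CZZZZF", "CASSDDDDDDDF", trbv = "TRBV9")
  ref <- reference_repertoire(
    paste0("CASS", c("AAAAAAA", "GGGGGGG", "HHHHHHH", "LLLLLLL"), "F"))
  cmap <- c(S1 = "A", S2 = "A", S3 = "B", S4 = "B")
  sg1 <- specificity_groups(make_cs(base_cells, cmap), ref, p_motif = 0.05)
  sg2 <- specificity_groups(make_cs(rbind(base_cells, extra), cmap), ref,
                            p_motif = 0.05)
  seeds1 <- sg1$groups$seed[sg1$groups$seed_type == "motif"]
  seeds2 <- sg2$groups$seed[sg2$groups$seed_type == "motif"]
  expect_true(all(seeds1 %in% seeds2))
  for (s in seeds1) {
    m1 <- sort(sg1$members$clonotype_id[sg1$members$group_id ==
      sg1$groups$group_id[sg1$groups$seed == s]])
    g2 <- sg2$groups$group_id[sg2$groups$seed == s]
    m2 <- sg2$members$clonotype_id[sg2$members$group_id == g2]
    # Compare by receptor, ids can shift with ordering.
    cs1 <- make_cs(base_cells, cmap); cs2 <- make_cs(rbind(base_cells, extra), cmap)
    r1 <- cs1$clonotypes$cdr3b_aa[match(m1, cs1$clonotypes$clonotype_id)]
    r2 <- cs2$clonotypes$cdr3b_aa[match(m2, cs2$clonotypes$clonotype_id)]
    expect_true(all(r1 %in% r2))
  }
})
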