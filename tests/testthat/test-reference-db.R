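# Reference database compilation, exact-match annotation, motif
# annotation transfer.

test_that("compilation drops invalid and duplicate rows, keeping source-distinct entries", {
  set.seed(10)
  clean <- data.frame(
    cdr3b = paste0("CASS", vapply(1:100, function(i)
      paste(sample(c("A", "G", "Q", "E", "T", "Y"), 6, replace = TRUE),
            collapse = ""), character(1)), "F"),
    peptide = "PEPTIDEAA", antigen = "AG1", disease = "flu",
    species = "human", v_gene = "TRBV1", j_gene = "TRBJ1",
    source = "src1", stringsAsFactors = FALSE)
  clean <- clean[!duplicated(clean$cdr3b), ]
  n_clean <- nrow(clean)
  dups <- clean[sample.int(n_clean, 10), ]
  bad <- clean[1:5, ]
  bad$cdr3b <- paste0("CAS", c("*", "_", "*", "_", "*"), "SF")
  db <- compile_reference(rbind(clean, dups, bad))
  expect_equal(nrow(db), n_clean)
  expect_true(all(grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", db$cdr3b)))
})

test_that("the same (cdr3b, peptide) from two sources is kept twice", {
  t1 <- data.frame(cdr3 = "CASSQETQYF", pep = "AAAAAAAAA", stringsAsFactors = FALSE)
  t2 <- data.frame(junction = "CASSQETQYF", epitope = "AAAAAAAAA",
                   stringsAsFactors = FALSE)
  db <- compile_reference(
    list(vdjdb = t1, mcpas = t2),
    mappings = list(vdjdb = c(cdr3b = "cdr3", peptide = "pep"),
                    mcpas = c(cdr3b = "junction", peptide = "epitope")))
  expect_equal(nrow(db), 2)
  expect_setequal(db$source, c("vdjdb", "mcpas"))
})

test_that("empty inputs give an empty database with the full schema", {
  db <- compile_reference(data.frame(cdr3b = character(0),
                                     peptide = character(0)))
  expect_equal(nrow(db), 0)
  expect_true(all(c("cdr3b", "peptide", "antigen", "disease_class",
                    "source") %in% names(db)))
})

test_that("compilation is idempotent and applies the disease-class lookup", {
  raw <- data.frame(cdr3b = c("CASSAF", "CASSGF", "CASSHF"),
                    peptide = "AAAAAAAAA",
                    disease = c("lupus", "influenza", "unknown-thing"),
                    stringsAsFactors = FALSE)
  db <- compile_reference(raw, disease_class_map = c(lupus = "autoimmune",
                                                     influenza = "virus"))
  expect_equal(db$disease_class, c("autoimmune", "virus", "other"))
  expect_equal(compile_reference(db), db)
})

test_that("unmapped mandatory columns fail naming source and column", {
  expect_error(compile_reference(list(bad = data.frame(x = 1)),
                                 mappings = list(bad = c(cdr3b = "x"))),
               "bad.*peptide")
})

test_that("exact matching annotates every database occurrence of a CDR3beta", {
  cells <- rbind(cell_row("S1", "b1", "CAAAAF", "CASSQETQYF"),
                 cell_row("S1", "b2", "CACCCF", "CASSMULTIF"),
                 cell_row("S1", "b3", "CADDDF", "CASSNOPEYF"))
  cs <- make_cs(cells, c(S1 = "A"))
  db <- data.frame(cdr3b = c("CASSQETQYF", rep("CASSMULTIF", 3)),
                   peptide = c("AAAAAAAAA", "BBBBBBBBB", "CCCCCCCCC", "DDDDDDDDD"),
                   antigen = "AG", disease_class = "virus", source = "s",
                   stringsAsFactors = FALSE)
  em <- exact_match(cs, db)
  expect_equal(sum(em$annotations$cdr3b == "CASSQETQYF"), 1)
  expect_equal(sum(em$annotations$cdr3b == "CASSMULTIF"), 3)
  expect_equal(em$matched_fraction, 2 / 3)
  # Annotation count identity vs a brute-force join.
  brute <- merge(cs$clonotypes, db, by.x = "cdr3b_aa", by.y = "cdr3b")
  expect_equal(nrow(em$annotations), nrow(brute))
  # No overlap at all.
  em0 <- exact_match(cs, db[0, ])
  expect_equal(em0$matched_fraction, 0)
  expect_equal(nrow(em0$annotations), 0)
})

# Shared fixture: query groups seeded by the planted motif inherit the
# planted peptide through database groups.
make_transfer_fixture <- function(majority = 30, minority = 10) {
  n <- majority + minority
  aa <- c("A", "G", "H", "L", "M")
  grid <- expand.grid(aa, aa, aa, stringsAsFactors = FALSE)
  prefix <- apply(grid[seq_len(n), ], 1, paste, collapse = "")
  db_cdr3 <- paste0("CASS", prefix, "QETQGF")
  db <- data.frame(cdr3b = db_cdr3,
                   peptide = rep(c("PPPPPPPP1", "QQQQQQQQ2"),
                                 c(majority, minority)),
                   antigen = rep(c("AG1", "AG2"), c(majority, minority)),
                   disease = "d", disease_class = "autoimmune",
                   species = "mouse", v_gene = "TRBV5", j_gene = "TRBJ1",
                   source = "synth", stringsAsFactors = FALSE)
  ref <- reference_repertoire(
    paste0("CASS", c("AAAAAAA", "GGGGGGG", "HHHHHHH", "LLLLLLL",
                     "MMMMMMM", "NNNNNNN", "PPPPPPP", "RRRRRRR",
                     "DDDDDDD", "EEEEEEE"), "F"))
  list(db = db, ref = ref)
}

test_that("motif transfer inherits the majority peptide unambiguously", {
  fx <- make_transfer_fixture(30, 10)
  dbg <- db_specificity_groups(fx$db, fx$ref, p_motif = 0.01)
  cells <- rbind(cell_row("S1", "b1", "CAAAAF", "CASSWQETQWWF"),
                 cell_row("S2", "b2", "CACCCF", "CASSYQETQYYF"),
                 cell_row("S3", "b3", "CADDDF", "CASSPQETQPPF"),
                 cell_row("S4", "b4", "CAEEEF", "CASSMQETQMMF"))
  cs <- make_cs(cells, c(S1 = "A", S2 = "A", S3 = "B", S4 = "B"))
  sg <- specificity_groups(cs, fx$ref, p_motif = 0.05)
  tr <- motif_transfer(sg$groups, dbg)
  g <- tr[tr$seed == "QETQ", ]
  expect_true(g$annotated)
  expect_equal(g$pred_peptide, "PPPPPPPP1")
  expect_false(g$annotation_ambiguous)
  expect_gt(attr(tr, "annotated_fraction"), 0)
})

test_that("tied database peptides attach both annotations with an ambiguity flag", {
  fx <- make_transfer_fixture(10, 10)
  dbg <- db_specificity_groups(fx$db, fx$ref, p_motif = 0.01)
  cells <- rbind(cell_row("S1", "b1", "CAAAAF", "CASSWQETQWWF"),
                 cell_row("S2", "b2", "CACCCF", "CASSYQETQYYF"))
  cs <- make_cs(cells, c(S1 = "A", S2 = "B"))
  sg <- specificity_groups(cs, fx$ref, p_motif = 0.05)
  tr <- motif_transfer(sg$groups, dbg)
  g <- tr[tr$seed == "QETQ", ]
  expect_true(g$annotation_ambiguous)
  expect_equal(g$pred_peptide, "PPPPPPPP1;QQQQQQQQ2")
})

test_that("disjoint seeds transfer nothing", {
  fx <- make_transfer_fixture(10, 2)
  dbg <- db_specificity_groups(fx$db, fx$ref, p_motif = 0.01)
  cells <- rbind(cell_row("S1", "b1", "CAAAAF", "CASSWRDWGWWF"),
                 cell_row("S2", "b2", "CACCCF", "CASSYRDWGYYF"))
  cs <- make_cs(cells, c(S1 = "A", S2 = "B"))
  sg <- specificity_groups(cs, fx$ref, p_motif = 0.05)
  tr <- motif_transfer(sg$groups, dbg)
  expect_false(any(tr$annotated[tr$seed_type == "motif" &
                                  !grepl("RDWG|RDW|DWG", tr$seed)]))
  expect_equal(unname(attr(tr, "annotated_fraction")), 0)
})
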