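# Contig reading, pairing filter, clonotype calling.

write_tenx_fixture <- function(path, rows) {
  header <- "barcode,is_cell,contig_id,chain,v_gene,d_gene,j_gene,c_gene,full_length,productive,cdr3,cdr3_nt,reads,umis"
  writeLines(c(header, rows), path)
}

test_that("an empty contig file with header yields an empty record set", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_tenx_fixture(f, character(0))
  rec <- read_contigs(f, "tenx_csv", sample_id = "S1")
  expect_equal(nrow(rec), 0)
})

test_that("10x rows parse with normalized chain enums and booleans", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_tenx_fixture(f, c(
    "BC1,True,c1,TRA,TRAV1,None,TRAJ1,TRAC,True,True,CAVRF,,100,5",
    "BC1,True,c2,TRB,TRBV1,None,TRBJ1-1,TRBC,True,True,CASSF,,80,4",
    "BC1,True,c3,Multi,TRBV2,None,TRBJ1-1,TRBC,False,False,CXXXF,,10,1",
    "BC2,True,c4,TRA,TRAV2,None,TRAJ2,TRAC,True,True,CAASF,,90,3",
    "BC2,True,c5,TRB,TRBV3,None,TRBJ2-1,TRBC,True,False,CASRF,,70,2",
    "BC2,True,c6,TRB,TRBV3,None,TRBJ2-1,TRBC,True,True,CASTF,,60,2"))
  rec <- read_contigs(f, "tenx_csv", sample_id = "S1")
  expect_equal(nrow(rec), 6)
  expect_equal(rec$chain, c("TRA", "TRB", "other", "TRA", "TRB", "TRB"))
  expect_type(rec$productive, "logical")
  expect_equal(sum(rec$productive), 4)
})

test_that("AIRR TSV reads to the same records as the equivalent 10x CSV", {
  f1 <- withr::local_tempfile(fileext = ".csv")
  write_tenx_fixture(f1, c(
    "BC1,True,c1,TRA,TRAV1,None,TRAJ1,TRAC,True,True,CAVRF,,100,5",
    "BC1,True,c2,TRB,TRBV1,None,TRBJ1-1,TRBC,True,True,CASSF,,80,4"))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste("cell_id", "locus", "v_call", "j_call", "junction_aa", "productive",
          "complete_vdj", "duplicate_count", sep = "\t"),
    paste("BC1", "TRA", "TRAV1", "TRAJ1", "CAVRF", "T", "T", "5", sep = "\t"),
    paste("BC1", "TRB", "TRBV1", "TRBJ1-1", "CASSF", "T", "T", "4", sep = "\t")),
    f2)
  a <- read_contigs(f1, "tenx_csv", sample_id = "S1")
  b <- read_contigs(f2, "airr_tsv", sample_id = "S1")
  cols <- c("sample_id", "barcode", "chain", "cdr3_aa", "v_gene", "j_gene",
            "full_length", "productive", "umis")
  expect_equal(a[, cols], b[, cols])
})

test_that("missing mandatory columns and bad booleans fail informatively", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("barcode,chain,v_gene,j_gene,cdr3,full_length",
               "BC1,TRA,TRAV1,TRAJ1,CAVRF,True"), f)
  expect_error(read_contigs(f, "tenx_csv"), "productive")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_tenx_fixture(f2, "BC1,True,c1,TRA,TRAV1,None,TRAJ1,TRAC,maybe,True,CAVRF,,100,5")
  expect_error(read_contigs(f2, "tenx_csv"), "row 1")
})

test_that("pairing filter drops unpaired and unproductive cells, keeps top-UMI chains", {
  rec <- rbind(
    contig_row(barcode = "P1", chain = "TRA", cdr3 = "CAVRF"),
    contig_row(barcode = "P1", chain = "TRB", cdr3 = "CASSF", umis = 3),
    contig_row(barcode = "P1", chain = "TRB", cdr3 = "CASTF", umis = 7),
    contig_row(barcode = "U1", chain = "TRA", cdr3 = "CAVSF"),       # TRA only
    contig_row(barcode = "U2", chain = "TRB", cdr3 = "CASWF",
               productive = FALSE))                                   # unproductive
  cells <- filter_productive_paired(rec)
  expect_equal(nrow(cells), 1)
  expect_equal(cells$cdr3b_aa, "CASTF")  # higher-UMI TRB wins
  # UMI tie broken by lexicographically smallest CDR3.
  rec2 <- rbind(contig_row(barcode = "T1", chain = "TRA", cdr3 = "CAVRF"),
                contig_row(barcode = "T1", chain = "TRB", cdr3 = "CASZF", umis = 5),
                contig_row(barcode = "T1", chain = "TRB", cdr3 = "CASAF", umis = 5))
  expect_equal(filter_productive_paired(rec2)$cdr3b_aa, "CASAF")
  # drop mode removes multichain cells entirely.
  expect_equal(nrow(filter_productive_paired(rec2, multichain = "drop")), 0)
})

test_that("a mixed 10-cell fixture retains exactly the fully paired cells", {
  rows <- list()
  for (i in 1:6) {
    rows[[length(rows) + 1]] <- contig_row(barcode = paste0("OK", i),
                                           chain = "TRA", cdr3 = "CAVRF")
    rows[[length(rows) + 1]] <- contig_row(barcode = paste0("OK", i),
                                           chain = "TRB", cdr3 = "CASSF")
  }
  for (i in 1:3)
    rows[[length(rows) + 1]] <- contig_row(barcode = paste0("UN", i),
                                           chain = "TRA", cdr3 = "CAVSF")
  rows[[length(rows) + 1]] <- contig_row(barcode = "BAD1", chain = "TRB",
                                         cdr3 = "CASWF", productive = FALSE)
  cells <- filter_productive_paired(do.call(rbind, rows))
  expect_equal(nrow(cells), 6)
})

test_that("clonotypes are identity classes of the CDR3 alpha/beta pair", {
  cells <- rbind(
    do.call(rbind, lapply(1:5, function(i)
      cell_row("S1", paste0("B", i), "CAVRNTGNYKYVF", "CASSQETQYF"))),
    cell_row("S1", "B6", "CAASDNYQLIW", "CASSQETQYF"))
  cs <- make_cs(cells, c(S1 = "A"))
  expect_equal(nrow(cs$clonotypes), 2)   # same beta, different alpha: distinct
  expect_equal(cs$clonotypes$size, c(5, 1))
})

test_that("an 8-cell 3-clonotype fixture gives sizes 4, 3, 1 and conserves cells", {
  cells <- rbind(
    do.call(rbind, lapply(1:4, function(i) cell_row("S1", paste0("a", i), "CAAAF", "CBBBF"))),
    do.call(rbind, lapply(1:3, function(i) cell_row("S2", paste0("b", i), "CCCCF", "CDDDF"))),
    cell_row("S1", "c1", "CEEEF", "CFFFF"))
  cs <- make_cs(cells, c(S1 = "A", S2 = "B"))
  expect_equal(cs$clonotypes$size, c(4, 3, 1))
  expect_equal(sum(cs$clonotypes$size), nrow(cells))
  expect_equal(unname(colSums(cs$counts)),
               as.vector(table(cells$sample_id)[colnames(cs$counts)]))
})

test_that("unmapped sample ids are rejected", {
  cells <- cell_row("S1", "b1", "CAAAF", "CBBBF")
  expect_error(call_clonotypes(cells, c(S2 = "A")), "S1")
})

test_that("clonotype calling is invariant to input row order", {
  set.seed(1)
  cells <- do.call(rbind, lapply(1:20, function(i)
    cell_row(sample(c("S1", "S2"), 1), paste0("b", i),
             sample(c("CAAAF", "CCCCF"), 1), sample(c("CBBBF", "CDDDF"), 1))))
  cs1 <- make_cs(cells, c(S1 = "A", S2 = "B"))
  cs2 <- make_cs(cells[sample(nrow(cells)), ], c(S1 = "A", S2 = "B"))
  expect_equal(cs1$clonotypes, cs2$clonotypes)
  expect_equal(cs1$counts, cs2$counts)
})

test_that("repertoire matrices respect sizes, public rows and condition collapse", {
  cells <- rbind(
    do.call(rbind, lapply(1:3, function(i) cell_row("S1", paste0("x", i), "CAAAF", "CBBBF"))),
    do.call(rbind, lapply(1:2, function(i) cell_row("A1", paste0("y", i), "CPPPF", "CQQQF"))),
    do.call(rbind, lapply(1:5, function(i) cell_row("B1", paste0("z", i), "CPPPF", "CQQQF"))))
  cs <- make_cs(cells, c(S1 = "WT", A1 = "WT", B1 = "AU"))
  m <- repertoire_matrix(cs, "sample")
  expect_equal(unname(rowSums(m)), cs$clonotypes$size)
  pub_row <- m[cs$clonotypes$clonotype_id[cs$clonotypes$cdr3b_aa == "CQQQF"], ]
  expect_equal(unname(pub_row[c("A1", "B1")]), c(2, 5))
  mc <- repertoire_matrix(cs, "condition")
  expect_equal(sum(mc), sum(m))
  expect_equal(sort(colnames(mc)), c("AU", "WT"))
})

test_that("clonotype tables round-trip through TSV", {
  cells <- rbind(cell_row("S1", "b1", "CAAAF", "CBBBF"),
                 cell_row("S2", "b2", "CAAAF", "CBBBF"),
                 cell_row("S2", "b3", "CCCCF", "CDDDF"))
  cs <- make_cs(cells, c(S1 = "A", S2 = "B"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_clonotypes_tsv(cs, f)
  back <- read_clonotypes_tsv(f, cs$condition_map)
  expect_equal(back$clonotypes, cs$clonotypes)
  expect_equal(back$counts, cs$counts)
})
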