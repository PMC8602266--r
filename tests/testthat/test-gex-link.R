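# Barcode joining, clone-size correlation, DE, entity averages, module
# scores.

make_linked_fixture <- function() {
  cells <- rbind(
    do.call(rbind, lapply(1:4, function(i)
      cell_row("S1", paste0("B", i), "CAAAAF", "CBBBBF"))),
    do.call(rbind, lapply(5:7, function(i)
      cell_row("S1", paste0("B", i), "CCCCCF", "CDDDDF"))))
  make_cs(cells, c(S1 = "WT"))
}

test_that("barcode matching reports per-sample matched fractions", {
  cs <- make_linked_fixture()
  meta <- data.frame(barcode = paste0("B", 1:10), sample_id = "S1",
                     condition = "WT", cluster = "c0", stringsAsFactors = FALSE)
  out <- attach_clonotypes(meta, cs)
  expect_equal(unname(attr(out, "matched_fraction")["S1"]), 0.7)
  expect_equal(sum(out$clone_size > 0) + sum(out$clone_size == 0), nrow(meta))
  # Disjoint barcodes: nothing matches.
  meta2 <- meta; meta2$barcode <- paste0("Z", 1:10)
  expect_equal(unname(attr(attach_clonotypes(meta2, cs),
                           "matched_fraction")["S1"]), 0)
  # 10x "-1" suffixes are normalized away.
  meta3 <- meta; meta3$barcode <- paste0(meta$barcode, "-1")
  expect_equal(unname(attr(attach_clonotypes(meta3, cs),
                           "matched_fraction")["S1"]), 0.7)
  # Duplicate barcodes within a sample are an error.
  meta4 <- rbind(meta, meta[1, ])
  expect_error(attach_clonotypes(meta4, cs), "duplicate barcode")
})

test_that("clone-size correlation handles exact monotone and degenerate genes", {
  cs <- make_linked_fixture()
  meta <- data.frame(barcode = paste0("B", 1:7), sample_id = "S1",
                     condition = "WT", cluster = "c0", stringsAsFactors = FALSE)
  cells <- attach_clonotypes(meta, cs)
  expr <- rbind(size_gene = cells$clone_size,        # identical to clone size
                flat_gene = rep(1, 7),               # constant
                anti_gene = -cells$clone_size)
  colnames(expr) <- cells$barcode
  res <- clone_size_correlation(expr, cells, min_cells = 5)
  expect_equal(res$rho[res$gene == "size_gene"], 1)
  expect_equal(res$rho[res$gene == "anti_gene"], -1)
  expect_equal(res$rho[res$gene == "flat_gene"], 0)
  expect_true(res$degenerate[res$gene == "flat_gene"])
  # Spearman is invariant under strictly monotone transforms.
  expr2 <- expr; expr2["size_gene", ] <- exp(expr["size_gene", ] / 2)
  res2 <- clone_size_correlation(expr2, cells, min_cells = 5)
  expect_equal(res2$rho[res2$gene == "size_gene"], 1)
  # Small strata are skipped with a message.
  expect_message(
    out <- clone_size_correlation(expr, cells, stratify_by = "cluster",
                                  min_cells = 100),
    "skipped")
  expect_null(out$gene)
})

test_that("planted size-correlated genes are recovered with the right sign", {
  cfg <- small_synth_config(seed = 14, n_genes = 60,
                            n_size_correlated_genes = 6, n_condition_genes = 0)
  set.seed(15)
  cells <- data.frame(barcode = sprintf("b%04d", 1:1500), sample_id = "S1",
                      condition = "WT",
                      clone_size = pairtcr:::rzipf(1500, 2.5, 150),
                      stringsAsFactors = FALSE)
  ex <- generate_expression(cells, cfg)
  expr <- normalize_log1p_cp10k(ex$counts)
  cells$clonotype_id <- "ct"
  res <- clone_size_correlation(expr, cells)
  truth <- ex$gene_truth
  m <- merge(res, truth, by = "gene")
  expect_true(all(sign(m$rho[m$sign != 0]) == m$sign[m$sign != 0]))
})

test_that("rank-sum DE is null on identical groups and detects planted shifts", {
  set.seed(16)
  n <- 120
  expr <- matrix(rpois(40 * 2 * n, 3), nrow = 40,
                 dimnames = list(sprintf("g%02d", 1:40),
                                 sprintf("c%03d", 1:(2 * n))))
  expr <- normalize_log1p_cp10k(expr)
  A <- colnames(expr)[1:n]; B <- colnames(expr)[(n + 1):(2 * n)]
  de0 <- differential_expression(expr, A, A)
  expect_true(all(de0$p_adjusted == 1))
  # Shift one gene 3x in group B.
  raw <- matrix(rpois(40 * 2 * n, 3), nrow = 40,
                dimnames = dimnames(expr))
  raw["g01", B] <- rpois(n, 9)
  de <- differential_expression(normalize_log1p_cp10k(raw), A, B)
  hit <- de[de$gene == "g01", ]
  expect_lt(hit$p_adjusted, 0.01)
  expect_gt(hit$log2fc, 0.2)
  expect_error(differential_expression(expr, A[1:2], B, min_cells = 3),
               "at least 3")
})

test_that("entity averages are arithmetic means of raw counts", {
  counts <- matrix(c(2, 4, 10, 1, 5, 3), nrow = 1,
                   dimnames = list("g1", paste0("c", 1:6)))
  cells <- data.frame(barcode = paste0("c", 1:6),
                      clonotype_id = c("ct1", "ct1", "ct2", NA, "ct3", "ct3"),
                      stringsAsFactors = FALSE)
  avg <- average_expression_by(counts, cells)
  expect_equal(avg$mean_counts["ct1", "g1"], 3)     # (2 + 4) / 2
  expect_equal(avg$mean_counts["ct2", "g1"], 10)    # single-cell entity
  expect_equal(nrow(avg$mean_counts), 3)            # NA cell contributes no entity
  expect_equal(unname(avg$entity_size["ct3"]), 2L)
})

test_that("module scores are seed-deterministic and self-controlled", {
  set.seed(17)
  expr <- matrix(rpois(200 * 150, 4), nrow = 200,
                 dimnames = list(sprintf("g%03d", 1:200),
                                 sprintf("c%03d", 1:150)))
  expr <- normalize_log1p_cp10k(expr)
  s1 <- module_score(expr, rownames(expr)[1:20], seed = 3)
  s2 <- module_score(expr, rownames(expr)[1:20], seed = 3)
  expect_identical(s1, s2)
  # Scoring every gene against its own controls stays near zero.
  s_all <- module_score(expr, rownames(expr), seed = 3)
  expect_lt(max(abs(s_all)), 0.05)
  expect_error(module_score(expr, c("nope1", "nope2")), "no overlap")
})

test_that("condition-shifted genes score higher in the shifted condition", {
  cfg <- small_synth_config(seed = 18, n_genes = 80,
                            n_size_correlated_genes = 0,
                            n_condition_genes = 8, condition_shift = 1.5)
  set.seed(19)
  cells <- data.frame(barcode = sprintf("b%04d", 1:600), sample_id = "S1",
                      condition = rep(c("WT", "AU"), 300),
                      clone_size = pmax(1, rpois(600, 2)),
                      stringsAsFactors = FALSE)
  ex <- generate_expression(cells, cfg)
  expr <- normalize_log1p_cp10k(ex$counts)
  shifted <- ex$gene_truth$gene[ex$gene_truth$condition_shifted]
  sc <- module_score(expr, shifted, seed = 4)
  expect_gt(mean(sc[cells$condition == "AU"]), mean(sc[cells$condition == "WT"]))
})

test_that("expression matrices round-trip through the MTX triplet writer", {
  cfg <- small_synth_config(seed = 20, clones_per_sample = 20, n_genes = 30)
  rep <- generate_repertoire(cfg)
  ex <- generate_expression(rep$cells, cfg)
  dir <- withr::local_tempdir()
  write_expression_mtx(ex$counts, ex$meta, dir)
  back <- read_expression_mtx(dir)
  expect_equal(as.matrix(back$counts), as.matrix(ex$counts))
  expect_equal(back$meta, ex$meta)
})
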