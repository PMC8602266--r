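# Joining clonotype identity to per-cell expression via barcodes, and
# the expression-side analyses: clone-size correlation, group
# differential expression, per-entity average expression, module scores.

#' Log-normalize a count matrix to counts-per-10k
#'
#' `ln(1 + 1e4 * count / column total)`, the log-normalized convention
#' the display expressions of this analysis imply. Raw counts are kept
#' separately for per-entity averaging.
#' @param counts Gene x cell count matrix (dense or sparse).
#' @return Matrix of the same shape.
#' @export
normalize_log1p_cp10k <- function(counts) {
  tot <- Matrix::colSums(counts)
  tot[tot == 0] <- 1
  if (inherits(counts, "sparseMatrix")) {
    out <- counts %*% Matrix::Diagonal(x = 1e4 / tot)
    out@x <- log1p(out@x)
    colnames(out) <- colnames(counts)
    out
  } else {
    log1p(sweep(counts, 2, tot / 1e4, "/"))
  }
}

#' Attach clonotype identity to cells via barcodes
#'
#' Matches expression-side cells to TCR-side clonotypes within samples
#' after an optional barcode suffix normalizer (strips a trailing
#' `-<digits>`); each cell matches at most one clonotype. Unmatched
#' cells keep `clone_size = 0`.
#'
#' @param meta Per-cell metadata (columns `barcode`, `sample_id`,
#'   optionally `condition`, `cluster`).
#' @param cs A `clonotype_set` whose `cells` carry barcodes.
#' @param strip_suffix Apply the `-<digits>` suffix normalizer to both
#'   sides before matching (default TRUE).
#' @return `meta` with `clonotype_id` (NA when unmatched) and
#'   `clone_size` columns; attribute `matched_fraction` (per-sample named
#'   vector) records the match rate.
#' @export
attach_clonotypes <- function(meta, cs, strip_suffix = TRUE) {
  if (is.null(cs$cells)) stop("clonotype_set carries no cell-level membership")
  norm <- function(x) if (strip_suffix) strip_barcode_suffix(x) else x
  key_meta <- paste(meta$sample_id, norm(meta$barcode), sep = "\r")
  if (anyDuplicated(key_meta))
    stop("duplicate barcode within a sample: ",
         meta$barcode[which(duplicated(key_meta))[1]])
  key_tcr <- paste(cs$cells$sample_id, norm(cs$cells$barcode), sep = "\r")
  idx <- match(key_meta, key_tcr)
  meta$clonotype_id <- cs$cells$clonotype_id[idx]
  sz <- cs$clonotypes$size[match(meta$clonotype_id, cs$clonotypes$clonotype_id)]
  meta$clone_size <- ifelse(is.na(sz), 0L, sz)
  mf <- tapply(!is.na(meta$clonotype_id), meta$sample_id, mean)
  attr(meta, "matched_fraction") <- mf
  meta
}

# Spearman rho and asymptotic p for every row of a matrix against y.
spearman_by_gene <- function(expr, y) {
  n <- length(y)
  ry <- rank(y)
  rx <- t(apply(as.matrix(expr), 1, rank))
  sdx <- apply(rx, 1, sd)
  degenerate <- sdx == 0 | sd(ry) == 0
  rho <- rep(0, nrow(rx))
  ok <- !degenerate
  if (any(ok))
    rho[ok] <- as.numeric(cor(t(rx[ok, , drop = FALSE]), ry))
  tstat <- rho * sqrt(pmax(n - 2, 1) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[degenerate] <- 1
  data.frame(rho = rho, p = p, degenerate = degenerate)
}

#' Spearman correlation of every gene with clone size
#'
#' Computed per stratum (all cells, or within condition/cluster strata)
#' over cells with a clonotype match; strata below `min_cells` matched
#' cells are skipped with a message. Genes with constant expression get
#' `rho = 0` and a degeneracy flag. Ties take average ranks.
#'
#' @param expr Gene x cell normalized expression matrix.
#' @param cells Cell table from [attach_clonotypes()] (needs
#'   `clone_size` > 0 rows for matched cells).
#' @param stratify_by Optional character vector of `cells` columns to
#'   stratify by (e.g. `"condition"`, `"cluster"`).
#' @param min_cells Minimum matched cells per stratum (default 10).
#' @return Data frame `gene`, `rho`, `p`, `n`, `stratum`, `degenerate`,
#'   ranked by `rho` (descending) within stratum.
#' @export
clone_size_correlation <- function(expr, cells, stratify_by = NULL,
                                   min_cells = 10) {
  matched <- cells$clone_size > 0
  strata <- if (is.null(stratify_by)) rep("all", nrow(cells)) else
    do.call(paste, c(cells[stratify_by], sep = "/"))
  out <- list()
  for (s in unique(strata[matched])) {
    idx <- which(matched & strata == s)
    if (length(idx) < min_cells) {
      message("stratum '", s, "' skipped: ", length(idx), " matched cells < ",
              min_cells)
      next
    }
    sub <- expr[, cells$barcode[idx], drop = FALSE]
    res <- spearman_by_gene(sub, cells$clone_size[idx])
    res <- data.frame(gene = rownames(expr), res, n = length(idx), stratum = s,
                      stringsAsFactors = FALSE)
    out[[s]] <- res[order(-res$rho, res$gene), ]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("gene", "rho", "p", "n", "stratum", "degenerate")]
}

#' Rank-sum differential expression between two cell groups
#'
#' Two-sided Wilcoxon rank-sum test per gene on normalized expression
#' with Bonferroni adjustment; the log2 fold change is computed from the
#' de-logged group means (`log2((mean(expm1 x_B) + 1) / (mean(expm1 x_A)
#' + 1))`). The conventional display filter is adjusted p < 0.01 and
#' log2FC > 0.2.
#'
#' @param expr Gene x cell normalized expression matrix.
#' @param barcodes_A,barcodes_B Cell barcodes of the two groups.
#' @param min_cells Minimum group size (default 3); smaller groups error.
#' @return Data frame `gene`, `log2fc` (B over A), `p`, `p_adjusted`,
#'   `pct_A`, `pct_B`, ordered by `p`.
#' @export
differential_expression <- function(expr, barcodes_A, barcodes_B,
                                    min_cells = 3) {
  if (length(barcodes_A) < min_cells || length(barcodes_B) < min_cells)
    stop("both groups need at least ", min_cells, " cells (got ",
         length(barcodes_A), " and ", length(barcodes_B), ")")
  A <- as.matrix(expr[, barcodes_A, drop = FALSE])
  B <- as.matrix(expr[, barcodes_B, drop = FALSE])
  p <- vapply(seq_len(nrow(A)), function(g) {
    if (sd(A[g, ]) == 0 && sd(B[g, ]) == 0 && A[g, 1] == B[g, 1]) return(1)
    suppressWarnings(wilcox.test(B[g, ], A[g, ], exact = FALSE)$p.value)
  }, numeric(1))
  p[is.na(p)] <- 1
  mA <- rowMeans(expm1(A))
  mB <- rowMeans(expm1(B))
  out <- data.frame(gene = rownames(expr),
                    log2fc = log2((mB + 1) / (mA + 1)),
                    p = p, p_adjusted = p.adjust(p, "bonferroni"),
                    pct_A = rowMeans(A > 0), pct_B = rowMeans(B > 0),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$gene), ]
  rownames(out) <- NULL
  out
}

#' Average raw counts per clonotype or specificity group
#'
#' Arithmetic mean of raw counts of each gene across all cells belonging
#' to each entity (the average-expression convention for entity-level
#' displays and module scores).
#'
#' @param counts Gene x cell raw count matrix.
#' @param cells Cell table with `barcode` and the entity column.
#' @param key Column of `cells` defining the entity (e.g.
#'   `"clonotype_id"`); rows with NA are dropped.
#' @return List `mean_counts` (entity x gene matrix) and `entity_size`.
#' @export
average_expression_by <- function(counts, cells, key = "clonotype_id") {
  keep <- !is.na(cells[[key]])
  ent <- as.character(cells[[key]][keep])
  bc <- cells$barcode[keep]
  sums <- rowsum(t(as.matrix(counts[, bc, drop = FALSE])), group = ent)
  sizes <- as.integer(table(ent)[rownames(sums)])
  list(mean_counts = sums / sizes,
       entity_size = setNames(sizes, rownames(sums)))
}

#' Module score with expression-matched control genes
#'
#' Mean normalized expression of the gene set minus the mean of control
#' genes drawn (seeded) from expression-matched bins: all genes are
#' binned by average expression into `n_bins` bins and `n_control`
#' controls are sampled per gene-set gene from its bin.
#'
#' @param expr Gene x cell normalized expression matrix.
#' @param gene_set Character vector of gene names.
#' @param n_bins Number of average-expression bins (default 24).
#' @param n_control Controls sampled per gene-set gene (default 100).
#' @param seed Integer seed for the control draw.
#' @return Named numeric vector of per-cell scores.
#' @export
module_score <- function(expr, gene_set, n_bins = 24, n_control = 100,
                         seed = 1) {
  gene_set <- intersect(gene_set, rownames(expr))
  if (length(gene_set) == 0)
    stop("gene_set has no overlap with measured genes")
  avg <- Matrix::rowMeans(expr)
  brk <- unique(quantile(avg, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(avg, breaks = brk, include.lowest = TRUE, labels = FALSE)
  names(bin) <- rownames(expr)
  set.seed(seed)
  ctrl <- unlist(lapply(gene_set, function(g) {
    pool <- names(bin)[bin == bin[g]]
    pool[sample.int(length(pool), min(n_control, length(pool)))]
  }))
  ctrl <- unique(ctrl)
  score <- Matrix::colMeans(expr[gene_set, , drop = FALSE]) -
    Matrix::colMeans(expr[ctrl, , drop = FALSE])
  setNames(as.numeric(score), colnames(expr))
}

#' Write / read an expression matrix as MTX triplet plus metadata
#'
#' Writes `matrix.mtx`, `barcodes.tsv`, `features.tsv` and
#' `metadata.csv` under `dir`.
#' @param counts Gene x cell sparse count matrix.
#' @param meta Per-cell metadata with a `barcode` column.
#' @param dir Output directory (created).
#' @return `dir` (write) or a list `counts`, `meta` (read).
#' @export
write_expression_mtx <- function(counts, meta, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(counts, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  writeLines(rownames(counts), file.path(dir, "features.tsv"))
  write.table(meta, file.path(dir, "metadata.csv"), sep = ",",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_expression_mtx
#' @export
read_expression_mtx <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  colnames(counts) <- readLines(file.path(dir, "barcodes.tsv"))
  rownames(counts) <- readLines(file.path(dir, "features.tsv"))
  meta <- read.csv(file.path(dir, "metadata.csv"), stringsAsFactors = FALSE)
  list(counts = counts, meta = meta)
}
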