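# Repertoire-level statistics: diversity, rarefaction, public clonotypes,
# ordination, networks, CDR3 spectra, expansion fold-change labels.

#' Shannon diversity of a clone-count vector
#'
#' `H = -sum(p_i * ln(p_i))` with natural log (the ecology convention of
#' vegan, which this delegates to).
#' @param counts Vector of positive integer clone counts.
#' @return Shannon index (nats).
#' @examples shannon_diversity(c(5, 5, 5, 5))  # ln 4
#' @export
shannon_diversity <- function(counts) {
  if (length(counts) == 0) stop("counts must be nonempty")
  if (any(counts <= 0)) stop("all counts must be positive")
  unname(vegan::diversity(counts, index = "shannon"))
}

#' Analytic rarefaction curve
#'
#' Expected clonotype richness in random subsamples of m cells,
#' `E[S(m)] = sum_i (1 - choose(N - n_i, m) / choose(N, m))`, evaluated
#' at `m = step, 2 step, ...` and always at `m = N`. Exact (hypergeometric)
#' expectation via [vegan::rarefy()], not repeated subsampling.
#'
#' @param counts Positive integer clone counts.
#' @param step Subsample-size step (default 20, the delegated package's
#'   convention in this analysis).
#' @return Data frame with columns `m` and `richness`.
#' @export
rarefaction_curve <- function(counts, step = 20) {
  if (step < 1) stop("step must be >= 1")
  if (any(counts <= 0)) stop("all counts must be positive")
  N <- sum(counts)
  m <- unique(c(seq(step, N, by = step), N))
  m <- m[m >= 1]
  # vegan warns when no clone is a singleton; that is legitimate for
  # clone-count vectors, so the advisory is muffled.
  rich <- withCallingHandlers(
    as.numeric(vegan::rarefy(counts, sample = m)),
    warning = function(w) {
      if (grepl("smallest count", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  data.frame(m = m, richness = rich)
}

#' Public clonotypes of a clonotype x sample count matrix
#'
#' A clonotype is public when present (count > 0) in at least two
#' samples. Each public clonotype is annotated with the conditions that
#' carry it; the condition-shared subset (present in more than one
#' condition) is flagged.
#'
#' @param counts Clonotype x sample count matrix.
#' @param condition_map Named vector mapping sample to condition.
#' @return Data frame `clonotype_id`, `n_samples`, `conditions`
#'   (comma-separated), `condition_shared` (logical).
#' @export
public_clonotypes <- function(counts, condition_map) {
  pres <- counts > 0
  pub <- rowSums(pres) >= 2
  out <- data.frame(clonotype_id = rownames(counts)[pub],
                    n_samples = as.integer(rowSums(pres)[pub]),
                    stringsAsFactors = FALSE)
  cond <- as.character(condition_map[colnames(counts)])
  conds <- apply(pres[pub, , drop = FALSE], 1, function(p)
    paste(sort(unique(cond[p])), collapse = ","))
  out$conditions <- as.character(conds)
  out$condition_shared <- vapply(strsplit(out$conditions, ","), length, integer(1)) >= 2
  rownames(out) <- NULL
  out
}

#' Bray-Curtis dissimilarity between rows of a count matrix
#'
#' `d_ij = sum|x_i - x_j| / sum(x_i + x_j)`, in `[0, 1]`, zero diagonal.
#' @param mat Entity x feature non-negative matrix.
#' @return Square symmetric dissimilarity matrix.
#' @export
bray_curtis <- function(mat) {
  as.matrix(vegan::vegdist(mat, method = "bray"))
}

#' Non-metric multidimensional scaling with random restarts
#'
#' Kruskal stress-1 NMDS (monotone regression, iterative majorization via
#' [vegan::monoMDS()]), best of `n_restarts` random initial
#' configurations; deterministic given `seed`. A warning is raised when
#' the best stress is >= 0.1 (the conventional adequacy bound this
#' analysis confirms via Shepard plots).
#'
#' @param dissimilarity Square symmetric hollow non-negative matrix (or
#'   `dist`).
#' @param k Embedding dimension (2 for condition comparisons).
#' @param seed Integer seed.
#' @param n_restarts Number of random initializations (default 50).
#' @return List of class `nmds_result`: `coordinates` (entity x k),
#'   `stress` in `[0, 1]`, `n_restarts`, `seed`, `converged_flag`
#'   (`stress < 0.1`).
#' @export
nmds <- function(dissimilarity, k = 2, seed = 1, n_restarts = 50) {
  if (inherits(dissimilarity, "dist")) dissimilarity <- as.matrix(dissimilarity)
  if (!isSymmetric(unname(dissimilarity), tol = 1e-8))
    stop("dissimilarity matrix must be symmetric")
  if (any(dissimilarity < 0)) stop("dissimilarity must be non-negative")
  d <- stats::as.dist(dissimilarity)
  n <- attr(d, "Size")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- matrix(rnorm(n * k), n, k)
    fit <- try(vegan::monoMDS(d, y = init, k = k, model = "global"),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  if (is.null(best)) stop("NMDS failed for every restart")
  coords <- best$points
  rownames(coords) <- rownames(dissimilarity)
  res <- list(coordinates = coords, stress = best$stress,
              n_restarts = n_restarts, seed = seed,
              converged_flag = best$stress < 0.1)
  if (!res$converged_flag)
    warning(sprintf("NMDS stress %.3f >= 0.1: embedding may be inadequate",
                    res$stress))
  class(res) <- "nmds_result"
  res
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("NMDS: %d points, k = %d, stress = %.4g (%s)\n",
              nrow(x$coordinates), ncol(x$coordinates), x$stress,
              if (x$converged_flag) "stress < 0.1" else "stress >= 0.1"))
  invisible(x)
}

#' Bipartite sample-clonotype network of expanded clonotypes
#'
#' Nodes are samples and clonotypes with size strictly greater than
#' `min_size` (default 10, the expansion cut of the network display);
#' one unweighted edge per (sample, clonotype) with count > 0.
#'
#' @param cs A `clonotype_set`.
#' @param min_size Clone-size floor (strict).
#' @return List with `edges` (data frame `sample_id`, `clonotype_id`,
#'   `size`) and `graph` (igraph bipartite graph).
#' @export
sample_clonotype_network <- function(cs, min_size = 10) {
  big <- cs$clonotypes$clonotype_id[cs$clonotypes$size > min_size]
  sub <- cs$counts[big, , drop = FALSE]
  idx <- which(sub > 0, arr.ind = TRUE)
  edges <- data.frame(
    sample_id = as.character(colnames(sub)[idx[, 2]]),
    clonotype_id = as.character(rownames(sub)[idx[, 1]]),
    stringsAsFactors = FALSE)
  edges$size <- cs$clonotypes$size[match(edges$clonotype_id,
                                         cs$clonotypes$clonotype_id)]
  edges <- edges[order(edges$sample_id, edges$clonotype_id), ]
  rownames(edges) <- NULL
  g <- igraph::make_empty_graph(directed = FALSE)
  if (nrow(edges) > 0) {
    g <- igraph::graph_from_data_frame(edges[, c("sample_id", "clonotype_id")],
                                       directed = FALSE)
    igraph::V(g)$type <- igraph::V(g)$name %in% edges$clonotype_id
  }
  list(edges = edges, graph = g)
}

#' Label entities by preferential expansion between two conditions
#'
#' `log2fc = log2((count_B + pseudocount) / (count_A + pseudocount))`;
#' an entity is labelled enriched in a condition when `|log2fc|` exceeds
#' the threshold and total count exceeds the size floor, otherwise
#' shared. The clonotype-level display uses threshold 3 and floor 10;
#' the specificity-group display uses threshold 2.5 and floor 10.
#'
#' @param count_A,count_B Non-negative counts per entity.
#' @param entity_id Optional ids.
#' @param log2fc_threshold Absolute log2 fold-change threshold (strict).
#' @param size_floor Total-count floor (strict).
#' @param pseudocount Added to both numerator and denominator.
#' @param labels Length-2 character: labels of condition A and B.
#' @return Data frame `entity_id`, `count_A`, `count_B`, `log2fc`,
#'   `label` (`A_enriched`-style labels or `shared`).
#' @export
expansion_labels <- function(count_A, count_B, entity_id = NULL,
                             log2fc_threshold = 3, size_floor = 10,
                             pseudocount = 1, labels = c("A", "B")) {
  if (any(count_A < 0) || any(count_B < 0)) stop("counts must be non-negative")
  if (is.null(entity_id)) entity_id <- seq_along(count_A)
  log2fc <- log2((count_B + pseudocount) / (count_A + pseudocount))
  total <- count_A + count_B
  lab <- rep("shared", length(count_A))
  hit <- abs(log2fc) > log2fc_threshold & total > size_floor
  lab[hit & log2fc > 0] <- paste0(labels[2], "_enriched")
  lab[hit & log2fc < 0] <- paste0(labels[1], "_enriched")
  data.frame(entity_id = entity_id, count_A = count_A, count_B = count_B,
             log2fc = log2fc, label = lab, stringsAsFactors = FALSE)
}

#' CDR3 length histogram and positional frequency spectrum
#'
#' @param cdr3 Character vector of CDR3 amino-acid sequences.
#' @param length_for_matrix CDR3 length at which to compute the
#'   position x amino-acid relative-frequency matrix; default the modal
#'   length.
#' @return List with `lengths` (table of lengths) and `freq` (L x 20
#'   matrix, rows sum to 1; `NULL` when no sequence has the chosen
#'   length).
#' @export
cdr3_spectrum <- function(cdr3, length_for_matrix = NULL) {
  len <- nchar(cdr3)
  hist <- table(len)
  if (is.null(length_for_matrix))
    length_for_matrix <- as.integer(names(hist)[which.max(hist)])
  sel <- cdr3[len == length_for_matrix]
  freq <- NULL
  if (length(sel) > 0) {
    chars <- do.call(rbind, strsplit(sel, ""))
    freq <- t(apply(chars, 2, function(col) {
      tabulate(factor(col, levels = AA20), nbins = 20) / length(col)
    }))
    colnames(freq) <- AA20
    rownames(freq) <- seq_len(length_for_matrix)
  }
  list(lengths = hist, freq = freq, length_for_matrix = length_for_matrix)
}

#' Geometric mean clone size
#'
#' `exp(mean(ln size_i))` over clonotypes, the summary used to compare
#' expansion between conditions.
#' @param sizes Positive clone sizes.
#' @return Geometric mean.
#' @export
geometric_mean_clone_size <- function(sizes) {
  if (any(sizes <= 0)) stop("sizes must be positive")
  exp(mean(log(sizes)))
}
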