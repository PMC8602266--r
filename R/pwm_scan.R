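# Profile-based antigen search: clone-weighted 9-mer peptides from
# database-annotated, condition-expanded clonotypes build a
# position-weight matrix of per-position amino-acid enrichment ratios;
# the PWM scores every 9-residue window of a proteome, with empirical
# p-values over the realized window-score distribution and Bonferroni
# correction.

#' Select clone-weighted training peptides for one condition's PWM
#'
#' Keeps 9-mer peptides annotated (by exact CDR3beta match) to clonotypes
#' with clone size strictly greater than `min_clone_size` and a log2
#' fold change whose sign matches the requested condition. The weight is
#' `clone_size * 2^|log2fc|` (fold enrichment on the linear scale).
#'
#' @param annotations Exact-match annotation table (columns
#'   `clonotype_id`, `peptide`, `clone_size`).
#' @param labels Expansion-label table from [expansion_labels()] on
#'   clonotype per-condition counts (columns `entity_id`, `log2fc`).
#' @param condition `"A"` or `"B"`: keep clonotypes enriched toward that
#'   side (negative or positive `log2fc` respectively).
#' @param min_clone_size Strict clone-size floor (default 3).
#' @return Data frame `peptide`, `weight` (summed over contributing
#'   clonotypes).
#' @export
select_weighted_peptides <- function(annotations, labels,
                                     condition = c("B", "A"),
                                     min_clone_size = 3) {
  condition <- match.arg(condition)
  ann <- merge(annotations, labels[, c("entity_id", "log2fc")],
               by.x = "clonotype_id", by.y = "entity_id")
  ann <- ann[nchar(ann$peptide) == 9 & ann$clone_size > min_clone_size, ]
  ann <- if (condition == "B") ann[ann$log2fc > 0, ] else ann[ann$log2fc < 0, ]
  if (nrow(ann) == 0)
    return(data.frame(peptide = character(0), weight = numeric(0)))
  ann$weight <- ann$clone_size * 2^abs(ann$log2fc)
  agg <- tapply(ann$weight, ann$peptide, sum)
  out <- data.frame(peptide = names(agg), weight = as.numeric(agg),
                    stringsAsFactors = FALSE)
  out[order(out$peptide), ]
}

#' Build a position-weight matrix from weighted 9-mer peptides
#'
#' Weights are first normalized to sum 1; per position j and amino acid
#' a, `f(j,a) = (sum of normalized weights of peptides with a at j +
#' pseudocount) / (1 + 20 * pseudocount)`, and the matrix entry is the
#' enrichment ratio `f(j,a) / background(a)`. Normalizing before the
#' pseudocount makes the PWM exactly invariant under global rescaling
#' of the weights.
#'
#' @param peptides Character vector of 9-mers.
#' @param weights Positive weights (default all 1).
#' @param background Named amino-acid frequency vector (default uniform
#'   1/20); typically the scanned proteome's composition.
#' @param pseudocount Per-cell pseudocount (default 0.01).
#' @return Object of class `pwm`: list with `matrix` (9 x 20 enrichment
#'   ratios), `background`, `pseudocount`, `n_training_peptides`.
#' @export
build_pwm <- function(peptides, weights = NULL, background = NULL,
                      pseudocount = 0.01) {
  if (length(peptides) == 0) stop("cannot build a PWM from zero peptides")
  if (any(nchar(peptides) != 9)) stop("all training peptides must be 9-mers")
  if (is.null(weights)) weights <- rep(1, length(peptides))
  if (any(weights <= 0)) stop("weights must be positive")
  if (is.null(background)) background <- setNames(rep(1 / 20, 20), AA20)
  background <- background[AA20]
  chars <- do.call(rbind, strsplit(peptides, ""))
  w <- weights / sum(weights)
  mat <- matrix(0, 9, 20, dimnames = list(1:9, AA20))
  for (j in 1:9) {
    wsum <- tapply(w, factor(chars[, j], levels = AA20), sum)
    wsum[is.na(wsum)] <- 0
    f <- (wsum + pseudocount) / (1 + 20 * pseudocount)
    mat[j, ] <- f / background
  }
  structure(list(matrix = mat, background = background,
                 pseudocount = pseudocount,
                 n_training_peptides = length(peptides)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM: 9 x 20 enrichment ratios from", x$n_training_peptides,
      "weighted peptides\n")
  invisible(x)
}

#' Score a 9-mer against a PWM
#'
#' Log-sum of positional enrichment ratios,
#' `sum_j ln(entry(j, peptide[j]))`; 0 for a uniform PWM.
#' @param pwm A [build_pwm()] object.
#' @param peptide One or more 9-mer strings.
#' @return Numeric score(s); `NA` for windows with non-standard letters.
#' @export
score_peptide <- function(pwm, peptide) {
  lw <- log(pwm$matrix)
  aa_idx <- setNames(seq_len(20), AA20)
  vapply(peptide, function(p) {
    idx <- aa_idx[strsplit(p, "")[[1]]]
    if (anyNA(idx) || length(idx) != 9) return(NA_real_)
    sum(lw[cbind(1:9, idx)])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Scan a proteome with a PWM using a 9-mer sliding window
#'
#' Scores every 9-residue window of every protein. Under the default
#' `p_mode = "empirical_all_windows"`, the p-value of a window is the
#' fraction of all scanned windows with score at least as high (ties
#' share the maximal rank): the probability of randomly selecting a
#' peptide with fitness at least as good from the realized window
#' population (note p >= 1/n_windows by construction, so the Bonferroni
#' column cannot fall below 1 in this mode). Under
#' `p_mode = "composition_null"`, the null is `n_null` random 9-mers
#' drawn (seeded) from the PWM's background composition, and
#' `p = (1 + #null >= score) / (n_null + 1)`. Bonferroni:
#' `min(1, p * n_windows)`. Windows containing letters outside the 20
#' standard amino acids are skipped and counted.
#'
#' @param pwm A [build_pwm()] object.
#' @param proteome Named character vector of protein sequences, or an
#'   `AAStringSet`, or a FASTA path.
#' @param top Return only the `top` best-scoring hits (default all).
#' @param score_threshold,p_threshold Optional reporting filters.
#' @param p_mode Null model for the p-value (see above).
#' @param n_null,null_seed Size and seed of the composition null draw.
#' @return List with `hits` (data frame `protein_id`, `start`, `peptide`,
#'   `score`, `p`, `p_bonferroni`, sorted by decreasing score),
#'   `n_windows`, `n_skipped`, and summary counts `n_unique_peptides`,
#'   `n_unique_antigens` over the reported hits.
#' @export
scan_proteome <- function(pwm, proteome, top = Inf,
                          score_threshold = -Inf, p_threshold = 1,
                          p_mode = c("empirical_all_windows",
                                     "composition_null"),
                          n_null = 1e5, null_seed = 1) {
  p_mode <- match.arg(p_mode)
  if (is.character(proteome) && length(proteome) == 1 && file.exists(proteome))
    proteome <- read_proteome_fasta(proteome)
  if (inherits(proteome, "AAStringSet"))
    proteome <- setNames(as.character(proteome), names(proteome))
  if (length(proteome) == 0) stop("proteome is empty")
  lens <- nchar(proteome)
  nwin <- pmax(lens - 8L, 0L)
  prot_id <- rep(names(proteome), nwin)
  start <- unlist(lapply(nwin, function(n) if (n > 0) seq_len(n) else integer(0)),
                  use.names = FALSE)
  if (length(start) == 0)
    return(list(hits = data.frame(protein_id = character(0), start = integer(0),
                                  peptide = character(0), score = numeric(0),
                                  p = numeric(0), p_bonferroni = numeric(0)),
                n_windows = 0L, n_skipped = 0L,
                n_unique_peptides = 0L, n_unique_antigens = 0L))
  pep <- substr(rep(proteome, nwin), start, start + 8L)
  score <- score_windows(pwm, pep)
  ok <- !is.na(score)
  n_skipped <- sum(!ok)
  prot_id <- prot_id[ok]; start <- start[ok]; pep <- pep[ok]; score <- score[ok]
  n <- length(score)
  if (p_mode == "empirical_all_windows") {
    # Fraction of windows scoring >= this window (maximal tie rank).
    ge <- n + 1L - rank(score, ties.method = "min")
    p <- ge / n
  } else {
    set.seed(null_seed)
    null_pep <- matrix(sample(AA20, 9 * n_null, replace = TRUE,
                              prob = pwm$background), ncol = 9)
    lw <- log(pwm$matrix)
    null_score <- numeric(n_null)
    for (j in 1:9)
      null_score <- null_score + lw[j, match(null_pep[, j], AA20)]
    null_sorted <- sort(null_score)
    ge_null <- n_null - findInterval(score, null_sorted,
                                     left.open = TRUE)
    p <- (1 + ge_null) / (n_null + 1)
  }
  hits <- data.frame(protein_id = prot_id, start = start, peptide = pep,
                     score = score, p = p,
                     p_bonferroni = pmin(1, p * n), stringsAsFactors = FALSE)
  hits <- hits[hits$score >= score_threshold & hits$p <= p_threshold, ]
  hits <- hits[order(-hits$score, hits$protein_id, hits$start), ]
  if (is.finite(top)) hits <- head(hits, top)
  rownames(hits) <- NULL
  list(hits = hits, n_windows = n, n_skipped = n_skipped,
       n_unique_peptides = length(unique(hits$peptide)),
       n_unique_antigens = length(unique(hits$protein_id)))
}

# Vectorized window scoring: positions of all 9 residues looked up at
# once; windows with non-standard letters get NA.
score_windows <- function(pwm, peptides) {
  lw <- log(pwm$matrix)
  n <- length(peptides)
  if (n == 0) return(numeric(0))
  score <- numeric(n)
  bad <- logical(n)
  for (j in 1:9) {
    ch <- substr(peptides, j, j)
    idx <- match(ch, AA20)
    bad <- bad | is.na(idx)
    idx[is.na(idx)] <- 1L
    score <- score + lw[j, idx]
  }
  score[bad] <- NA_real_
  score
}

#' Amino-acid composition of a proteome
#'
#' Background frequencies over the 20 standard letters (others ignored),
#' the default PWM background for scanning that proteome.
#' @param proteome Named character vector or `AAStringSet`.
#' @return Named frequency vector over [AA20].
#' @export
proteome_background <- function(proteome) {
  if (inherits(proteome, "AAStringSet"))
    proteome <- as.character(proteome)
  tab <- table(factor(strsplit(paste(proteome, collapse = ""), "")[[1]],
                      levels = AA20))
  freq <- as.numeric(tab) / sum(tab)
  setNames(freq, AA20)
}

#' Write / read a proteome FASTA
#' @param proteome Named character vector of protein sequences.
#' @param path FASTA path.
#' @return `path` (write) or a named character vector (read).
#' @export
write_proteome_fasta <- function(proteome, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(proteome), path)
  invisible(path)
}

#' @rdname write_proteome_fasta
#' @export
read_proteome_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), sub(" .*", "", names(x)))
}
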