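#' @keywords internal
"_PACKAGE"

#' @importFrom stats phyper rnorm rpois rnbinom runif cor pt p.adjust
#'   wilcox.test setNames quantile sd
#' @importFrom utils read.csv read.delim write.table head
NULL

# The 20 standard amino acids, alphabetical one-letter codes.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' One-sided ("greater") Fisher exact p-value for 2x2 tables
#'
#' Computes the upper hypergeometric tail P(X >= a) for the table
#' `[a, b; c, d]`, i.e. the one-sided Fisher exact test for
#' over-representation of the first row's feature in the first column's
#' class. Vectorized over table entries.
#'
#' @param a,b,c,d Non-negative integer vectors: `a` feature-positive in the
#'   query class, `b` feature-negative in the query class, `c`
#'   feature-positive in the reference class, `d` feature-negative in the
#'   reference class.
#' @return Numeric vector of p-values in (0, 1].
#' @examples
#' fisher_p_greater(3, 1, 2, 4)
#' @export
fisher_p_greater <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("table entries must be non-negative")
  # White balls = first row (a + b), draws = first column (a + c).
  p <- phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)
  pmin(pmax(p, .Machine$double.xmin), 1)
}

# Most frequent value; ties broken by sort order for determinism.
modal_value <- function(x) {
  tab <- sort(table(x), decreasing = TRUE)
  names(tab)[1]
}

# TRUE where the string uses only the 20 standard amino-acid letters.
is_standard_aa <- function(x) {
  !is.na(x) & nzchar(x) & !grepl(paste0("[^", paste(AA20, collapse = ""), "]"), x)
}

# Strip a trailing 10x-style "-<digits>" barcode suffix.
strip_barcode_suffix <- function(x) sub("-[0-9]+$", "", x)

random_aa <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(AA20, len[if (length(len) > 1L) i else 1L], replace = TRUE),
          collapse = "")
  }, character(1))
}
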