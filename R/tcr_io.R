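# Contig IO, productivity/pairing filter, clonotype calling.
#
# The unit of analysis is the paired clonotype: the set of cells sharing
# identical CDR3alpha and CDR3beta amino-acid sequences. Clone size is
# the number of unique cell barcodes in the clonotype.

TENX_REQUIRED <- c("barcode", "chain", "v_gene", "j_gene", "cdr3",
                   "full_length", "productive")
AIRR_REQUIRED <- c("cell_id", "locus", "v_call", "j_call", "junction_aa",
                   "productive", "complete_vdj")

parse_bool <- function(x, file = "<input>") {
  x <- as.character(x)
  out <- rep(NA, length(x))
  out[x %in% c("True", "true", "TRUE", "T")] <- TRUE
  out[x %in% c("False", "false", "FALSE", "F")] <- FALSE
  out[x %in% c("None", "", "NA")] <- FALSE
  if (anyNA(out))
    stop("unparseable boolean value '", x[which(is.na(out))[1]], "' at row ",
         which(is.na(out))[1], " of ", file)
  out
}

#' Read a per-sample contig annotation table
#'
#' Supports the 10x `filtered_contig_annotations.csv` dialect and the
#' AIRR Rearrangement TSV dialect, normalised to one common contig
#' schema.
#'
#' @param path File path.
#' @param dialect `"tenx_csv"` or `"airr_tsv"`.
#' @param sample_id Sample identifier attached to every record; defaults
#'   to the file name stripped of extension and a
#'   `_filtered_contig_annotations`/`_contigs`/`_airr` suffix.
#' @return Data frame of contig records with columns `sample_id`,
#'   `barcode`, `chain` (`TRA`/`TRB`/`other`), `cdr3_aa`, `cdr3_nt`,
#'   `v_gene`, `j_gene`, `full_length`, `productive` (logical), `umis`.
#' @export
read_contigs <- function(path, dialect = c("tenx_csv", "airr_tsv"),
                         sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("contig file not found: ", path)
  if (is.null(sample_id))
    sample_id <- sub("(_filtered_contig_annotations|_contigs|_airr)$", "",
                     tools::file_path_sans_ext(basename(path)))
  if (dialect == "tenx_csv") {
    raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
    missing <- setdiff(TENX_REQUIRED, names(raw))
    if (length(missing) > 0)
      stop("missing mandatory column(s) in ", path, ": ",
           paste(missing, collapse = ", "))
    out <- data.frame(
      sample_id = rep(sample_id, nrow(raw)),
      barcode = raw$barcode,
      chain = ifelse(raw$chain %in% c("TRA", "TRB"), raw$chain, "other"),
      cdr3_aa = raw$cdr3,
      cdr3_nt = if ("cdr3_nt" %in% names(raw)) raw$cdr3_nt else "",
      v_gene = raw$v_gene, j_gene = raw$j_gene,
      full_length = parse_bool(raw$full_length, path),
      productive = parse_bool(raw$productive, path),
      umis = if ("umis" %in% names(raw)) as.integer(raw$umis) else 1L,
      stringsAsFactors = FALSE)
  } else {
    raw <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
    missing <- setdiff(AIRR_REQUIRED, names(raw))
    if (length(missing) > 0)
      stop("missing mandatory column(s) in ", path, ": ",
           paste(missing, collapse = ", "))
    out <- data.frame(
      sample_id = rep(sample_id, nrow(raw)),
      barcode = raw$cell_id,
      chain = ifelse(raw$locus %in% c("TRA", "TRB"), raw$locus, "other"),
      cdr3_aa = raw$junction_aa,
      cdr3_nt = if ("junction" %in% names(raw)) raw$junction else "",
      v_gene = raw$v_call, j_gene = raw$j_call,
      full_length = parse_bool(raw$complete_vdj, path),
      productive = parse_bool(raw$productive, path),
      umis = if ("duplicate_count" %in% names(raw)) as.integer(raw$duplicate_count) else 1L,
      stringsAsFactors = FALSE)
  }
  if (nrow(out) > 0 && anyNA(out$umis)) out$umis[is.na(out$umis)] <- 0L
  out
}

#' Read a set of contig files, one per sample
#'
#' @param paths Character vector of file paths; names, if present, are
#'   used as sample ids.
#' @param dialect Passed to [read_contigs()].
#' @return Combined contig data frame.
#' @export
read_contig_set <- function(paths, dialect = c("tenx_csv", "airr_tsv")) {
  dialect <- match.arg(dialect)
  ids <- names(paths)
  do.call(rbind, lapply(seq_along(paths), function(i)
    read_contigs(paths[i], dialect,
                 sample_id = if (!is.null(ids) && nzchar(ids[i])) ids[i] else NULL)))
}

#' Keep full-length productive contigs and retain paired cells
#'
#' Keeps contigs that are both full length and productive; within each
#' (sample, barcode, chain), when multiple contigs survive, keeps the one
#' with the highest UMI count (ties broken by lexicographically smallest
#' CDR3); retains only cells with both a surviving TRA and TRB.
#'
#' @param records Contig data frame from [read_contigs()].
#' @param multichain `"top_umi"` (keep best contig per chain, the Cell
#'   Ranger-like convention) or `"drop"` (discard cells with more than
#'   one surviving contig for a chain).
#' @return Data frame of paired cells, one row per cell, with columns
#'   `sample_id`, `barcode`, `cdr3a_aa`, `trav`, `traj`, `cdr3b_aa`,
#'   `trbv`, `trbj`.
#' @export
filter_productive_paired <- function(records, multichain = c("top_umi", "drop")) {
  multichain <- match.arg(multichain)
  keep <- records[records$full_length & records$productive &
                    records$chain %in% c("TRA", "TRB"), , drop = FALSE]
  empty <- data.frame(sample_id = character(0), barcode = character(0),
                      cdr3a_aa = character(0), trav = character(0), traj = character(0),
                      cdr3b_aa = character(0), trbv = character(0), trbj = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(keep) == 0) return(empty)
  # Deterministic best-contig order: highest umis first, then smallest cdr3.
  keep <- keep[order(keep$sample_id, keep$barcode, keep$chain,
                     -keep$umis, keep$cdr3_aa), ]
  key <- paste(keep$sample_id, keep$barcode, keep$chain, sep = "\r")
  dup <- duplicated(key)
  if (multichain == "drop") {
    multis <- unique(paste(keep$sample_id, keep$barcode, sep = "\r")[dup])
    keep <- keep[!(paste(keep$sample_id, keep$barcode, sep = "\r") %in% multis), ]
  } else {
    keep <- keep[!dup, ]
  }
  if (nrow(keep) == 0) return(empty)
  cell_key <- paste(keep$sample_id, keep$barcode, sep = "\r")
  tra <- keep[keep$chain == "TRA", ]
  trb <- keep[keep$chain == "TRB", ]
  common <- intersect(paste(tra$sample_id, tra$barcode, sep = "\r"),
                      paste(trb$sample_id, trb$barcode, sep = "\r"))
  if (length(common) == 0) return(empty)
  tra <- tra[match(common, paste(tra$sample_id, tra$barcode, sep = "\r")), ]
  trb <- trb[match(common, paste(trb$sample_id, trb$barcode, sep = "\r")), ]
  out <- data.frame(sample_id = tra$sample_id, barcode = tra$barcode,
                    cdr3a_aa = tra$cdr3_aa, trav = tra$v_gene, traj = tra$j_gene,
                    cdr3b_aa = trb$cdr3_aa, trbv = trb$v_gene, trbj = trb$j_gene,
                    stringsAsFactors = FALSE)
  out <- out[order(out$sample_id, out$barcode), ]
  rownames(out) <- NULL
  out
}

#' Call clonotypes from paired cells
#'
#' Clonotypes are identity classes of the (CDR3alpha, CDR3beta)
#' amino-acid pair; clone size is the number of member cells. V/J genes
#' are the modal usage across members. Ordering is deterministic: size
#' descending, then CDR3beta, then CDR3alpha.
#'
#' @param cells Paired-cell data frame from [filter_productive_paired()].
#' @param condition_map Named character vector mapping every `sample_id`
#'   to a condition label.
#' @return Object of class `clonotype_set`: list with `clonotypes` (data
#'   frame: `clonotype_id`, `cdr3a_aa`, `cdr3b_aa`, `trav`, `traj`,
#'   `trbv`, `trbj`, `size`, `n_samples`), `counts` (clonotype x sample
#'   integer matrix), `condition_map`, and `cells` (input cells with a
#'   `clonotype_id` column).
#' @export
call_clonotypes <- function(cells, condition_map) {
  unmapped <- setdiff(unique(cells$sample_id), names(condition_map))
  if (length(unmapped) > 0)
    stop("sample id(s) missing from condition map: ",
         paste(unmapped, collapse = ", "))
  key <- paste(cells$cdr3a_aa, cells$cdr3b_aa, sep = "|")
  samples <- sort(unique(cells$sample_id))
  counts_tab <- table(key, factor(cells$sample_id, levels = samples))
  counts <- matrix(as.integer(counts_tab), nrow = nrow(counts_tab),
                   dimnames = list(rownames(counts_tab), samples))
  size <- rowSums(counts)
  first <- !duplicated(key)
  info <- data.frame(key = key[first], cdr3a_aa = cells$cdr3a_aa[first],
                     cdr3b_aa = cells$cdr3b_aa[first], stringsAsFactors = FALSE)
  info <- info[match(rownames(counts), info$key), ]
  ord <- order(-size, info$cdr3b_aa, info$cdr3a_aa)
  counts <- counts[ord, , drop = FALSE]
  info <- info[ord, ]
  size <- size[ord]
  ids <- sprintf("CT%06d", seq_len(nrow(info)))
  modal_by <- function(col) {
    vapply(split(cells[[col]], key), modal_value, character(1))[info$key]
  }
  clonotypes <- data.frame(clonotype_id = ids,
                           cdr3a_aa = info$cdr3a_aa, cdr3b_aa = info$cdr3b_aa,
                           trav = modal_by("trav"), traj = modal_by("traj"),
                           trbv = modal_by("trbv"), trbj = modal_by("trbj"),
                           size = as.integer(size),
                           n_samples = as.integer(rowSums(counts > 0)),
                           stringsAsFactors = FALSE)
  rownames(clonotypes) <- NULL
  rownames(counts) <- ids
  cells_out <- cells
  cells_out$clonotype_id <- ids[match(key, info$key)]
  structure(list(clonotypes = clonotypes, counts = counts,
                 condition_map = condition_map[samples], cells = cells_out),
            class = "clonotype_set")
}

#' @export
print.clonotype_set <- function(x, ...) {
  cat("clonotype_set:", nrow(x$clonotypes), "clonotypes,",
      nrow(x$cells), "cells,", ncol(x$counts), "samples\n")
  invisible(x)
}

#' Clonotype count matrix by sample or condition
#'
#' @param cs A `clonotype_set` from [call_clonotypes()].
#' @param axis `"sample"` or `"condition"`.
#' @return Integer matrix, clonotype x sample (or condition); row sums
#'   equal clone sizes.
#' @export
repertoire_matrix <- function(cs, axis = c("sample", "condition")) {
  axis <- match.arg(axis)
  if (axis == "sample") return(cs$counts)
  cond <- cs$condition_map[colnames(cs$counts)]
  t(rowsum(t(cs$counts), group = as.character(cond)))
}

#' Per-condition clone counts of every clonotype
#'
#' @param cs A `clonotype_set`.
#' @return Data frame `clonotype_id` plus one count column per condition.
#' @export
condition_counts <- function(cs) {
  m <- repertoire_matrix(cs, "condition")
  out <- data.frame(clonotype_id = rownames(m), stringsAsFactors = FALSE)
  for (cn in colnames(m)) out[[cn]] <- as.integer(m[, cn])
  out
}

#' Write / read a clonotype table as TSV
#'
#' The TSV carries the clonotype table joined with the per-sample count
#' matrix, so a written set round-trips losslessly.
#' @param cs A `clonotype_set`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_clonotypes_tsv <- function(cs, path) {
  df <- cbind(cs$clonotypes,
              as.data.frame(cs$counts, check.names = FALSE)[cs$clonotypes$clonotype_id, , drop = FALSE])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_clonotypes_tsv
#' @param condition_map Condition map to re-attach when reading.
#' @export
read_clonotypes_tsv <- function(path, condition_map) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  base_cols <- c("clonotype_id", "cdr3a_aa", "cdr3b_aa", "trav", "traj",
                 "trbv", "trbj", "size", "n_samples")
  samples <- setdiff(names(df), base_cols)
  counts <- as.matrix(df[, samples, drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- df$clonotype_id
  structure(list(clonotypes = df[, base_cols], counts = counts,
                 condition_map = condition_map[samples], cells = NULL),
            class = "clonotype_set")
}
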