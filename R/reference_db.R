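# Harmonized CDR3beta -> antigen reference database: compilation from
# heterogeneous source tables, exact CDR3beta annotation of clonotypes,
# and motif-level annotation transfer to specificity groups.

DB_SCHEMA <- c("cdr3b", "peptide", "antigen", "disease", "disease_class",
               "species", "v_gene", "j_gene", "source")

DISEASE_CLASSES <- c("virus", "bacteria", "parasite", "autoimmune", "cancer",
                     "transplant", "immunodeficiency", "allergy", "other")

#' Compile a harmonized CDR3beta-antigen reference database
#'
#' Each raw source table is mapped to the unified schema through its
#' declared column mapping, then cleaned: rows whose CDR3beta contains
#' characters outside the 20 standard amino-acid letters are dropped, as
#' are exact duplicate rows. The disease class is assigned from a
#' configurable disease-to-class lookup with fallback `"other"`.
#' Idempotent: compiling a compiled database returns it unchanged.
#'
#' @param tables Named list of raw data frames (names become `source`
#'   unless the mapping provides one).
#' @param mappings Named list (parallel to `tables`) of column mappings:
#'   each a named character vector `schema_column = raw_column` covering
#'   at least `cdr3b` and `peptide`.
#' @param disease_class_map Optional named character vector mapping
#'   `disease` values to one of the disease classes; entries whose raw
#'   table already carries a `disease_class` keep it.
#' @return Data frame in the unified schema.
#' @export
compile_reference <- function(tables, mappings = NULL,
                              disease_class_map = NULL) {
  if (is.data.frame(tables)) tables <- list(db = tables)
  if (is.null(mappings))
    mappings <- lapply(tables, function(t) {
      setNames(intersect(DB_SCHEMA, names(t)), intersect(DB_SCHEMA, names(t)))
    })
  out <- vector("list", length(tables))
  for (i in seq_along(tables)) {
    raw <- tables[[i]]
    map <- mappings[[i]]
    src <- names(tables)[i]
    for (col in c("cdr3b", "peptide")) {
      if (!col %in% names(map) || !(map[[col]] %in% names(raw)))
        stop("source '", src, "': mandatory column '", col,
             "' is unmapped or absent")
    }
    df <- as.data.frame(lapply(setNames(DB_SCHEMA, DB_SCHEMA), function(col) {
      if (col %in% names(map) && map[[col]] %in% names(raw))
        as.character(raw[[map[[col]]]]) else rep(NA_character_, nrow(raw))
    }), stringsAsFactors = FALSE)
    if (nrow(df) > 0 && all(is.na(df$source))) df$source <- src
    out[[i]] <- df
  }
  db <- do.call(rbind, out)
  if (is.null(db) || nrow(db) == 0) {
    db <- as.data.frame(setNames(rep(list(character(0)), length(DB_SCHEMA)),
                                 DB_SCHEMA), stringsAsFactors = FALSE)
    return(db)
  }
  db <- db[is_standard_aa(db$cdr3b), , drop = FALSE]
  # Disease class: keep valid existing labels, else look up, else "other".
  lk <- if (is.null(disease_class_map)) character(0) else disease_class_map
  have <- !is.na(db$disease_class) & db$disease_class %in% DISEASE_CLASSES
  looked <- unname(lk[db$disease])
  db$disease_class <- ifelse(have, db$disease_class,
                             ifelse(!is.na(looked) & looked %in% DISEASE_CLASSES,
                                    looked, "other"))
  db <- db[!duplicated(db), , drop = FALSE]
  rownames(db) <- NULL
  db
}

#' Annotate clonotypes by exact CDR3beta match against the database
#'
#' A clonotype receives every (peptide, antigen, disease class)
#' annotation whose database CDR3beta equals its CDR3beta exactly.
#'
#' @param cs A `clonotype_set`.
#' @param db Compiled reference database.
#' @return List with `annotations` (data frame `clonotype_id`, `cdr3b`,
#'   `peptide`, `antigen`, `disease_class`, `source`) and
#'   `matched_fraction` (share of unique query CDR3betas with at least
#'   one match).
#' @export
exact_match <- function(cs, db) {
  clo <- cs$clonotypes
  hit <- merge(clo[, c("clonotype_id", "cdr3b_aa", "size")],
               db[, c("cdr3b", "peptide", "antigen", "disease_class", "source")],
               by.x = "cdr3b_aa", by.y = "cdr3b")
  ann <- data.frame(clonotype_id = hit$clonotype_id, cdr3b = hit$cdr3b_aa,
                    clone_size = hit$size, peptide = hit$peptide,
                    antigen = hit$antigen, disease_class = hit$disease_class,
                    source = hit$source, stringsAsFactors = FALSE)
  ann <- ann[order(ann$clonotype_id, ann$peptide, ann$source), ]
  rownames(ann) <- NULL
  uq <- unique(clo$cdr3b_aa)
  list(annotations = ann,
       matched_fraction = if (length(uq) == 0) 0 else
         length(intersect(uq, db$cdr3b)) / length(uq))
}

#' Build specificity groups over the reference database itself
#'
#' Runs the specificity-grouping machinery on the database's CDR3betas
#' (each unique CDR3beta treated as one single-cell clonotype in one
#' pseudo-sample per source), producing motif-seeded database groups
#' whose annotations can be transferred to query groups.
#'
#' @param db Compiled reference database.
#' @param reference A [reference_repertoire()] background.
#' @param ... Passed to [specificity_groups()] (e.g. `p_motif`).
#' @return As [specificity_groups()], with each group carrying its member
#'   database entries.
#' @export
db_specificity_groups <- function(db, reference, ...) {
  uq <- db[!duplicated(db$cdr3b), , drop = FALSE]
  cells <- data.frame(sample_id = uq$source, barcode = paste0("db", seq_len(nrow(uq))),
                      cdr3a_aa = "CA.DB.F", trav = "NA", traj = "NA",
                      cdr3b_aa = uq$cdr3b,
                      trbv = ifelse(is.na(uq$v_gene), "unknown", uq$v_gene),
                      trbj = ifelse(is.na(uq$j_gene), "unknown", uq$j_gene),
                      stringsAsFactors = FALSE)
  # Distinct alpha per entry so each CDR3beta is its own clonotype.
  cells$cdr3a_aa <- paste0("CADB", seq_len(nrow(uq)), "F")
  cmap <- setNames(unique(cells$sample_id), unique(cells$sample_id))
  cs <- call_clonotypes(cells, cmap)
  sg <- specificity_groups(cs, reference, ...)
  sg$db_cdr3b <- setNames(cs$clonotypes$cdr3b_aa, cs$clonotypes$clonotype_id)
  sg$db <- db
  sg
}

#' Transfer database annotations to query groups via shared seed motifs
#'
#' A query group whose seed motif equals a database group's seed motif
#' inherits the database group's majority peptide/antigen/disease-class
#' annotation (majority by unique database CDR3beta count). Ties attach
#' all tied annotations and flag the group ambiguous.
#'
#' @param query_groups Group table from [specificity_groups()] on the
#'   query repertoire.
#' @param db_groups Result of [db_specificity_groups()].
#' @return `query_groups` with columns `pred_peptide`, `pred_antigen`,
#'   `pred_disease_class` (each possibly `;`-separated on ties),
#'   `annotation_ambiguous`, `annotated`; plus an `annotated_fraction`
#'   attribute.
#' @export
motif_transfer <- function(query_groups, db_groups) {
  qg <- query_groups
  qg$pred_peptide <- rep(NA_character_, nrow(qg))
  qg$pred_antigen <- rep(NA_character_, nrow(qg))
  qg$pred_disease_class <- rep(NA_character_, nrow(qg))
  qg$annotation_ambiguous <- rep(FALSE, nrow(qg))
  qg$annotated <- rep(FALSE, nrow(qg))
  if (nrow(qg) == 0 || nrow(db_groups$groups) == 0) {
    attr(qg, "annotated_fraction") <- 0
    return(qg)
  }
  dbg <- db_groups$groups[db_groups$groups$seed_type == "motif", , drop = FALSE]
  db <- db_groups$db
  members <- db_groups$members
  for (i in seq_len(nrow(qg))) {
    if (qg$seed_type[i] != "motif") next
    j <- which(dbg$seed == qg$seed[i])
    if (length(j) == 0) next
    mem_ids <- members$clonotype_id[members$group_id %in% dbg$group_id[j]]
    cdr3s <- unique(db_groups$db_cdr3b[mem_ids])
    entries <- db[db$cdr3b %in% cdr3s, , drop = FALSE]
    if (nrow(entries) == 0) next
    # Majority by unique database CDR3beta per peptide.
    votes <- tapply(entries$cdr3b, entries$peptide,
                    function(x) length(unique(x)))
    top <- names(votes)[votes == max(votes)]
    sel <- entries[entries$peptide %in% top, , drop = FALSE]
    qg$pred_peptide[i] <- paste(sort(top), collapse = ";")
    qg$pred_antigen[i] <- paste(sort(unique(sel$antigen)), collapse = ";")
    qg$pred_disease_class[i] <- paste(sort(unique(sel$disease_class)), collapse = ";")
    qg$annotation_ambiguous[i] <- length(top) > 1
    qg$annotated[i] <- TRUE
  }
  attr(qg, "annotated_fraction") <- mean(qg$annotated)
  qg
}

#' Write / read the unified reference database as TSV
#' @param db Compiled database.
#' @param path TSV path.
#' @return `path` (write) or the database (read).
#' @export
write_reference_tsv <- function(db, path) {
  write.table(db, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_reference_tsv
#' @export
read_reference_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                   na.strings = character(0))
  for (col in setdiff(DB_SCHEMA, names(df))) df[[col]] <- NA_character_
  df[df == ""] <- NA_character_
  df[, DB_SCHEMA]
}
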