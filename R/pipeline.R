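# End-to-end orchestration: one config drives contig reading, clonotype
# calling, repertoire statistics, specificity grouping, database
# annotation, PWM proteome scanning and the expression-side analyses,
# writing every artifact plus a checksummed run manifest.

#' Default analysis thresholds
#'
#' The expansion and filtering thresholds of the analysis, collected in
#' one place: clonotype expansion |log2FC| > 3 with clone size > 10;
#' specificity-group expansion |log2FC| > 2.5 with total size > 10;
#' group filters (>= 4 unique clonotypes, >= 3 samples, V-bias p < 0.05,
#' final score < 1e-5); DE display filter (adjusted p < 0.01, log2FC >
#' 0.2); PWM training clone-size floor (> 3).
#' @return Named list of thresholds.
#' @export
default_thresholds <- function() {
  list(clonotype_log2fc = 3, clonotype_floor = 10,
       group_log2fc = 2.5, group_floor = 10,
       min_clonotypes = 4, min_samples = 3,
       max_vgene_p = 0.05, max_final = 1e-5,
       p_motif = 1e-3,
       de_adj_p = 0.01, de_log2fc = 0.2,
       pwm_min_clone = 3,
       network_min_size = 10,
       rarefaction_step = 20,
       nmds_k = 2, nmds_restarts = 50)
}

#' Assemble and validate a pipeline configuration
#'
#' @param contig_files Named character vector of per-sample contig
#'   files (names are sample ids).
#' @param dialect Contig dialect (`"tenx_csv"` or `"airr_tsv"`).
#' @param expression_dir Directory with `matrix.mtx`, `barcodes.tsv`,
#'   `features.tsv`, `metadata.csv`.
#' @param reference_repertoire_file TSV with columns `cdr3b`, `v_gene`.
#' @param reference_db_file Unified reference database TSV.
#' @param proteome_file Proteome FASTA.
#' @param condition_map Named character vector, sample id to condition.
#' @param thresholds Threshold block; defaults [default_thresholds()].
#' @param seed Integer seed for every stochastic stage.
#' @param out_dir Output directory.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(contig_files, dialect = "tenx_csv",
                            expression_dir = NULL,
                            reference_repertoire_file = NULL,
                            reference_db_file = NULL,
                            proteome_file = NULL,
                            condition_map, thresholds = default_thresholds(),
                            seed = 1L, out_dir = "results") {
  cfg <- list(contig_files = contig_files, dialect = dialect,
              expression_dir = expression_dir,
              reference_repertoire_file = reference_repertoire_file,
              reference_db_file = reference_db_file,
              proteome_file = proteome_file,
              condition_map = condition_map,
              thresholds = utils::modifyList(default_thresholds(), thresholds),
              seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' Schema, file-existence and threshold-sanity checks (probabilities in
#' (0, 1], sizes non-negative).
#' @param config A [pipeline_config()].
#' @return Character vector of error messages; empty when valid.
#' @export
validate_config <- function(config) {
  errs <- character(0)
  th <- config$thresholds
  for (f in config$contig_files)
    if (!file.exists(f)) errs <- c(errs, paste("contig file not found:", f))
  for (nm in c("reference_repertoire_file", "reference_db_file", "proteome_file"))
    if (!is.null(config[[nm]]) && !file.exists(config[[nm]]))
      errs <- c(errs, paste(nm, "not found:", config[[nm]]))
  if (!is.null(config$expression_dir) && !dir.exists(config$expression_dir))
    errs <- c(errs, paste("expression_dir not found:", config$expression_dir))
  missing_cond <- setdiff(names(config$contig_files), names(config$condition_map))
  if (length(missing_cond) > 0)
    errs <- c(errs, paste("samples missing from condition map:",
                          paste(missing_cond, collapse = ", ")))
  for (nm in c("max_vgene_p", "max_final", "p_motif", "de_adj_p"))
    if (!is.numeric(th[[nm]]) || th[[nm]] <= 0 || th[[nm]] > 1)
      errs <- c(errs, paste("threshold", nm, "must be a probability in (0, 1]"))
  for (nm in c("clonotype_floor", "group_floor", "min_clonotypes",
               "min_samples", "pwm_min_clone", "network_min_size"))
    if (!is.numeric(th[[nm]]) || th[[nm]] < 0)
      errs <- c(errs, paste("threshold", nm, "must be non-negative"))
  errs
}

run_stage <- function(name, fn) {
  tryCatch(fn(), error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  path
}

#' Run the full analysis pipeline
#'
#' Executes contig reading and pairing, clonotype calling, repertoire
#' statistics (diversity, rarefaction, public clonotypes, Bray-Curtis +
#' NMDS ordination over public clonotypes, sample-clonotype network,
#' expansion labels), specificity grouping, database annotation (exact
#' match and motif transfer), PWM proteome scanning per condition, and
#' the expression analyses (clone-size correlation, condition DE,
#' per-clonotype average expression, signature module score), writing
#' every table under `config$out_dir` plus a checksummed `manifest.json`.
#' Identical config and inputs give byte-identical outputs.
#'
#' @param config A validated [pipeline_config()].
#' @return Invisible list of in-memory results (`clonotype_set`, group
#'   tables, hit tables, ...) with element `manifest`.
#' @export
run_pipeline <- function(config) {
  errs <- validate_config(config)
  if (length(errs) > 0)
    stop("invalid pipeline config:\n  ", paste(errs, collapse = "\n  "))
  th <- config$thresholds
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  res <- list()

  cs <- run_stage("tcr_io", function() {
    contigs <- read_contig_set(config$contig_files, config$dialect)
    cells <- filter_productive_paired(contigs)
    call_clonotypes(cells, config$condition_map)
  })
  res$clonotype_set <- cs
  written <- c(written, write_tsv(cs$clonotypes, file.path(out, "clonotypes.tsv")))

  res$repertoire <- run_stage("repertoire_stats", function() {
    counts <- cs$counts
    per_sample <- data.frame(
      sample_id = colnames(counts),
      condition = as.character(config$condition_map[colnames(counts)]),
      n_cells = as.integer(colSums(counts)),
      n_clonotypes = as.integer(colSums(counts > 0)),
      shannon = apply(counts, 2, function(x) shannon_diversity(x[x > 0])),
      geometric_mean_size = apply(counts, 2, function(x)
        geometric_mean_clone_size(x[x > 0])),
      stringsAsFactors = FALSE)
    pub <- public_clonotypes(counts, config$condition_map)
    cond <- repertoire_matrix(cs, "condition")
    conds <- colnames(cond)
    lab <- expansion_labels(cond[, 1], cond[, 2], entity_id = rownames(cond),
                            log2fc_threshold = th$clonotype_log2fc,
                            size_floor = th$clonotype_floor,
                            labels = conds)
    net <- sample_clonotype_network(cs, th$network_min_size)
    rar <- do.call(rbind, lapply(colnames(counts), function(s) {
      x <- counts[, s]; x <- x[x > 0]
      cbind(sample_id = s, rarefaction_curve(x, th$rarefaction_step))
    }))
    ord <- NULL
    if (nrow(pub) >= 1 && ncol(counts) >= 3) {
      pubm <- t(counts[pub$clonotype_id, , drop = FALSE])
      keep <- rowSums(pubm) > 0
      if (sum(keep) >= 3) {
        ord <- nmds(bray_curtis(pubm[keep, , drop = FALSE]), k = th$nmds_k,
                    seed = config$seed, n_restarts = th$nmds_restarts)
      }
    }
    list(per_sample = per_sample, public = pub, labels = lab,
         network = net$edges, rarefaction = rar, nmds = ord)
  })
  rp <- res$repertoire
  written <- c(written,
               write_tsv(rp$per_sample, file.path(out, "per_sample_stats.tsv")),
               write_tsv(rp$public, file.path(out, "public_clonotypes.tsv")),
               write_tsv(rp$labels, file.path(out, "clonotype_expansion.tsv")),
               write_tsv(rp$network, file.path(out, "network_edges.tsv")),
               write_tsv(rp$rarefaction, file.path(out, "rarefaction.tsv")))
  if (!is.null(rp$nmds)) {
    nm <- data.frame(sample_id = rownames(rp$nmds$coordinates),
                     round(rp$nmds$coordinates, 10),
                     stress = rp$nmds$stress)
    written <- c(written, write_tsv(nm, file.path(out, "nmds_public.tsv")))
  }

  if (!is.null(config$reference_repertoire_file)) {
    sg <- run_stage("specificity_grouping", function() {
      bg <- read.delim(config$reference_repertoire_file,
                       stringsAsFactors = FALSE)
      ref <- reference_repertoire(bg$cdr3b, bg$v_gene)
      specificity_groups(cs, ref, p_motif = th$p_motif,
                         min_clonotypes = th$min_clonotypes,
                         min_samples = th$min_samples,
                         max_vgene_p = th$max_vgene_p,
                         max_final = th$max_final,
                         enrich_log2fc = th$group_log2fc,
                         enrich_floor = th$group_floor)
    })
    res$specificity <- sg
    written <- c(written,
                 write_tsv(sg$groups, file.path(out, "specificity_groups.tsv")),
                 write_tsv(sg$members, file.path(out, "group_members.tsv")))
  }

  if (!is.null(config$reference_db_file)) {
    ann <- run_stage("reference_db", function() {
      db <- compile_reference(read_reference_tsv(config$reference_db_file))
      em <- exact_match(cs, db)
      out_ann <- list(db = db, exact = em, transferred = NULL)
      if (!is.null(res$specificity)) {
        bg <- read.delim(config$reference_repertoire_file,
                         stringsAsFactors = FALSE)
        ref <- reference_repertoire(bg$cdr3b, bg$v_gene)
        dbg <- db_specificity_groups(db, ref, p_motif = th$p_motif)
        out_ann$transferred <- motif_transfer(res$specificity$groups, dbg)
      }
      out_ann
    })
    res$annotation <- ann
    written <- c(written,
                 write_tsv(ann$exact$annotations,
                           file.path(out, "exact_match_annotations.tsv")))
    if (!is.null(ann$transferred))
      written <- c(written, write_tsv(ann$transferred,
                                      file.path(out, "annotated_groups.tsv")))
  }

  if (!is.null(config$proteome_file) && !is.null(res$annotation)) {
    pw <- run_stage("pwm_scan", function() {
      proteome <- read_proteome_fasta(config$proteome_file)
      bgfreq <- proteome_background(proteome)
      labels <- res$repertoire$labels
      scans <- list()
      for (side in c("A", "B")) {
        wp <- select_weighted_peptides(res$annotation$exact$annotations,
                                       labels, condition = side,
                                       min_clone_size = th$pwm_min_clone)
        if (nrow(wp) == 0) next
        pwm <- build_pwm(wp$peptide, wp$weight, background = bgfreq)
        cond_name <- colnames(repertoire_matrix(cs, "condition"))[if (side == "A") 1 else 2]
        scans[[cond_name]] <- scan_proteome(pwm, proteome)
      }
      scans
    })
    res$pwm <- pw
    for (cond_name in names(pw))
      written <- c(written, write_tsv(pw[[cond_name]]$hits,
                                      file.path(out, paste0("pwm_hits_", cond_name, ".tsv"))))
  }

  if (!is.null(config$expression_dir)) {
    gx <- run_stage("gex_link", function() {
      ex <- read_expression_mtx(config$expression_dir)
      expr <- normalize_log1p_cp10k(ex$counts)
      cells <- attach_clonotypes(ex$meta, cs)
      corr <- clone_size_correlation(expr, cells)
      conds <- sort(unique(cells$condition))
      de <- NULL
      if (length(conds) == 2) {
        de <- differential_expression(expr,
                                      cells$barcode[cells$condition == conds[1]],
                                      cells$barcode[cells$condition == conds[2]])
        de$display_hit <- de$p_adjusted < th$de_adj_p & abs(de$log2fc) > th$de_log2fc
      }
      avg <- average_expression_by(ex$counts, cells, "clonotype_id")
      sig <- NULL
      if (!is.null(de)) {
        top <- head(de$gene[de$display_hit & de$log2fc > 0], 10)
        if (length(top) >= 2) {
          ms <- module_score(expr, top, seed = config$seed)
          sig <- data.frame(barcode = names(ms), score = as.numeric(ms),
                            condition = cells$condition[match(names(ms), cells$barcode)],
                            stringsAsFactors = FALSE)
        }
      }
      list(cells = cells, correlation = corr, de = de,
           avg_by_clonotype = avg, signature = sig)
    })
    res$gex <- gx
    written <- c(written,
                 write_tsv(gx$correlation, file.path(out, "clone_size_correlation.tsv")))
    if (!is.null(gx$de))
      written <- c(written, write_tsv(gx$de, file.path(out, "differential_expression.tsv")))
    if (!is.null(gx$signature))
      written <- c(written, write_tsv(gx$signature, file.path(out, "signature_scores.tsv")))
  }

  manifest <- list(
    config = list(dialect = config$dialect, seed = config$seed,
                  thresholds = th,
                  condition_map = as.list(config$condition_map)),
    outputs = as.list(setNames(unname(tools::md5sum(written)),
                               basename(written))))
  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest
  res$manifest_path <- manifest_path
  invisible(res)
}

#' Write per-sample 10x-dialect contig CSVs
#'
#' @param contigs Contig data frame (reader schema, with `sample_id`).
#' @param dir Output directory.
#' @return Named character vector of file paths (names are sample ids).
#' @export
write_contigs_csv <- function(contigs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (s in sort(unique(contigs$sample_id))) {
    sub <- contigs[contigs$sample_id == s, ]
    df <- data.frame(barcode = sub$barcode, is_cell = "True",
                     contig_id = paste0(sub$barcode, "_contig_", seq_len(nrow(sub))),
                     chain = sub$chain, v_gene = sub$v_gene, d_gene = "None",
                     j_gene = sub$j_gene, c_gene = "None",
                     full_length = ifelse(sub$full_length, "True", "False"),
                     productive = ifelse(sub$productive, "True", "False"),
                     cdr3 = sub$cdr3_aa, cdr3_nt = sub$cdr3_nt,
                     reads = sub$umis * 10L, umis = sub$umis,
                     stringsAsFactors = FALSE)
    p <- file.path(dir, paste0(s, "_contigs.csv"))
    write.table(df, p, sep = ",", quote = FALSE, row.names = FALSE)
    paths[s] <- p
  }
  paths
}

#' One-command synthetic demo of the whole pipeline
#'
#' Generates a complete synthetic dataset (contigs, expression,
#' reference repertoire, reference database, proteome) under
#' `out_dir/inputs`, then runs [run_pipeline()] on those files with
#' outputs under `out_dir/results`. Deterministic: the same seed gives
#' byte-identical outputs.
#'
#' @param out_dir Demo directory (created).
#' @param seed Integer seed.
#' @param config Optional [synth_config()] override (its seed is
#'   replaced by `seed`).
#' @return Invisible result bundle from [run_pipeline()], with the
#'   ground truth attached as `$truth`.
#' @export
run_demo <- function(out_dir, seed = 1L, config = NULL) {
  if (is.null(config)) config <- synth_config(seed = seed)
  else { config$seed <- as.integer(seed); validate_synth_config(config) }
  inputs <- file.path(out_dir, "inputs")
  dir.create(inputs, recursive = TRUE, showWarnings = FALSE)

  rep_data <- generate_repertoire(config)
  contig_paths <- write_contigs_csv(rep_data$contigs, file.path(inputs, "contigs"))
  ex <- generate_expression(rep_data$cells, config)
  write_expression_mtx(ex$counts, ex$meta, file.path(inputs, "expression"))
  bg <- synth_background_repertoire(5000, config)
  bg_path <- file.path(inputs, "reference_repertoire.tsv")
  write.table(bg, bg_path, sep = "\t", quote = FALSE, row.names = FALSE)
  db_raw <- generate_reference_db(config, repertoire = rep_data)
  db_path <- write_reference_tsv(db_raw, file.path(inputs, "reference_db.tsv"))
  pr <- generate_proteome(config)
  prot_path <- write_proteome_fasta(pr$proteome, file.path(inputs, "proteome.fasta"))
  jsonlite::write_json(list(motifs = rep_data$truth$motifs,
                            public_keys = rep_data$truth$public_keys,
                            placements = pr$placements),
                       file.path(inputs, "ground_truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  pcfg <- pipeline_config(contig_files = contig_paths,
                          dialect = "tenx_csv",
                          expression_dir = file.path(inputs, "expression"),
                          reference_repertoire_file = bg_path,
                          reference_db_file = db_path,
                          proteome_file = prot_path,
                          condition_map = synth_condition_map(config),
                          seed = seed,
                          out_dir = file.path(out_dir, "results"))
  res <- run_pipeline(pcfg)
  res$truth <- rep_data$truth
  res$synth_config <- config
  invisible(res)
}
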