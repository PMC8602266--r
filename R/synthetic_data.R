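# Synthetic paired scTCR/scRNA data with planted ground truth.
#
# The generator emulates the study conditions of a two-condition mouse
# follicular T cell experiment: 5 wild-type (WT) and 5 autoimmune (AU)
# chimeras, heavy-tailed per-sample clone-size distributions, a small set
# of public clonotypes shared between conditions, planted CDR3beta
# specificity motifs whose carriers also share a biased TRBV gene, an
# expression matrix with genes whose log-mean is monotone in log clone
# size or shifted by condition, an annotated CDR3beta reference database
# containing the planted motifs, and a toy proteome carrying planted
# 9-mer target peptides.

#' Configuration for the synthetic-data generator
#'
#' All downstream inputs of the pipeline are generated from one config;
#' identical configs produce byte-identical outputs. Defaults encode the
#' emulated study design: 5 samples per condition, 300 clonotypes per
#' sample, Zipf clone sizes, 8 condition-shared public clonotypes, and 5
#' planted 4-residue CDR3beta motifs at carrier fraction 0.05 whose
#' carriers preferentially use one TRBV gene.
#'
#' @param n_samples_per_condition Samples per condition (WT and AU).
#' @param clones_per_sample Clonotypes generated per sample.
#' @param clone_size_alpha Power-law exponent of the discrete (truncated
#'   Zipf) clone-size distribution; must be > 1.
#' @param max_clone_size Truncation point of the Zipf distribution.
#' @param n_public_clonotypes Clonotypes emitted in both conditions.
#' @param planted_motifs Data frame with columns `motif` (2-4 aa),
#'   `condition` (one of `"shared"`, `"WT"`, `"AU"`) and
#'   `carrier_fraction` in (0, 1].
#' @param v_bias Probability that a motif carrier uses its motif's
#'   designated TRBV gene instead of a uniform draw from the pool.
#' @param v_gene_pool,j_gene_pool TRB gene name pools.
#' @param va_gene_pool,ja_gene_pool TRA gene name pools.
#' @param cdr3_length_range Integer pair; CDR3 lengths are uniform on this
#'   range (both chains). Minimum 6.
#' @param decoy_fraction Fraction of emitted cells that are decoys
#'   (unpaired or unproductive) and must be removed by the pairing filter.
#' @param n_genes,n_size_correlated_genes,n_condition_genes Expression
#'   panel sizes.
#' @param effect_size Log-fold shift in gene mean per unit centred
#'   log clone size for size-correlated genes.
#' @param condition_shift log2 fold change applied to condition-shifted
#'   genes in the AU condition.
#' @param dispersion Negative-binomial dispersion (1/size) of counts.
#' @param n_target_peptides Number of planted 9-mer antigen peptides.
#' @param db_entries_per_motif,db_background_entries,db_n_duplicates,db_n_invalid
#'   Reference-database composition: motif-annotated entries per planted
#'   motif, clean background entries, exact duplicate rows, and rows with
#'   non-amino-acid characters (the latter two exercise database cleaning).
#' @param proteome_n_proteins,protein_length Toy proteome dimensions.
#' @param n_plant_copies Copies of each target peptide planted in the
#'   proteome.
#' @param seed Integer seed; the single source of randomness.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_samples_per_condition = 5,
                         clones_per_sample = 300,
                         clone_size_alpha = 2.5,
                         max_clone_size = 150,
                         n_public_clonotypes = 8,
                         planted_motifs = default_planted_motifs(),
                         v_bias = 0.8,
                         v_gene_pool = paste0("TRBV", c(1, 2, 3, 4, 5, 12, 13, 14, 15, 16, 19, 20, 23, 26, 29)),
                         j_gene_pool = paste0("TRBJ", c("1-1", "1-2", "1-3", "2-1", "2-3", "2-5", "2-7")),
                         va_gene_pool = paste0("TRAV", c(1, 3, 4, 6, 7, 8, 9, 12, 13, 14, 16, 21)),
                         ja_gene_pool = paste0("TRAJ", c(2, 9, 12, 15, 21, 23, 27, 31, 33, 37, 40, 43, 49, 52, 56)),
                         cdr3_length_range = c(12L, 16L),
                         decoy_fraction = 0.05,
                         n_genes = 200,
                         n_size_correlated_genes = 20,
                         n_condition_genes = 10,
                         effect_size = 1.0,
                         condition_shift = 1.0,
                         dispersion = 0.5,
                         n_target_peptides = 5,
                         db_entries_per_motif = 30,
                         db_background_entries = 200,
                         db_n_duplicates = 10,
                         db_n_invalid = 5,
                         proteome_n_proteins = 50,
                         protein_length = 300,
                         n_plant_copies = 2,
                         seed = 1L) {
  cfg <- list(n_samples_per_condition = as.integer(n_samples_per_condition),
              clones_per_sample = as.integer(clones_per_sample),
              clone_size_alpha = clone_size_alpha,
              max_clone_size = as.integer(max_clone_size),
              n_public_clonotypes = as.integer(n_public_clonotypes),
              planted_motifs = planted_motifs,
              v_bias = v_bias,
              v_gene_pool = v_gene_pool, j_gene_pool = j_gene_pool,
              va_gene_pool = va_gene_pool, ja_gene_pool = ja_gene_pool,
              cdr3_length_range = as.integer(cdr3_length_range),
              decoy_fraction = decoy_fraction,
              n_genes = as.integer(n_genes),
              n_size_correlated_genes = as.integer(n_size_correlated_genes),
              n_condition_genes = as.integer(n_condition_genes),
              effect_size = effect_size,
              condition_shift = condition_shift,
              dispersion = dispersion,
              n_target_peptides = as.integer(n_target_peptides),
              db_entries_per_motif = as.integer(db_entries_per_motif),
              db_background_entries = as.integer(db_background_entries),
              db_n_duplicates = as.integer(db_n_duplicates),
              db_n_invalid = as.integer(db_n_invalid),
              proteome_n_proteins = as.integer(proteome_n_proteins),
              protein_length = as.integer(protein_length),
              n_plant_copies = as.integer(n_plant_copies),
              seed = as.integer(seed))
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

#' Default planted specificity motifs
#'
#' Five 4-residue motifs, a mix of condition-shared and condition-biased,
#' each carried by 5% of clonotypes of its condition.
#' @return Data frame with columns `motif`, `condition`, `carrier_fraction`.
#' @export
default_planted_motifs <- function() {
  data.frame(motif = c("QETQ", "GTNE", "RDWG", "SPLH", "YNQF"),
             condition = c("shared", "WT", "AU", "shared", "shared"),
             carrier_fraction = 0.05,
             stringsAsFactors = FALSE)
}

validate_synth_config <- function(cfg) {
  stopifnot(cfg$clone_size_alpha > 1,
            cfg$cdr3_length_range[1] >= 6,
            cfg$n_samples_per_condition >= 1,
            cfg$clones_per_sample >= 1,
            cfg$decoy_fraction >= 0, cfg$decoy_fraction < 1)
  pm <- cfg$planted_motifs
  if (nrow(pm) > 0) {
    stopifnot(all(nchar(pm$motif) >= 2), all(nchar(pm$motif) <= 4),
              all(pm$condition %in% c("shared", "WT", "AU")),
              all(pm$carrier_fraction > 0), all(pm$carrier_fraction <= 1),
              all(is_standard_aa(pm$motif)))
    if (nrow(pm) > length(cfg$v_gene_pool))
      stop("need at least one TRBV pool gene per planted motif")
  }
  if (cfg$n_size_correlated_genes + cfg$n_condition_genes > cfg$n_genes)
    stop("n_size_correlated_genes + n_condition_genes exceeds n_genes")
  invisible(cfg)
}

# Discrete truncated Zipf draw via inverse CDF: P(k) proportional to
# k^-alpha on 1..max.
rzipf <- function(n, alpha, max) {
  pmf <- (seq_len(max))^(-alpha)
  cdf <- cumsum(pmf) / sum(pmf)
  findInterval(runif(n), cdf) + 1L
}

synth_sample_ids <- function(cfg) {
  c(paste0("WT", seq_len(cfg$n_samples_per_condition)),
    paste0("AU", seq_len(cfg$n_samples_per_condition)))
}

#' Condition map of a synthetic run
#'
#' @param config A [synth_config()].
#' @return Named character vector, sample id to condition (`WT`/`AU`).
#' @export
synth_condition_map <- function(config) {
  ids <- synth_sample_ids(config)
  setNames(sub("[0-9]+$", "", ids), ids)
}

# Insert a motif into the trimmed interior of a CDR3 (never in the first
# 3 or last 2 residues), at a seeded random admissible start.
insert_motif <- function(cdr3, motif) {
  L <- nchar(cdr3)
  k <- nchar(motif)
  lo <- 4L
  hi <- L - 1L - k  # motif ends at position <= L - 2
  if (hi < lo) stop("CDR3 too short to carry motif '", motif, "' in its interior")
  start <- sample(lo:hi, 1L)
  paste0(substr(cdr3, 1, start - 1L), motif, substr(cdr3, start + k, L))
}

#' Generate a synthetic paired scTCR contig table with ground truth
#'
#' Emits, per paired cell, one full-length productive TRA and one TRB
#' contig, plus a `decoy_fraction` of unpaired or unproductive decoy
#' cells. Per-sample clone sizes follow the truncated Zipf law; public
#' clonotypes appear in both conditions; each planted motif's carriers
#' contain the motif at an interior CDR3beta position and preferentially
#' use one TRBV gene.
#'
#' @param config A [synth_config()].
#' @return List with elements `contigs` (contig-level data frame in the
#'   reader's schema), `cells` (paired-cell table with clonotype key,
#'   global clone size and cluster label), `clonotypes` (generator-level
#'   clonotype truth table) and `truth` (ground-truth list: motif carrier
#'   keys and samples, public clonotype keys, condition labels).
#' @export
generate_repertoire <- function(config) {
  cfg <- validate_synth_config(config)
  set.seed(cfg$seed)
  samples <- synth_sample_ids(cfg)
  cond_map <- synth_condition_map(cfg)
  n_per <- cfg$clones_per_sample
  lens <- cfg$cdr3_length_range

  # Clonotype skeleton: one row per (sample, local clone).
  clo <- do.call(rbind, lapply(samples, function(s) {
    data.frame(sample_id = s,
               cdr3a = paste0("CA", random_aa(n_per, sample(lens[1]:lens[2], n_per, replace = TRUE) - 3L), "F"),
               cdr3b = paste0("CA", random_aa(n_per, sample(lens[1]:lens[2], n_per, replace = TRUE) - 3L), "F"),
               trav = sample(cfg$va_gene_pool, n_per, replace = TRUE),
               traj = sample(cfg$ja_gene_pool, n_per, replace = TRUE),
               trbv = sample(cfg$v_gene_pool, n_per, replace = TRUE),
               trbj = sample(cfg$j_gene_pool, n_per, replace = TRUE),
               size = rzipf(n_per, cfg$clone_size_alpha, cfg$max_clone_size),
               stringsAsFactors = FALSE)
  }))

  # Public clonotypes: one shared receptor emitted in two samples of each
  # condition (first rows of those samples are overwritten).
  wt <- samples[cond_map[samples] == "WT"]
  au <- samples[cond_map[samples] == "AU"]
  n_pub <- min(cfg$n_public_clonotypes, n_per)
  public_keys <- character(0)
  if (n_pub > 0 && length(wt) >= 1 && length(au) >= 1) {
    for (i in seq_len(n_pub)) {
      a <- paste0("CA", random_aa(1, sample(lens[1]:lens[2], 1) - 3L), "F")
      b <- paste0("CA", random_aa(1, sample(lens[1]:lens[2], 1) - 3L), "F")
      carry <- c(sample(wt, min(2, length(wt))), sample(au, min(2, length(au))))
      for (s in carry) {
        row <- which(clo$sample_id == s)[i]
        clo$cdr3a[row] <- a
        clo$cdr3b[row] <- b
        clo$trbv[row] <- clo$trbv[which(clo$sample_id == carry[1])[i]]
      }
      public_keys <- c(public_keys, paste(a, b, sep = "|"))
    }
  }

  # Planted motifs: carriers drawn round-robin across the eligible
  # samples so every motif spans >= 3 samples; carriers get the motif
  # inserted in the CDR3beta interior and a biased TRBV gene.
  pm <- cfg$planted_motifs
  clo$motif <- NA_character_
  motif_truth <- list()
  if (nrow(pm) > 0) {
    pub_rows <- paste(clo$cdr3a, clo$cdr3b, sep = "|") %in% public_keys
    for (i in seq_len(nrow(pm))) {
      eligible_samples <- switch(pm$condition[i], shared = samples, WT = wt, AU = au)
      n_eligible_clones <- sum(clo$sample_id %in% eligible_samples)
      n_carrier <- round(pm$carrier_fraction[i] * n_eligible_clones)
      if (n_carrier < 4 || length(eligible_samples) < 3)
        stop("planted motif '", pm$motif[i],
             "' cannot satisfy the ground-truth invariant (needs >= 4 carriers over >= 3 samples)")
      free <- which(clo$sample_id %in% eligible_samples & is.na(clo$motif) & !pub_rows)
      # Round-robin over samples for even spread.
      by_sample <- split(free, clo$sample_id[free])
      order_idx <- unlist(lapply(seq_len(max(lengths(by_sample))), function(j) {
        vapply(by_sample, function(v) if (j <= length(v)) v[j] else NA_integer_, integer(1))
      }))
      pick <- order_idx[!is.na(order_idx)][seq_len(n_carrier)]
      motif_v <- cfg$v_gene_pool[i]
      for (r in pick) {
        clo$cdr3b[r] <- insert_motif(clo$cdr3b[r], pm$motif[i])
        if (runif(1) < cfg$v_bias) clo$trbv[r] <- motif_v
      }
      clo$motif[pick] <- pm$motif[i]
      motif_truth[[pm$motif[i]]] <- list(
        condition = pm$condition[i], v_gene = motif_v,
        carrier_keys = unique(paste(clo$cdr3a[pick], clo$cdr3b[pick], sep = "|")),
        carrier_samples = unique(clo$sample_id[pick]))
    }
  }

  clo$key <- paste(clo$cdr3a, clo$cdr3b, sep = "|")
  global_size <- tapply(clo$size, clo$key, sum)

  # Paired cells.
  cells <- clo[rep(seq_len(nrow(clo)), clo$size), c("sample_id", "key")]
  cells$barcode <- paste0(cells$sample_id, "_", sprintf("C%05d", unlist(lapply(
    table(factor(cells$sample_id, levels = samples)), seq_len))))
  rownames(cells) <- NULL
  cells$condition <- unname(cond_map[cells$sample_id])
  cells$clone_size <- as.integer(global_size[cells$key])
  clusters <- c("TFR", "TFH_activated", "TFH_Sostdc1", "TFH_CM", "TFH_effector", "TFH_ISG")
  cells$cluster <- sample(clusters, nrow(cells), replace = TRUE,
                          prob = c(0.2, 0.3, 0.15, 0.15, 0.1, 0.1))

  cell_rows <- clo[rep(seq_len(nrow(clo)), clo$size), ]
  contigs <- rbind(
    data.frame(sample_id = cells$sample_id, barcode = cells$barcode, chain = "TRA",
               cdr3_aa = cell_rows$cdr3a, cdr3_nt = "",
               v_gene = cell_rows$trav, j_gene = cell_rows$traj,
               full_length = TRUE, productive = TRUE,
               umis = 1L + rpois(nrow(cells), 3), stringsAsFactors = FALSE),
    data.frame(sample_id = cells$sample_id, barcode = cells$barcode, chain = "TRB",
               cdr3_aa = cell_rows$cdr3b, cdr3_nt = "",
               v_gene = cell_rows$trbv, j_gene = cell_rows$trbj,
               full_length = TRUE, productive = TRUE,
               umis = 1L + rpois(nrow(cells), 3), stringsAsFactors = FALSE))

  # Decoy cells: unpaired single chains or unproductive pairs, so that
  # the expected decoy share of all cells equals decoy_fraction.
  if (cfg$decoy_fraction > 0) {
    d <- cfg$decoy_fraction
    n_decoy <- stats::rbinom(1, nrow(cells), d / (1 - d))
    if (n_decoy > 0) {
      ds <- sample(samples, n_decoy, replace = TRUE)
      dbc <- paste0(ds, "_", sprintf("D%05d", seq_len(n_decoy)))
      kind <- rep_len(c("tra_only", "trb_only", "unproductive"), n_decoy)
      dlen <- sample(lens[1]:lens[2], n_decoy, replace = TRUE) - 3L
      dec <- data.frame(sample_id = ds, barcode = dbc,
                        chain = ifelse(kind == "trb_only", "TRB", "TRA"),
                        cdr3_aa = paste0("CA", random_aa(n_decoy, dlen), "F"), cdr3_nt = "",
                        v_gene = sample(cfg$va_gene_pool, n_decoy, replace = TRUE),
                        j_gene = sample(cfg$ja_gene_pool, n_decoy, replace = TRUE),
                        full_length = kind != "unproductive",
                        productive = kind != "unproductive",
                        umis = 1L + rpois(n_decoy, 3), stringsAsFactors = FALSE)
      # Unproductive decoys carry both chains, neither productive.
      unp <- which(kind == "unproductive")
      if (length(unp) > 0) {
        second <- dec[unp, ]
        second$chain <- "TRB"
        second$cdr3_aa <- paste0("CA", random_aa(length(unp), dlen[unp]), "F")
        dec <- rbind(dec, second)
      }
      contigs <- rbind(contigs, dec)
    }
  }
  contigs <- contigs[order(contigs$sample_id, contigs$barcode, contigs$chain), ]
  rownames(contigs) <- NULL

  list(contigs = contigs,
       cells = cells[, c("barcode", "sample_id", "condition", "key", "clone_size", "cluster")],
       clonotypes = clo,
       truth = list(motifs = motif_truth, public_keys = public_keys,
                    condition_map = as.list(cond_map)),
       config = cfg)
}

#' Generate synthetic per-cell expression counts tied to clone size
#'
#' Counts follow a negative-binomial model. The first
#' `n_size_correlated_genes` genes have log-mean shifted by
#' `effect_size * sign * centred log clone size` (signs alternate); the
#' next `n_condition_genes` genes are shifted by `condition_shift` (log2)
#' in the AU condition; remaining genes are independent of both.
#'
#' @param cells Paired-cell table as returned by [generate_repertoire()]
#'   (columns `barcode`, `sample_id`, `condition`, `clone_size`, and
#'   optionally `cluster`).
#' @param config A [synth_config()].
#' @return List with `counts` (gene x cell sparse dgCMatrix), `meta`
#'   (per-cell metadata) and `gene_truth` (per-gene planted effects).
#' @export
generate_expression <- function(cells, config) {
  cfg <- validate_synth_config(config)
  if (cfg$n_size_correlated_genes > cfg$n_genes)
    stop("n_size_correlated_genes exceeds n_genes")
  set.seed(cfg$seed + 1L)
  n_genes <- cfg$n_genes
  n_cells <- nrow(cells)
  genes <- sprintf("G%04d", seq_len(n_genes))

  base_log_mu <- rnorm(n_genes, mean = log(2), sd = 0.8)
  n_sc <- cfg$n_size_correlated_genes
  n_cd <- cfg$n_condition_genes
  sign_vec <- integer(n_genes)
  if (n_sc > 0) sign_vec[seq_len(n_sc)] <- rep_len(c(1L, -1L), n_sc)
  cond_flag <- logical(n_genes)
  if (n_cd > 0) cond_flag[n_sc + seq_len(n_cd)] <- TRUE

  z <- log(cells$clone_size)
  z <- z - mean(z)
  is_au <- cells$condition == "AU"

  log_mu <- matrix(base_log_mu, n_genes, n_cells)
  if (n_sc > 0)
    log_mu[seq_len(n_sc), ] <- log_mu[seq_len(n_sc), , drop = FALSE] +
      cfg$effect_size * outer(sign_vec[seq_len(n_sc)], z)
  if (n_cd > 0)
    log_mu[which(cond_flag), is_au] <- log_mu[which(cond_flag), is_au, drop = FALSE] +
      cfg$condition_shift * log(2)

  counts <- matrix(rnbinom(n_genes * n_cells, mu = exp(log_mu), size = 1 / cfg$dispersion),
                   n_genes, n_cells, dimnames = list(genes, cells$barcode))
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"), "CsparseMatrix")

  meta <- data.frame(barcode = cells$barcode, sample_id = cells$sample_id,
                     condition = cells$condition,
                     cluster = if ("cluster" %in% names(cells)) cells$cluster else "all",
                     stringsAsFactors = FALSE)
  gene_truth <- data.frame(gene = genes,
                           size_correlated = sign_vec != 0,
                           sign = sign_vec,
                           effect = ifelse(sign_vec != 0, cfg$effect_size, 0),
                           condition_shifted = cond_flag,
                           stringsAsFactors = FALSE)
  list(counts = counts, meta = meta, gene_truth = gene_truth)
}

#' Planted 9-mer target peptides of a synthetic run
#'
#' Planted motif `i` of the config is annotated (in the reference
#' database) to target peptide `i`; the same peptides are planted in the
#' synthetic proteome, so database annotation and proteome scanning have
#' a common ground truth.
#' @param config A [synth_config()].
#' @return Character vector of 9-mers, length `n_target_peptides`.
#' @export
synth_target_peptides <- function(config) {
  cfg <- validate_synth_config(config)
  set.seed(cfg$seed + 5L)
  random_aa(cfg$n_target_peptides, rep(9L, cfg$n_target_peptides))
}

#' Generate a raw (uncleaned) synthetic CDR3beta-antigen reference table
#'
#' Emits motif-annotated entries (each planted motif inserted into the
#' CDR3beta interior, annotated to its target peptide and antigen, with
#' the motif's biased V gene), clean random background entries, plus
#' deliberate exact-duplicate rows and rows with non-amino-acid
#' characters, so that [compile_reference()] cleaning is exercised.
#'
#' @param config A [synth_config()].
#' @param repertoire Optional output of [generate_repertoire()]; when
#'   given, `db_repertoire_entries` of its clonotype CDR3betas
#'   (expanded clones preferred) are included as annotated entries, so
#'   that exact-match annotation and the downstream PWM stage have
#'   realistic hits (a few percent of unique CDR3betas, as in real
#'   databases).
#' @param db_repertoire_entries Number of repertoire-derived entries.
#' @return Data frame with columns `cdr3b`, `peptide`, `antigen`,
#'   `disease`, `species`, `v_gene`, `j_gene`, `source`.
#' @export
generate_reference_db <- function(config, repertoire = NULL,
                                  db_repertoire_entries = 80) {
  cfg <- validate_synth_config(config)
  set.seed(cfg$seed + 2L)
  pm <- cfg$planted_motifs
  peptides <- synth_target_peptides(cfg)
  classes <- c("autoimmune", "virus", "bacteria", "parasite", "cancer")
  lens <- cfg$cdr3_length_range
  rows <- list()
  if (nrow(pm) > 0) {
    for (i in seq_len(nrow(pm))) {
      n <- cfg$db_entries_per_motif
      cdr3 <- paste0("CA", random_aa(n, sample(lens[1]:lens[2], n, replace = TRUE) - 3L), "F")
      cdr3 <- vapply(cdr3, insert_motif, character(1), motif = pm$motif[i], USE.NAMES = FALSE)
      pep <- peptides[((i - 1) %% length(peptides)) + 1]
      use_bias <- runif(n) < cfg$v_bias
      rows[[length(rows) + 1]] <- data.frame(
        cdr3b = cdr3, peptide = pep, antigen = paste0("AG", i),
        disease = paste0("disease", i),
        disease_class = classes[((i - 1) %% length(classes)) + 1],
        species = "MusMusculus",
        v_gene = ifelse(use_bias, cfg$v_gene_pool[i],
                        sample(cfg$v_gene_pool, n, replace = TRUE)),
        j_gene = sample(cfg$j_gene_pool, n, replace = TRUE),
        source = "synthdb", stringsAsFactors = FALSE)
    }
  }
  if (!is.null(repertoire) && db_repertoire_entries > 0) {
    clo <- repertoire$clonotypes
    uq <- clo[!duplicated(clo$cdr3b), , drop = FALSE]
    gsize <- tapply(clo$size, clo$cdr3b, sum)[uq$cdr3b]
    # Prefer expanded clones (clone size > 3) so condition-expanded,
    # annotated clonotypes exist for PWM training; pad with the rest.
    big <- which(gsize > 3)
    n_take <- min(db_repertoire_entries, nrow(uq))
    pick <- c(big[sample.int(length(big), min(length(big), n_take))],
              sample(setdiff(seq_len(nrow(uq)), big)))[seq_len(n_take)]
    # Motif carriers keep their motif's peptide; the rest draw a target
    # peptide at random.
    carried <- uq$motif[pick]
    pep_idx <- ifelse(is.na(carried), NA_integer_,
                      match(carried, cfg$planted_motifs$motif))
    pep_idx[is.na(pep_idx)] <- sample.int(length(peptides), sum(is.na(pep_idx)),
                                          replace = TRUE)
    rows[[length(rows) + 1]] <- data.frame(
      cdr3b = uq$cdr3b[pick],
      peptide = peptides[((pep_idx - 1L) %% length(peptides)) + 1L],
      antigen = paste0("AG", ((pep_idx - 1L) %% length(peptides)) + 1L),
      disease = paste0("disease", ((pep_idx - 1L) %% length(peptides)) + 1L),
      disease_class = classes[((pep_idx - 1L) %% length(classes)) + 1L],
      species = "MusMusculus",
      v_gene = uq$trbv[pick], j_gene = uq$trbj[pick],
      source = "synthdb", stringsAsFactors = FALSE)
  }
  nb <- cfg$db_background_entries
  if (nb > 0) {
    bg_pep <- random_aa(max(1, nb %/% 10), rep(9L, max(1, nb %/% 10)))
    rows[[length(rows) + 1]] <- data.frame(
      cdr3b = paste0("CA", random_aa(nb, sample(lens[1]:lens[2], nb, replace = TRUE) - 3L), "F"),
      peptide = sample(bg_pep, nb, replace = TRUE),
      antigen = paste0("BGAG", sample.int(max(1, nb %/% 20), nb, replace = TRUE)),
      disease = "background",
      disease_class = sample(classes, nb, replace = TRUE),
      species = "HomoSapiens",
      v_gene = sample(cfg$v_gene_pool, nb, replace = TRUE),
      j_gene = sample(cfg$j_gene_pool, nb, replace = TRUE),
      source = "synthdb", stringsAsFactors = FALSE)
  }
  db <- do.call(rbind, rows)
  if (is.null(db))
    db <- data.frame(cdr3b = character(0), peptide = character(0),
                     antigen = character(0), disease = character(0),
                     disease_class = character(0), species = character(0),
                     v_gene = character(0), j_gene = character(0),
                     source = character(0), stringsAsFactors = FALSE)
  if (nrow(db) > 0 && cfg$db_n_duplicates > 0)
    db <- rbind(db, db[sample.int(nrow(db), min(cfg$db_n_duplicates, nrow(db))), ])
  if (cfg$db_n_invalid > 0) {
    n <- cfg$db_n_invalid
    bad <- data.frame(
      cdr3b = paste0("CASS", random_aa(n, rep(4L, n)),
                     rep_len(c("*", "_"), n), random_aa(n, rep(3L, n)), "F"),
      peptide = random_aa(n, rep(9L, n)), antigen = "BADAG", disease = "noise",
      disease_class = "other", species = "HomoSapiens",
      v_gene = sample(cfg$v_gene_pool, n, replace = TRUE),
      j_gene = sample(cfg$j_gene_pool, n, replace = TRUE),
      source = "synthdb", stringsAsFactors = FALSE)
    db <- rbind(db, bad)
  }
  rownames(db) <- NULL
  db
}

#' Generate a toy proteome FASTA with planted target peptides
#'
#' Random-composition proteins; each target peptide of
#' [synth_target_peptides()] is written into `n_plant_copies` distinct
#' proteins at recorded positions (one placement per protein, so planted
#' windows never overlap).
#'
#' @param config A [synth_config()].
#' @return List with `proteome` (named character vector of protein
#'   sequences) and `placements` (data frame `peptide`, `protein_id`,
#'   `start`).
#' @export
generate_proteome <- function(config) {
  cfg <- validate_synth_config(config)
  set.seed(cfg$seed + 3L)
  n <- cfg$proteome_n_proteins
  len <- cfg$protein_length
  prot <- random_aa(n, rep(len, n))
  names(prot) <- sprintf("P%04d", seq_len(n))
  peptides <- synth_target_peptides(cfg)
  placements <- data.frame(peptide = character(0), protein_id = character(0),
                           start = integer(0), stringsAsFactors = FALSE)
  n_slots <- length(peptides) * cfg$n_plant_copies
  if (n_slots > 0 && len >= 9) {
    if (n_slots > n) stop("not enough proteins to host all planted peptide copies")
    hosts <- sample.int(n, n_slots)
    k <- 0
    for (pep in peptides) for (cp in seq_len(cfg$n_plant_copies)) {
      k <- k + 1
      pid <- names(prot)[hosts[k]]
      start <- sample.int(len - 8L, 1L)
      prot[pid] <- paste0(substr(prot[pid], 1, start - 1L), pep,
                          substr(prot[pid], start + 9L, len))
      placements <- rbind(placements, data.frame(peptide = pep, protein_id = pid,
                                                 start = start, stringsAsFactors = FALSE))
    }
  }
  list(proteome = prot, placements = placements)
}

#' Generate a motif-free background CDR3beta repertoire
#'
#' Used as the reference repertoire for specificity grouping (the analogue
#' of an external naive CD4 reference): random CDR3beta sequences with
#' uniform V-gene usage and the config's length distribution.
#'
#' @param n Number of background sequences.
#' @param config A [synth_config()].
#' @return Data frame with columns `cdr3b`, `v_gene`.
#' @export
synth_background_repertoire <- function(n, config) {
  cfg <- validate_synth_config(config)
  set.seed(cfg$seed + 4L)
  lens <- cfg$cdr3_length_range
  data.frame(cdr3b = paste0("CA", random_aa(n, sample(lens[1]:lens[2], n, replace = TRUE) - 3L), "F"),
             v_gene = sample(cfg$v_gene_pool, n, replace = TRUE),
             stringsAsFactors = FALSE)
}
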