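# End-to-end orchestration: flat key-value config, staged execution
# (QC -> DE -> intersection -> enrichment -> classification -> correlation
# -> protein features -> structure comparison -> concordance), persisted
# TSV/JSON artifacts and a run report. Orchestration is in-process and
# deterministic given (config, seed).

#' Read a flat key-value pipeline configuration
#'
#' One `key: value` pair per line; blank lines and `#` comments are ignored.
#' Values that parse as numbers or `true`/`false` are converted. Relative
#' paths are resolved against the config file's directory.
#'
#' @param path path to the config file.
#' @return a named list of class `fog_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  bad <- !grepl("^[A-Za-z0-9_.]+\\s*:", lines)
  if (any(bad)) stop_config("config: cannot parse line: '", lines[which(bad)[1L]], "'")
  keys <- sub("\\s*:.*$", "", lines)
  vals <- trimws(sub("^[^:]*:", "", lines))
  if (anyDuplicated(keys)) {
    stop_config("config: duplicated key(s): ",
                paste(unique(keys[duplicated(keys)]), collapse = ", "))
  }
  parse_val <- function(v) {
    if (grepl("^-?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", v)) {
      return(as.numeric(v))
    }
    if (tolower(v) %in% c("true", "false")) return(tolower(v) == "true")
    v
  }
  cfg <- stats::setNames(lapply(vals, parse_val), keys)
  base_dir <- dirname(normalizePath(path))
  path_keys <- intersect(names(cfg), c("counts_dir", "samples", "species",
                                       "orthologs", "gene_sets", "fasta",
                                       "pdb_dir", "outdir"))
  for (k in path_keys) {
    if (is.character(cfg[[k]]) && !grepl("^/", cfg[[k]])) {
      cfg[[k]] <- file.path(base_dir, cfg[[k]])
    }
  }
  structure(cfg, class = "fog_config")
}

default_thresholds <- function() {
  list(alpha = 0.05, lfc_min = 1, r_min = 0.85, p_max = 0.01, q_max = 0.05,
       s_hi = 0.7, tm_lo = 0.5, seed = 1)
}

#' Run the full discovery pipeline
#'
#' Stages run in order: replicate QC, per-species differential expression,
#' ortholog-aware DEG intersection, gene-set enrichment (if `gene_sets` is
#' configured), signature/flip-over classification, photosynthetic-type
#' correlation, protein features and structure comparison (if `fasta` /
#' `pdb_dir` are configured), and dual-similarity concordance. Missing
#' optional inputs skip their stages with a notice; missing required inputs
#' abort before any computation. Every stage's output is persisted under
#' `outdir` and summarized in `report.json`.
#'
#' @param config a `fog_config` (or path to one).
#' @return the run report (a list of class `fog_report`), invisibly;
#'   artifacts are written under `config$outdir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- utils::modifyList(default_thresholds(), unclass(config))
  for (k in c("counts_dir", "samples", "species", "orthologs", "outdir")) {
    if (is.null(cfg[[k]])) stop_config("config: required key '", k, "' is missing")
  }
  for (k in intersect(names(cfg), c("counts_dir", "samples", "species",
                                    "orthologs", "gene_sets", "fasta", "pdb_dir"))) {
    if (!file.exists(cfg[[k]])) stop_config("config: path for '", k,
                                            "' does not exist: ", cfg[[k]])
  }
  set.seed(as.integer(cfg$seed))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  notices <- character(0L)

  sheets <- read_sheets(cfg$samples, cfg$species)
  samples <- sheets$samples
  species_sheet <- sheets$species
  count_files <- file.path(cfg$counts_dir,
                           paste0("counts_", species_sheet$species_id, ".tsv"))
  missing <- !file.exists(count_files)
  if (any(missing)) {
    stop_data("count file(s) missing: ",
              paste(basename(count_files[missing]), collapse = ", "))
  }
  counts <- Map(read_counts, count_files, species_sheet$species_id)
  names(counts) <- species_sheet$species_id
  orthologs <- read_ortholog_map(cfg$orthologs, counts = counts)

  # QC + DE per species
  de_results <- list()
  qc_removed <- list()
  deg_counts <- list()
  size_factors <- list()
  for (sp in species_sheet$species_id) {
    sheet_sp <- samples[samples$species_id == sp, , drop = FALSE]
    ana <- de_analysis(counts[[sp]], sheet_sp, alpha = cfg$alpha,
                       lfc_min = cfg$lfc_min, r_min = cfg$r_min)
    de_results[[sp]] <- ana$de
    qc_removed[[sp]] <- ana$qc$removed_samples
    size_factors[[sp]] <- ana$size_factors
    utils::write.table(ana$de, file.path(cfg$outdir, paste0("de_", sp, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    deg_counts[[sp]] <- list(n_deg = sum(ana$de$is_deg), n_genes = nrow(ana$de),
                             proportion = sum(ana$de$is_deg) / nrow(ana$de))
  }

  deg_sets <- lapply(de_results, call_degs, alpha = cfg$alpha, lfc_min = cfg$lfc_min)
  membership <- project_degs(deg_sets, orthologs)
  venn <- venn_partition(membership, species_sheet)

  enrichment <- NULL
  pathway_filter <- NULL
  if (!is.null(cfg$gene_sets)) {
    collection <- read_gene_sets(cfg$gene_sets)
    enrichment <- hypergeometric_enrichment(venn$common_all,
                                            rownames(membership), collection,
                                            p_max = cfg$p_max, q_max = cfg$q_max)
    utils::write.table(enrichment, file.path(cfg$outdir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    pathway_filter <- unique(unlist(collection$sets[enrichment$set[enrichment$enriched]]))
    if (!length(pathway_filter)) {
      notices <- c(notices, "no gene set enriched; pathway filter not applied")
      pathway_filter <- NULL
    }
  } else {
    notices <- c(notices, "gene_sets not configured; enrichment stage skipped")
  }

  patterns <- classify_patterns(de_results, orthologs, species_sheet,
                                pathway_filter = pathway_filter,
                                alpha = cfg$alpha, lfc_min = cfg$lfc_min)
  sig <- patterns$class %in% c("conserved_signature", "flip_over")
  patterns$type_correlation <- NA_real_
  for (g in patterns$group_id[sig]) {
    vals <- lapply(species_sheet$species_id, function(sp) {
      gene <- orthologs$gene_id[orthologs$group_id == g & orthologs$species_id == sp]
      keep <- setdiff(colnames(counts[[sp]]), qc_removed[[sp]])
      sheet_sp <- samples[samples$species_id == sp, , drop = FALSE]
      replicate_log2fc(unclass(counts[[sp]])[, keep, drop = FALSE],
                       sheet_sp, gene, size_factors = size_factors[[sp]])
    })
    names(vals) <- species_sheet$species_id
    patterns$type_correlation[patterns$group_id == g] <-
      type_correlation(vals, species_sheet)
  }
  utils::write.table(patterns, file.path(cfg$outdir, "signatures.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # optional protein / structure stages
  features <- NULL
  seq_sim <- NULL
  struct_sim <- NULL
  concordance <- NULL
  proteins <- NULL
  if (!is.null(cfg$fasta)) {
    proteins <- read_fasta(cfg$fasta)
    features <- data.frame(seq_id = proteins$seq_id,
                           t(vapply(proteins$residues, aa_composition,
                                    numeric(4L))),
                           pI = vapply(proteins$residues, isoelectric_point,
                                       numeric(1L)),
                           row.names = NULL, check.names = FALSE)
    utils::write.table(features, file.path(cfg$outdir, "protein_features.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(proteins) >= 2L) {
      seq_sim <- sequence_similarity_matrix(proteins)
      utils::write.table(seq_sim, file.path(cfg$outdir, "seq_similarity.tsv"),
                         sep = "\t", quote = FALSE)
    }
  } else {
    notices <- c(notices, "fasta not configured; protein stages skipped")
  }
  if (!is.null(cfg$pdb_dir) && !is.null(seq_sim)) {
    pdbs <- list.files(cfg$pdb_dir, pattern = "\\.pdb$", full.names = TRUE)
    structures <- lapply(pdbs, read_pdb_ca)
    names(structures) <- vapply(structures, `[[`, character(1L), "struct_id")
    have <- proteins$seq_id %in% names(structures)
    if (sum(have) >= 2L) {
      struct_sim <- structure_similarity_matrix(structures,
                                                proteins[have, , drop = FALSE])
      utils::write.table(struct_sim, file.path(cfg$outdir, "struct_similarity.tsv"),
                         sep = "\t", quote = FALSE)
      concordance <- dual_similarity_concordance(
        seq_sim[rownames(struct_sim), colnames(struct_sim)], struct_sim,
        s_hi = cfg$s_hi, tm_lo = cfg$tm_lo)
    } else {
      notices <- c(notices, "fewer than 2 structures match sequences; structure stage skipped")
    }
  } else if (is.null(cfg$pdb_dir)) {
    notices <- c(notices, "pdb_dir not configured; structure stages skipped")
  }

  report <- structure(list(
    provenance = list(seed = cfg$seed,
                      version = as.character(utils::packageVersion("fogsig")),
                      config_keys = names(config)),
    deg = deg_counts,
    venn = list(subset_counts = as.list(venn$subset_counts),
                common_all = venn$common_all,
                c4_specific = venn$c4_specific),
    enrichment = if (!is.null(enrichment))
      enrichment[enrichment$enriched, "set", drop = TRUE],
    classes = as.list(table(patterns$class)),
    flip_over = patterns$group_id[patterns$class == "flip_over"],
    conserved_signature = patterns$group_id[patterns$class == "conserved_signature"],
    type_correlation = stats::setNames(
      as.list(patterns$type_correlation[sig]), patterns$group_id[sig]),
    concordance = if (!is.null(concordance)) list(
      spearman_rho = concordance$spearman_rho,
      discordant_pairs = concordance$discordant_pairs),
    notices = notices), class = "fog_report")
  jsonlite::write_json(unclass(report), file.path(cfg$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(report)
}

#' @export
print.fog_report <- function(x, ...) {
  cat("fog_report:\n")
  for (sp in names(x$deg)) {
    cat(sprintf("  %s: %d DEGs (%.2f%%)\n", sp, x$deg[[sp]]$n_deg,
                100 * x$deg[[sp]]$proportion))
  }
  cat("  common to all species:", length(x$venn$common_all), "\n")
  cat("  C4-specific:", length(x$venn$c4_specific), "\n")
  cat("  flip-over:", length(x$flip_over),
      "| conserved signature:", length(x$conserved_signature), "\n")
  invisible(x)
}
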