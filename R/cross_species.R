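# Ortholog-aware cross-species analysis: DEG projection onto ortholog
# groups, Venn partitioning (common / C4-specific sets), hypergeometric
# gene-set enrichment, signature/flip-over classification, and Pearson
# correlation of per-replicate log2FC with photosynthetic type.

#' Project per-species DEG sets onto ortholog groups
#'
#' A group is "DEG in species s" iff its s-gene exists in the map and is in
#' s's DEG set. Groups with no mapped gene in some species are `NA`
#' (unmappable) for that species.
#'
#' @param deg_sets named list (by species) of DEG gene-id vectors.
#' @param ortholog_map data.frame with `group_id`, `species_id`, `gene_id`.
#' @return logical matrix, groups x species, with `NA` for unmappable cells.
#' @export
project_degs <- function(deg_sets, ortholog_map) {
  map <- ortholog_map
  gkey <- paste(map$species_id, map$gene_id, sep = "\r")
  if (anyDuplicated(gkey)) {
    tab <- split(map$group_id, gkey)
    multi <- names(tab)[vapply(tab, function(g) length(unique(g)) > 1L, logical(1L))]
    if (length(multi)) {
      bad <- strsplit(multi[1L], "\r", fixed = TRUE)[[1L]]
      stop_data("gene '", bad[2L], "' (species '", bad[1L],
                "') is mapped to more than one ortholog group")
    }
  }
  groups <- unique(map$group_id)
  species <- names(deg_sets)
  member <- matrix(NA, length(groups), length(species),
                   dimnames = list(groups, species))
  for (sp in species) {
    sub <- map[map$species_id == sp, , drop = FALSE]
    idx <- match(sub$group_id, groups)
    member[idx, sp] <- sub$gene_id %in% deg_sets[[sp]]
  }
  member
}

#' Partition ortholog groups by the exact subset of species calling them DEG
#'
#' Counts, over groups DEG in at least one species, the number whose DEG
#' membership is exactly each species subset, and extracts the named sets
#' `common_all` (DEG in every species) and `c4_specific` (DEG in every C4
#' species and in no C3 species). Unmappable (`NA`) cells count as not-DEG.
#'
#' @param membership logical matrix from [project_degs()].
#' @param species_sheet data.frame with `species_id`, `photosynthesis_type`.
#' @return list of class `fog_venn`: `subset_counts` (named integer vector,
#'   names are `&`-joined species subsets), `common_all`, `c4_specific`
#'   (character vectors of group ids).
#' @export
venn_partition <- function(membership, species_sheet) {
  mem <- membership
  mem[is.na(mem)] <- FALSE
  species <- colnames(mem)
  sheet <- species_sheet[match(species, species_sheet$species_id), , drop = FALSE]
  if (anyNA(sheet$species_id)) stop_data("species sheet is missing species present in the membership")
  any_deg <- rowSums(mem) > 0L
  key <- apply(mem[any_deg, , drop = FALSE], 1L, function(r) {
    paste(species[r], collapse = "&")
  })
  subset_counts <- table(key)
  subset_counts <- stats::setNames(as.integer(subset_counts), names(subset_counts))
  c3 <- species[sheet$photosynthesis_type == "C3"]
  c4 <- species[sheet$photosynthesis_type == "C4"]
  common_all <- rownames(mem)[rowSums(mem) == length(species)]
  c4_specific <- rownames(mem)[
    rowSums(mem[, c4, drop = FALSE]) == length(c4) &
      rowSums(mem[, c3, drop = FALSE]) == 0L]
  structure(list(subset_counts = subset_counts, common_all = common_all,
                 c4_specific = c4_specific), class = "fog_venn")
}

#' Hypergeometric gene-set enrichment
#'
#' For each set, `p = P(X >= k)` for drawing `n = |query|` from a universe of
#' size `N` containing `K = |set (intersected with universe)|` successes; `q`
#' is the BH adjustment over the tested sets. A set is enriched iff
#' `p < p_max` and `q < q_max`.
#'
#' @param query group-id set (must be a subset of `universe`).
#' @param universe background group-id set.
#' @param collection a `fog_gene_sets` (or plain named list of id vectors).
#' @param p_max,q_max enrichment cutoffs.
#' @return data.frame with `set`, `k`, `K`, `n`, `N`, `p_value`, `q_value`,
#'   `enriched`.
#' @export
hypergeometric_enrichment <- function(query, universe, collection,
                                      p_max = 0.01, q_max = 0.05) {
  if (length(universe) == 0L) stop_data("empty universe")
  universe <- unique(universe)
  query <- unique(query)
  if (!all(query %in% universe)) stop_data("query must be a subset of the universe")
  sets <- if (inherits(collection, "fog_gene_sets")) collection$sets else collection
  N <- length(universe)
  n <- length(query)
  res <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    K <- length(s)
    k <- length(intersect(s, query))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- bh_adjust(out$p_value)
  out$enriched <- out$p_value < p_max & out$q_value < q_max
  out
}

#' Classify ortholog groups into signature / flip-over pattern classes
#'
#' Per group, evaluation proceeds in order: `not_common` (unmappable
#' anywhere, or not DEG in every species) -> `dropped_null` (the
#' null-expression flag in any species) -> outside the optional
#' `pathway_filter` -> sign test on per-species log2FC: one uniform sign
#' everywhere gives `conserved_signature`; uniform within each photosynthetic
#' type but opposite between types gives `flip_over`; anything else is
#' `inconsistent`.
#'
#' @param de_results named list (by species) of [de_result()] tables.
#' @param ortholog_map data.frame with `group_id`, `species_id`, `gene_id`.
#' @param species_sheet data.frame with `species_id`, `photosynthesis_type`.
#' @param pathway_filter optional group-id set; groups outside it are set to
#'   `not_common` (they are not part of the common enriched pathways).
#' @param alpha,lfc_min DEG thresholds used on the per-species tables.
#' @return data.frame with `group_id`, `class`, `sign_vector` (e.g. `++---`
#'   over species in sheet order), and per-species `log2fc_*` / `p_adj_*`
#'   columns.
#' @export
classify_patterns <- function(de_results, ortholog_map, species_sheet,
                              pathway_filter = NULL, alpha = 0.05, lfc_min = 1) {
  species <- species_sheet$species_id
  missing <- setdiff(species, names(de_results))
  if (length(missing)) {
    stop_data("no DE results for species: ", paste(missing, collapse = ", "))
  }
  groups <- unique(ortholog_map$group_id)
  n_g <- length(groups)
  n_s <- length(species)
  lfc <- padj <- matrix(NA_real_, n_g, n_s, dimnames = list(groups, species))
  deg <- nullf <- matrix(NA, n_g, n_s, dimnames = list(groups, species))
  for (sp in species) {
    sub <- ortholog_map[ortholog_map$species_id == sp, , drop = FALSE]
    de <- de_results[[sp]]
    hit <- match(sub$gene_id, de$gene_id)
    gi <- match(sub$group_id, groups)
    lfc[gi, sp] <- de$log2fc[hit]
    padj[gi, sp] <- de$p_adj[hit]
    deg[gi, sp] <- de$p_adj[hit] < alpha & abs(de$log2fc[hit]) > lfc_min
    nullf[gi, sp] <- de$null_flag[hit]
  }
  deg[is.na(deg)] <- FALSE
  sgn <- sign(lfc)
  type <- species_sheet$photosynthesis_type[match(species, species_sheet$species_id)]
  is_c3 <- type == "C3"

  cls <- character(n_g)
  all_deg <- rowSums(deg) == n_s
  cls[!all_deg] <- "not_common"
  has_null <- rowSums(nullf, na.rm = TRUE) > 0L
  todo <- all_deg
  cls[todo & has_null] <- "dropped_null"
  todo <- todo & !has_null
  if (!is.null(pathway_filter)) {
    outside <- !(groups %in% pathway_filter)
    cls[todo & outside] <- "not_common"
    todo <- todo & !outside
  }
  uni_all <- abs(rowSums(sgn)) == n_s
  cls[todo & uni_all] <- "conserved_signature"
  uni_c3 <- abs(rowSums(sgn[, is_c3, drop = FALSE])) == sum(is_c3)
  uni_c4 <- abs(rowSums(sgn[, !is_c3, drop = FALSE])) == sum(!is_c3)
  opp <- uni_c3 & uni_c4 &
    (sign(rowSums(sgn[, is_c3, drop = FALSE])) !=
       sign(rowSums(sgn[, !is_c3, drop = FALSE])))
  cls[todo & !uni_all & opp] <- "flip_over"
  cls[todo & !uni_all & !opp] <- "inconsistent"

  sign_vec <- apply(sgn, 1L, function(r) {
    paste(ifelse(is.na(r), ".", ifelse(r > 0, "+", ifelse(r < 0, "-", "0"))),
          collapse = "")
  })
  out <- data.frame(group_id = groups, class = cls, sign_vector = sign_vec,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (sp in species) {
    out[[paste0("log2fc_", sp)]] <- lfc[, sp]
    out[[paste0("p_adj_", sp)]] <- padj[, sp]
  }
  out
}

#' Per-replicate log2 fold changes for one gene
#'
#' `log2((BS_i + 1) / (M_i + 1))` on size-factor-normalized counts,
#' replicates paired by index; the +1 pseudocount keeps zeros finite.
#'
#' @param counts integer matrix for one species.
#' @param sample_sheet sheet rows for these samples.
#' @param gene_id gene to extract.
#' @param size_factors optional precomputed factors.
#' @return numeric vector, one value per paired replicate index.
#' @export
replicate_log2fc <- function(counts, sample_sheet, gene_id, size_factors = NULL) {
  cnt <- unclass(counts)
  if (!gene_id %in% rownames(cnt)) stop_data("gene '", gene_id, "' not in counts")
  sheet <- sample_sheet[match(colnames(cnt), sample_sheet$sample_id), , drop = FALSE]
  sf <- size_factors %||% tryCatch(compute_size_factors(cnt),
    error = function(e) compute_size_factors(cnt, pseudo_reference = TRUE))
  norm <- cnt[gene_id, ] / sf
  bs <- sheet$sample_id[sheet$cell_type == "BS"]
  m <- sheet$sample_id[sheet$cell_type == "M"]
  idx <- intersect(sheet$replicate[sheet$sample_id %in% bs],
                   sheet$replicate[sheet$sample_id %in% m])
  vapply(sort(idx), function(i) {
    b <- norm[sheet$sample_id[sheet$cell_type == "BS" & sheet$replicate == i]]
    mm <- norm[sheet$sample_id[sheet$cell_type == "M" & sheet$replicate == i]]
    log2((b + 1) / (mm + 1))
  }, numeric(1L))
}

#' Pearson correlation of per-replicate log2FC with photosynthetic type
#'
#' Types are coded C3 = 0, C4 = 1; `r` is the standard Pearson correlation
#' over all (replicate value, type code) pairs. When either vector is
#' constant the correlation is undefined and `NA` is returned (distinct
#' from 0).
#'
#' @param values named list (by species) of per-replicate log2FC vectors.
#' @param species_sheet data.frame with `species_id`, `photosynthesis_type`.
#' @return Pearson r, or `NA` if undefined.
#' @export
type_correlation <- function(values, species_sheet) {
  type <- species_sheet$photosynthesis_type[
    match(names(values), species_sheet$species_id)]
  if (anyNA(type)) stop_data("species missing from the species sheet")
  x <- unlist(values, use.names = FALSE)
  code <- rep(as.numeric(type == "C4"), lengths(values))
  if (length(x) < 3L) stop_data("fewer than 3 (value, type) pairs")
  if (stats::sd(x) == 0 || stats::sd(code) == 0) return(NA_real_)
  stats::cor(x, code)
}
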