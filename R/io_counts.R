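# Readers/writers for count matrices, sample/species sheets, ortholog maps
# and GMT gene-set collections. All tabular formats are plain TSV; count
# tables follow the htseq-count dialect (tab-separated, '#' comments ignored,
# first header cell arbitrary).

#' Read a gene x sample count matrix
#'
#' Parses a tab-separated count table (header row of sample ids, first column
#' gene ids, integer cells; lines starting with `#` are ignored) and validates
#' it: no negative or non-integer entries, no duplicated gene or sample ids,
#' at least one gene and two samples.
#'
#' @param path path to the TSV file.
#' @param species_id label attached to the matrix.
#' @return an integer matrix (genes x samples, dimnames set) of class
#'   `fog_counts` with attribute `species_id`.
#' @export
read_counts <- function(path, species_id) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop_format("count file '", path, "': no data rows")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  sample_ids <- header[-1L]
  ncol_expected <- length(header)
  body <- fields[-1L]
  gene_ids <- vapply(body, `[[`, character(1L), 1L)
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s)) {
    stop_format("duplicated sample id(s): ", paste(dup_s, collapse = ", "))
  }
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g)) {
    stop_format("duplicated gene id(s): ", paste(dup_g, collapse = ", "))
  }
  n_fields <- lengths(body)
  if (any(n_fields != ncol_expected)) {
    bad <- which(n_fields != ncol_expected)[1L]
    stop_format("row for gene '", gene_ids[bad], "' has ", n_fields[bad],
                " fields, expected ", ncol_expected)
  }
  mat <- matrix(NA_integer_, length(gene_ids), length(sample_ids),
                dimnames = list(gene_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    cells <- vapply(body, `[[`, character(1L), j + 1L)
    ok <- grepl("^[0-9]+$", cells)
    if (!all(ok)) {
      bad <- which(!ok)[1L]
      stop_format("cell for gene '", gene_ids[bad], "', sample '",
                  sample_ids[j], "' is '", cells[bad],
                  "': counts must be nonnegative integers")
    }
    mat[, j] <- as.integer(cells)
  }
  new_counts(mat, species_id)
}

new_counts <- function(mat, species_id) {
  if (nrow(mat) < 1L || ncol(mat) < 2L) {
    stop_format("count matrix needs >= 1 gene and >= 2 samples")
  }
  storage.mode(mat) <- "integer"
  structure(mat, species_id = species_id, class = c("fog_counts", "matrix", "array"))
}

#' Write a count matrix in the canonical TSV dialect
#'
#' @param x a `fog_counts` matrix (or any integer matrix with dimnames).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path) {
  header <- paste(c("gene_id", colnames(x)), collapse = "\t")
  rows <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], format(x[i, ], scientific = FALSE, trim = TRUE)),
          collapse = "\t")
  }, character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @export
print.fog_counts <- function(x, ...) {
  cat(sprintf("fog_counts: %d genes x %d samples (species '%s')\n",
              nrow(x), ncol(x), attr(x, "species_id")))
  invisible(x)
}

read_tsv_cols <- function(path, required) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", comment.char = "#",
                          check.names = FALSE)
  missing <- setdiff(required, colnames(df))
  if (length(missing)) {
    stop_format("'", path, "': missing column(s): ", paste(missing, collapse = ", "))
  }
  df
}

#' Read the sample sheet
#'
#' TSV with columns `sample_id`, `species_id`, `cell_type` (BS or M) and
#' `replicate` (positive integer). Every species present must contribute at
#' least one bundle-sheath and one mesophyll sample.
#'
#' @param path path to the sample sheet TSV.
#' @return a data.frame with validated columns.
#' @export
read_sample_sheet <- function(path) {
  df <- read_tsv_cols(path, c("sample_id", "species_id", "cell_type", "replicate"))
  if (anyDuplicated(df$sample_id)) {
    stop_format("sample sheet: duplicated sample id(s): ",
                paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  if (!all(df$cell_type %in% c("BS", "M"))) {
    stop_format("sample sheet: cell_type must be 'BS' or 'M'")
  }
  rep_idx <- suppressWarnings(as.integer(df$replicate))
  if (anyNA(rep_idx) || any(rep_idx < 1L)) {
    stop_format("sample sheet: replicate must be a positive integer")
  }
  df$replicate <- rep_idx
  for (sp in unique(df$species_id)) {
    ct <- df$cell_type[df$species_id == sp]
    if (!all(c("BS", "M") %in% ct)) {
      stop_format("sample sheet: species '", sp, "' lacks a BS or M sample")
    }
  }
  df
}

#' Read the species sheet
#'
#' TSV with columns `species_id` and `photosynthesis_type` (C3 or C4).
#'
#' @param path path to the species sheet TSV.
#' @param require_both require at least one C3 and one C4 species, as the
#'   cross-type analyses do.
#' @return a data.frame with validated columns.
#' @export
read_species_sheet <- function(path, require_both = TRUE) {
  df <- read_tsv_cols(path, c("species_id", "photosynthesis_type"))
  if (anyDuplicated(df$species_id)) {
    stop_format("species sheet: duplicated species id(s)")
  }
  if (!all(df$photosynthesis_type %in% c("C3", "C4"))) {
    stop_format("species sheet: photosynthesis_type must be 'C3' or 'C4'")
  }
  if (require_both && !all(c("C3", "C4") %in% df$photosynthesis_type)) {
    stop_format("species sheet: both C3 and C4 species are required")
  }
  df
}

#' Read sample and species sheets together
#'
#' @param sample_path,species_path paths to the two sheets.
#' @param require_both passed to [read_species_sheet()].
#' @return a list with elements `samples` and `species`.
#' @export
read_sheets <- function(sample_path, species_path, require_both = TRUE) {
  list(samples = read_sample_sheet(sample_path),
       species = read_species_sheet(species_path, require_both = require_both))
}

#' Read an ortholog-group map
#'
#' TSV with columns `group_id`, `species_id`, `gene_id`; at most one gene per
#' (group, species) pair.
#'
#' @param path path to the map TSV.
#' @param counts optional named list of count matrices used to check that the
#'   mapped genes exist in their species' matrix.
#' @return a data.frame with the three columns.
#' @export
read_ortholog_map <- function(path, counts = NULL) {
  df <- read_tsv_cols(path, c("group_id", "species_id", "gene_id"))
  key <- paste(df$group_id, df$species_id, sep = "\r")
  if (anyDuplicated(key)) {
    bad <- df[duplicated(key), , drop = FALSE][1L, ]
    stop_format("ortholog map: duplicated (group, species) pair: (",
                bad$group_id, ", ", bad$species_id, ")")
  }
  if (!is.null(counts)) {
    for (sp in intersect(unique(df$species_id), names(counts))) {
      genes <- df$gene_id[df$species_id == sp]
      missing <- setdiff(genes, rownames(counts[[sp]]))
      if (length(missing)) {
        stop_format("ortholog map: gene(s) absent from counts of '", sp,
                    "': ", paste(utils::head(missing, 5L), collapse = ", "))
      }
    }
  }
  df
}

#' Read a GMT gene-set collection
#'
#' Each line is `name<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path path to the GMT file.
#' @return a list of class `fog_gene_sets` with elements `sets` (named list of
#'   character vectors) and `descriptions` (named character vector).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(lines)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  line_no <- which(keep)
  short <- lengths(fields) < 3L
  if (any(short)) {
    stop_format("GMT '", path, "': line ", line_no[which(short)[1L]],
                " has fewer than 3 fields")
  }
  nms <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(nms)) {
    stop_format("GMT '", path, "': duplicated set name(s): ",
                paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  sets <- lapply(fields, function(f) unique(f[-c(1L, 2L)][nzchar(f[-c(1L, 2L)])]))
  names(sets) <- nms
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    stop_format("GMT '", path, "': empty set(s): ",
                paste(nms[empty], collapse = ", "))
  }
  desc <- vapply(fields, `[[`, character(1L), 2L)
  names(desc) <- nms
  structure(list(sets = sets, descriptions = desc), class = "fog_gene_sets")
}
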