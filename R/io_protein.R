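# FASTA and PDB (CA trace) input/output, plus NCBI-format substitution
# matrices. FASTA parsing is delegated to Biostrings; the CA extractor is a
# fixed-column PDB reader (no mmCIF, first model only).

AMINO_ACIDS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Read protein sequences from FASTA
#'
#' Headers are parsed as `seq_id|species_id`; when no `|` is present the
#' species is taken from `species_map` (named by seq_id) or left `NA`.
#' Residues outside the 20 standard one-letter codes are rejected unless
#' `drop_nonstandard = TRUE`, in which case they are removed with a warning
#' (the composition and pI formulas are defined on the 20 codes only).
#'
#' @param path path to the FASTA file.
#' @param species_map optional named character vector mapping seq_id to
#'   species_id for headers without a `|`.
#' @param drop_nonstandard drop non-standard residues instead of erroring.
#' @return a data.frame of class `fog_proteins` with columns `seq_id`,
#'   `species_id`, `residues`.
#' @export
read_fasta <- function(path, species_map = NULL, drop_nonstandard = FALSE) {
  raw <- readLines(path)
  first <- which(nzchar(trimws(raw)))[1L]
  if (is.na(first) || !startsWith(raw[first], ">")) {
    stop_format("FASTA '", path, "': line ", if (is.na(first)) 1L else first,
                ": expected a '>' header")
  }
  seqs <- Biostrings::readAAStringSet(path)
  headers <- names(seqs)
  res <- toupper(as.character(seqs))
  has_pipe <- grepl("|", headers, fixed = TRUE)
  seq_id <- ifelse(has_pipe, sub("\\|.*$", "", headers), sub("\\s.*$", "", headers))
  species_id <- rep(NA_character_, length(headers))
  species_id[has_pipe] <- sub("^[^|]*\\|", "", sub("\\s.*$", "", headers[has_pipe]))
  if (!is.null(species_map)) {
    hit <- !has_pipe & seq_id %in% names(species_map)
    species_id[hit] <- unname(species_map[seq_id[hit]])
  }
  if (anyDuplicated(seq_id)) {
    stop_format("FASTA '", path, "': duplicated seq id(s): ",
                paste(unique(seq_id[duplicated(seq_id)]), collapse = ", "))
  }
  for (i in seq_along(res)) {
    chars <- strsplit(res[i], "", fixed = TRUE)[[1L]]
    bad <- !(chars %in% AMINO_ACIDS)
    if (any(bad)) {
      if (drop_nonstandard) {
        warning("sequence '", seq_id[i], "': dropping ", sum(bad),
                " non-standard residue(s): ",
                paste(unique(chars[bad]), collapse = ""), call. = FALSE)
        res[i] <- paste(chars[!bad], collapse = "")
      } else {
        stop_format("sequence '", seq_id[i], "' contains non-standard residue(s): ",
                    paste(unique(chars[bad]), collapse = ""))
      }
    }
    if (!nzchar(res[i])) stop_format("sequence '", seq_id[i], "' is empty")
  }
  structure(data.frame(seq_id = seq_id, species_id = species_id,
                       residues = res, stringsAsFactors = FALSE),
            class = c("fog_proteins", "data.frame"))
}

#' Write protein sequences to FASTA
#'
#' @param proteins a `fog_proteins` data.frame.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  out <- character(0L)
  for (i in seq_len(nrow(proteins))) {
    hdr <- if (is.na(proteins$species_id[i])) proteins$seq_id[i] else
      paste0(proteins$seq_id[i], "|", proteins$species_id[i])
    s <- proteins$residues[i]
    starts <- seq(1L, nchar(s), by = width)
    out <- c(out, paste0(">", hdr), substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a CA trace from a PDB file
#'
#' Extracts one CA coordinate per residue from ATOM records. Alternate
#' locations other than blank/'A' are skipped; records carrying insertion
#' codes are skipped with a warning; only the first chain is read unless
#' `chain` is given. Residue numbering must be strictly increasing.
#'
#' @param path path to the PDB file.
#' @param chain single chain identifier, or `NULL` for the first chain seen.
#' @param struct_id label for the structure (defaults to the file stem).
#' @return a list of class `fog_structure` with `struct_id`, `coords`
#'   (n x 3 matrix, Angstrom) and `residue_numbers`.
#' @export
read_pdb_ca <- function(path, chain = NULL, struct_id = NULL) {
  lines <- readLines(path)
  atoms <- lines[startsWith(lines, "ATOM")]
  name <- trimws(substr(atoms, 13L, 16L))
  altloc <- substr(atoms, 17L, 17L)
  icode <- substr(atoms, 27L, 27L)
  ch <- substr(atoms, 22L, 22L)
  keep <- name == "CA" & altloc %in% c(" ", "A", "")
  n_icode <- sum(keep & icode != " ")
  if (n_icode > 0L) {
    warning("skipping ", n_icode, " CA record(s) with insertion codes", call. = FALSE)
    keep <- keep & icode == " "
  }
  if (!any(keep)) stop_format("'", path, "': no CA atoms found")
  if (is.null(chain)) chain <- ch[keep][1L]
  keep <- keep & ch == chain
  if (!any(keep)) stop_format("'", path, "': no CA atoms in chain '", chain, "'")
  sel <- atoms[keep]
  resno <- as.integer(substr(sel, 23L, 26L))
  coords <- cbind(as.numeric(substr(sel, 31L, 38L)),
                  as.numeric(substr(sel, 39L, 46L)),
                  as.numeric(substr(sel, 47L, 54L)))
  if (anyNA(coords) || any(!is.finite(coords))) {
    stop_format("'", path, "': non-numeric CA coordinates")
  }
  if (anyNA(resno) || any(diff(resno) <= 0L)) {
    stop_format("'", path, "': residue numbering not strictly increasing in chain '",
                chain, "'")
  }
  new_structure(coords, resno,
                struct_id %||% sub("\\.[^.]*$", "", basename(path)))
}

new_structure <- function(coords, residue_numbers = seq_len(nrow(coords)),
                          struct_id = "structure") {
  if (nrow(coords) < 3L) stop_format("structure '", struct_id, "': fewer than 3 residues")
  if (any(!is.finite(coords))) stop_format("structure '", struct_id, "': non-finite coordinates")
  colnames(coords) <- c("x", "y", "z")
  structure(list(struct_id = struct_id, coords = coords,
                 residue_numbers = as.integer(residue_numbers)),
            class = "fog_structure")
}

#' @export
print.fog_structure <- function(x, ...) {
  cat(sprintf("fog_structure '%s': %d CA atoms\n", x$struct_id, nrow(x$coords)))
  invisible(x)
}

#' Write a CA trace as a minimal PDB file
#'
#' @param struct a `fog_structure`.
#' @param path output path.
#' @param chain chain identifier to write.
#' @return `path`, invisibly.
#' @export
write_pdb_ca <- function(struct, path, chain = "A") {
  n <- nrow(struct$coords)
  lines <- sprintf(
    "ATOM  %5d  CA  GLY %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(n), chain, struct$residue_numbers,
    struct$coords[, 1L], struct$coords[, 2L], struct$coords[, 3L])
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a substitution matrix in NCBI text format
#'
#' Lines starting with `#` are comments; the first data row lists the column
#' residues, subsequent rows are `residue score score ...`.
#'
#' @param path path to the matrix file.
#' @return a symmetric integer matrix with residue dimnames.
#' @export
read_substitution_matrix <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines[!startsWith(lines, "#")])
  lines <- lines[nzchar(lines)]
  cols <- strsplit(lines[1L], "\\s+")[[1L]]
  rows <- strsplit(lines[-1L], "\\s+")
  rn <- vapply(rows, `[[`, character(1L), 1L)
  m <- t(vapply(rows, function(f) as.numeric(f[-1L]), numeric(length(cols))))
  dimnames(m) <- list(rn, cols)
  m
}

#' The BLOSUM62 substitution matrix bundled with the package
#'
#' @return the BLOSUM62 scoring matrix (NCBI distribution values).
#' @export
blosum62 <- function() {
  read_substitution_matrix(system.file("extdata", "BLOSUM62.txt",
                                       package = "fogsig", mustWork = TRUE))
}
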