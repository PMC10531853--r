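# Synthetic-data generators: negative-binomial two-cell-type count matrices
# for a C3/C4 species panel with planted flip-over / conserved-signature /
# species-specific genes, homolog sequence families with controlled
# divergence, and noisy (optionally rigidly moved) CA-trace helices.
# Every generator is a pure function of (parameters, seed).

#' Simulation design for the cross-species count experiment
#'
#' Defaults state the emulated world: 2 C3 + 3 C4 species, 3 replicates per
#' cell type, 2,000 ortholog groups, 10 planted flip-over and 20 conserved
#' signature genes at |log2FC| = 2, NB dispersion 0.05, lognormal library
#' sizes (mean 1, CV 0.3) and per-gene baseline means spanning 10-1000
#' counts (log10 range 1-3), i.e. moderately-to-highly expressed genes as
#' left after a null-expression filter.
#'
#' @param n_species_c3,n_species_c4 number of C3 / C4 species.
#' @param n_replicates replicates per cell type per species.
#' @param n_groups number of ortholog groups (one gene per species each).
#' @param n_fog,n_conserved,n_species_specific planted gene counts.
#' @param lfc_planted planted |log2 fold change| (BS vs M), split as
#'   +/- lfc/2 across the two cell types so mean abundance is unchanged.
#' @param dispersion NB dispersion alpha >= 0 (variance mu + alpha mu^2).
#' @param lib_size_mean,lib_size_cv lognormal library-size factor model.
#' @param base_mean_log_range log10 range of per-gene baseline means.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return a validated list of class `fog_sim_design`.
#' @export
sim_design <- function(n_species_c3 = 2L, n_species_c4 = 3L, n_replicates = 3L,
                       n_groups = 2000L, n_fog = 10L, n_conserved = 20L,
                       n_species_specific = 20L, lfc_planted = 2,
                       dispersion = 0.05, lib_size_mean = 1, lib_size_cv = 0.3,
                       base_mean_log_range = c(1, 3), seed = 1L) {
  d <- list(n_species_c3 = as.integer(n_species_c3),
            n_species_c4 = as.integer(n_species_c4),
            n_replicates = as.integer(n_replicates),
            n_groups = as.integer(n_groups), n_fog = as.integer(n_fog),
            n_conserved = as.integer(n_conserved),
            n_species_specific = as.integer(n_species_specific),
            lfc_planted = lfc_planted, dispersion = dispersion,
            lib_size_mean = lib_size_mean, lib_size_cv = lib_size_cv,
            base_mean_log_range = base_mean_log_range, seed = as.integer(seed))
  if (d$n_fog + d$n_conserved + d$n_species_specific > d$n_groups) {
    stop_config("planted gene counts exceed n_groups")
  }
  assert_scalar_number(d$dispersion, "dispersion", lower = 0)
  assert_scalar_number(d$lib_size_mean, "lib_size_mean", lower = 1e-12)
  if (d$n_species_c3 + d$n_species_c4 < 1L || d$n_replicates < 2L) {
    stop_config("need >= 1 species and >= 2 replicates per cell type")
  }
  if (d$n_fog > 0L && (d$n_species_c3 < 1L || d$n_species_c4 < 1L)) {
    stop_config("flip-over genes require both C3 and C4 species")
  }
  structure(d, class = "fog_sim_design")
}

rnbinom_mu <- function(n, mu, dispersion) {
  if (dispersion <= 0) stats::rpois(n, mu) else
    stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate the full cross-species two-cell-type experiment
#'
#' Counts are drawn NB(mean = s_j * mu_g * 2^(+/- lfc_gs / 2), dispersion
#' alpha), the sign being + in bundle sheath and - in mesophyll for genes up
#' in BS. Flip-over genes take one sign in C3 species and the opposite sign
#' in all C4 species (direction randomized per gene); conserved signature
#' genes take one sign everywhere; species-specific genes are perturbed in
#' exactly one species; the rest are null.
#'
#' @param design a [sim_design()].
#' @return a list of class `fog_simulation` with per-species `counts`
#'   (named list of `fog_counts`), `samples`, `species`, `orthologs`
#'   (data.frames) and `truth` (per-group class plus per-(group, species)
#'   true log2FC matrix).
#' @export
simulate_experiment <- function(design) {
  stopifnot(inherits(design, "fog_sim_design"))
  set.seed(design$seed)
  d <- design
  species <- c(if (d$n_species_c3 > 0L) paste0("c3_", seq_len(d$n_species_c3)),
               if (d$n_species_c4 > 0L) paste0("c4_", seq_len(d$n_species_c4)))
  type <- c(rep("C3", d$n_species_c3), rep("C4", d$n_species_c4))
  n_sp <- length(species)
  groups <- sprintf("OG%05d", seq_len(d$n_groups))

  classes <- rep("null", d$n_groups)
  planted <- sample.int(d$n_groups, d$n_fog + d$n_conserved + d$n_species_specific)
  idx_fog <- planted[seq_len(d$n_fog)]
  idx_con <- planted[d$n_fog + seq_len(d$n_conserved)]
  idx_sps <- planted[d$n_fog + d$n_conserved + seq_len(d$n_species_specific)]
  classes[idx_fog] <- "flip_over"
  classes[idx_con] <- "conserved_signature"
  classes[idx_sps] <- "species_specific"

  true_lfc <- matrix(0, d$n_groups, n_sp, dimnames = list(groups, species))
  if (d$n_fog > 0L) {
    c3_sign <- sample(c(-1, 1), d$n_fog, replace = TRUE)
    true_lfc[idx_fog, type == "C3"] <- c3_sign * d$lfc_planted
    true_lfc[idx_fog, type == "C4"] <- -c3_sign * d$lfc_planted
  }
  if (d$n_conserved > 0L) {
    true_lfc[idx_con, ] <- sample(c(-1, 1), d$n_conserved, replace = TRUE) * d$lfc_planted
  }
  if (d$n_species_specific > 0L) {
    sp_pick <- sample.int(n_sp, d$n_species_specific, replace = TRUE)
    sgn <- sample(c(-1, 1), d$n_species_specific, replace = TRUE)
    for (i in seq_len(d$n_species_specific)) {
      true_lfc[idx_sps[i], sp_pick[i]] <- sgn[i] * d$lfc_planted
    }
  }

  mu_g <- 10^stats::runif(d$n_groups, d$base_mean_log_range[1L],
                          d$base_mean_log_range[2L])
  lib_sdlog <- sqrt(log(1 + d$lib_size_cv^2))
  lib_meanlog <- log(d$lib_size_mean) - lib_sdlog^2 / 2

  counts <- list()
  samples <- NULL
  orthologs <- NULL
  n_samp <- 2L * d$n_replicates
  for (s in seq_len(n_sp)) {
    sp <- species[s]
    gene_ids <- paste0(sp, "_g", sprintf("%05d", seq_len(d$n_groups)))
    sample_ids <- c(paste0(sp, "_BS_r", seq_len(d$n_replicates)),
                    paste0(sp, "_M_r", seq_len(d$n_replicates)))
    cell_sign <- rep(c(1, -1), each = d$n_replicates)
    lib <- stats::rlnorm(n_samp, lib_meanlog, lib_sdlog)
    mu <- outer(mu_g, lib) * 2^(outer(true_lfc[, s], cell_sign) / 2)
    cnt <- matrix(rnbinom_mu(length(mu), mu, d$dispersion),
                  d$n_groups, n_samp,
                  dimnames = list(gene_ids, sample_ids))
    counts[[sp]] <- new_counts(cnt, sp)
    samples <- rbind(samples, data.frame(
      sample_id = sample_ids, species_id = sp,
      cell_type = rep(c("BS", "M"), each = d$n_replicates),
      replicate = rep(seq_len(d$n_replicates), 2L), stringsAsFactors = FALSE))
    orthologs <- rbind(orthologs, data.frame(
      group_id = groups, species_id = sp, gene_id = gene_ids,
      stringsAsFactors = FALSE))
  }

  structure(list(
    counts = counts,
    samples = samples,
    species = data.frame(species_id = species, photosynthesis_type = type,
                         stringsAsFactors = FALSE),
    orthologs = orthologs,
    truth = list(classes = data.frame(group_id = groups, class = classes,
                                      stringsAsFactors = FALSE),
                 log2fc = true_lfc),
    design = design), class = "fog_simulation")
}

#' Simulate a homolog protein family by per-site substitution
#'
#' An ancestor of the given length is drawn uniformly over the 20 standard
#' residues; each species copy substitutes each site independently with its
#' rate, uniformly over the other 19 residues.
#'
#' @param ancestor_length number of residues.
#' @param per_species_substitution_rate named numeric vector of rates in
#'   `[0, 1)`, one per species.
#' @param seed integer seed.
#' @return a list with `ancestor` (string) and `family` (a `fog_proteins`
#'   data.frame, one row per species).
#' @export
simulate_protein_family <- function(ancestor_length,
                                    per_species_substitution_rate,
                                    seed = 1L) {
  rates <- per_species_substitution_rate
  if (any(rates < 0 | rates >= 1)) stop_config("substitution rates must be in [0, 1)")
  if (is.null(names(rates))) names(rates) <- paste0("sp", seq_along(rates))
  set.seed(seed)
  anc <- sample(AMINO_ACIDS, ancestor_length, replace = TRUE)
  fam <- vapply(names(rates), function(sp) {
    chars <- anc
    hit <- stats::runif(ancestor_length) < rates[[sp]]
    for (i in which(hit)) {
      chars[i] <- sample(setdiff(AMINO_ACIDS, chars[i]), 1L)
    }
    paste(chars, collapse = "")
  }, character(1L))
  list(ancestor = paste(anc, collapse = ""),
       family = structure(data.frame(seq_id = names(rates),
                                     species_id = names(rates),
                                     residues = unname(fam),
                                     stringsAsFactors = FALSE),
                          class = c("fog_proteins", "data.frame")))
}

#' Simulate a noisy CA-trace helix
#'
#' An ideal alpha-helical CA trace (radius 2.3 A, rise 1.5 A/residue, turn
#' 100 deg/residue) with i.i.d. Gaussian coordinate noise, optionally
#' followed by a rigid motion.
#'
#' @param length number of residues (>= 3).
#' @param noise_sigma per-coordinate Gaussian noise sd, Angstrom (>= 0).
#' @param rigid_transform optional list with `rotation` (3 x 3) and
#'   `translation` (length 3), applied after the noise.
#' @param seed integer seed.
#' @param struct_id structure label.
#' @return a `fog_structure`.
#' @export
simulate_helix_structure <- function(length, noise_sigma = 0,
                                     rigid_transform = NULL, seed = 1L,
                                     struct_id = "helix") {
  if (length < 3L) stop_config("helix length must be >= 3")
  assert_scalar_number(noise_sigma, "noise_sigma", lower = 0)
  set.seed(seed)
  i <- seq_len(length) - 1L
  theta <- i * 100 * pi / 180
  coords <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
  if (noise_sigma > 0) {
    coords <- coords + matrix(stats::rnorm(3L * length, sd = noise_sigma), length, 3L)
  }
  if (!is.null(rigid_transform)) coords <- apply_transform(coords, rigid_transform)
  new_structure(coords, struct_id = struct_id)
}

#' Write a simulated experiment to disk as plain-text inputs
#'
#' Writes `counts_<species>.tsv` per species plus `samples.tsv`,
#' `species.tsv`, `orthologs.tsv` and `truth.tsv` into `outdir`.
#'
#' @param sim a `fog_simulation`.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (sp in names(sim$counts)) {
    write_counts(sim$counts[[sp]], file.path(outdir, paste0("counts_", sp, ".tsv")))
  }
  utils::write.table(sim$samples, file.path(outdir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$species, file.path(outdir, "species.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$orthologs, file.path(outdir, "orthologs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- cbind(sim$truth$classes,
                 as.data.frame(sim$truth$log2fc, check.names = FALSE))
  utils::write.table(truth, file.path(outdir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}
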