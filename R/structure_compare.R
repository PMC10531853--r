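# Rigid-body superposition (Kabsch, SVD with determinant correction),
# TM-score with the iterative seed-fragment / distance-cutoff search,
# structure-similarity matrices over sequence-derived correspondences, and
# dual sequence/structure concordance with discordance flagging.

# Optimal rigid fit of P onto Q (rows are points); no degeneracy checks.
kabsch_fit <- function(P, Q) {
  cp <- colMeans(P)
  cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp)
  Qc <- sweep(Q, 2L, cq)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- cq - as.numeric(R %*% cp)
  fitted <- Pc %*% t(R)
  rmsd <- sqrt(sum((fitted - Qc)^2) / nrow(P))
  list(rotation = R, translation = t_vec, rmsd = rmsd)
}

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Least-squares rigid fit of `P` onto `Q` via SVD of the covariance of the
#' centered coordinates, with determinant correction so the rotation is
#' proper. The returned motion maps a point `x` to `rotation %*% x +
#' translation`.
#'
#' @param P,Q n x 3 coordinate matrices (or `fog_structure`s).
#' @param correspondence optional 2-column index matrix (P-index, Q-index);
#'   defaults to the identity correspondence (equal sizes required).
#' @return list of class `fog_superposition`: `rotation` (3 x 3, det +1),
#'   `translation` (length 3), `rmsd` (Angstrom).
#' @export
kabsch_superpose <- function(P, Q, correspondence = NULL) {
  P <- if (inherits(P, "fog_structure")) P$coords else as.matrix(P)
  Q <- if (inherits(Q, "fog_structure")) Q$coords else as.matrix(Q)
  if (is.null(correspondence)) {
    if (nrow(P) != nrow(Q)) stop_data("P and Q differ in size; give a correspondence")
    correspondence <- cbind(seq_len(nrow(P)), seq_len(nrow(P)))
  }
  P <- P[correspondence[, 1L], , drop = FALSE]
  Q <- Q[correspondence[, 2L], , drop = FALSE]
  if (nrow(P) < 3L) stop_data("need >= 3 corresponding pairs")
  for (X in list(P, Q)) {
    s <- svd(sweep(X, 2L, colMeans(X)), nu = 0L, nv = 0L)$d
    if (s[2L] <= 1e-9 * max(s[1L], 1e-12)) {
      stop_data("degenerate (collinear) point configuration")
    }
  }
  structure(kabsch_fit(P, Q), class = "fog_superposition")
}

#' TM-score normalization length scale
#'
#' `d0(L) = 1.24 (L - 15)^(1/3) - 1.8` Angstrom, floored at 0.5 (the
#' unfloored formula is negative for short chains).
#'
#' @param l_norm normalization length.
#' @return d0 in Angstrom.
#' @export
tm_d0 <- function(l_norm) {
  x <- l_norm - 15
  max(1.24 * sign(x) * abs(x)^(1 / 3) - 1.8, 0.5)
}

tm_from_d <- function(d, d0, l_norm) sum(1 / (1 + (d / d0)^2)) / l_norm

pair_dists <- function(P, Q) sqrt(rowSums((P - Q)^2))

# One seeded superposition refined by the distance-cutoff iteration.
tm_refine <- function(P, Q, seed_idx, d0, l_norm, max_iter = 20L) {
  sel <- seed_idx
  best <- 0
  for (it in seq_len(max_iter)) {
    if (length(sel) < 3L) break
    fit <- kabsch_fit(P[sel, , drop = FALSE], Q[sel, , drop = FALSE])
    d <- pair_dists(sweep(P %*% t(fit$rotation), 2L, -fit$translation), Q)
    best <- max(best, tm_from_d(d, d0, l_norm))
    d_cut <- d0
    repeat {
      new_sel <- which(d < d_cut)
      if (length(new_sel) >= 3L) break
      d_cut <- d_cut + 0.5
    }
    if (length(new_sel) == length(sel) && all(new_sel == sel)) break
    sel <- new_sel
  }
  best
}

#' TM-score between two CA-trace structures
#'
#' `TM = max over superpositions of (1/L_norm) sum_i 1 / (1 + (d_i/d0)^2)`
#' over the corresponding residue pairs, with `d0` from [tm_d0()]. The
#' maximization seeds Kabsch superpositions on contiguous fragments of the
#' correspondence (lengths L, L/2, L/4, never below 4) and refines each by
#' the distance-cutoff iteration (keep pairs closer than the cutoff,
#' re-superpose, at most `max_iter` rounds). The search always includes the
#' whole-length superposition, so its result is never below the plain
#' Kabsch TM. The score is invariant to rigid motion of either input.
#'
#' @param query,ref `fog_structure`s (or n x 3 coordinate matrices).
#' @param correspondence 2-column index matrix (query-index, ref-index);
#'   defaults to the identity correspondence.
#' @param l_norm `"reference"` (length of `ref`), `"shorter"`, or
#'   `"mean_of_both_directions"` (average of the two normalizations).
#' @param search run the seed-fragment search; `FALSE` scores the single
#'   whole-length superposition.
#' @param superpose with `FALSE`, score the coordinates exactly as given
#'   (no superposition at all; used to test the scoring formula).
#' @param max_iter distance-cutoff refinement cap per seed.
#' @return the TM-score, in (0, 1].
#' @export
tm_score <- function(query, ref, correspondence = NULL,
                     l_norm = c("reference", "shorter", "mean_of_both_directions"),
                     search = TRUE, superpose = TRUE, max_iter = 20L) {
  l_norm <- match.arg(l_norm)
  qc <- if (inherits(query, "fog_structure")) query$coords else as.matrix(query)
  rc <- if (inherits(ref, "fog_structure")) ref$coords else as.matrix(ref)
  if (l_norm == "mean_of_both_directions") {
    a <- tm_score(qc, rc, correspondence, "reference", search, superpose, max_iter)
    corr_rev <- if (is.null(correspondence)) NULL else correspondence[, 2:1]
    b <- tm_score(rc, qc, corr_rev, "reference", search, superpose, max_iter)
    return((a + b) / 2)
  }
  if (is.null(correspondence)) {
    if (nrow(qc) != nrow(rc)) stop_data("sizes differ; give a correspondence")
    correspondence <- cbind(seq_len(nrow(qc)), seq_len(nrow(qc)))
  }
  if (nrow(correspondence) == 0L) stop_data("empty correspondence")
  L_norm <- if (l_norm == "reference") nrow(rc) else min(nrow(qc), nrow(rc))
  d0 <- tm_d0(L_norm)
  P <- qc[correspondence[, 1L], , drop = FALSE]
  Q <- rc[correspondence[, 2L], , drop = FALSE]
  L <- nrow(P)
  if (!superpose) return(tm_from_d(pair_dists(P, Q), d0, L_norm))
  fit <- kabsch_fit(P, Q)
  base <- tm_from_d(pair_dists(sweep(P %*% t(fit$rotation), 2L, -fit$translation), Q),
                    d0, L_norm)
  if (!search) return(base)
  best <- base
  lens <- unique(pmax(c(L, ceiling(L / 2), ceiling(L / 4)), 4L))
  lens <- lens[lens <= L]
  for (len in lens) {
    starts <- unique(c(seq(1L, L - len + 1L, by = max(ceiling(len / 2), 1L)),
                       L - len + 1L))
    for (s in starts) {
      best <- max(best, tm_refine(P, Q, seq(s, s + len - 1L), d0, L_norm, max_iter))
    }
  }
  best
}

#' Structure-similarity matrix over a homolog family
#'
#' The residue correspondence for each pair is taken from the global
#' alignment of their sequences (aligned non-gap columns); the matrix entry
#' is the mean of the TM-score normalized by each chain's length (TM itself
#' is asymmetric, the heatmap is not). Pairs whose alignment yields fewer
#' than 3 corresponding residues are set to `NA`.
#'
#' @param structures named list of `fog_structure`s (one per sequence; each
#'   structure must have at least as many residues as its sequence).
#' @param sequences a `fog_proteins` data.frame with matching `seq_id`s.
#' @param substitution_matrix,gap_open,gap_extend alignment parameters.
#' @param ... passed to [tm_score()].
#' @return square numeric matrix in `[0, 1]`, unit diagonal, `NA` for
#'   undefined entries.
#' @export
structure_similarity_matrix <- function(structures, sequences,
                                        substitution_matrix = blosum62(),
                                        gap_open = 10, gap_extend = 1, ...) {
  ids <- sequences$seq_id
  if (!all(ids %in% names(structures))) {
    stop_data("structures missing for: ",
              paste(setdiff(ids, names(structures)), collapse = ", "))
  }
  n <- length(ids)
  if (n < 2L) stop_data("need >= 2 structures")
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      aln <- global_similarity(sequences$residues[i], sequences$residues[j],
                               substitution_matrix, gap_open, gap_extend)$alignment
      corr <- alignment_correspondence(aln[1L], aln[2L])
      if (nrow(corr) < 3L) {
        m[i, j] <- m[j, i] <- NA_real_
        next
      }
      tm <- tm_score(structures[[ids[i]]], structures[[ids[j]]], corr,
                     l_norm = "mean_of_both_directions", ...)
      m[i, j] <- m[j, i] <- tm
    }
  }
  m
}

# Residue index pairs of the non-gap aligned columns of two gapped strings.
alignment_correspondence <- function(ga, gb) {
  a <- strsplit(ga, "", fixed = TRUE)[[1L]]
  b <- strsplit(gb, "", fixed = TRUE)[[1L]]
  ia <- cumsum(a != "-")
  ib <- cumsum(b != "-")
  keep <- a != "-" & b != "-"
  cbind(ia[keep], ib[keep])
}

#' Dual sequence/structure similarity concordance
#'
#' Spearman rank correlation (mid-rank ties) between the upper-triangle
#' entries of the two matrices, plus flagging of discordant pairs: high
#' sequence similarity (`>= s_hi`) but structure similarity below the
#' same-fold threshold (`< tm_lo`; 0.5 is the conventional TM-score cut).
#'
#' @param seq_m,struct_m similarity matrices over the same labels.
#' @param s_hi,tm_lo discordance thresholds.
#' @return list of class `fog_concordance`: `spearman_rho` (`NA` when fewer
#'   than 3 complete off-diagonal pairs), `discordant_pairs` (data.frame
#'   `id_a`, `id_b`, `seq_sim`, `tm`), and the thresholds.
#' @export
dual_similarity_concordance <- function(seq_m, struct_m, s_hi = 0.7, tm_lo = 0.5) {
  if (!identical(dimnames(seq_m), dimnames(struct_m))) {
    stop_data("matrices must share labels in the same order")
  }
  ut <- which(upper.tri(seq_m), arr.ind = TRUE)
  s <- seq_m[ut]
  t_ <- struct_m[ut]
  ok <- is.finite(s) & is.finite(t_)
  rho <- if (sum(ok) >= 3L) stats::cor(s[ok], t_[ok], method = "spearman") else NA_real_
  disc <- ok & s >= s_hi & t_ < tm_lo
  structure(list(
    spearman_rho = rho,
    discordant_pairs = data.frame(
      id_a = rownames(seq_m)[ut[disc, 1L]],
      id_b = colnames(seq_m)[ut[disc, 2L]],
      seq_sim = s[disc], tm = t_[disc],
      stringsAsFactors = FALSE, row.names = NULL),
    s_hi = s_hi, tm_lo = tm_lo), class = "fog_concordance")
}
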