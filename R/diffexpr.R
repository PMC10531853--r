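# Per-species replicate QC and bundle-sheath vs mesophyll differential
# expression: median-of-ratios size factors, method-of-moments NB dispersion,
# a negative-binomial Wald test (log-link GLM fitted by IRLS at fixed
# dispersion) and Benjamini-Hochberg correction. Deliberately simplified
# relative to full DESeq2: no dispersion-trend shrinkage, no outlier
# replacement, no independent filtering.

#' Median-of-ratios size factors
#'
#' `factor_j = median_g(count_gj / geomean_g)` over the reference genes (rows
#' with no zero count). With `pseudo_reference = TRUE` the geometric mean is
#' taken over positive counts only, so genes with some zeros can serve as
#' reference (useful for sparse matrices with no zero-free row).
#'
#' @param counts integer matrix, genes x samples.
#' @param pseudo_reference fall back to a positive-count geometric mean.
#' @return named positive numeric vector, one factor per sample.
#' @export
compute_size_factors <- function(counts, pseudo_reference = FALSE) {
  cnt <- unclass(counts)
  if (pseudo_reference) {
    # poscounts-style: geometric mean over positive counts with the full
    # sample count in the denominator; medians taken over positive ratios
    lg <- log(cnt)
    lg[!is.finite(lg)] <- NA
    geo <- rowSums(lg, na.rm = TRUE) / ncol(cnt)
    ref <- rowSums(cnt > 0) >= 1L
  } else {
    ref <- rowSums(cnt == 0L) == 0L
    if (!any(ref)) {
      stop_data("no gene has all-positive counts; rerun with ",
                "pseudo_reference = TRUE to use a positive-count reference")
    }
    geo <- rowMeans(log(cnt[ref, , drop = FALSE]))
    geo <- replace(rep(NA_real_, nrow(cnt)), which(ref), geo)
  }
  lref <- log(cnt[ref, , drop = FALSE]) - geo[ref]
  lref[!is.finite(lref)] <- NA
  sf <- exp(apply(lref, 2L, stats::median, na.rm = TRUE))
  if (any(!is.finite(sf) | sf <= 0)) stop_data("non-positive size factor estimated")
  stats::setNames(sf, colnames(cnt))
}

#' Method-of-moments NB dispersion per gene
#'
#' On size-factor-normalized counts, the within-group variances are pooled
#' and `alpha = max((pooled_var - mean) / mean^2, alpha_min)`. Genes with
#' zero mean get `alpha_min` and are flagged (attribute `zero_mean`).
#'
#' @param counts integer matrix, genes x samples.
#' @param size_factors per-sample positive factors.
#' @param groups per-sample group labels (two groups, >= 2 samples each).
#' @param alpha_min dispersion floor.
#' @return named numeric vector of dispersions with logical attribute
#'   `zero_mean`.
#' @export
estimate_dispersion <- function(counts, size_factors, groups, alpha_min = 1e-8) {
  cnt <- unclass(counts)
  grp <- as.character(groups)
  lev <- unique(grp)
  if (any(table(grp) < 2L)) stop_data("each group needs >= 2 samples")
  norm <- sweep(cnt, 2L, size_factors, "/")
  ss <- 0
  df <- 0
  for (g in lev) {
    sub <- norm[, grp == g, drop = FALSE]
    ss <- ss + rowSums((sub - rowMeans(sub))^2)
    df <- df + ncol(sub) - 1L
  }
  pooled_var <- ss / df
  m <- rowMeans(norm)
  alpha <- (pooled_var - m) / m^2
  zero <- m == 0
  alpha[zero | !is.finite(alpha)] <- alpha_min
  alpha <- pmax(alpha, alpha_min)
  structure(stats::setNames(alpha, rownames(cnt)), zero_mean = zero)
}

#' Negative-binomial Wald test for a two-group contrast
#'
#' Fits, per gene, the NB log-link GLM `log mu = b0 + b1 * [group == BS] +
#' log size_factor` by iteratively reweighted least squares at fixed
#' dispersion, and tests `b1 = 0` with a two-sided normal Wald p-value.
#' `log2fc` is `b1 / ln 2`, i.e. BS relative to M. Genes with zero counts in
#' every sample get `log2fc = 0`, `p = 1` and the `null_flag`;
#' non-converged fits are flagged and given `p = 1` (conservative).
#'
#' @param counts integer matrix, genes x samples.
#' @param size_factors per-sample positive factors.
#' @param dispersions per-gene NB dispersion (recycled if scalar).
#' @param groups per-sample labels, `"BS"` or `"M"` (>= 2 samples each).
#' @param maxit,tol IRLS iteration cap and coefficient tolerance.
#' @return data.frame with columns `gene_id`, `base_mean`, `log2fc`, `se`,
#'   `wald_stat`, `p_value`, `null_flag`, `converged`.
#' @export
wald_test <- function(counts, size_factors, dispersions, groups,
                      maxit = 100L, tol = 1e-10) {
  cnt <- unclass(counts)
  grp <- as.character(groups)
  if (!all(grp %in% c("BS", "M"))) stop_data("groups must be 'BS' or 'M'")
  if (sum(grp == "BS") < 2L || sum(grp == "M") < 2L) {
    stop_data("need >= 2 samples per cell type")
  }
  G <- nrow(cnt)
  x <- as.numeric(grp == "BS")
  a <- rep_len(dispersions, G)
  off <- matrix(log(size_factors), G, ncol(cnt), byrow = TRUE)
  norm <- sweep(cnt, 2L, size_factors, "/")
  base_mean <- rowMeans(norm)
  null_flag <- base_mean == 0

  m_bs <- rowMeans(norm[, x == 1, drop = FALSE])
  m_m <- rowMeans(norm[, x == 0, drop = FALSE])
  b0 <- log(pmax(m_m, 1e-8))
  b1 <- log(pmax(m_bs, 1e-8)) - b0
  active <- !null_flag
  converged <- null_flag  # all-zero genes trivially "done"
  Sw <- Swx <- Swxx <- det <- rep(NA_real_, G)
  for (it in seq_len(maxit)) {
    if (!any(active)) break
    eta <- b0 + outer(b1, x) + off
    mu <- pmin(exp(eta), 1e12)
    w <- mu / (1 + a * mu)
    z <- (eta - off) + (cnt - mu) / mu
    Sw_i <- rowSums(w)
    Swx_i <- rowSums(sweep(w, 2L, x, "*"))
    Swxx_i <- Swx_i  # x is 0/1 so x^2 = x
    Swz <- rowSums(w * z)
    Swxz <- rowSums(sweep(w * z, 2L, x, "*"))
    det_i <- Sw_i * Swxx_i - Swx_i^2
    b1n <- (Sw_i * Swxz - Swx_i * Swz) / det_i
    b0n <- (Swz - Swx_i * b1n) / Sw_i
    delta <- pmax(abs(b1n - b1), abs(b0n - b0))
    upd <- active & is.finite(delta)
    b1[upd] <- b1n[upd]
    b0[upd] <- b0n[upd]
    Sw[upd] <- Sw_i[upd]; Swx[upd] <- Swx_i[upd]
    Swxx[upd] <- Swxx_i[upd]; det[upd] <- det_i[upd]
    newly <- upd & delta < tol
    converged[newly] <- TRUE
    active <- active & !newly
  }
  se <- sqrt(Sw / det)
  stat <- b1 / se
  p <- 2 * stats::pnorm(-abs(stat))
  bad <- null_flag | !converged | !is.finite(p)
  p[bad] <- 1
  stat[bad] <- 0
  b1[null_flag] <- 0
  se[null_flag] <- NA_real_
  data.frame(gene_id = rownames(cnt) %||% as.character(seq_len(G)),
             base_mean = base_mean,
             log2fc = b1 / log(2), se = se / log(2),
             wald_stat = stat, p_value = p,
             null_flag = null_flag, converged = converged,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return adjusted p-values (monotone, capped at 1).
#' @export
bh_adjust <- function(p_values) {
  p <- p_values
  if (anyNA(p) || any(p < 0 | p > 1)) stop_data("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0L) return(numeric(0L))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / seq(m, 1L) * p[o]))[ro]
}

#' Attach BH-adjusted p-values and the DEG call to a Wald-test table
#'
#' @param wald data.frame from [wald_test()].
#' @param alpha adjusted-p threshold (strict `<`).
#' @param lfc_min absolute log2FC threshold (strict `>`).
#' @return the table with `p_adj` and `is_deg` columns added.
#' @export
de_result <- function(wald, alpha = 0.05, lfc_min = 1) {
  wald$p_adj <- bh_adjust(wald$p_value)
  wald$is_deg <- wald$p_adj < alpha & abs(wald$log2fc) > lfc_min
  wald
}

#' Extract the DEG id set
#'
#' Strict thresholds, exactly: adjusted p < `alpha` and |log2FC| > `lfc_min`.
#'
#' @param de a [de_result()] table.
#' @param alpha,lfc_min thresholds.
#' @return character vector of DEG gene ids.
#' @export
call_degs <- function(de, alpha = 0.05, lfc_min = 1) {
  de$gene_id[de$p_adj < alpha & abs(de$log2fc) > lfc_min]
}

#' Replicate quality control by Pearson correlation
#'
#' Correlations are computed on `log2(normalized count + 1)` over all samples
#' of the species. A sample is removed when its maximum correlation with the
#' other replicates of the same cell type falls below `r_min`; removal is
#' recorded, never silent. If removing a sample would leave its cell type
#' with fewer than two replicates the sample is kept and flagged instead,
#' with a warning.
#'
#' @param counts integer matrix, genes x samples, for one species.
#' @param sample_sheet data.frame with `sample_id` and `cell_type` rows for
#'   these samples.
#' @param r_min removal threshold.
#' @return a list of class `fog_qc`: `correlations` (samples x samples),
#'   `within_group_max`, `removed_samples`, `kept_flagged`.
#' @export
replicate_qc <- function(counts, sample_sheet, r_min = 0.85) {
  cnt <- unclass(counts)
  sheet <- sample_sheet[match(colnames(cnt), sample_sheet$sample_id), , drop = FALSE]
  if (anyNA(sheet$sample_id)) stop_data("samples missing from the sample sheet")
  sf <- tryCatch(compute_size_factors(cnt),
                 error = function(e) compute_size_factors(cnt, pseudo_reference = TRUE))
  lg <- log2(sweep(cnt, 2L, sf, "/") + 1)
  cm <- suppressWarnings(stats::cor(lg))
  cm[!is.finite(cm)] <- 0
  diag(cm) <- 1
  wmax <- vapply(seq_len(ncol(cnt)), function(j) {
    mates <- which(sheet$cell_type == sheet$cell_type[j])
    mates <- setdiff(mates, j)
    if (!length(mates)) NA_real_ else max(cm[j, mates])
  }, numeric(1L))
  names(wmax) <- colnames(cnt)
  candidate <- which(!is.na(wmax) & wmax < r_min)
  removed <- character(0L)
  flagged <- character(0L)
  for (j in candidate) {
    ct <- sheet$cell_type[j]
    left <- sum(sheet$cell_type == ct) -
      sum(sheet$sample_id[sheet$cell_type == ct] %in% removed) - 1L
    if (left < 2L) {
      warning("sample '", colnames(cnt)[j], "' fails QC (max within-group r = ",
              signif(wmax[j], 3), ") but removal would leave < 2 replicates; kept",
              call. = FALSE)
      flagged <- c(flagged, colnames(cnt)[j])
    } else {
      removed <- c(removed, colnames(cnt)[j])
    }
  }
  structure(list(correlations = cm, within_group_max = wmax,
                 removed_samples = removed, kept_flagged = flagged,
                 r_min = r_min), class = "fog_qc")
}

#' Full per-species differential-expression analysis
#'
#' Runs replicate QC, drops failing samples, estimates size factors and
#' dispersions, applies the NB Wald test and BH correction, and calls DEGs.
#' By default the per-gene dispersion estimates are floored at their
#' across-gene median (`disp_floor = "median"`): with few replicates the raw
#' method-of-moments estimate is so noisy that the normal-theory Wald p is
#' anticonservative, and this minimal cross-gene information sharing restores
#' type-I calibration without any trend fitting. Set `disp_floor = "none"`
#' for the raw per-gene estimates.
#'
#' @param counts integer matrix, genes x samples, one species.
#' @param sample_sheet sample sheet rows for these samples.
#' @param alpha,lfc_min DEG thresholds.
#' @param r_min replicate QC threshold.
#' @param disp_floor `"median"` or `"none"`.
#' @return list with `de` (the [de_result()] table), `qc` (the `fog_qc`),
#'   `size_factors`, `dispersions`.
#' @export
de_analysis <- function(counts, sample_sheet, alpha = 0.05, lfc_min = 1,
                        r_min = 0.85, disp_floor = c("median", "none")) {
  disp_floor <- match.arg(disp_floor)
  cnt <- unclass(counts)
  qc <- replicate_qc(cnt, sample_sheet, r_min = r_min)
  keep <- setdiff(colnames(cnt), qc$removed_samples)
  cnt <- cnt[, keep, drop = FALSE]
  sheet <- sample_sheet[match(keep, sample_sheet$sample_id), , drop = FALSE]
  sf <- tryCatch(compute_size_factors(cnt),
                 error = function(e) compute_size_factors(cnt, pseudo_reference = TRUE))
  disp <- estimate_dispersion(cnt, sf, sheet$cell_type)
  if (disp_floor == "median") disp <- pmax(disp, stats::median(disp))
  wald <- wald_test(cnt, sf, disp, sheet$cell_type)
  list(de = de_result(wald, alpha = alpha, lfc_min = lfc_min),
       qc = qc, size_factors = sf, dispersions = disp)
}
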