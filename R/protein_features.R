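# Physicochemical protein profiling (four-group amino-acid composition,
# Henderson-Hasselbalch isoelectric point by bisection) and pairwise global
# sequence similarity via Needleman-Wunsch alignment with affine gaps.

#' The four physicochemical amino-acid groups
#'
#' Hydrophobic (G, A, V, L, I, P, F), amphipathic (W, Y, M), polar
#' (S, T, C, N, Q) and charged (D, E, K, R, H); together they partition the
#' 20 standard residues (7 + 3 + 5 + 5).
#'
#' @format named list of character vectors.
#' @export
AA_GROUPS <- list(
  hydrophobic = c("G", "A", "V", "L", "I", "P", "F"),
  amphipathic = c("W", "Y", "M"),
  polar       = c("S", "T", "C", "N", "Q"),
  charged     = c("D", "E", "K", "R", "H"))

seq_chars <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  if (!length(chars)) stop_data("empty sequence")
  bad <- setdiff(unique(chars), AMINO_ACIDS)
  if (length(bad)) {
    stop_data("non-standard residue(s): ", paste(bad, collapse = ""))
  }
  chars
}

#' Four-group amino-acid composition
#'
#' @param seq a protein sequence (string over the 20 standard codes).
#' @return named numeric vector of the four group fractions (sums to 1).
#' @export
aa_composition <- function(seq) {
  chars <- seq_chars(seq)
  vapply(AA_GROUPS, function(g) mean(chars %in% g), numeric(1L))
}

#' Default pKa set (EMBOSS values)
#'
#' N-terminus 8.6, C-terminus 3.6 and side chains D 3.9, E 4.1, C 8.5,
#' Y 10.1, H 6.5, K 10.8, R 12.5.
#'
#' @return named numeric vector.
#' @export
default_pka <- function() {
  c(Nterm = 8.6, Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5, Y = 10.1,
    H = 6.5, K = 10.8, R = 12.5)
}

net_charge <- function(pH, counts, pka) {
  basic <- c("Nterm", "H", "K", "R")
  acidic <- c("Cterm", "D", "E", "C", "Y")
  pos <- sum(counts[basic] / (1 + 10^(pH - pka[basic])))
  neg <- sum(counts[acidic] / (1 + 10^(pka[acidic] - pH)))
  pos - neg
}

#' Isoelectric point by bisection
#'
#' The net charge `Q(pH)` sums Henderson-Hasselbalch terms for the termini
#' and the ionizable side chains (D, E, C, Y acidic; H, K, R basic); `Q` is
#' strictly decreasing in pH, and the pI is its root on `[0, 14]`, found by
#' bisection to `|Q| < 1e-6` (at most 60 iterations).
#'
#' @param seq a protein sequence.
#' @param pka pKa set, as from [default_pka()].
#' @return the pI.
#' @export
isoelectric_point <- function(seq, pka = default_pka()) {
  if (any(pka <= 0 | pka >= 14)) stop_config("pKa values must lie in (0, 14)")
  chars <- seq_chars(seq)
  counts <- c(Nterm = 1, Cterm = 1,
              vapply(c("D", "E", "C", "Y", "H", "K", "R"),
                     function(a) sum(chars == a), numeric(1L)))
  lo <- 0
  hi <- 14
  for (i in seq_len(60L)) {
    mid <- (lo + hi) / 2
    q <- net_charge(mid, counts, pka)
    if (abs(q) < 1e-6) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Needleman-Wunsch global alignment with affine gaps
#'
#' Gotoh three-state dynamic programming; a gap of length `k` costs
#' `gap_open + k * gap_extend`. Similarity is the fraction of identical
#' aligned positions over the full alignment length, gap columns included.
#'
#' @param a,b protein sequences (strings over the 20 standard codes).
#' @param substitution_matrix scoring matrix, as from [blosum62()].
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @return list with `score`, `similarity`, and `alignment` (two gapped
#'   strings).
#' @export
global_similarity <- function(a, b, substitution_matrix = blosum62(),
                              gap_open = 10, gap_extend = 1) {
  ca <- seq_chars(a)
  cb <- seq_chars(b)
  n <- length(ca)
  m <- length(cb)
  S <- substitution_matrix[ca, cb, drop = FALSE]
  NEG <- -1e18
  go <- gap_open + gap_extend  # cost of opening a one-residue gap
  ge <- gap_extend
  M <- Ix <- Iy <- matrix(NEG, n + 1L, m + 1L)
  M[1L, 1L] <- 0
  Ix[-1L, 1L] <- -(go + ge * (seq_len(n) - 1L))  # gap in b (vertical)
  Iy[1L, -1L] <- -(go + ge * (seq_len(m) - 1L))
  # traceback pointers: 1 = M, 2 = Ix, 3 = Iy
  tbM <- tbX <- tbY <- matrix(0L, n + 1L, m + 1L)
  if (n >= 1L) tbX[seq_len(n) + 1L, 1L] <- c(1L, rep(2L, n - 1L))
  if (m >= 1L) tbY[1L, seq_len(m) + 1L] <- c(1L, rep(3L, m - 1L))
  for (i in seq_len(n) + 1L) {
    prevM <- M[i - 1L, ]
    prevX <- Ix[i - 1L, ]
    for (j in seq_len(m) + 1L) {
      cand <- c(prevM[j - 1L], Ix[i - 1L, j - 1L], Iy[i - 1L, j - 1L])
      w <- which.max(cand)
      M[i, j] <- cand[w] + S[i - 1L, j - 1L]
      tbM[i, j] <- w
      candx <- c(prevM[j] - go, prevX[j] - ge)
      wx <- which.max(candx)
      Ix[i, j] <- candx[wx]
      tbX[i, j] <- c(1L, 2L)[wx]
      candy <- c(M[i, j - 1L] - go, Iy[i, j - 1L] - ge)
      wy <- which.max(candy)
      Iy[i, j] <- candy[wy]
      tbY[i, j] <- c(1L, 3L)[wy]
    }
  }
  finals <- c(M[n + 1L, m + 1L], Ix[n + 1L, m + 1L], Iy[n + 1L, m + 1L])
  state <- which.max(finals)
  score <- finals[state]
  # traceback
  i <- n + 1L
  j <- m + 1L
  al_a <- character(0L)
  al_b <- character(0L)
  while (i > 1L || j > 1L) {
    if (state == 1L) {
      al_a <- c(ca[i - 1L], al_a)
      al_b <- c(cb[j - 1L], al_b)
      state <- tbM[i, j]
      i <- i - 1L
      j <- j - 1L
    } else if (state == 2L) {
      al_a <- c(ca[i - 1L], al_a)
      al_b <- c("-", al_b)
      state <- tbX[i, j]
      i <- i - 1L
    } else {
      al_a <- c("-", al_a)
      al_b <- c(cb[j - 1L], al_b)
      state <- tbY[i, j]
      j <- j - 1L
    }
  }
  ident <- sum(al_a == al_b & al_a != "-")
  list(score = score,
       similarity = ident / length(al_a),
       alignment = c(paste(al_a, collapse = ""), paste(al_b, collapse = "")))
}

#' Pairwise sequence-similarity matrix for a homolog family
#'
#' All unordered pairs via [global_similarity()]; symmetric with unit
#' diagonal by construction.
#'
#' @param family a `fog_proteins` data.frame (>= 2 sequences).
#' @param ... passed to [global_similarity()].
#' @return square numeric matrix in `[0, 1]` with seq-id dimnames.
#' @export
sequence_similarity_matrix <- function(family, ...) {
  n <- nrow(family)
  if (n < 2L) stop_data("need >= 2 sequences")
  ids <- family$seq_id
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      s <- global_similarity(family$residues[i], family$residues[j], ...)$similarity
      m[i, j] <- m[j, i] <- s
    }
  }
  m
}
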