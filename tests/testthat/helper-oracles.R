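# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive (loops, enumeration, grid search) and share no code
# with the implementation paths they check.

# Step-up BH as an explicit loop over the sorted p-values.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m / (i:m) * ps[i:m]))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Upper-tail hypergeometric by direct combinatorial summation.
hyper_oracle <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Optimal global alignment score by exhaustive recursion (no DP reuse).
# Gap of length L costs gap_open + L * gap_extend.
nw_enum_oracle <- function(a, b, submat, gap_open = 10, gap_extend = 1) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca)
  m <- length(cb)
  rec <- function(i, j, prev) {
    if (i == n && j == m) return(0)
    best <- -Inf
    if (i < n && j < m) {
      best <- max(best, submat[ca[i + 1], cb[j + 1]] + rec(i + 1, j + 1, "M"))
    }
    if (i < n) {
      cost <- if (prev == "X") gap_extend else gap_open + gap_extend
      best <- max(best, -cost + rec(i + 1, j, "X"))
    }
    if (j < m) {
      cost <- if (prev == "Y") gap_extend else gap_open + gap_extend
      best <- max(best, -cost + rec(i, j + 1, "Y"))
    }
    best
  }
  rec(0, 0, "M")
}

# Minimal RMSD over rigid motions by Euler-angle grid search plus local
# refinement (translation handled in closed form by centering).
kabsch_grid_oracle <- function(P, Q, grid_step_deg = 10) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  M <- t(Pc) %*% Qc  # rmsd^2 = (|P|^2 + |Q|^2 - 2 tr(R M)) / n
  const <- sum(Pc^2) + sum(Qc^2)
  n <- nrow(P)
  euler_R <- function(a, b, c) {
    Rz1 <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)
    Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3)
    Rz2 <- matrix(c(cos(c), sin(c), 0, -sin(c), cos(c), 0, 0, 0, 1), 3)
    Rz1 %*% Ry %*% Rz2
  }
  obj <- function(ang) {
    R <- euler_R(ang[1], ang[2], ang[3])
    (const - 2 * sum(R * t(M))) / n
  }
  step <- grid_step_deg * pi / 180
  grid_a <- seq(0, 2 * pi - step / 2, by = step)
  grid_b <- seq(0, pi, by = step)
  best <- Inf
  best_ang <- c(0, 0, 0)
  for (a in grid_a) for (b in grid_b) for (c in grid_a) {
    v <- obj(c(a, b, c))
    if (v < best) {
      best <- v
      best_ang <- c(a, b, c)
    }
  }
  ref <- optim(best_ang, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 2000))
  sqrt(max(min(best, ref$value), 0))
}

# Spearman rho via explicit mid-ranks and the Pearson formula.
spearman_oracle <- function(x, y) {
  midrank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    r
  }
  rx <- midrank(x)
  ry <- midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Plain closed-form Pearson correlation.
pearson_oracle <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# Random amino-acid sequence from the current RNG.
random_protein <- function(len) {
  paste(sample(fogsig::AA_GROUPS$hydrophobic |> c(
    fogsig::AA_GROUPS$amphipathic, fogsig::AA_GROUPS$polar,
    fogsig::AA_GROUPS$charged), len, replace = TRUE), collapse = "")
}

# Tiny count fixture and sheet for one species. Per-gene baseline means are
# spread over 10-1000 so replicates correlate (as in real libraries).
toy_counts <- function(n_genes = 50, n_reps = 3, seed = 1, species = "spA") {
  set.seed(seed)
  mu <- 10^runif(n_genes, 1, 3)
  cnt <- matrix(rnbinom(n_genes * 2 * n_reps, mu = mu, size = 10),
                n_genes, 2 * n_reps)
  rownames(cnt) <- paste0("g", seq_len(n_genes))
  colnames(cnt) <- c(paste0("BS_r", 1:n_reps), paste0("M_r", 1:n_reps))
  sheet <- data.frame(sample_id = colnames(cnt), species_id = species,
                      cell_type = rep(c("BS", "M"), each = n_reps),
                      replicate = rep(1:n_reps, 2))
  list(counts = cnt, sheet = sheet)
}

run_de_stack <- function(cnt, sheet, disp_floor = "median") {
  de_analysis(cnt, sheet, disp_floor = disp_floor)
}
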