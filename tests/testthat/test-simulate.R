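# Synthetic-data generators: determinism, planted structure, NB moments.

test_that("sim_design validates planted counts and replicate minima", {
  expect_s3_class(sim_design(n_groups = 10, n_fog = 2, n_conserved = 2,
                             n_species_specific = 2), "fog_sim_design")
  expect_error(sim_design(n_groups = 10, n_fog = 6, n_conserved = 5,
                          n_species_specific = 0), "exceed",
               class = "fog_config_error")
  expect_error(sim_design(dispersion = -1), class = "fog_config_error")
  expect_error(sim_design(n_species_c4 = 0, n_fog = 1), "both C3 and C4")
})

test_that("no planting gives all-null truth; same seed gives identical output", {
  d <- sim_design(n_groups = 40, n_fog = 0, n_conserved = 0,
                  n_species_specific = 0, n_species_c3 = 1, n_species_c4 = 1,
                  seed = 11)
  sim <- simulate_experiment(d)
  expect_true(all(sim$truth$classes$class == "null"))
  expect_true(all(sim$truth$log2fc == 0))
  sim2 <- simulate_experiment(d)
  expect_identical(sim$counts, sim2$counts)
  expect_identical(sim$truth, sim2$truth)
  # a different seed actually changes the draws
  sim3 <- simulate_experiment(sim_design(n_groups = 40, n_fog = 0,
                                         n_conserved = 0,
                                         n_species_specific = 0,
                                         n_species_c3 = 1, n_species_c4 = 1,
                                         seed = 12))
  expect_false(identical(sim$counts, sim3$counts))
})

test_that("simulated counts carry the planted layout", {
  d <- sim_design(n_groups = 300, n_fog = 8, n_conserved = 8,
                  n_species_specific = 8, seed = 3)
  sim <- simulate_experiment(d)
  cls <- sim$truth$classes$class
  expect_identical(sum(cls == "flip_over"), 8L)
  expect_identical(sum(cls == "conserved_signature"), 8L)
  expect_identical(sum(cls == "species_specific"), 8L)
  lfc <- sim$truth$log2fc
  type <- sim$species$photosynthesis_type
  fog <- cls == "flip_over"
  # flip-over: uniform sign within type, opposite between types
  expect_true(all(sign(lfc[fog, type == "C3", drop = FALSE][, 1]) ==
                    -sign(lfc[fog, type == "C4", drop = FALSE][, 1])))
  expect_true(all(apply(sign(lfc[fog, , drop = FALSE]), 1,
                        function(r) length(unique(r[type == "C3"])) == 1 &&
                          length(unique(r[type == "C4"])) == 1)))
  sps <- cls == "species_specific"
  expect_true(all(rowSums(lfc[sps, , drop = FALSE] != 0) == 1))
  # samples/orthologs agree with counts
  expect_setequal(sim$samples$sample_id, unlist(lapply(sim$counts, colnames)))
  expect_identical(nrow(sim$orthologs), 300L * 5L)
})

test_that("per-group empirical BS/M log ratio recovers the planted sign", {
  d <- sim_design(seed = 21)  # default: 2 C3 + 3 C4, 2000 groups, 10 FOGs
  sim <- simulate_experiment(d)
  planted <- sim$truth$log2fc != 0
  hit <- 0L
  tot <- 0L
  for (s in seq_along(sim$counts)) {
    cnt <- unclass(sim$counts[[s]])
    ct <- sim$samples$cell_type[match(colnames(cnt), sim$samples$sample_id)]
    emp <- log2((rowMeans(cnt[, ct == "BS"]) + 0.5) /
                  (rowMeans(cnt[, ct == "M"]) + 0.5))
    idx <- which(planted[, s])
    hit <- hit + sum(sign(emp[idx]) == sign(sim$truth$log2fc[idx, s]))
    tot <- tot + length(idx)
  }
  expect_gt(hit / tot, 0.95)
})

test_that("NB moments match mean mu and variance mu + alpha mu^2", {
  set.seed(8)
  n <- 10000
  for (case in list(c(mu = 50, alpha = 0.1), c(mu = 200, alpha = 0.02))) {
    x <- fogsig:::rnbinom_mu(n, case[["mu"]], case[["alpha"]])
    mu <- case[["mu"]]
    v <- mu + case[["alpha"]] * mu^2
    se_mean <- sqrt(v / n)
    expect_lt(abs(mean(x) - mu), 3 * se_mean)
    # SE of the sample variance of an overdispersed count, normal approx
    m4 <- mean((x - mean(x))^4)
    se_var <- sqrt((m4 - var(x)^2) / n)
    expect_lt(abs(var(x) - v), 3 * se_var)
  }
})

test_that("protein families: rate zero, expected divergence, determinism", {
  fam0 <- simulate_protein_family(100, c(a = 0, b = 0), seed = 4)
  expect_identical(unique(fam0$family$residues), fam0$ancestor)

  fam <- simulate_protein_family(200, c(x = 0.5), seed = 4)
  ident <- mean(strsplit(fam$family$residues, "")[[1]] ==
                  strsplit(fam$ancestor, "")[[1]])
  expect_lt(abs(ident - 0.5), 0.08)

  expect_identical(simulate_protein_family(50, c(a = 0.2, b = 0.6), seed = 9),
                   simulate_protein_family(50, c(a = 0.2, b = 0.6), seed = 9))
  expect_error(simulate_protein_family(50, c(a = 1)), "rates")
})

test_that("helix generator: geometry, determinism, rigid invariance", {
  h <- simulate_helix_structure(30, 0, seed = 1)
  expect_identical(h, simulate_helix_structure(30, 0, seed = 1))
  # stated geometry: radius 2.3, rise 1.5
  expect_equal(unname(sqrt(h$coords[, 1]^2 + h$coords[, 2]^2)),
               rep(2.3, 30))
  expect_equal(unname(diff(h$coords[, 3])), rep(1.5, 29))
  expect_error(simulate_helix_structure(2, 0), "length")

  set.seed(77)
  tr <- fogsig:::random_rigid_transform()
  moved <- simulate_helix_structure(30, 0, rigid_transform = tr, seed = 1)
  sup <- kabsch_superpose(moved$coords, h$coords)
  expect_lt(sup$rmsd, 1e-9)
})

test_that("noisier helices score lower against the clean reference", {
  clean <- simulate_helix_structure(60, 0, seed = 1)
  wins <- 0L
  for (s in 1:20) {
    lo <- simulate_helix_structure(60, 0.5, seed = 1000 + s)
    hi <- simulate_helix_structure(60, 2.0, seed = 1000 + s)
    if (tm_score(lo, clean) > tm_score(hi, clean)) wins <- wins + 1L
  }
  expect_gt(wins, 10L)
})

test_that("write_simulation persists a readable world", {
  d <- sim_design(n_groups = 25, n_fog = 1, n_conserved = 1,
                  n_species_specific = 1, seed = 2)
  sim <- simulate_experiment(d)
  out <- tempfile()
  write_simulation(sim, out)
  cm <- read_counts(file.path(out, "counts_c3_1.tsv"), "c3_1")
  expect_identical(unclass(cm), unclass(sim$counts$c3_1),
                   ignore_attr = TRUE)
  sheets <- read_sheets(file.path(out, "samples.tsv"),
                        file.path(out, "species.tsv"))
  expect_identical(nrow(sheets$samples), nrow(sim$samples))
  truth <- read.delim(file.path(out, "truth.tsv"))
  expect_identical(nrow(truth), 25L)
})
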