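# Ortholog projection, Venn partitioning, enrichment, classification,
# type correlation.

make_map <- function(groups, species) {
  do.call(rbind, lapply(species, function(sp) {
    data.frame(group_id = groups, species_id = sp,
               gene_id = paste0(sp, "_", groups), stringsAsFactors = FALSE)
  }))
}

test_that("project_degs: contracts and exhaustive oracle", {
  map <- make_map(paste0("OG", 1:4), c("spA", "spB"))
  empty <- project_degs(list(spA = character(0), spB = character(0)), map)
  expect_true(all(!empty))

  # drop spB's gene for OG4: membership NA there
  map2 <- map[!(map$group_id == "OG4" & map$species_id == "spB"), ]
  mem <- project_degs(list(spA = c("spA_OG1", "spA_OG4"), spB = "spB_OG1"), map2)
  expect_true(mem["OG1", "spA"] && mem["OG1", "spB"])
  expect_true(is.na(mem["OG4", "spB"]))
  expect_true(mem["OG4", "spA"])

  dupmap <- rbind(map, data.frame(group_id = "OG9", species_id = "spA",
                                  gene_id = "spA_OG1"))
  expect_error(project_degs(list(spA = character(0), spB = character(0)),
                            dupmap), "more than one ortholog group")

  set.seed(20)
  for (rep in 1:5) {
    sps <- paste0("sp", 1:4)
    groups <- paste0("OG", 1:30)
    map_r <- make_map(groups, sps)
    map_r <- map_r[runif(nrow(map_r)) < 0.8, ]  # incomplete mapping
    degs <- lapply(sps, function(sp) {
      genes <- map_r$gene_id[map_r$species_id == sp]
      sample(genes, size = rbinom(1, length(genes), 0.3))
    })
    names(degs) <- sps
    mem_r <- project_degs(degs, map_r)
    for (g in rownames(mem_r)) for (sp in sps) {
      gene <- map_r$gene_id[map_r$group_id == g & map_r$species_id == sp]
      want <- if (length(gene) == 0) NA else gene %in% degs[[sp]]
      expect_identical(unname(mem_r[g, sp]), want)
    }
  }
})

test_that("venn_partition counts subsets exactly and extracts named sets", {
  sheet <- data.frame(species_id = c("a", "b", "c", "d", "e"),
                      photosynthesis_type = c("C3", "C3", "C4", "C4", "C4"))
  # disjoint DEG sets: common empty
  mem <- matrix(FALSE, 3, 5, dimnames = list(paste0("OG", 1:3), sheet$species_id))
  mem[1, "a"] <- TRUE
  mem[2, "b"] <- TRUE
  vp <- venn_partition(mem, sheet)
  expect_length(vp$common_all, 0L)
  expect_identical(sum(vp$subset_counts), 2L)

  set.seed(30)
  for (rep in 1:5) {
    n_sp <- sample(3:6, 1)
    sps <- letters[1:n_sp]
    sheet_r <- data.frame(species_id = sps,
                          photosynthesis_type = c("C3", rep("C4", n_sp - 1)))
    mem_r <- matrix(runif(40 * n_sp) < 0.4, 40, n_sp,
                    dimnames = list(paste0("OG", 1:40), sps))
    vp_r <- venn_partition(mem_r, sheet_r)
    # brute force over all nonempty subsets
    for (mask in 1:(2^n_sp - 1)) {
      in_set <- sps[bitwAnd(mask, 2^(seq_len(n_sp) - 1)) > 0]
      want <- sum(apply(mem_r, 1, function(r) setequal(sps[r], in_set)))
      key <- paste(in_set, collapse = "&")
      got <- if (key %in% names(vp_r$subset_counts)) vp_r$subset_counts[[key]] else 0L
      expect_identical(got, as.integer(want))
    }
    expect_identical(sum(vp_r$subset_counts), sum(rowSums(mem_r) > 0))
    # common_all is contained in every per-species projection
    for (sp in sps) {
      expect_true(all(mem_r[vp_r$common_all, sp]))
    }
    c4 <- sps[sheet_r$photosynthesis_type == "C4"]
    c3 <- sps[sheet_r$photosynthesis_type == "C3"]
    for (g in vp_r$c4_specific) {
      expect_true(all(mem_r[g, c4]) && !any(mem_r[g, c3]))
    }
  }
})

test_that("hypergeometric enrichment matches direct combinatorial sums", {
  uni <- paste0("OG", 1:10)
  coll <- list(s5 = paste0("OG", 1:5))
  # query = universe: k = K, p = 1
  full <- hypergeometric_enrichment(uni, uni, coll)
  expect_identical(full$k, full$K)
  expect_equal(full$p_value, 1)
  # N=10, K=5, n=4, k=4
  r <- hypergeometric_enrichment(paste0("OG", 1:4), uni, coll)
  expect_equal(r$p_value, 5 / 210, tolerance = 1e-12)
  # k = 0 never enriched
  r0 <- hypergeometric_enrichment(paste0("OG", 6:9), uni, coll)
  expect_identical(r0$k, 0L)
  expect_gte(r0$p_value, 0.5)
  expect_false(r0$enriched)
  expect_error(hypergeometric_enrichment("OG1", character(0), coll), "universe")
  expect_error(hypergeometric_enrichment("nope", uni, coll), "subset")

  set.seed(40)
  for (i in 1:50) {
    N <- sample(5:60, 1)
    uni <- paste0("g", 1:N)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    coll_i <- list(s = sample(uni, K))
    q <- sample(uni, n)
    got <- hypergeometric_enrichment(q, uni, coll_i)
    k <- length(intersect(coll_i$s, q))
    expect_identical(got$k, k)
    expect_lt(abs(got$p_value - hyper_oracle(k, K, n, N)), 1e-12)
  }
})

fake_de <- function(genes, lfc, padj, null = FALSE) {
  data.frame(gene_id = genes, log2fc = lfc, p_adj = padj,
             null_flag = rep_len(null, length(genes)),
             stringsAsFactors = FALSE)
}

test_that("classify_patterns reproduces the pattern truth table", {
  sps <- c("c3a", "c3b", "c4a", "c4b", "c4c")
  sheet <- data.frame(species_id = sps,
                      photosynthesis_type = c("C3", "C3", "C4", "C4", "C4"))
  map <- make_map(paste0("OG", 1:5), sps)
  lfc_by_group <- list(
    OG1 = c(2, 2, -2, -2, -2),    # flip_over
    OG2 = c(2, 2, 2, 2, 2),       # conserved_signature
    OG3 = c(2, -2, -2, -2, -2),   # inconsistent (within-C3 conflict)
    OG4 = c(2, 2, -2, -2, -2),    # dropped_null (null flag in c4c)
    OG5 = c(2, 2, 2, 0.5, 2))     # not_common (no DEG in c4b)
  de <- lapply(sps, function(sp) {
    i <- match(sp, sps)
    lfc <- vapply(paste0("OG", 1:5), function(g) lfc_by_group[[g]][i], 0)
    fake_de(paste0(sp, "_OG", 1:5), lfc, rep(0.001, 5),
            null = c(FALSE, FALSE, FALSE, sp == "c4c", FALSE))
  })
  names(de) <- sps
  got <- classify_patterns(de, map, sheet)
  expect_identical(got$class[match(paste0("OG", 1:5), got$group_id)],
                   c("flip_over", "conserved_signature", "inconsistent",
                     "dropped_null", "not_common"))
  expect_identical(got$sign_vector[got$group_id == "OG1"], "++---")

  # all-minus conserved and C4-up flip both count, symmetric in sign
  lfc_by_group$OG1 <- -lfc_by_group$OG1
  lfc_by_group$OG2 <- -lfc_by_group$OG2
  de2 <- lapply(sps, function(sp) {
    i <- match(sp, sps)
    lfc <- vapply(paste0("OG", 1:5), function(g) lfc_by_group[[g]][i], 0)
    fake_de(paste0(sp, "_OG", 1:5), lfc, rep(0.001, 5))
  })
  names(de2) <- sps
  got2 <- classify_patterns(de2, map, sheet)
  expect_identical(got2$class[got2$group_id == "OG1"], "flip_over")
  expect_identical(got2$class[got2$group_id == "OG2"], "conserved_signature")

  # pathway filter drops groups outside it after the null screen
  got3 <- classify_patterns(de, map, sheet, pathway_filter = c("OG2", "OG4"))
  expect_identical(got3$class[got3$group_id == "OG1"], "not_common")
  expect_identical(got3$class[got3$group_id == "OG2"], "conserved_signature")
  expect_identical(got3$class[got3$group_id == "OG4"], "dropped_null")

  expect_error(classify_patterns(de[1:4], map, sheet), "no DE results")
})

test_that("type_correlation: perfect separation, undefined, closed form", {
  sheet <- data.frame(species_id = c("a", "b", "c"),
                      photosynthesis_type = c("C3", "C3", "C4"))
  vals <- list(a = c(2, 2), b = c(2, 2), c = c(-2, -2))
  expect_equal(type_correlation(vals, sheet), -1)

  expect_true(is.na(type_correlation(list(a = c(1, 1), b = 1, c = c(1, 1)),
                                     sheet)))
  expect_error(type_correlation(list(a = 1, c = 1), sheet[-2, ]), "fewer than 3")

  vals2 <- list(a = c(1.8, 2.1), b = -1.9, c = c(-2.2, -2.0))
  sheet2 <- data.frame(species_id = c("a", "b", "c"),
                       photosynthesis_type = c("C3", "C4", "C4"))
  x <- c(1.8, 2.1, -1.9, -2.2, -2.0)
  code <- c(0, 0, 1, 1, 1)
  expect_lt(abs(type_correlation(vals2, sheet2) - pearson_oracle(x, code)),
            1e-12)
})

test_that("end-to-end recovery on the default synthetic design", {
  sim <- simulate_experiment(sim_design(seed = 101))
  de <- lapply(names(sim$counts), function(sp) {
    sheet <- sim$samples[sim$samples$species_id == sp, ]
    de_analysis(sim$counts[[sp]], sheet)$de
  })
  names(de) <- names(sim$counts)
  pat <- classify_patterns(de, sim$orthologs, sim$species)
  truth <- sim$truth$classes
  called <- pat$class[match(truth$group_id, pat$group_id)]
  fog_sens <- mean(called[truth$class == "flip_over"] == "flip_over")
  expect_gte(fog_sens, 0.8)
  expect_identical(sum(called[truth$class == "conserved_signature"] ==
                         "flip_over"), 0L)
  null_hits <- mean(called[truth$class == "null"] %in%
                      c("flip_over", "conserved_signature"))
  expect_lte(null_hits, 0.01)

  # planted FOGs separate C3 from C4 more sharply than conserved genes
  per_group_r <- function(g) {
    vals <- lapply(sim$species$species_id, function(sp) {
      gene <- sim$orthologs$gene_id[sim$orthologs$group_id == g &
                                      sim$orthologs$species_id == sp]
      replicate_log2fc(sim$counts[[sp]],
                       sim$samples[sim$samples$species_id == sp, ], gene)
    })
    names(vals) <- sim$species$species_id
    type_correlation(vals, sim$species)
  }
  r_fog <- vapply(truth$group_id[truth$class == "flip_over"], per_group_r, 0)
  r_con <- vapply(truth$group_id[truth$class == "conserved_signature"],
                  per_group_r, 0)
  expect_gt(median(abs(r_fog)), max(abs(r_con)))
  expect_gt(median(abs(r_fog)), 0.9)
})
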