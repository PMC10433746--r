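test_that("ORA computes the exact hypergeometric upper tail", {
  universe <- sprintf("g%02d", 1:10)
  sets <- gene_set_collection(list(inset = universe[1:5], nohit = universe[9:10]))
  res <- ora(universe[1:4], universe, sets)
  row <- res[res$set == "inset", ]
  expect_equal(row$p_hyper, 5 / 210, tolerance = 1e-14) # C(5,4)C(5,0)/C(10,4)
  expect_equal(row$k, 4)
  expect_identical(row$members_hit, "g01,g02,g03,g04")
  # upper tail at k = 0 is 1
  expect_equal(res$p_hyper[res$set == "nohit"], 1)
  expect_error(
    ora(c("g01", "zz"), universe, sets), "zz",
    class = "cryomics_domain_error"
  )
})

test_that("ORA tail equals exhaustive subset enumeration on small instances", {
  withr::with_seed(31, {
    for (i in 1:25) {
      N <- sample(4:12, 1)
      K <- sample(0:N, 1)
      n <- sample(1:N, 1)
      k <- sample(0:min(K, n), 1)
      expect_equal(
        cryomics:::hyper_tail(k, K, N, n), hyper_brute(k, K, N, n),
        tolerance = 1e-12
      )
    }
  })
})

test_that("co-enrichment finds the planted pathway with both omics contributing", {
  sim <- generate_paired_omics(sim_config(seed = 4, noise_sd_log2 = 0))
  deg <- names(sim$truth$de_genes)
  dep <- names(sim$truth$de_proteins)
  co <- co_ora(
    deg, dep, sim$id_map, sim$gene_sets,
    rownames(sim$genes$values), rownames(sim$proteins$values)
  )
  row <- co[co$set == "planted_pathway", ]
  expect_lt(row$p_hyper, 0.05)
  expect_true(row$significant)
  expect_gt(nchar(row$gene_hits), 0)
  expect_gt(nchar(row$protein_hits), 0)
  expect_true(sim$truth$consensus_candidate %in%
    strsplit(row$gene_hits, ",")[[1]])
})

test_that("co-enrichment saturates at p = 1 and logs unmapped proteins", {
  universe <- sprintf("g%02d", 1:8)
  map <- id_map(universe[1:4], paste0("p", 1:4))
  sets <- gene_set_collection(list(s1 = universe[1:3], s2 = universe[4:8]))
  # selection = universe: upper tail with n = N gives k = K hence p = 1
  sat <- co_ora(universe, paste0("p", 1:4), map, sets, universe, paste0("p", 1:4))
  expect_true(all(sat$p_hyper == 1))
  dropped <- co_ora(
    universe[1], c("p1", "orphan"), map, sets, universe,
    c(paste0("p", 1:4), "orphan")
  )
  expect_true("orphan" %in% attr(dropped, "dropped_proteins"))
})

test_that("GSEA running sum matches hand enumeration and edge cases", {
  scores <- stats::setNames(c(3, 2.5, 2, -1, -2, -3), letters[1:6])
  all_set <- gene_set_collection(list(everything = letters[1:6]))
  res <- gsea(scores, all_set, n_perm = 100, seed = 1)
  expect_equal(res$es, 1) # no misses: running sum peaks at the full weight

  withr::with_seed(17, {
    for (i in 1:30) {
      N <- sample(4:10, 1)
      sc <- stats::setNames(stats::rnorm(N), sample(letters, N))
      members <- sample(names(sc), sample(1:(N - 1), 1))
      w <- sample(c(0, 1), 1)
      got <- gsea(sc, gene_set_collection(list(s = members)),
        n_perm = 100, weight = w, seed = 2
      )
      expect_equal(got$es, es_brute(sc, members, w), tolerance = 1e-12)
    }
  })
})

test_that("GSEA ES agrees with the fgsea implementation", {
  withr::with_seed(41, {
    for (i in 1:10) {
      N <- 50
      sc <- stats::setNames(stats::rnorm(N), sprintf("f%02d", 1:N))
      members <- sample(names(sc), 8)
      got <- gsea(sc, gene_set_collection(list(s = members)),
        n_perm = 100, weight = 1, seed = 3
      )
      ord <- order(-sc, names(sc))
      ref <- fgsea::calcGseaStat(
        stats::setNames(sc[ord], names(sc)[ord]),
        selectedStats = which(names(sc)[ord] %in% members),
        gseaParam = 1
      )
      expect_equal(got$es, unname(ref), tolerance = 1e-12)
    }
  })
})

test_that("rank-only GSEA is invariant to monotone score rescaling", {
  withr::with_seed(6, {
    sc <- stats::setNames(stats::rnorm(20), sprintf("f%02d", 1:20))
    members <- sample(names(sc), 5)
    sets <- gene_set_collection(list(s = members))
    a <- gsea(sc, sets, n_perm = 100, weight = 0, seed = 9)
    b <- gsea(2 * sc + 100, sets, n_perm = 100, weight = 0, seed = 9)
    expect_equal(a$es, b$es)
  })
})

test_that("permutation p-values are smoothed, reproducible and calibrated", {
  sim <- generate_paired_omics(sim_config(seed = 10))
  deg_tab <- differential_table(sim$genes)
  # rank with the down-regulated planted pathway at the top
  scores <- stats::setNames(-deg_tab$log2FC, deg_tab$feature)
  planted <- gene_set_collection(
    list(planted_pathway = sim$gene_sets$planted_pathway)
  )
  res1 <- gsea(scores, planted, n_perm = 199, seed = 77)
  res2 <- gsea(scores, planted, n_perm = 199, seed = 77)
  expect_identical(res1, res2)
  expect_gte(res1$p_perm, 1 / 200)
  expect_gt(res1$es, 0)

  # the planted (top-ranked) set is significant across generator seeds
  hits <- vapply(1:20, function(s) {
    simi <- generate_paired_omics(sim_config(seed = s))
    sc <- stats::setNames(
      -differential_table(simi$genes)$log2FC,
      differential_table(simi$genes)$feature
    )
    g <- gsea(sc, gene_set_collection(
      list(planted_pathway = simi$gene_sets$planted_pathway)
    ), n_perm = 199, seed = s)
    g$p_perm <= 0.05 && g$es > 0
  }, TRUE)
  expect_gte(mean(hits), 0.95)

  expect_warning(
    gsea(stats::setNames(1:4, letters[1:4]),
      gene_set_collection(list(ghost = c("zz"))),
      n_perm = 100, seed = 1
    ),
    "skipped"
  )
  expect_error(
    gsea(stats::setNames(1:4, letters[1:4]),
      gene_set_collection(list(s = "a")),
      n_perm = 10
    ),
    class = "cryomics_domain_error"
  )
})
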