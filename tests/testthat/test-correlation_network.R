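test_that("pearson matches hand computation and cor.test", {
  exact <- pearson(c(1, 2, 3), c(2, 4, 6))
  expect_equal(exact$rho, 1)
  expect_equal(exact$p, 0)
  anti <- pearson(c(1, 2, 3), c(3, 2, 1))
  expect_equal(anti$rho, -1)
  # hand computation: centered cross products 15.5 over sqrt(17.5 * 17.5)
  x <- 1:6
  y <- c(1, 3, 2, 5, 4, 6)
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  got <- pearson(x, y)
  expect_equal(got$rho, hand, tolerance = 1e-14)
  expect_equal(got$rho, 15.5 / 17.5, tolerance = 1e-14)
  withr::with_seed(14, {
    for (i in 1:15) {
      a <- stats::rnorm(sample(3:8, 1))
      b <- stats::rnorm(length(a))
      ref <- stats::cor.test(a, b)
      p <- pearson(a, b)
      expect_equal(p$rho, unname(ref$estimate), tolerance = 1e-12)
      expect_equal(p$p, ref$p.value, tolerance = 1e-12)
      sym <- pearson(b, a)
      expect_equal(p$rho, sym$rho)
      expect_equal(p$p, sym$p)
    }
  })
  expect_error(pearson(c(1, 1, 1), 1:3), class = "cryomics_undefined_correlation_error")
  expect_error(pearson(1:2, 1:2), class = "cryomics_domain_error")
  expect_error(pearson(1:3, 1:4), class = "cryomics_domain_error")
})

test_that("network keeps planted edges and respects both gates", {
  for (s in 1:3) {
    sim <- generate_paired_omics(sim_config(seed = s))
    tr <- sim$truth
    net <- build_network(
      subset_features(sim$genes, tr$planted_pairs$gene_id),
      subset_features(sim$proteins, tr$planted_pairs$protein_id)
    )
    cand_edge <- net$edges$gene_id == tr$consensus_candidate &
      net$edges$protein_id == tr$consensus_candidate_protein
    expect_true(any(cand_edge))
    expect_true(all(abs(net$edges$rho) > 0.8))
    expect_true(all(net$edges$p < 0.05))
  }
})

test_that("null edge rate matches the closed-form gate probability", {
  # with n = 6 the p < 0.05 gate implies |rho| > 0.811, so the combined gate
  # fires with probability 0.05 under independence
  withr::with_seed(70, {
    G <- matrix(2^stats::rnorm(200 * 6), 200, 6,
      dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:6))
    )
    P <- matrix(2^stats::rnorm(50 * 6), 50, 6,
      dimnames = list(sprintf("p%03d", 1:50), paste0("s", 1:6))
    )
  })
  gr <- stats::setNames(rep(c("FS", "PS"), each = 3), paste0("s", 1:6))
  net <- build_network(expression_matrix(G, gr), expression_matrix(P, gr))
  r_star <- sqrt(stats::qt(0.975, 4)^2 / (stats::qt(0.975, 4)^2 + 4))
  expect_gt(r_star, 0.8) # p-gate is the binding one
  expect_lt(abs(nrow(net$edges) / 10000 - 0.05), 0.015)
})

test_that("network filtering is monotone and permutation invariant", {
  sim <- generate_paired_omics(sim_config(seed = 8))
  gx <- subset_features(sim$genes, names(sim$truth$de_genes)[1:6])
  px <- subset_features(sim$proteins, names(sim$truth$de_proteins))
  base <- build_network(gx, px, rho_threshold = 0.8, alpha = 0.05)
  key <- function(n) paste(n$edges$gene_id, n$edges$protein_id)
  stricter_rho <- build_network(gx, px, rho_threshold = 0.9, alpha = 0.05)
  stricter_a <- build_network(gx, px, rho_threshold = 0.8, alpha = 0.01)
  expect_true(all(key(stricter_rho) %in% key(base)))
  expect_true(all(key(stricter_a) %in% key(base)))
  exact_gate <- build_network(gx, px, rho_threshold = 1.0)
  expect_equal(nrow(exact_gate$edges), 0)

  perm <- withr::with_seed(2, sample(ncol(gx$values)))
  gxp <- expression_matrix(gx$values[, perm], gx$groups[perm])
  pxp <- expression_matrix(px$values[, perm], px$groups[perm])
  permuted <- build_network(gxp, pxp)
  expect_identical(key(base), key(permuted))
  expect_equal(base$edges$rho, permuted$edges$rho, tolerance = 1e-12)

  bad <- expression_matrix(
    px$values[, rev(seq_len(6))], px$groups
  )
  expect_error(build_network(gx, bad), class = "cryomics_alignment_error")
})

test_that("degree ranking orders hubs with deterministic tie-break", {
  empty <- build_network(
    make_em(rbind(c(1, 2, 3)), rbind(c(1, 2, 3)), "g1"),
    make_em(rbind(c(9, 1, 4)), rbind(c(2, 8, 3)), "p1"),
    rho_threshold = 1
  )
  expect_equal(nrow(degree_ranking(empty)), 0)

  # planted hub: gA tracks 5 proteins, gB tracks 1, across 6 samples
  withr::with_seed(33, {
    latent <- stats::rnorm(6)
    gA <- 2^(6 + latent)
    gB <- 2^(6 + stats::rnorm(6))
    prot <- rbind(
      t(replicate(5, 2^(5 + latent + stats::rnorm(6, sd = 0.05)))),
      2^(5 + log2(gB) - 6 + stats::rnorm(6, sd = 0.05))
    )
  })
  gm <- matrix(c(gA, gB), 2, byrow = TRUE,
    dimnames = list(c("gA", "gB"), paste0("s", 1:6))
  )
  colnames(prot) <- paste0("s", 1:6)
  rownames(prot) <- paste0("p", 1:6)
  gr <- stats::setNames(rep(c("FS", "PS"), each = 3), paste0("s", 1:6))
  net <- build_network(expression_matrix(gm, gr), expression_matrix(prot, gr))
  rank <- degree_ranking(net, top_n = 5)
  expect_identical(rank$gene_id[1], "gA")
  expect_gte(rank$degree[1], 4)
})

test_that("phenotype correlation recovers the planted linear link", {
  # exact linear phenotype gives rho = 1
  ab <- stats::setNames(c(1, 2, 3, 4, 5, 6), paste0("s", 1:6))
  ph <- data.frame(sample_id = paste0("s", 1:6), viability = 10 + 5 * (1:6))
  exact <- phenotype_correlation(ab, ph, "viability")
  expect_equal(exact$rho, 1)
  expect_equal(exact$n, 6)
  expect_error(
    phenotype_correlation(ab, ph, "motility"), "motility",
    class = "cryomics_domain_error"
  )

  hits <- vapply(1:100, function(s) {
    sim <- generate_paired_omics(sim_config(seed = s))
    x <- log2(sim$genes$values[sim$truth$consensus_candidate, ])
    phenotype_correlation(x, sim$phenotype, "viability")$rho > 0.9
  }, TRUE)
  expect_gte(mean(hits), 0.9)

  # shuffling the sample pairing destroys the correlation on average
  sim <- generate_paired_omics(sim_config(seed = 123))
  x <- log2(sim$genes$values[sim$truth$consensus_candidate, ])
  shuffled <- withr::with_seed(55, vapply(1:200, function(i) {
    names(x) <- sample(names(x))
    phenotype_correlation(x, sim$phenotype, "viability")$rho
  }, 0))
  expect_lt(abs(mean(shuffled)), 0.15)
})
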