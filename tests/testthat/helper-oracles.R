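# Fixture builders and independent oracle implementations used across the
# suite. The oracles deliberately use a different computational route from
# the package (explicit loops, exhaustive enumeration) so that agreement is
# evidence, not tautology.

# Small two-group expression matrix; `fs`/`ps` are features x n matrices or
# vectors recycled per feature.
make_em <- function(fs, ps, feature_ids = NULL) {
  fs <- as.matrix(fs)
  ps <- as.matrix(ps)
  if (is.null(feature_ids)) feature_ids <- sprintf("f%02d", seq_len(nrow(fs)))
  vals <- cbind(fs, ps)
  dimnames(vals) <- list(
    feature_ids,
    c(sprintf("FS_%d", seq_len(ncol(fs))), sprintf("PS_%d", seq_len(ncol(ps))))
  )
  groups <- stats::setNames(
    rep(c("FS", "PS"), c(ncol(fs), ncol(ps))), colnames(vals)
  )
  expression_matrix(vals, groups)
}

# Brute-force BH step-up: for every rank position take the minimum of
# p_(j) * m / j over all positions j at or above it, capped at 1.
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (pos in seq_len(m)) {
    cands <- vapply(pos:m, function(j) min(1, p[ord[j]] * m / j), 0)
    adj[ord[pos]] <- min(cands)
  }
  adj
}

# Exhaustive hypergeometric upper tail: enumerate every n-subset of 1..N and
# count how often its overlap with 1..K reaches k.
hyper_brute <- function(k, K, N, n) {
  if (k <= 0) return(1)
  if (n == 0) return(0)
  subsets <- utils::combn(N, n)
  overlap <- colSums(subsets <= K)
  mean(overlap >= k)
}

# Hand-enumerated GSEA running sum: explicit walk down the ranked list.
es_brute <- function(scores, members, weight) {
  ord <- order(-scores, names(scores))
  s <- scores[ord]
  hit <- names(s) %in% members
  s <- unname(s)
  N <- length(s)
  K <- sum(hit)
  denom <- sum(abs(s[hit])^weight)
  run <- 0
  best <- 0
  for (i in seq_len(N)) {
    run <- run + if (hit[i]) {
      if (denom > 0) abs(s[i])^weight / denom else 1 / K
    } else {
      -1 / (N - K)
    }
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# Latent-dominated simulation: planted cross-omics pairs dominate the shared
# variation (weak group effects), used for the O2PLS recovery properties.
latent_fixture_config <- function(seed, n_per_group = 3, n_genes = 60,
                                  n_proteins = 40) {
  sim_config(
    n_genes = n_genes, n_proteins = n_proteins,
    n_shared_ids = min(30, n_proteins), n_per_group = n_per_group,
    gene_effect_log2 = 0.2, protein_effect_log2 = 0.2,
    n_de_genes = 2, n_de_proteins = 2, latent_rho = 0.9,
    n_planted_pairs = 8, pathway_size = 5, noise_sd_log2 = 0.2, seed = seed
  )
}
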