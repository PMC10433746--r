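# Synthetic paired transcriptome-proteome generator with known planted truth.
#
# The generator emulates the study conditions of a 3-vs-3 paired fresh (FS)
# versus programmed-freezing (PS) design: log-normal abundances (Gaussian on
# the log2 scale), planted group effects on a subset of genes and proteins,
# cross-omics correlated pairs driven by a shared per-sample latent factor,
# one pathway enriched in both omics, and a phenotype (motility/viability)
# linearly tied to the planted consensus candidate. Every downstream screen
# can therefore be validated against a recoverable ground truth.

#' Simulation configuration
#'
#' Defaults mirror the study design scaled to desk size: 3 samples per group,
#' 500 genes of which 22 are differential (matching the observed differential
#' rate of roughly 4.4%), 300 proteins of which 9 are differential (roughly
#' 3%), planted log2 effects of 2.0 (genes) and 0.6 (proteins) so both clear
#' their calling gates (1 and 0.263), a planted pathway of 20 members, and 8
#' cross-omics pairs targeting a correlation of 0.95. The log2 noise standard
#' deviation of 0.05 reflects the high precision of TMT reporter ratios and
#' keeps the pinned protein effect detectable at n = 3 under BH control; it
#' understates biological RNA-seq noise (see the package vignette).
#'
#' @param n_genes,n_proteins Feature counts per block.
#' @param n_shared_ids Number of proteins with an id-map entry to a gene
#'   (proteins `1..n_shared_ids` pair with genes `1..n_shared_ids`).
#' @param n_per_group Samples per group (default 3).
#' @param gene_effect_log2,protein_effect_log2 Planted absolute log2
#'   fold-change magnitudes.
#' @param n_de_genes,n_de_proteins Numbers of differential features
#'   (including the consensus candidate in both).
#' @param latent_rho Target cross-omics Pearson correlation for planted pairs,
#'   in \[0, 1).
#' @param n_planted_pairs Number of latent-factor-coupled gene-protein pairs
#'   (the first is the consensus candidate).
#' @param pathway_size Size of the planted pathway.
#' @param noise_sd_log2 Gaussian noise SD on the log2 scale (>= 0).
#' @param seed Integer seed; all stochastic draws flow from this single
#'   generator state.
#' @return A validated `SimConfig` list.
#' @export
sim_config <- function(n_genes = 500, n_proteins = 300, n_shared_ids = 250,
                       n_per_group = 3, gene_effect_log2 = 2.0,
                       protein_effect_log2 = 0.6, n_de_genes = 22,
                       n_de_proteins = 9, latent_rho = 0.95,
                       n_planted_pairs = 8, pathway_size = 20,
                       noise_sd_log2 = 0.05, seed = 1) {
  cfg <- list(
    n_genes = n_genes, n_proteins = n_proteins, n_shared_ids = n_shared_ids,
    n_per_group = n_per_group, gene_effect_log2 = gene_effect_log2,
    protein_effect_log2 = protein_effect_log2, n_de_genes = n_de_genes,
    n_de_proteins = n_de_proteins, latent_rho = latent_rho,
    n_planted_pairs = n_planted_pairs, pathway_size = pathway_size,
    noise_sd_log2 = noise_sd_log2, seed = seed
  )
  for (nm in c(
    "n_genes", "n_proteins", "n_shared_ids", "n_per_group", "n_de_genes",
    "n_de_proteins", "n_planted_pairs", "pathway_size"
  )) {
    if (!is_count(cfg[[nm]])) {
      cry_abort(sprintf("invariant violated: %s must be an integer >= 1", nm), "config")
    }
  }
  if (cfg$n_shared_ids > min(cfg$n_genes, cfg$n_proteins)) {
    cry_abort("invariant violated: n_shared_ids <= min(n_genes, n_proteins)", "config")
  }
  if (cfg$n_de_genes > cfg$n_genes) {
    cry_abort("invariant violated: n_de_genes <= n_genes", "config")
  }
  if (cfg$n_de_proteins > cfg$n_proteins) {
    cry_abort("invariant violated: n_de_proteins <= n_proteins", "config")
  }
  if (!is_scalar_num(cfg$latent_rho) || cfg$latent_rho < 0 || cfg$latent_rho >= 1) {
    cry_abort("invariant violated: latent_rho must lie in [0, 1)", "config")
  }
  if (!is_scalar_num(cfg$noise_sd_log2) || cfg$noise_sd_log2 < 0) {
    cry_abort("invariant violated: noise_sd_log2 must be >= 0", "config")
  }
  if (!is_scalar_num(cfg$gene_effect_log2) || !is_scalar_num(cfg$protein_effect_log2)) {
    cry_abort("effect sizes must be finite numbers", "config")
  }
  if (!is_count(abs(cfg$seed) + 1)) cry_abort("seed must be an integer", "config")
  layout_indices(cfg) # validates that the planted layout fits
  structure(cfg, class = "SimConfig")
}

# Fractions of up-regulated features among the differential ones, taken from
# the observed study-scale rates; pathway members are planted down-regulated
# (the cryo-response direction of the candidate's pathway).
UP_FRACTION_GENES <- 45 / 336
UP_FRACTION_PROTEINS <- 30 / 78
N_DECOY_SETS <- 9
PHENOTYPE_BETA <- 22 # percentage points per log2 unit of candidate abundance
PHENOTYPE_NOISE_SD <- 1.5
PHENOTYPE_TARGET_FS <- c(motility = 82.6, viability = 89.5)

# Deterministic index layout of the planted structure. Gene i pairs with
# protein i for i <= n_shared_ids.
#   gene/protein 1                         : consensus candidate (DE both)
#   genes/proteins 2..n_planted_pairs      : non-DE latent-coupled pairs
#   proteins np+1 .. np+n_de_proteins-1    : non-candidate DE proteins
#   genes (top of the range)               : non-candidate DE genes (no map)
#   pathway = candidate + some DE genes + some DE-protein genes + fillers
layout_indices <- function(cfg) {
  np <- cfg$n_planted_pairs
  if (np > cfg$n_shared_ids) {
    cry_abort("invariant violated: n_planted_pairs <= n_shared_ids", "config")
  }
  dep_idx <- c(1, if (cfg$n_de_proteins > 1) np + seq_len(cfg$n_de_proteins - 1))
  if (max(dep_idx) > cfg$n_shared_ids) {
    cry_abort("layout does not fit: n_planted_pairs + n_de_proteins - 1 must be <= n_shared_ids", "config")
  }
  deg_idx <- c(1, if (cfg$n_de_genes > 1) {
    (cfg$n_genes - cfg$n_de_genes + 2):cfg$n_genes
  })
  n_pw_deg <- min(cfg$n_de_genes - 1, ceiling((cfg$pathway_size - 1) * 0.35))
  n_pw_dep <- min(cfg$n_de_proteins - 1, ceiling((cfg$pathway_size - 1) * 0.25))
  overshoot <- n_pw_deg + n_pw_dep - (cfg$pathway_size - 1)
  if (overshoot > 0) {
    cut <- min(n_pw_deg, overshoot)
    n_pw_deg <- n_pw_deg - cut
    n_pw_dep <- n_pw_dep - (overshoot - cut)
  }
  n_fill <- cfg$pathway_size - 1 - n_pw_deg - n_pw_dep
  fill_start <- np + cfg$n_de_proteins
  fill_idx <- if (n_fill > 0) fill_start + seq_len(n_fill) - 1 else integer()
  pw_idx <- c(
    1,
    if (n_pw_deg > 0) deg_idx[-1][seq_len(n_pw_deg)],
    if (n_pw_dep > 0) dep_idx[-1][seq_len(n_pw_dep)],
    fill_idx
  )
  if (length(fill_idx) && max(fill_idx) >= min(deg_idx[-1], cfg$n_genes + 1)) {
    cry_abort("layout does not fit: pathway fillers collide with the DE gene block", "config")
  }
  if (anyDuplicated(pw_idx)) {
    cry_abort("layout does not fit: pathway member indices collide", "config")
  }
  list(
    candidate = 1L, pair_idx = seq_len(np), dep_idx = dep_idx,
    deg_idx = deg_idx, pathway_idx = sort(pw_idx)
  )
}

# Latent loading for one planted pair: smallest lambda >= 0 such that the
# model correlation (group response + shared latent + noise) meets the
# target. For non-differential pairs this is the closed form
# sigma * sqrt(r / (1 - r)); for differential pairs the group response may
# already exceed the target, in which case lambda = 0.
pair_lambda <- function(a_g, a_p, sigma, r) {
  if (sigma == 0 || r == 0) return(0)
  model_rho <- function(l) {
    (a_g * a_p + l^2) /
      sqrt((a_g^2 + l^2 + sigma^2) * (a_p^2 + l^2 + sigma^2))
  }
  if (a_g == 0 && a_p == 0) return(sigma * sqrt(r / (1 - r)))
  if (model_rho(0) >= r) return(0)
  upper <- sigma * sqrt(r / (1 - r)) + abs(a_g) + abs(a_p) + 1
  while (model_rho(upper) < r) upper <- upper * 2
  stats::uniroot(function(l) model_rho(l) - r, c(0, upper), tol = 1e-12)$root
}

#' Generate a paired synthetic transcriptome-proteome data set
#'
#' Log2-scale abundances are `baseline + group effect (planted features) +
#' latent factor (planted pairs) + Gaussian noise`; matrices are returned on
#' the raw scale (`2^log2value`). The per-sample latent factor is centered
#' within each group, so planted group-mean effects are realized exactly at
#' zero noise. The phenotype (motility and viability percentages) is
#' `intercept + beta * candidate log2 abundance + noise`, with intercepts
#' anchoring the fresh group near typical fresh-semen values. Identical
#' configurations and seeds yield identical output.
#'
#' @param config A [sim_config()].
#' @return A `PairedOmicsSim` list: `genes` and `proteins`
#'   ([expression_matrix()]s), `id_map`, `gene_sets` (the planted pathway plus
#'   decoy sets), `phenotype`, and `truth` (a `SyntheticTruth` list: signed
#'   planted effects `de_genes`/`de_proteins`, `planted_pairs` with target
#'   correlations and realized latent loadings, `planted_pathway`,
#'   `consensus_candidate`, `phenotype_beta`).
#' @details With `noise_sd_log2 = 0` the latent term vanishes (a fractional
#'   target correlation is not representable without noise) and planted
#'   effects are exact. At `latent_rho` near 1 the latent loading grows as
#'   `sigma * sqrt(r / (1 - r))`.
#' @export
generate_paired_omics <- function(config) {
  if (!inherits(config, "SimConfig")) config <- do.call(sim_config, config)
  withr::with_seed(config$seed, generate_paired_omics_impl(config))
}

generate_paired_omics_impl <- function(cfg) {
  lay <- layout_indices(cfg)
  n <- cfg$n_per_group
  sigma <- cfg$noise_sd_log2
  sample_ids <- c(paste0("FS_", seq_len(n)), paste0("PS_", seq_len(n)))
  groups <- stats::setNames(rep(c("FS", "PS"), each = n), sample_ids)
  code <- rep(c(-1, 1), each = n) # PS minus FS group-mean difference = effect

  gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
  protein_ids <- sprintf("P%04d", seq_len(cfg$n_proteins))

  # Signed half-effects on the log2 scale.
  half_g <- numeric(cfg$n_genes)
  half_p <- numeric(cfg$n_proteins)
  sign_of <- function(k, up_fraction) ifelse(stats::runif(k) < up_fraction, 1, -1)
  deg_other <- setdiff(lay$deg_idx, lay$candidate)
  dep_other <- setdiff(lay$dep_idx, lay$candidate)
  half_g[lay$candidate] <- -cfg$gene_effect_log2 / 2
  half_p[lay$candidate] <- -cfg$protein_effect_log2 / 2
  half_g[deg_other] <- sign_of(length(deg_other), UP_FRACTION_GENES) *
    cfg$gene_effect_log2 / 2
  half_p[dep_other] <- sign_of(length(dep_other), UP_FRACTION_PROTEINS) *
    cfg$protein_effect_log2 / 2
  # Pathway members respond coherently (down-regulated after freezing).
  half_g[intersect(deg_other, lay$pathway_idx)] <- -cfg$gene_effect_log2 / 2
  half_p[intersect(dep_other, lay$pathway_idx)] <- -cfg$protein_effect_log2 / 2

  # Shared latent factor, centered within group so it never moves group means.
  latent <- stats::rnorm(2 * n)
  latent <- latent - rep(tapply(latent, groups, mean), each = n)
  lambda <- vapply(lay$pair_idx, function(i) {
    pair_lambda(half_g[i], half_p[i], sigma, cfg$latent_rho)
  }, 0)

  baseline_g <- stats::runif(cfg$n_genes, 3, 10)
  baseline_p <- stats::runif(cfg$n_proteins, 3, 10)

  build_block <- function(n_feat, baseline, half, ids) {
    L <- matrix(baseline, n_feat, 2 * n) +
      outer(half, code) +
      matrix(stats::rnorm(n_feat * 2 * n, sd = sigma), n_feat, 2 * n)
    dimnames(L) <- list(ids, sample_ids)
    L
  }
  Lg <- build_block(cfg$n_genes, baseline_g, half_g, gene_ids)
  Lp <- build_block(cfg$n_proteins, baseline_p, half_p, protein_ids)
  for (j in seq_along(lay$pair_idx)) {
    i <- lay$pair_idx[j]
    Lg[i, ] <- Lg[i, ] + lambda[j] * latent
    Lp[i, ] <- Lp[i, ] + lambda[j] * latent
  }

  genes <- expression_matrix(2^Lg, groups)
  proteins <- expression_matrix(2^Lp, groups)
  map <- id_map(
    gene_ids[seq_len(cfg$n_shared_ids)],
    protein_ids[seq_len(cfg$n_shared_ids)]
  )

  pathway_members <- gene_ids[lay$pathway_idx]
  decoys <- lapply(seq_len(N_DECOY_SETS), function(i) {
    sort(sample(gene_ids, cfg$pathway_size))
  })
  sets <- gene_set_collection(
    c(list(planted_pathway = pathway_members),
      stats::setNames(decoys, sprintf("decoy_set_%02d", seq_len(N_DECOY_SETS)))
    ),
    descriptions = c(
      planted_pathway = "pathway planted with coherent differential members in both omics",
      stats::setNames(
        rep("random decoy set", N_DECOY_SETS),
        sprintf("decoy_set_%02d", seq_len(N_DECOY_SETS))
      )
    )
  )

  # Phenotype tied linearly to the candidate's log2 abundance.
  x_cand <- Lg[lay$candidate, ]
  fs_expected <- baseline_g[lay$candidate] - half_g[lay$candidate] # code = -1 in FS
  pheno <- data.frame(sample_id = sample_ids, stringsAsFactors = FALSE)
  intercepts <- numeric(0)
  for (ph in names(PHENOTYPE_TARGET_FS)) {
    intercept <- PHENOTYPE_TARGET_FS[[ph]] - PHENOTYPE_BETA * fs_expected
    intercepts[ph] <- intercept
    val <- intercept + PHENOTYPE_BETA * x_cand +
      stats::rnorm(2 * n, sd = PHENOTYPE_NOISE_SD)
    pheno[[ph]] <- pmin(100, pmax(0, val))
  }
  pheno <- validate_phenotype(pheno)

  truth <- structure(list(
    de_genes = stats::setNames(2 * half_g[lay$deg_idx], gene_ids[lay$deg_idx]),
    de_proteins = stats::setNames(2 * half_p[lay$dep_idx], protein_ids[lay$dep_idx]),
    planted_pairs = data.frame(
      gene_id = gene_ids[lay$pair_idx],
      protein_id = protein_ids[lay$pair_idx],
      target_rho = cfg$latent_rho, lambda = lambda,
      stringsAsFactors = FALSE
    ),
    planted_pathway = list(name = "planted_pathway", members = pathway_members),
    consensus_candidate = gene_ids[lay$candidate],
    consensus_candidate_protein = protein_ids[lay$candidate],
    phenotype_beta = PHENOTYPE_BETA,
    phenotype_intercepts = intercepts,
    phenotype_noise_sd = PHENOTYPE_NOISE_SD
  ), class = "SyntheticTruth")

  structure(list(
    genes = genes, proteins = proteins, id_map = map, gene_sets = sets,
    phenotype = pheno, truth = truth, config = cfg
  ), class = "PairedOmicsSim")
}

#' Validate a simulation against its planted truth
#'
#' Checks that realized group-mean log2 differences match the planted signed
#' effects within `tolerance` for every differential gene and protein, and
#' that the consensus candidate is a member of every truth set (differential
#' genes, differential proteins via the id map, planted pathway, planted
#' pairs).
#'
#' @param sim A [generate_paired_omics()] result.
#' @param tolerance Allowed absolute deviation between realized and planted
#'   log2 effects.
#' @param truth Truth object to validate against; defaults to the
#'   simulation's own. Supplying an edited truth turns this into a negative
#'   control.
#' @return Data frame with columns `check`, `feature`, `expected`, `observed`,
#'   `pass`; attribute `pass_rate` gives the fraction of passing checks.
#' @export
validate_truth <- function(sim, tolerance = 0.1, truth = sim$truth) {
  stopifnot(inherits(sim, "PairedOmicsSim"))
  missing_ids <- c(
    setdiff(names(truth$de_genes), rownames(sim$genes$values)),
    setdiff(names(truth$de_proteins), rownames(sim$proteins$values))
  )
  if (length(missing_ids)) {
    cry_abort(sprintf(
      "truth names feature(s) absent from the matrices: %s",
      paste(missing_ids, collapse = ", ")
    ), "validation")
  }
  realized <- function(x) {
    idx <- split(seq_along(x$groups), x$groups)
    L <- log2(x$values)
    rowMeans(L[, idx$PS, drop = FALSE]) - rowMeans(L[, idx$FS, drop = FALSE])
  }
  rg <- realized(sim$genes)
  rp <- realized(sim$proteins)
  effect_rows <- function(check, effects, realized_fc) {
    data.frame(
      check = check, feature = names(effects), expected = unname(effects),
      observed = unname(realized_fc[names(effects)]),
      pass = abs(unname(realized_fc[names(effects)]) - unname(effects)) <= tolerance,
      stringsAsFactors = FALSE
    )
  }
  cand <- truth$consensus_candidate
  cand_prot <- map_gene_to_protein(cand, sim$id_map)
  member_rows <- data.frame(
    check = c(
      "candidate_in_de_genes", "candidate_in_de_proteins",
      "candidate_in_pathway", "candidate_in_planted_pairs"
    ),
    feature = cand,
    expected = 1,
    observed = as.numeric(c(
      cand %in% names(truth$de_genes),
      !is.na(cand_prot) && cand_prot %in% names(truth$de_proteins),
      cand %in% truth$planted_pathway$members,
      cand %in% truth$planted_pairs$gene_id
    )),
    stringsAsFactors = FALSE
  )
  member_rows$pass <- member_rows$observed == 1
  out <- rbind(
    effect_rows("gene_effect", truth$de_genes, rg),
    effect_rows("protein_effect", truth$de_proteins, rp),
    member_rows
  )
  rownames(out) <- NULL
  attr(out, "pass_rate") <- mean(out$pass)
  attr(out, "all_pass") <- all(out$pass)
  out
}

#' Write a simulated data set to disk
#'
#' Writes the gene and protein matrices, group labels, id map, gene sets
#' (GMT), phenotype table (all TSV) and the truth object (JSON) into a
#' directory.
#'
#' @param sim A [generate_paired_omics()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_paired_omics <- function(sim, dir) {
  stopifnot(inherits(sim, "PairedOmicsSim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genes = file.path(dir, "genes.tsv"),
    proteins = file.path(dir, "proteins.tsv"),
    groups = file.path(dir, "groups.tsv"),
    id_map = file.path(dir, "id_map.tsv"),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    phenotype = file.path(dir, "phenotype.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_expression_matrix(sim$genes, paths["genes"])
  write_expression_matrix(sim$proteins, paths["proteins"])
  utils::write.table(
    data.frame(
      sample_id = names(sim$genes$groups),
      group = as.character(sim$genes$groups)
    ),
    paths["groups"], sep = "\t", quote = FALSE, row.names = FALSE
  )
  write_id_map(sim$id_map, paths["id_map"])
  write_gmt(sim$gene_sets, paths["gene_sets"])
  write_phenotype(sim$phenotype, paths["phenotype"])
  truth <- sim$truth
  truth_json <- list(
    de_genes = as.list(truth$de_genes),
    de_proteins = as.list(truth$de_proteins),
    planted_pairs = truth$planted_pairs,
    planted_pathway = truth$planted_pathway,
    consensus_candidate = truth$consensus_candidate,
    consensus_candidate_protein = truth$consensus_candidate_protein,
    phenotype_beta = truth$phenotype_beta
  )
  jsonlite::write_json(truth_json, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
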