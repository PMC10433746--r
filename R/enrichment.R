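# Over-representation analysis (exact hypergeometric upper tail), co-enrichment
# over the combined DEG/DEP selection in gene-id space, and a weighted
# Kolmogorov-Smirnov gene set enrichment statistic with a feature-relabeling
# permutation null.

# Exact hypergeometric upper tail P(X >= k) for overlap k, set size K,
# universe size N, selection size n.
hyper_tail <- function(k, K, N, n) {
  if (k <= 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis against a gene set collection
#'
#' For each set, tests whether the selected features overlap the set more than
#' expected by chance within the universe, using the exact hypergeometric
#' upper tail `P(X >= k)`. Sets are intersected with the universe before
#' testing; BH adjustment is applied across sets.
#'
#' @param selected Character vector of selected feature ids (e.g. differential
#'   features). Must be a subset of `universe`.
#' @param universe Character vector of all quantified feature ids (the
#'   enrichment background).
#' @param sets A [gene_set_collection()].
#' @return Data frame sorted by p-value with columns `set`, `k` (overlap), `K`
#'   (set size in universe), `n` (selection size), `N` (universe size),
#'   `p_hyper`, `fdr`, `members_hit` (comma-separated).
#' @export
ora <- function(selected, universe, sets) {
  stopifnot(inherits(sets, "GeneSetCollection"))
  selected <- unique(as.character(selected))
  universe <- unique(as.character(universe))
  outside <- setdiff(selected, universe)
  if (length(outside)) {
    cry_abort(sprintf(
      "selected feature(s) not in universe: %s", paste(outside, collapse = ", ")
    ), "domain")
  }
  N <- length(universe)
  n <- length(selected)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], universe)
    hit <- intersect(members, selected)
    k <- length(hit)
    data.frame(
      set = nm, k = k, K = length(members), n = n, N = N,
      p_hyper = hyper_tail(k, length(members), N, n),
      members_hit = paste(sort(hit), collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p_hyper)
  out <- out[order(out$p_hyper, out$set), c(
    "set", "k", "K", "n", "N", "p_hyper", "fdr", "members_hit"
  )]
  rownames(out) <- NULL
  out
}

#' Co-enrichment of differential genes and proteins in gene-id space
#'
#' Maps differential proteins to gene ids through the id map, forms the union
#' selection (DEGs plus mapped DEPs) and the union universe (quantified genes
#' plus mapped quantified proteins), and runs [ora()]. Each set additionally
#' reports which hits came from the gene side and which from the protein
#' side. Proteins without an id-map entry are excluded and recorded in the
#' `dropped_proteins` attribute.
#'
#' @param deg_ids Character vector of differential gene ids.
#' @param dep_ids Character vector of differential protein ids.
#' @param map An [id_map()].
#' @param sets A [gene_set_collection()] in gene-id space.
#' @param gene_universe Quantified gene ids.
#' @param protein_universe Quantified protein ids.
#' @param alpha Raw p-value significance gate for the `significant` column
#'   (default 0.05; an FDR column is still emitted).
#' @return The [ora()] table plus columns `gene_hits`, `protein_hits`,
#'   `significant`; attribute `dropped_proteins` lists unmapped protein ids.
#'   An empty selection yields an empty result with a warning.
#' @export
co_ora <- function(deg_ids, dep_ids, map, sets, gene_universe,
                   protein_universe, alpha = 0.05) {
  mapped_dep <- map_protein_to_gene(dep_ids, map)
  mapped_uni <- map_protein_to_gene(protein_universe, map)
  dropped <- unique(c(
    names(mapped_dep)[is.na(mapped_dep)],
    names(mapped_uni)[is.na(mapped_uni)]
  ))
  dep_genes <- unname(mapped_dep[!is.na(mapped_dep)])
  selection <- union(deg_ids, dep_genes)
  universe <- union(gene_universe, unname(mapped_uni[!is.na(mapped_uni)]))
  if (length(selection) == 0) {
    warning("empty DEG/DEP union; returning empty co-enrichment table")
    out <- ora(character(), universe, sets)[0, ]
    out$gene_hits <- out$protein_hits <- character(0)
    out$significant <- logical(0)
    attr(out, "dropped_proteins") <- dropped
    return(out)
  }
  out <- ora(selection, universe, sets)
  out$gene_hits <- vapply(out$set, function(nm) {
    paste(sort(intersect(intersect(sets[[nm]], universe), deg_ids)), collapse = ",")
  }, "")
  out$protein_hits <- vapply(out$set, function(nm) {
    paste(sort(intersect(intersect(sets[[nm]], universe), dep_genes)), collapse = ",")
  }, "")
  out$significant <- out$p_hyper < alpha
  attr(out, "dropped_proteins") <- dropped
  out
}

# Weighted KS running-sum enrichment score for hit positions `hit` (logical
# over the ranked list) given |score|^weight increments; misses decrement by
# 1/(N - K). Returns the signed extremum and its position.
gsea_es <- function(abs_w, hit) {
  N <- length(abs_w)
  K <- sum(hit)
  denom <- sum(abs_w[hit])
  inc <- if (N > K) rep(-1 / (N - K), N) else rep(0, N)
  inc[hit] <- if (denom > 0) abs_w[hit] / denom else 1 / K
  run <- cumsum(inc)
  i <- which.max(abs(run))
  list(es = run[i], peak = i)
}

#' Gene set enrichment analysis over a ranked feature list
#'
#' Classic weighted Kolmogorov-Smirnov running-sum statistic: walking down the
#' ranking, set members increment the sum proportionally to
#' `|score|^weight` (normalized over the set) and non-members decrement it by
#' `1/(N - K)`; the enrichment score ES is the signed extremum. The null is
#' built by relabeling set membership (drawing random sets of the same size
#' from the ranked features), appropriate for designs whose sample size admits
#' too few phenotype permutations. `NES` divides ES by the mean |ES| of
#' same-sign null draws; the permutation p-value uses add-one smoothing,
#' `p = (1 + #(null at least as extreme, same sign)) / (n_perm + 1)`, so it is
#' never zero.
#'
#' @param scores Named numeric vector of per-feature ranking scores (e.g.
#'   signed log2 fold change); no duplicated names. Features are ranked by
#'   decreasing score, ties broken by feature id for determinism.
#' @param sets A [gene_set_collection()].
#' @param n_perm Number of permutations (at least 100; default 999).
#' @param weight Score weight exponent; `1` is the classic weighted statistic,
#'   `0` makes the ES rank-only (invariant to monotone score rescaling).
#' @param seed Optional integer seed making the permutation null reproducible.
#' @return Data frame with columns `set`, `size`, `es`, `nes`, `p_perm`,
#'   `leading_edge` (comma-separated). Sets with no ranked members are skipped
#'   with a warning.
#' @export
gsea <- function(scores, sets, n_perm = 999, weight = 1, seed = NULL) {
  stopifnot(inherits(sets, "GeneSetCollection"))
  if (is.null(names(scores)) || anyDuplicated(names(scores))) {
    cry_abort("scores must be uniquely named by feature id", "domain")
  }
  if (!is_count(n_perm) || n_perm < 100) {
    cry_abort("n_perm must be an integer >= 100", "domain")
  }
  ord <- order(-scores, names(scores))
  s <- scores[ord]
  nm <- names(s)
  N <- length(s)
  abs_w <- abs(s)^weight
  run_one <- function(nm_set) {
    members <- intersect(sets[[nm_set]], nm)
    K <- length(members)
    if (K == 0) {
      warning(sprintf("set '%s' has no ranked members; skipped", nm_set))
      return(NULL)
    }
    hit <- nm %in% members
    obs <- gsea_es(abs_w, hit)
    null_es <- vapply(seq_len(n_perm), function(i) {
      h <- logical(N)
      h[sample.int(N, K)] <- TRUE
      gsea_es(abs_w, h)$es
    }, 0)
    same_sign <- if (obs$es >= 0) null_es >= 0 else null_es < 0
    extreme <- if (obs$es >= 0) null_es >= obs$es else null_es <= obs$es
    nes <- if (any(same_sign)) obs$es / mean(abs(null_es[same_sign])) else NA_real_
    le <- if (obs$es >= 0) {
      nm[seq_len(obs$peak)][hit[seq_len(obs$peak)]]
    } else {
      nm[obs$peak:N][hit[obs$peak:N]]
    }
    data.frame(
      set = nm_set, size = K, es = obs$es, nes = nes,
      p_perm = (1 + sum(extreme)) / (n_perm + 1),
      leading_edge = paste(le, collapse = ","), stringsAsFactors = FALSE
    )
  }
  runner <- function() do.call(rbind, Filter(Negate(is.null), lapply(names(sets), run_one)))
  out <- if (is.null(seed)) runner() else withr::with_seed(seed, runner())
  if (is.null(out)) {
    out <- data.frame(
      set = character(), size = integer(), es = numeric(), nes = numeric(),
      p_perm = numeric(), leading_edge = character(), stringsAsFactors = FALSE
    )
  }
  rownames(out) <- NULL
  out
}
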