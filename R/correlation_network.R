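# Bipartite Pearson correlation network between pathway-enriched differential
# genes and proteins across matched samples, degree ranking of gene hubs, and
# phenotype-candidate correlation.

#' Pearson correlation with a t-based two-sided p-value
#'
#' Sample Pearson correlation with the two-sided p-value from
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#' Exactly collinear inputs (`|rho| = 1`) are assigned p = 0. Zero-variance
#' input is an error (the correlation is undefined), not rho = 0.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`.
#' @return List with elements `rho` and `p`.
#' @examples
#' pearson(c(1, 2, 3), c(2, 4, 6)) # rho = 1, p = 0
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) cry_abort("x and y must have equal length", "domain")
  n <- length(x)
  if (n < 3) cry_abort("at least 3 paired observations are required", "domain")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    cry_abort("inputs must be finite", "domain")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    cry_abort("correlation undefined: zero variance input", "undefined_correlation")
  }
  rho <- stats::cor(x, y)
  rho <- max(-1, min(1, rho))
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tval), n - 2)
  }
  list(rho = rho, p = p)
}

#' Bipartite gene-protein correlation network
#'
#' Tests every gene x protein pair across the matched samples (all samples
#' pooled over groups, by design: the screen correlates per-sample abundance,
#' not within-group residuals) and keeps edges passing both gates strictly:
#' `|rho| > rho_threshold` and `p < alpha`. Edge p-values are not
#' multiplicity-adjusted by default, matching the raw-gate convention of this
#' screen; set `adjust = TRUE` to gate on BH-adjusted values instead.
#' Abundances are log2-transformed before correlation by default. Features
#' with zero variance are dropped (correlation undefined) and recorded in the
#' `dropped` attribute.
#'
#' @param gene_x An [expression_matrix()] of the gene rows to test (typically
#'   pathway-enriched differential genes).
#' @param protein_x An [expression_matrix()] of the protein rows to test, with
#'   identical sample ids in identical order.
#' @param rho_threshold Absolute correlation gate (default 0.8).
#' @param alpha P-value gate (default 0.05).
#' @param log2_scale Correlate `log2(value + eps)` (default) or raw values.
#' @param eps Pseudocount for the log transform.
#' @param adjust Gate on BH-adjusted p-values across all tested pairs.
#' @return A `BipartiteNetwork`: list with `edges` (data frame `gene_id`,
#'   `protein_id`, `rho`, `p`), `gene_ids`, `protein_ids`, `degree_gene`,
#'   `degree_protein`, `n_samples`, `params`.
#' @export
build_network <- function(gene_x, protein_x, rho_threshold = 0.8, alpha = 0.05,
                          log2_scale = TRUE, eps = 1e-3, adjust = FALSE) {
  stopifnot(inherits(gene_x, "ExpressionMatrix"), inherits(protein_x, "ExpressionMatrix"))
  gs <- colnames(gene_x$values)
  ps <- colnames(protein_x$values)
  if (!identical(gs, ps)) {
    cry_abort("gene and protein blocks must share identical sample ids in identical order", "alignment")
  }
  n <- length(gs)
  if (n < 3) cry_abort("at least 3 matched samples are required", "domain")
  G <- gene_x$values
  P <- protein_x$values
  if (log2_scale) {
    G <- log2(G + eps)
    P <- log2(P + eps)
  }
  sd_g <- apply(G, 1, stats::sd)
  sd_p <- apply(P, 1, stats::sd)
  dropped <- c(
    if (any(sd_g == 0)) paste0(rownames(G)[sd_g == 0], " (zero variance)"),
    if (any(sd_p == 0)) paste0(rownames(P)[sd_p == 0], " (zero variance)")
  )
  G <- G[sd_g > 0, , drop = FALSE]
  P <- P[sd_p > 0, , drop = FALSE]
  edges <- data.frame(
    gene_id = character(), protein_id = character(),
    rho = numeric(), p = numeric(), stringsAsFactors = FALSE
  )
  if (nrow(G) > 0 && nrow(P) > 0) {
    R <- stats::cor(t(G), t(P))
    R[R > 1] <- 1
    R[R < -1] <- -1
    pmat <- matrix(0, nrow(R), ncol(R), dimnames = dimnames(R))
    inner <- abs(R) < 1
    tv <- R[inner] * sqrt((n - 2) / (1 - R[inner]^2))
    pmat[inner] <- 2 * stats::pt(-abs(tv), n - 2)
    gate_p <- if (adjust) matrix(bh_adjust(as.vector(pmat)), nrow(pmat)) else pmat
    keep <- which(abs(R) > rho_threshold & gate_p < alpha, arr.ind = TRUE)
    if (nrow(keep)) {
      edges <- data.frame(
        gene_id = rownames(R)[keep[, 1]],
        protein_id = colnames(R)[keep[, 2]],
        rho = R[keep], p = pmat[keep], stringsAsFactors = FALSE
      )
      edges <- edges[order(edges$gene_id, edges$protein_id), ]
      rownames(edges) <- NULL
    }
  }
  deg_g <- table(factor(edges$gene_id, levels = rownames(gene_x$values)))
  deg_p <- table(factor(edges$protein_id, levels = rownames(protein_x$values)))
  structure(list(
    edges = edges,
    gene_ids = rownames(gene_x$values),
    protein_ids = rownames(protein_x$values),
    degree_gene = stats::setNames(as.integer(deg_g), names(deg_g)),
    degree_protein = stats::setNames(as.integer(deg_p), names(deg_p)),
    n_samples = n,
    params = list(
      rho_threshold = rho_threshold, alpha = alpha,
      log2_scale = log2_scale, eps = eps, adjust = adjust
    ),
    dropped = dropped
  ), class = "BipartiteNetwork")
}

#' @export
print.BipartiteNetwork <- function(x, ...) {
  cat(sprintf(
    "BipartiteNetwork: %d gene(s) x %d protein(s), %d significant edge(s) (|rho| > %g, p < %g)\n",
    length(x$gene_ids), length(x$protein_ids), nrow(x$edges),
    x$params$rho_threshold, x$params$alpha
  ))
  invisible(x)
}

#' Rank gene nodes by network degree
#'
#' Genes with at least one significant edge, sorted by degree descending with
#' lexicographic tie-break, truncated to `top_n`.
#'
#' @param network A [build_network()] result.
#' @param top_n Number of genes to return (default 5).
#' @return Data frame with columns `gene_id`, `degree`.
#' @export
degree_ranking <- function(network, top_n = 5) {
  stopifnot(inherits(network, "BipartiteNetwork"))
  deg <- network$degree_gene[network$degree_gene > 0]
  if (length(deg) == 0) {
    return(data.frame(gene_id = character(), degree = integer(), stringsAsFactors = FALSE))
  }
  ord <- order(-deg, names(deg))
  out <- data.frame(
    gene_id = names(deg)[ord], degree = as.integer(deg[ord]),
    stringsAsFactors = FALSE
  )
  utils::head(out, top_n)
}

#' Correlate a feature's abundance with a phenotype column
#'
#' Aligns per-sample abundance with a phenotype measurement by sample id and
#' delegates to [pearson()].
#'
#' @param abundance Named numeric vector of per-sample abundance (names are
#'   sample ids).
#' @param phenotype A [read_phenotype()] table (or data frame with a
#'   `sample_id` column).
#' @param column Name of the phenotype column to correlate.
#' @return List with elements `rho`, `p`, `n` (matched samples used).
#' @export
phenotype_correlation <- function(abundance, phenotype, column) {
  if (!column %in% names(phenotype)) {
    cry_abort(sprintf("phenotype column '%s' not found", column), "domain")
  }
  common <- intersect(names(abundance), phenotype$sample_id)
  if (length(common) < 3) {
    cry_abort("at least 3 matched samples are required", "domain")
  }
  y <- phenotype[[column]][match(common, phenotype$sample_id)]
  r <- pearson(unname(abundance[common]), y)
  c(r, list(n = length(common)))
}
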