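# Consensus candidate screening: the three method-specific candidate sets
# (co-enrichment, correlation network, O2PLS joint loadings) expressed in
# gene-id space, their pairwise and triple intersections, and the end-to-end
# pipeline wiring differential calling through to the consensus report.

# Canonical spelling table for case-insensitive set algebra: first-seen
# spelling wins.
canonical_ids <- function(...) {
  ids <- unlist(list(...), use.names = FALSE)
  ids <- ids[!is.na(ids)]
  ids[!duplicated(id_key(ids))]
}

canonize <- function(ids, canon) {
  ids <- ids[!is.na(ids)]
  out <- canon[match(unique(id_key(ids)), id_key(canon))]
  sort(out[!is.na(out)])
}

#' Intersect the three method-specific candidate sets
#'
#' Performs exact set algebra on the candidate sets contributed by the
#' co-enrichment screen, the correlation-network screen and the O2PLS screen,
#' after case-insensitive id normalization (spellings may differ between
#' omics). Protein ids in any set may be translated to gene space beforehand
#' via `map`; unmappable ids are excluded and logged.
#'
#' @param set_kegg Gene-space candidate ids from significant co-enriched
#'   pathways.
#' @param set_pearson Gene-space candidate ids carrying at least one
#'   significant network edge (both edge endpoints, proteins mapped).
#' @param set_o2pls Gene-space candidate ids from the top joint loadings.
#' @param map Optional [id_map()]; ids found on the protein side are mapped to
#'   gene space.
#' @param gene_ids Optional character vector of known gene-space ids. When
#'   given, ids that are neither known genes nor mappable proteins are treated
#'   as unmappable: excluded from the sets and listed in `dropped`. Without
#'   it, unrecognized ids pass through as gene-space ids.
#' @param degrees Optional named vector of network degrees (gene space) used
#'   for provenance and ranking.
#' @param loadings Optional named vector of maximum absolute joint loadings
#'   (gene space).
#' @return A `ConsensusReport`: list with `sets` (the three normalized sets),
#'   `pairwise` (all three pairwise intersections), `triple`, `provenance`
#'   (per-candidate data frame: screens, degree, loading), and `dropped`
#'   (unmappable ids). All orderings are lexicographic and deterministic.
#' @export
intersect_candidates <- function(set_kegg, set_pearson, set_o2pls, map = NULL,
                                 gene_ids = NULL, degrees = NULL,
                                 loadings = NULL) {
  to_gene_space <- function(ids) {
    if (is.null(map) || length(ids) == 0) return(list(ids = ids, dropped = character()))
    on_protein_side <- id_key(ids) %in% id_key(map$protein_id)
    mapped <- unname(map_protein_to_gene(ids[on_protein_side], map))
    rest <- ids[!on_protein_side]
    dropped <- character()
    if (!is.null(gene_ids)) {
      known <- id_key(rest) %in% id_key(c(gene_ids, map$gene_id))
      dropped <- rest[!known]
      rest <- rest[known]
    }
    list(ids = c(rest, mapped), dropped = dropped)
  }
  k <- to_gene_space(as.character(set_kegg))
  p <- to_gene_space(as.character(set_pearson))
  o <- to_gene_space(as.character(set_o2pls))
  canon <- canonical_ids(k$ids, p$ids, o$ids)
  sets <- list(
    kegg = canonize(k$ids, canon),
    pearson = canonize(p$ids, canon),
    o2pls = canonize(o$ids, canon)
  )
  pairwise <- list(
    kegg_pearson = intersect(sets$kegg, sets$pearson),
    kegg_o2pls = intersect(sets$kegg, sets$o2pls),
    pearson_o2pls = intersect(sets$pearson, sets$o2pls)
  )
  triple <- intersect(pairwise$kegg_pearson, sets$o2pls)
  all_ids <- sort(unique(c(sets$kegg, sets$pearson, sets$o2pls)))
  lookup <- function(v, id) {
    if (is.null(v)) return(NA_real_)
    i <- match(id_key(id), id_key(names(v)))
    if (is.na(i)) NA_real_ else unname(v[i])
  }
  screens <- vapply(all_ids, function(id) {
    paste(c(
      if (id %in% sets$kegg) "kegg",
      if (id %in% sets$pearson) "pearson",
      if (id %in% sets$o2pls) "o2pls"
    ), collapse = "+")
  }, "")
  provenance <- data.frame(
    candidate = all_ids,
    screens = screens,
    n_screens = lengths(strsplit(screens, "+", fixed = TRUE)),
    degree = vapply(all_ids, lookup, 0, v = degrees),
    loading = vapply(all_ids, lookup, 0, v = loadings),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(
    sets = sets, pairwise = pairwise, triple = triple,
    provenance = provenance,
    dropped = sort(unique(c(k$dropped, p$dropped, o$dropped)))
  ), class = "ConsensusReport")
}

#' @export
print.ConsensusReport <- function(x, ...) {
  cat(sprintf(
    "ConsensusReport: |kegg| = %d, |pearson| = %d, |o2pls| = %d; triple intersection: %s\n",
    length(x$sets$kegg), length(x$sets$pearson), length(x$sets$o2pls),
    if (length(x$triple)) paste(x$triple, collapse = ", ") else "(empty)"
  ))
  invisible(x)
}

#' Rank consensus candidates
#'
#' Sort key: number of supporting screens (descending), network degree
#' (descending), maximum absolute joint loading (descending), candidate id
#' (ascending).
#'
#' @param report An [intersect_candidates()] result.
#' @return The provenance data frame ordered by the sort key.
#' @export
rank_candidates <- function(report) {
  stopifnot(inherits(report, "ConsensusReport"))
  pr <- report$provenance
  deg <- ifelse(is.na(pr$degree), -Inf, pr$degree)
  lod <- ifelse(is.na(pr$loading), -Inf, pr$loading)
  pr <- pr[order(-pr$n_screens, -deg, -lod, pr$candidate), ]
  rownames(pr) <- NULL
  pr
}

#' Run the full three-method integration screen
#'
#' Executes the pipeline end to end: differential calling per omics ->
#' single-omics over-representation (to define pathway-enriched features) and
#' co-enrichment in gene space -> bipartite Pearson network between the
#' pathway-enriched differential genes and proteins -> O2PLS on the full
#' quantified blocks with top-k joint loadings -> consensus intersection.
#'
#' @param genes,proteins [expression_matrix()] objects over the same samples.
#' @param map An [id_map()] linking gene and protein ids.
#' @param sets A [gene_set_collection()] in gene-id space.
#' @param gene_lfc_threshold,protein_lfc_threshold Fold-change gates (defaults
#'   1 and 0.263).
#' @param alpha FDR gate for differential calling (default 0.05).
#' @param enrich_alpha Raw-p significance gate for enriched pathways (default
#'   0.05).
#' @param rho_threshold,cor_alpha Correlation-network gates (defaults 0.8 and
#'   0.05).
#' @param top_k Joint-loading candidates per block (default 25).
#' @param n_joint,n_orth_x,n_orth_y O2PLS component counts (defaults 1, 0, 0).
#' @param o2pls_set `"both"` (default) keeps features present in both blocks'
#'   top-k lists (via the id map); `"union"` keeps features from either list.
#' @param eps Pseudocount shared by the fold-change/log transforms.
#' @return A list with every intermediate (`deg_table`, `dep_table`,
#'   `gene_ora`, `protein_ora`, `co_enrichment`, `network`, `degree_ranking`,
#'   `o2pls_model`, `top_loadings`, the three candidate `sets`) plus the
#'   consensus `report`, `ranked_candidates`, and run `params`.
#' @export
run_pipeline <- function(genes, proteins, map, sets,
                         gene_lfc_threshold = 1, protein_lfc_threshold = 0.263,
                         alpha = 0.05, enrich_alpha = 0.05,
                         rho_threshold = 0.8, cor_alpha = 0.05,
                         top_k = 25, n_joint = 1, n_orth_x = 0, n_orth_y = 0,
                         o2pls_set = c("both", "union"), eps = 1e-3) {
  o2pls_set <- match.arg(o2pls_set)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      cry_abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), "pipeline")
    })
  }
  key_in <- function(x, table) id_key(x) %in% id_key(table)

  deg_table <- stage("differential_genes", differential_table(
    genes, eps = eps, lfc_threshold = gene_lfc_threshold, alpha = alpha
  ))
  dep_table <- stage("differential_proteins", differential_table(
    proteins, eps = eps, lfc_threshold = protein_lfc_threshold, alpha = alpha
  ))
  deg_ids <- deg_table$feature[deg_table$call != "ns"]
  dep_ids <- dep_table$feature[dep_table$call != "ns"]

  gene_universe <- rownames(genes$values)
  protein_universe <- rownames(proteins$values)
  prot_gene_all <- map_protein_to_gene(protein_universe, map)
  prot_gene_universe <- unname(prot_gene_all[!is.na(prot_gene_all)])
  dep_genes <- map_protein_to_gene(dep_ids, map)
  dep_genes_mapped <- unname(dep_genes[!is.na(dep_genes)])

  gene_ora <- stage("gene_ora", ora(deg_ids, gene_universe, sets))
  protein_ora <- stage("protein_ora", ora(
    dep_genes_mapped, prot_gene_universe, sets
  ))
  co <- stage("co_enrichment", co_ora(
    deg_ids, dep_ids, map, sets, gene_universe, protein_universe,
    alpha = enrich_alpha
  ))

  split_hits <- function(s) unlist(strsplit(s[nzchar(s)], ",", fixed = TRUE))
  sig_co <- co[co$significant, , drop = FALSE]
  set_kegg <- sort(unique(c(
    split_hits(sig_co$gene_hits), split_hits(sig_co$protein_hits)
  )))

  # Pathway-enriched differential features for the network: members of sets
  # significant in the corresponding single-omics enrichment.
  sig_gene_sets <- gene_ora$set[gene_ora$p_hyper < enrich_alpha]
  sig_prot_sets <- protein_ora$set[protein_ora$p_hyper < enrich_alpha]
  enriched_deg <- deg_ids[key_in(deg_ids, unlist(sets[sig_gene_sets]))]
  enriched_dep <- dep_ids[key_in(
    unname(dep_genes[dep_ids]), unlist(sets[sig_prot_sets])
  )]

  network <- NULL
  net_rank <- data.frame(gene_id = character(), degree = integer())
  set_pearson <- character()
  degrees <- NULL
  if (length(enriched_deg) && length(enriched_dep)) {
    network <- stage("correlation_network", build_network(
      subset_features(genes, enriched_deg),
      subset_features(proteins, enriched_dep),
      rho_threshold = rho_threshold, alpha = cor_alpha, eps = eps
    ))
    net_rank <- degree_ranking(network, top_n = 5)
    edge_prot_genes <- map_protein_to_gene(unique(network$edges$protein_id), map)
    set_pearson <- sort(unique(c(
      unique(network$edges$gene_id),
      unname(edge_prot_genes[!is.na(edge_prot_genes)])
    )))
    deg_gene <- network$degree_gene
    deg_prot <- network$degree_protein
    names(deg_prot) <- unname(map_protein_to_gene(names(deg_prot), map))
    deg_prot <- deg_prot[!is.na(names(deg_prot))]
    degrees <- tapply(
      c(deg_gene, deg_prot), id_key(c(names(deg_gene), names(deg_prot))), max
    )
    names(degrees) <- canonical_ids(names(deg_gene), names(deg_prot))[
      match(names(degrees), id_key(canonical_ids(names(deg_gene), names(deg_prot))))
    ]
  } else {
    warning("no pathway-enriched differential features in one omics; Pearson screen is empty")
  }

  model <- stage("o2pls", fit_o2pls(
    t(log2(genes$values + eps)), t(log2(proteins$values + eps)),
    n_joint = n_joint, n_orth_x = n_orth_x, n_orth_y = n_orth_y
  ))
  top <- top_joint_loadings(model, k = top_k)
  top_prot_genes <- map_protein_to_gene(top$y$feature, map)
  top_prot_genes <- unname(top_prot_genes[!is.na(top_prot_genes)])
  set_o2pls <- if (o2pls_set == "both") {
    sort(top$x$feature[key_in(top$x$feature, top_prot_genes)])
  } else {
    sort(unique(c(top$x$feature, top_prot_genes)))
  }

  load_gene <- apply(abs(model$W), 1, max)
  load_prot <- apply(abs(model$C), 1, max)
  names(load_prot) <- unname(map_protein_to_gene(names(load_prot), map))
  load_prot <- load_prot[!is.na(names(load_prot))]
  canon_load <- canonical_ids(names(load_gene), names(load_prot))
  loadings <- tapply(
    c(load_gene, load_prot), id_key(c(names(load_gene), names(load_prot))), max
  )
  names(loadings) <- canon_load[match(names(loadings), id_key(canon_load))]

  report <- stage("consensus", intersect_candidates(
    set_kegg, set_pearson, set_o2pls, map, gene_ids = gene_universe,
    degrees = degrees, loadings = loadings
  ))
  if (length(report$triple) == 0) {
    warning("empty triple intersection: no candidate supported by all three screens")
  }

  list(
    deg_table = deg_table, dep_table = dep_table,
    gene_ora = gene_ora, protein_ora = protein_ora, co_enrichment = co,
    network = network, degree_ranking = net_rank,
    o2pls_model = model, top_loadings = top,
    sets = list(kegg = set_kegg, pearson = set_pearson, o2pls = set_o2pls),
    report = report, ranked_candidates = rank_candidates(report),
    params = list(
      gene_lfc_threshold = gene_lfc_threshold,
      protein_lfc_threshold = protein_lfc_threshold, alpha = alpha,
      enrich_alpha = enrich_alpha, rho_threshold = rho_threshold,
      cor_alpha = cor_alpha, top_k = top_k, n_joint = n_joint,
      n_orth_x = n_orth_x, n_orth_y = n_orth_y, o2pls_set = o2pls_set,
      eps = eps
    )
  )
}
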