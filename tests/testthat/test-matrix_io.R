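test_that("expression_matrix enforces its container invariants", {
  m <- matrix(1:6, 2, 3, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  em <- expression_matrix(m, c(s1 = "FS", s2 = "FS", s3 = "PS"))
  expect_s3_class(em, "ExpressionMatrix")
  expect_identical(dim(em), c(2L, 3L))

  dup <- m
  rownames(dup) <- c("g1", "g1")
  expect_error(
    expression_matrix(dup, c(s1 = "FS", s2 = "FS", s3 = "PS")),
    "g1",
    class = "cryomics_format_error"
  )
  expect_error(
    expression_matrix(m, c(s1 = "FS", s2 = "FS")),
    "s3",
    class = "cryomics_format_error"
  )
  bad <- m
  bad[1, 2] <- -1
  expect_error(
    expression_matrix(bad, c(s1 = "FS", s2 = "FS", s3 = "PS")),
    "negative",
    class = "cryomics_format_error"
  )
  bad[1, 2] <- NaN
  expect_error(
    expression_matrix(bad, c(s1 = "FS", s2 = "FS", s3 = "PS")),
    "non-finite",
    class = "cryomics_format_error"
  )
})

test_that("expression matrix TSV reading validates and preserves order", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "feature_id\ts1\ts2\ts3\ts4\ts5\ts6",
    "gB\t1\t2\t3\t4\t5\t6",
    "gA\t2\t2\t2\t9\t9\t9",
    "gC\t5\t5\t5\t5\t5\t5"
  ), path)
  spec <- stats::setNames(rep(c("FS", "PS"), each = 3), paste0("s", 1:6))
  em <- read_expression_matrix(path, spec)
  expect_identical(rownames(em$values), c("gB", "gA", "gC"))
  expect_identical(colnames(em$values), paste0("s", 1:6))
  expect_equal(em$values["gA", "s4"], 9)

  writeLines(c("feature_id\ts1\ts2", "gA\t1\t2", "gA\t3\t4"), path)
  expect_error(
    read_expression_matrix(path, c(s1 = "FS", s2 = "PS")),
    "gA",
    class = "cryomics_format_error"
  )

  writeLines(c("feature_id\ts1\ts2", "gA\t1\toops"), path)
  expect_error(
    read_expression_matrix(path, c(s1 = "FS", s2 = "PS")),
    "oops.*row 1.*gA.*s2",
    class = "cryomics_format_error"
  )

  writeLines(c("feature_id\ts1\ts2", "gA\t1\tNA", "gB\t1\t2"), path)
  expect_error(
    read_expression_matrix(path, c(s1 = "FS", s2 = "PS")),
    "missing value",
    class = "cryomics_format_error"
  )
  expect_warning(
    em2 <- read_expression_matrix(path, c(s1 = "FS", s2 = "PS"), drop_incomplete = TRUE),
    "dropped 1"
  )
  expect_identical(rownames(em2$values), "gB")
})

test_that("matrix write-read round trip is the identity to 1e-12", {
  sim <- generate_paired_omics(sim_config(
    n_genes = 40, n_proteins = 30, n_shared_ids = 25, n_de_genes = 5,
    n_de_proteins = 3, n_planted_pairs = 4, pathway_size = 8, seed = 11
  ))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(sim$genes, path)
  back <- read_expression_matrix(
    path, stats::setNames(as.character(sim$genes$groups), names(sim$genes$groups))
  )
  expect_identical(dimnames(back$values), dimnames(sim$genes$values))
  expect_lt(max(abs(back$values - sim$genes$values)), 1e-12)
})

test_that("GMT parsing, validation and round trip", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("pathA\tdesc\tg1\tg2", "pathB\tother\tg2\tg3\tg4"), path)
  gs <- read_gmt(path)
  expect_identical(gs$pathA, c("g1", "g2"))
  expect_identical(attr(gs, "descriptions")[["pathB"]], "other")

  writeLines(c("pathA\tdesc\tg1", "pathA\tdesc\tg2"), path)
  expect_error(read_gmt(path), "pathA", class = "cryomics_format_error")
  writeLines("lonely\tdesc", path)
  expect_error(read_gmt(path), "fewer than 3", class = "cryomics_format_error")

  sim <- generate_paired_omics(sim_config(
    n_genes = 50, n_proteins = 30, n_shared_ids = 20, n_de_genes = 4,
    n_de_proteins = 3, n_planted_pairs = 3, pathway_size = 6, seed = 3
  ))
  write_gmt(sim$gene_sets, path)
  back <- read_gmt(path)
  expect_identical(unclass(back)[names(back)], unclass(sim$gene_sets)[names(sim$gene_sets)])
})

test_that("id map rejects duplicates and looks up case-insensitively", {
  m <- id_map(c("FCGR1A", "Hck"), c("W5QHL1", "P08631"))
  expect_error(
    id_map(c("FCGR1A", "fcgr1a"), c("W5QHL1", "w5qhl1")),
    "duplicated pair",
    class = "cryomics_format_error"
  )
  expect_identical(unname(cryomics:::map_protein_to_gene("w5qhl1", m)), "FCGR1A")
  expect_identical(unname(cryomics:::map_gene_to_protein("HCK", m)), "P08631")
  expect_true(is.na(cryomics:::map_protein_to_gene("missing", m)))

  path <- withr::local_tempfile(fileext = ".tsv")
  write_id_map(m, path)
  expect_identical(read_id_map(path)$gene_id, m$gene_id)
})

test_that("phenotype tables are validated on read", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "sample_id\tmotility\tviability\tVSL",
    "s1\t82.6\t89.5\t43.6", "s2\t34.1\t44.8\t38.4"
  ), path)
  ph <- read_phenotype(path)
  expect_s3_class(ph, "PhenotypeTable")
  writeLines(c("sample_id\tmotility", "s1\t140"), path)
  expect_error(read_phenotype(path), "\\[0, 100\\]", class = "cryomics_format_error")
  writeLines(c("sample_id\tVSL", "s1\t-3"), path)
  expect_error(read_phenotype(path), "non-negative", class = "cryomics_format_error")
})

test_that("mapping rate uses half-up rounding and is scale invariant", {
  expect_identical(mapping_rate(310699628, 186669343), 60.08)
  expect_identical(mapping_rate(12345, 12345), 100)
  expect_identical(mapping_rate(3, 1), 33.33)
  for (k in c(2, 7, 1000)) {
    expect_identical(mapping_rate(k * 3, k * 1), mapping_rate(3, 1))
    expect_identical(
      mapping_rate(k * 310699628, k * 186669343),
      mapping_rate(310699628, 186669343)
    )
  }
  expect_error(mapping_rate(0, 0), "positive", class = "cryomics_domain_error")
  expect_error(mapping_rate(10, 11), class = "cryomics_domain_error")
})
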