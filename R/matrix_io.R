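# Containers and on-disk formats: abundance matrices (TSV), gene sets (GMT),
# gene<->protein id maps (TSV), phenotype tables (TSV), plus small QC
# arithmetic. TSV is the native dialect (UTF-8, '.' decimal separator).

#' Construct an expression matrix with group labels
#'
#' Wraps a non-negative abundance matrix (features x samples; FPKM-like for
#' RNA-seq, reporter-intensity-like for TMT proteomics) together with a
#' per-sample group label. This is the common input container for the
#' differential, correlation and O2PLS modules.
#'
#' @param values Numeric matrix, features in rows, samples in columns. Row and
#'   column names are required and must be unique; all values must be finite
#'   and non-negative.
#' @param groups Named character vector or factor mapping every sample id to
#'   its group (conventionally `"FS"` for fresh and `"PS"` for
#'   programmed-freezing/frozen samples).
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` (the matrix) and `groups` (a named factor over the samples).
#' @examples
#' m <- matrix(1:6, 2, 3, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' expression_matrix(m, c(s1 = "FS", s2 = "FS", s3 = "PS"))
#' @export
expression_matrix <- function(values, groups) {
  if (!is.matrix(values) || !is.numeric(values)) {
    cry_abort("`values` must be a numeric matrix", "format")
  }
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid)) {
    cry_abort("`values` must have row (feature) and column (sample) names", "format")
  }
  if (anyDuplicated(fid)) {
    cry_abort(sprintf(
      "duplicated feature id(s): %s",
      paste(unique(fid[duplicated(fid)]), collapse = ", ")
    ), "format")
  }
  if (anyDuplicated(sid)) {
    cry_abort(sprintf(
      "duplicated sample id(s): %s",
      paste(unique(sid[duplicated(sid)]), collapse = ", ")
    ), "format")
  }
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    cry_abort(sprintf(
      "non-finite value at feature '%s', sample '%s'", fid[bad[1]], sid[bad[2]]
    ), "format")
  }
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    cry_abort(sprintf(
      "negative abundance at feature '%s', sample '%s'", fid[bad[1]], sid[bad[2]]
    ), "format")
  }
  g <- groups
  if (is.null(names(g)) && length(g) == ncol(values)) names(g) <- sid
  missing_g <- setdiff(sid, names(g))
  if (length(missing_g)) {
    cry_abort(sprintf(
      "sample(s) without group label: %s", paste(missing_g, collapse = ", ")
    ), "format")
  }
  g <- factor(as.character(g[sid]))
  names(g) <- sid
  structure(list(values = values, groups = g), class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf(
    "ExpressionMatrix: %d features x %d samples (groups: %s)\n",
    nrow(x$values), ncol(x$values),
    paste(sprintf("%s=%d", levels(x$groups), tabulate(x$groups)), collapse = ", ")
  ))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Subset an expression matrix by feature ids
#'
#' @param x An `ExpressionMatrix`.
#' @param features Character vector of feature ids to keep (order preserved).
#' @return An `ExpressionMatrix` restricted to `features`.
#' @export
subset_features <- function(x, features) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  missing <- setdiff(features, rownames(x$values))
  if (length(missing)) {
    cry_abort(sprintf(
      "feature id(s) not present: %s", paste(missing, collapse = ", ")
    ), "domain")
  }
  expression_matrix(x$values[features, , drop = FALSE], x$groups)
}

# Per-group column index list; statistical ops require >= 2 samples per group.
group_index <- function(x, require_two = TRUE) {
  idx <- split(seq_along(x$groups), x$groups)
  if (require_two && any(vapply(idx, length, 1L) < 2)) {
    cry_abort("every group needs at least 2 samples for statistical operations", "domain")
  }
  idx
}

#' Read an abundance matrix from TSV
#'
#' Expects a tab-separated file whose first column holds feature ids and whose
#' header row holds sample ids. Input ordering of features and samples is
#' preserved. Missing values are rejected (the downstream statistics have no
#' imputation step) unless `drop_incomplete = TRUE`, in which case rows with
#' any missing cell are dropped with a warning.
#'
#' @param path Path to the TSV file.
#' @param group_spec Named character vector mapping sample ids to groups, or a
#'   two-column data frame (`sample_id`, `group`).
#' @param drop_incomplete Drop rows containing missing values instead of
#'   raising an error.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, group_spec, drop_incomplete = FALSE) {
  raw <- utils::read.delim(path,
    check.names = FALSE, stringsAsFactors = FALSE,
    colClasses = "character"
  )
  if (ncol(raw) < 2) cry_abort("matrix TSV needs a feature id column plus samples", "format")
  fid <- raw[[1]]
  if (anyDuplicated(fid)) {
    cry_abort(sprintf(
      "duplicated feature id(s): %s",
      paste(unique(fid[duplicated(fid)]), collapse = ", ")
    ), "format")
  }
  body <- raw[, -1, drop = FALSE]
  vals <- matrix(NA_real_, nrow(body), ncol(body),
    dimnames = list(fid, colnames(body))
  )
  for (j in seq_len(ncol(body))) {
    cell <- body[[j]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num) & !is.na(cell) & cell != "" & cell != "NA")
    if (length(bad)) {
      cry_abort(sprintf(
        "non-numeric cell '%s' at row %d (feature '%s'), column '%s'",
        cell[bad[1]], bad[1], fid[bad[1]], colnames(body)[j]
      ), "format")
    }
    vals[, j] <- num
  }
  if (anyNA(vals)) {
    if (drop_incomplete) {
      keep <- stats::complete.cases(vals)
      warning(sprintf("dropped %d incomplete row(s)", sum(!keep)))
      vals <- vals[keep, , drop = FALSE]
    } else {
      bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
      cry_abort(sprintf(
        "missing value at feature '%s', sample '%s' (use drop_incomplete = TRUE to drop rows)",
        rownames(vals)[bad[1]], colnames(vals)[bad[2]]
      ), "format")
    }
  }
  if (is.data.frame(group_spec)) {
    group_spec <- stats::setNames(
      as.character(group_spec[[2]]),
      as.character(group_spec[[1]])
    )
  }
  expression_matrix(vals, group_spec)
}

#' Write an abundance matrix to TSV
#'
#' @param x An `ExpressionMatrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  df <- data.frame(
    feature_id = rownames(x$values), x$values,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' Construct a gene set collection
#'
#' @param sets Named list of character vectors (feature ids per set). Names
#'   must be unique; members must be non-empty.
#' @param descriptions Optional named character vector of set descriptions.
#' @return A `GeneSetCollection` (named list with a `descriptions` attribute).
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || any(names(sets) == "")) {
    cry_abort("every gene set needs a name", "format")
  }
  if (anyDuplicated(names(sets))) {
    cry_abort(sprintf(
      "duplicated set name(s): %s",
      paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", ")
    ), "format")
  }
  if (any(vapply(sets, length, 1L) == 0)) {
    cry_abort("gene sets must have at least one member", "format")
  }
  sets <- lapply(sets, function(m) unique(as.character(m)))
  desc <- stats::setNames(rep("", length(sets)), names(sets))
  if (!is.null(descriptions)) desc[names(descriptions)] <- descriptions
  structure(sets, descriptions = desc, class = "GeneSetCollection")
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...` (at least three fields).
#'
#' @param path Path to the GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3)
  if (length(short)) {
    cry_abort(sprintf(
      "GMT line %d has fewer than 3 tab-separated fields", short[1]
    ), "format")
  }
  nm <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(nm)) {
    cry_abort(sprintf(
      "duplicated set name(s): %s",
      paste(unique(nm[duplicated(nm)]), collapse = ", ")
    ), "format")
  }
  desc <- stats::setNames(vapply(fields, `[[`, "", 2), nm)
  sets <- stats::setNames(lapply(fields, function(f) f[-(1:2)]), nm)
  gene_set_collection(sets, desc)
}

#' Write gene sets to a GMT file
#'
#' @param sets A `GeneSetCollection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(inherits(sets, "GeneSetCollection"))
  desc <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Construct a gene-protein id map
#'
#' Pairs gene ids with protein ids (e.g. gene symbols with UniProt
#' accessions). Lookups are case-insensitive; the stored spelling is
#' preserved.
#'
#' @param gene_id,protein_id Character vectors of equal length.
#' @return An `IdMap` data frame with columns `gene_id`, `protein_id`.
#' @export
id_map <- function(gene_id, protein_id) {
  gene_id <- as.character(gene_id)
  protein_id <- as.character(protein_id)
  if (length(gene_id) != length(protein_id)) {
    cry_abort("gene_id and protein_id must have equal length", "format")
  }
  key <- paste(id_key(gene_id), id_key(protein_id), sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))[1]
    cry_abort(sprintf(
      "duplicated pair (%s, %s)", gene_id[dup], protein_id[dup]
    ), "format")
  }
  structure(
    data.frame(gene_id = gene_id, protein_id = protein_id, stringsAsFactors = FALSE),
    class = c("IdMap", "data.frame")
  )
}

#' Read a gene-protein id map from TSV
#'
#' @param path Path to a two-column TSV (`gene_id`, `protein_id`) with header.
#' @return An [id_map()].
#' @export
read_id_map <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) cry_abort("id map TSV needs two columns", "format")
  id_map(df[[1]], df[[2]])
}

#' Write a gene-protein id map to TSV
#'
#' @param map An `IdMap`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_id_map <- function(map, path) {
  stopifnot(inherits(map, "IdMap"))
  utils::write.table(map, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    fileEncoding = "UTF-8"
  )
  invisible(path)
}

# Case-insensitive lookups. Return NA for ids without a partner.
map_protein_to_gene <- function(protein_ids, map) {
  stopifnot(inherits(map, "IdMap"))
  i <- match(id_key(protein_ids), id_key(map$protein_id))
  stats::setNames(map$gene_id[i], protein_ids)
}

map_gene_to_protein <- function(gene_ids, map) {
  stopifnot(inherits(map, "IdMap"))
  i <- match(id_key(gene_ids), id_key(map$gene_id))
  stats::setNames(map$protein_id[i], gene_ids)
}

#' Read a per-sample phenotype table from TSV
#'
#' First column is `sample_id`; remaining columns are numeric phenotype
#' measurements. Columns whose names contain "motility" or "viability" are
#' validated as percentages in \[0, 100\]; velocity/amplitude columns (VSL,
#' VCL, VAP, ALH) must be non-negative.
#'
#' @param path Path to the TSV file.
#' @return A data frame of class `PhenotypeTable`.
#' @export
read_phenotype <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) cry_abort("phenotype TSV needs sample_id plus measurements", "format")
  names(df)[1] <- "sample_id"
  validate_phenotype(df)
}

validate_phenotype <- function(df) {
  if (anyDuplicated(df$sample_id)) {
    cry_abort("duplicated sample id in phenotype table", "format")
  }
  for (col in setdiff(names(df), "sample_id")) {
    v <- df[[col]]
    if (!is.numeric(v)) cry_abort(sprintf("phenotype column '%s' is not numeric", col), "format")
    if (grepl("motility|viability", col, ignore.case = TRUE) &&
      any(v < 0 | v > 100, na.rm = TRUE)) {
      cry_abort(sprintf("percentage column '%s' outside [0, 100]", col), "format")
    }
    if (grepl("^(vsl|vcl|vap|alh)", col, ignore.case = TRUE) && any(v < 0, na.rm = TRUE)) {
      cry_abort(sprintf("velocity column '%s' must be non-negative", col), "format")
    }
  }
  structure(df, class = c("PhenotypeTable", "data.frame"))
}

#' Write a phenotype table to TSV
#'
#' @param phenotype A `PhenotypeTable` (or compatible data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotype <- function(phenotype, path) {
  utils::write.table(phenotype, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' Unique-mapping rate as a percentage
#'
#' Computes `100 * unique_mapped / total_reads` with half-up rounding to two
#' decimals, the convention used when reporting read-alignment summaries.
#'
#' @param total_reads Total read count (positive integer).
#' @param unique_mapped Uniquely mapped read count, `0 <= unique_mapped <=
#'   total_reads`.
#' @return The percentage, rounded half-up to 2 decimals.
#' @examples
#' mapping_rate(310699628, 186669343) # 60.08
#' @export
mapping_rate <- function(total_reads, unique_mapped) {
  if (!is_scalar_num(total_reads) || !is_scalar_num(unique_mapped)) {
    cry_abort("counts must be single finite numbers", "domain")
  }
  if (total_reads <= 0) cry_abort("total_reads must be positive", "domain")
  if (unique_mapped < 0 || unique_mapped > total_reads) {
    cry_abort("unique_mapped must lie in [0, total_reads]", "domain")
  }
  round_half_up(100 * unique_mapped / total_reads, 2)
}
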