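# Shared helpers: seeded evaluation and the TSV dialects the pipeline reads
# and writes.

# Evaluate expr under a temporary RNG state; NULL seed leaves the global
# stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic per-generator substream: fans a master seed out by stream
# name so adding one generator never perturbs another. Result < 2^31.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' Write a data.frame as TSV
#'
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a herb-compound table
#'
#' TSV with header `herb_id, compound_id, compound_name, ob, dl`.
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_compound_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  req <- c("herb_id", "compound_id", "ob", "dl")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L)
    stop(path, " is missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Read a compound-target table
#'
#' TSV with header `compound_id, gene_symbol`.
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_target_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("compound_id", "gene_symbol") %in% names(df)))
    stop(path, " needs columns compound_id, gene_symbol")
  df
}

#' Read disease-gene sources
#'
#' TSV with header `source_name, gene_symbol`.
#'
#' @param path TSV file path.
#' @return named list of gene-symbol vectors, one per source.
#' @export
read_disease_sources <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("source_name", "gene_symbol") %in% names(df)))
    stop(path, " needs columns source_name, gene_symbol")
  split(as.character(df$gene_symbol), as.character(df$source_name))
}

#' Read a feature table from TSV
#'
#' Features x samples TSV with a feature-id first column and an optional
#' `taxonomy` lineage column; samples are the remaining columns. An optional
#' group map assigns samples to groups.
#'
#' @param path TSV file path.
#' @param group_path optional TSV `sample, group`.
#' @param taxonomy_col name of the lineage column. Default "taxonomy".
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path, group_path = NULL,
                               taxonomy_col = "taxonomy") {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  feat <- as.character(df[[1]])
  df <- df[, -1, drop = FALSE]
  tax <- NULL
  if (taxonomy_col %in% names(df)) {
    tax <- stats::setNames(as.character(df[[taxonomy_col]]), feat)
    df[[taxonomy_col]] <- NULL
  }
  m <- base::t(as.matrix(df))
  colnames(m) <- feat
  groups <- if (!is.null(group_path)) read_group_map(group_path) else NULL
  feature_table(m, taxonomy = tax, groups = groups)
}

#' Read a sample-group map
#'
#' TSV with header `sample, group`.
#'
#' @param path TSV file path.
#' @return named character vector of group labels.
#' @export
read_group_map <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(df)))
    stop(path, " needs columns sample, group")
  stats::setNames(as.character(df$group), as.character(df$sample))
}

#' Read a minimal BIOM-format JSON feature table
#'
#' Supports the BIOM 1.0 JSON dialect with dense or sparse `data`, reading
#' row (feature) ids with optional `taxonomy` metadata and column (sample)
#' ids.
#'
#' @param path BIOM JSON file path.
#' @param group_path optional TSV `sample, group`.
#' @return a [feature_table()].
#' @export
read_biom_json <- function(path, group_path = NULL) {
  b <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- vapply(b$rows, `[[`, character(1), "id")
  samples <- vapply(b$columns, `[[`, character(1), "id")
  m <- matrix(0, nrow = length(samples), ncol = length(feats),
              dimnames = list(samples, feats))
  if (identical(b$matrix_type, "dense")) {
    # data rows are features
    m <- base::t(matrix(unlist(b$data), nrow = length(feats), byrow = TRUE,
                        dimnames = list(feats, samples)))
  } else {
    for (trip in b$data)
      m[trip[[2]] + 1L, trip[[1]] + 1L] <- trip[[3]]
  }
  tax <- vapply(b$rows, function(r) {
    md <- r$metadata
    if (is.null(md) || is.null(md$taxonomy)) return(NA_character_)
    paste(unlist(md$taxonomy), collapse = ";")
  }, character(1))
  names(tax) <- feats
  if (all(is.na(tax))) tax <- NULL
  groups <- if (!is.null(group_path)) read_group_map(group_path) else NULL
  feature_table(m, taxonomy = tax, groups = groups)
}
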