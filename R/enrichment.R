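# Over-representation analysis: one-sided hypergeometric tests of a query
# gene set against a GMT-style collection, Benjamini-Hochberg adjusted
# within each ontology category (BP / CC / MF / pathway).

#' Upper-tail hypergeometric p-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of seeing
#' at least `k` annotated genes when drawing `n` genes from a universe of `N`
#' containing `K` annotated ones. Vectorized over its arguments.
#'
#' @param k observed hits in the query.
#' @param K term size within the universe.
#' @param n query size within the universe.
#' @param N universe size.
#' @return numeric p-value(s) in (0, 1].
#' @examples
#' hypergeom_pvalue(5, 5, 5, 10) # 1/choose(10,5) = 1/252
#' @export
hypergeom_pvalue <- function(k, K, n, N) {
  v <- cbind(k = k, K = K, n = n, N = N)
  k <- v[, "k"]; K <- v[, "K"]; n <- v[, "n"]; N <- v[, "N"]
  if (any(v < 0) || any(v != floor(v)))
    stop("k, K, n, N must be non-negative integers")
  if (any(K > N) || any(n > N))
    stop("K and n cannot exceed the universe size N")
  if (any(k > pmin(K, n)))
    stop("k cannot exceed min(K, n)")
  unname(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1; input order preserved.
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  if (any(is.na(pvals) | pvals <= 0 | pvals > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT: term id, description, then member genes. The
#' ontology category of each term (BP, CC, MF or pathway) is taken from the
#' description field when it equals one of those labels, otherwise from
#' `default_category`.
#'
#' @param path GMT file path.
#' @param default_category category for terms without a recognized label.
#' @return a `gene_set_collection`: named list of terms, each a list with
#'   `name`, `category`, `genes`.
#' @export
read_gmt <- function(path, default_category = "pathway") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  terms <- lapply(parts, function(p) {
    if (length(p) < 3L)
      stop("malformed GMT line (need id, description, >=1 gene): ", p[1])
    cat_lab <- if (p[2] %in% c("BP", "CC", "MF", "pathway")) p[2]
               else default_category
    list(name = p[2], category = cat_lab,
         genes = normalize_gene_symbols(p[-(1:2)]))
  })
  names(terms) <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(names(terms)))
    stop("duplicate term id in GMT: ",
         names(terms)[duplicated(names(terms))][1])
  structure(terms, class = "gene_set_collection")
}

#' Build a gene-set collection in code
#'
#' @param genes named list of member-gene vectors (names are term ids).
#' @param names_ optional term names (defaults to ids).
#' @param categories per-term category, recycled; BP, CC, MF or pathway.
#' @return a `gene_set_collection`.
#' @export
gene_set_collection <- function(genes, names_ = names(genes),
                                categories = "pathway") {
  stopifnot(is.list(genes), !is.null(names(genes)))
  if (anyDuplicated(names(genes))) stop("term ids must be unique")
  categories <- rep_len(categories, length(genes))
  terms <- mapply(function(g, nm, cat_lab) {
    g <- normalize_gene_symbols(g)
    if (length(g) == 0L) stop("term with empty member set: ", nm)
    list(name = nm, category = cat_lab, genes = g)
  }, genes, names_, categories, SIMPLIFY = FALSE)
  structure(terms, class = "gene_set_collection")
}

#' Over-representation analysis of a query gene set
#'
#' One-sided hypergeometric test of the query against every term it hits,
#' with BH adjustment applied separately within each ontology category.
#' Query genes outside the universe are dropped with a warning; terms are
#' restricted to the universe; terms with zero query hits are omitted from
#' both the output and the BH family.
#'
#' @param query character vector of gene symbols.
#' @param collection a `gene_set_collection`.
#' @param universe background gene symbols; default is the union of all
#'   collection members.
#' @param alpha significance level on the adjusted p-value. Default 0.05.
#' @return data.frame with columns `term_id`, `term_name`, `category`, `k`,
#'   `K`, `n`, `N`, `p`, `p_adj`, `significant`, sorted by `p` within
#'   category; class `enrichment_result`.
#' @export
enrich_gene_set <- function(query, collection, universe = NULL, alpha = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- normalize_gene_symbols(query)
  if (is.null(universe)) {
    universe <- unique(unlist(lapply(collection, `[[`, "genes"),
                              use.names = FALSE))
  } else {
    universe <- normalize_gene_symbols(universe)
  }
  if (length(universe) == 0L) stop("empty universe")
  outside <- setdiff(query, universe)
  if (length(outside) > 0L) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(collection), function(id) {
    term <- collection[[id]]
    members <- intersect(term$genes, universe)
    k <- length(intersect(query, members))
    if (k == 0L) return(NULL)
    data.frame(term_id = id, term_name = term$name, category = term$category,
               k = k, K = length(members), n = n, N = N,
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    out <- data.frame(term_id = character(0), term_name = character(0),
                      category = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      p_adj = numeric(0), significant = logical(0))
    class(out) <- c("enrichment_result", "data.frame")
    return(out)
  }
  rows$p <- hypergeom_pvalue(rows$k, rows$K, rows$n, rows$N)
  rows$p_adj <- NA_real_
  for (cat_lab in unique(rows$category)) {
    idx <- rows$category == cat_lab
    rows$p_adj[idx] <- bh_adjust(rows$p[idx])
  }
  rows$significant <- rows$p_adj < alpha
  rows <- rows[order(rows$category, rows$p, rows$term_id), , drop = FALSE]
  row.names(rows) <- NULL
  class(rows) <- c("enrichment_result", "data.frame")
  rows
}
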