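# Herb-ingredient-target (HIT) network assembly: ADME filtering of herb
# compounds, multi-source disease-gene collation, and construction of the
# tripartite herb -> compound -> target network restricted to disease-shared
# targets.

#' Filter herb compounds by ADME criteria
#'
#' Keeps compounds whose oral bioavailability (OB, percent) and drug-likeness
#' (DL, unitless) both meet the standard activity cutoffs. Both thresholds are
#' inclusive: a compound at exactly `ob_min` / `dl_min` is retained.
#'
#' @param records data.frame with columns `herb_id`, `compound_id`,
#'   `compound_name`, `ob`, `dl` (one row per herb-compound pair).
#' @param ob_min minimum oral bioavailability in percent. Default 20.
#' @param dl_min minimum drug-likeness. Default 0.18.
#' @return the subset of `records` passing both cutoffs, input order preserved.
#' @examples
#' recs <- data.frame(herb_id = "Mf", compound_id = c("C1", "C2"),
#'                    compound_name = c("a", "b"), ob = c(20, 19.9),
#'                    dl = c(0.18, 0.9))
#' filter_adme(recs) # keeps only C1 (boundary inclusive)
#' @export
filter_adme <- function(records, ob_min = 20, dl_min = 0.18) {
  stopifnot(is.data.frame(records))
  req <- c("herb_id", "compound_id", "ob", "dl")
  miss <- setdiff(req, names(records))
  if (length(miss) > 0L)
    stop("records is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(records) == 0L) return(records)
  bad <- which(records$ob < 0 | records$dl < 0 | is.na(records$ob) |
                 is.na(records$dl))
  if (length(bad) > 0L)
    stop(sprintf(
      "invalid OB/DL for record %s/%s (row %d): ob=%s, dl=%s",
      records$herb_id[bad[1]], records$compound_id[bad[1]], bad[1],
      format(records$ob[bad[1]]), format(records$dl[bad[1]])))
  key <- paste(records$herb_id, records$compound_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (herb_id, compound_id) pair: ",
         sub("\r", "/", key[duplicated(key)][1]))
  records[records$ob >= ob_min & records$dl >= dl_min, , drop = FALSE]
}

#' Normalize gene symbols
#'
#' Trims whitespace, uppercases, and drops empty strings, `NA`s and
#' duplicates. No alias resolution is attempted: symbols that differ beyond
#' case/whitespace are treated as distinct genes.
#'
#' @param raw character vector of raw symbols.
#' @return character vector of unique normalized symbols (first-seen order).
#' @examples
#' normalize_gene_symbols(c("Tnf", "TNF", " il6 ")) # "TNF" "IL6"
#' @export
normalize_gene_symbols <- function(raw) {
  if (length(raw) == 0L) return(character(0))
  x <- toupper(trimws(as.character(raw)))
  x <- x[!is.na(x) & nzchar(x)]
  unique(x)
}

#' Collate disease genes from several sources
#'
#' Pools gene lists from several disease databases into their union and
#' tabulates the Venn regions: for every non-empty subset of sources, the
#' number of genes belonging to exactly those sources.
#'
#' @param sources named list of character vectors (names are source names,
#'   e.g. GeneCards, DrugBank, OMIM, PharmGkb, TTD), or a data.frame with
#'   columns `source_name` and `gene_symbol`.
#' @return list with `union` (normalized symbol vector), `region_counts`
#'   (named integer vector; names are `&`-joined source combinations; counts
#'   sum to `length(union)`), and `per_source` (named sizes after
#'   normalization).
#' @export
collate_disease_genes <- function(sources) {
  if (is.data.frame(sources)) {
    stopifnot(all(c("source_name", "gene_symbol") %in% names(sources)))
    sources <- split(as.character(sources$gene_symbol),
                     as.character(sources$source_name))
  }
  if (length(sources) < 1L) stop("need at least one source")
  nm <- names(sources)
  if (is.null(nm) || any(!nzchar(nm))) stop("sources must be named")
  if (anyDuplicated(nm))
    stop("duplicate source_name: ", nm[duplicated(nm)][1])
  sets <- lapply(sources, normalize_gene_symbols)
  all_genes <- unique(unlist(sets, use.names = FALSE))
  k <- length(sets)
  member <- vapply(sets, function(s) all_genes %in% s,
                   logical(length(all_genes)))
  if (length(all_genes) == 1L) member <- matrix(member, nrow = 1L)
  # all non-empty subsets of sources (exact-membership Venn regions)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1L, , drop = FALSE]
  region_counts <- integer(nrow(combos))
  names(region_counts) <- apply(combos, 1L,
                                function(z) paste(nm[as.logical(z)],
                                                  collapse = "&"))
  if (length(all_genes) > 0L) {
    pat <- apply(member, 1L, function(z) paste(nm[z], collapse = "&"))
    tab <- table(pat)
    region_counts[names(tab)] <- as.integer(tab)
  }
  list(union = all_genes,
       region_counts = region_counts,
       per_source = vapply(sets, length, integer(1)))
}

#' Intersect formula targets with disease genes
#'
#' @param gczx_targets normalized target symbols of the pooled formula.
#' @param disease_genes normalized disease-gene symbols.
#' @return character vector of shared genes.
#' @export
intersect_targets <- function(gczx_targets, disease_genes) {
  intersect(gczx_targets, disease_genes)
}

#' Build the tripartite herb-ingredient-target network
#'
#' Links herbs to their (ADME-filtered) compounds and compounds to their
#' targets, keeping only targets in `keep_targets` (typically the
#' formula-disease intersection). Compounds with no retained target and herbs
#' with no retained compound are pruned, so the network has no dangling nodes.
#' A compound appearing under several herbs is a single compound node with one
#' edge per parent herb.
#'
#' @param records ADME-filtered compound table (`herb_id`, `compound_id`,
#'   optional `compound_name`).
#' @param compound_targets data.frame `compound_id`, `gene_symbol`.
#' @param keep_targets normalized symbols to retain (NULL keeps all).
#' @return object of class `hit_network`: list with `nodes` (data.frame `id`,
#'   `type` in herb/compound/target, `label`) and `edges` (data.frame `from`,
#'   `to`, `type` in herb-compound/compound-target).
#' @export
build_hit_network <- function(records, compound_targets, keep_targets = NULL) {
  stopifnot(is.data.frame(records), is.data.frame(compound_targets))
  tg <- compound_targets
  tg$gene_symbol <- toupper(trimws(as.character(tg$gene_symbol)))
  tg <- tg[nzchar(tg$gene_symbol), , drop = FALSE]
  if (!is.null(keep_targets))
    tg <- tg[tg$gene_symbol %in% keep_targets, , drop = FALSE]
  tg <- unique(tg[, c("compound_id", "gene_symbol")])
  # prune closure: compounds need >=1 target, herbs >=1 compound
  recs <- records[records$compound_id %in% tg$compound_id, , drop = FALSE]
  tg <- tg[tg$compound_id %in% recs$compound_id, , drop = FALSE]
  if (nrow(recs) == 0L)
    warning("HIT network is empty after pruning")
  herb_edges <- unique(data.frame(from = recs$herb_id, to = recs$compound_id,
                                  type = rep_len("herb-compound", nrow(recs)),
                                  stringsAsFactors = FALSE))
  tgt_edges <- data.frame(from = tg$compound_id, to = tg$gene_symbol,
                          type = rep_len("compound-target", nrow(tg)),
                          stringsAsFactors = FALSE)
  cname <- if ("compound_name" %in% names(recs)) {
    stats::setNames(as.character(recs$compound_name), recs$compound_id)
  } else stats::setNames(character(0), character(0))
  herbs <- unique(herb_edges$from)
  comps <- unique(herb_edges$to)
  tgts <- unique(tgt_edges$to)
  nodes <- data.frame(
    id = c(herbs, comps, tgts),
    type = rep(c("herb", "compound", "target"),
               c(length(herbs), length(comps), length(tgts))),
    stringsAsFactors = FALSE)
  nodes$label <- ifelse(nodes$type == "compound" & nodes$id %in% names(cname),
                        unname(cname[nodes$id]), nodes$id)
  structure(list(nodes = nodes, edges = rbind(herb_edges, tgt_edges)),
            class = "hit_network")
}

#' @export
print.hit_network <- function(x, ...) {
  tab <- table(factor(x$nodes$type, levels = c("herb", "compound", "target")))
  cat("Herb-ingredient-target network\n")
  cat(sprintf("  %d herbs, %d compounds, %d targets; %d edges\n",
              tab[["herb"]], tab[["compound"]], tab[["target"]],
              nrow(x$edges)))
  invisible(x)
}

#' Per-herb target coverage
#'
#' For each herb, the number of targets reachable through its compounds and
#' the fraction of the network's target union that it covers. Fractions can
#' sum to more than 1 because herbs share targets. Combined coverage is also
#' reported for herb subsets (defaults to the all-herb set, which always
#' covers fraction 1).
#'
#' @param net a `hit_network`.
#' @param subsets optional list of herb-id vectors for combined coverage.
#' @return list with `per_herb` (data.frame `herb_id`, `n_targets`,
#'   `fraction`), `n_union` and `combined` (data.frame `herbs`, `n_targets`,
#'   `fraction`).
#' @export
herb_target_share <- function(net, subsets = NULL) {
  stopifnot(inherits(net, "hit_network"))
  if (nrow(net$nodes) == 0L) stop("empty network")
  hc <- net$edges[net$edges$type == "herb-compound", , drop = FALSE]
  ct <- net$edges[net$edges$type == "compound-target", , drop = FALSE]
  comp_targets <- split(ct$to, ct$from)
  herbs <- unique(hc$from)
  herb_targets <- lapply(stats::setNames(herbs, herbs), function(h) {
    comps <- hc$to[hc$from == h]
    unique(unlist(comp_targets[comps], use.names = FALSE))
  })
  n_union <- length(unique(unlist(herb_targets, use.names = FALSE)))
  per_herb <- data.frame(
    herb_id = herbs,
    n_targets = vapply(herb_targets, length, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  per_herb$fraction <- per_herb$n_targets / n_union
  if (is.null(subsets)) subsets <- list(herbs)
  combined <- data.frame(
    herbs = vapply(subsets, paste, character(1), collapse = "+"),
    n_targets = vapply(subsets, function(s)
      length(unique(unlist(herb_targets[s], use.names = FALSE))), integer(1)),
    stringsAsFactors = FALSE)
  combined$fraction <- combined$n_targets / n_union
  list(per_herb = per_herb, n_union = n_union, combined = combined)
}
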