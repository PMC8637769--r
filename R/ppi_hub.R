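# Confidence-filtered PPI graph construction and iterative six-centrality
# hub extraction (degree, betweenness, closeness, eigenvector, local average
# connectivity, network centrality), keeping nodes above the per-index median
# on all indices and recomputing on the induced subgraph each round.

#' Build a confidence-filtered PPI graph
#'
#' Keeps edges with confidence at or above `conf_min` (inclusive, matching
#' the usual STRING "high confidence" convention), drops self-loops, merges
#' duplicate edges keeping the maximum confidence, and removes nodes left
#' without any edge.
#'
#' @param edges data.frame with three columns: two interactor gene symbols
#'   and a confidence in \[0, 1\] (columns are taken positionally unless named
#'   `from`/`to`/`confidence`).
#' @param conf_min minimum edge confidence. Default 0.7.
#' @return an undirected simple [igraph::graph] with edge attribute
#'   `confidence`.
#' @export
build_ppi_graph <- function(edges, conf_min = 0.7) {
  stopifnot(is.data.frame(edges), ncol(edges) >= 3L)
  if (all(c("from", "to", "confidence") %in% names(edges))) {
    df <- edges[, c("from", "to", "confidence")]
  } else {
    df <- edges[, 1:3]
    names(df) <- c("from", "to", "confidence")
  }
  df$from <- as.character(df$from)
  df$to <- as.character(df$to)
  df$confidence <- as.numeric(df$confidence)
  if (any(is.na(df$confidence) | df$confidence < 0 | df$confidence > 1))
    stop("edge confidences must lie in [0, 1]")
  df <- df[df$from != df$to, , drop = FALSE]           # self-loops
  df <- df[df$confidence >= conf_min, , drop = FALSE]  # threshold, inclusive
  if (nrow(df) > 0L) {
    a <- pmin(df$from, df$to)
    b <- pmax(df$from, df$to)
    key <- paste(a, b, sep = "\r")
    conf <- tapply(df$confidence, key, max)
    pairs <- do.call(rbind, strsplit(names(conf), "\r", fixed = TRUE))
    df <- data.frame(from = pairs[, 1], to = pairs[, 2],
                     confidence = as.numeric(conf), stringsAsFactors = FALSE)
  }
  igraph::graph_from_data_frame(df, directed = FALSE)
}

#' Six-index centrality table
#'
#' Computes, for every node of an undirected simple graph (topology only;
#' edge confidences are not used as weights):
#' \describe{
#'   \item{dc}{degree.}
#'   \item{bc}{betweenness (unnormalized Brandes sum over unordered pairs;
#'     disconnected pairs contribute 0).}
#'   \item{cc}{per-component closeness `(n_c - 1) / sum of distances` to the
#'     other members of the node's connected component (0 for an isolated
#'     component of size 1).}
#'   \item{ec}{eigenvector centrality, principal eigenvector of the adjacency
#'     matrix scaled so its maximum entry is 1.}
#'   \item{lac}{local average connectivity: mean degree of the node's
#'     neighbors within the subgraph induced by the neighborhood; 0 for
#'     degree-0 nodes.}
#'   \item{nc}{network centrality: sum over incident edges of the edge
#'     clustering coefficient `ECC(u, v) = triangles(u, v) /
#'     min(deg(u) - 1, deg(v) - 1)`, with 0/0 defined as 0.}
#' }
#'
#' @param g an igraph, e.g. from [build_ppi_graph()].
#' @return data.frame with columns `node`, `dc`, `bc`, `cc`, `ec`, `lac`,
#'   `nc`, one row per node.
#' @export
compute_centralities <- function(g) {
  stopifnot(igraph::is_igraph(g))
  n <- igraph::vcount(g)
  if (n == 0L) stop("empty graph")
  A <- as.matrix(igraph::as_adjacency_matrix(g, type = "both", sparse = TRUE))
  A[A > 1] <- 1
  deg <- rowSums(A)
  bc <- igraph::betweenness(g, directed = FALSE, weights = NA)
  # per-component closeness
  dmat <- igraph::distances(g, weights = NA)
  cc <- vapply(seq_len(n), function(i) {
    d <- dmat[i, -i]
    d <- d[is.finite(d)]
    if (length(d) == 0L) 0 else length(d) / sum(d)
  }, numeric(1))
  # principal adjacency eigenvector via LAPACK (deterministic, unlike the
  # randomly initialized ARPACK path), folded to non-negative, max = 1
  ec <- if (igraph::ecount(g) == 0L) {
    rep(0, n)
  } else {
    v <- abs(eigen(A, symmetric = TRUE)$vectors[, 1])
    v / max(v)
  }
  tri <- A %*% A * A  # tri[u,v] = common neighbors of u,v if adjacent
  lac <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) == 0L) return(0)
    # degree within induced neighborhood = row sums of A[nb, nb]
    mean(rowSums(A[nb, nb, drop = FALSE]))
  }, numeric(1))
  nc <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) == 0L) return(0)
    den <- pmin(deg[i] - 1, deg[nb] - 1)
    ecc <- ifelse(den > 0, tri[i, nb] / den, 0)
    sum(ecc)
  }, numeric(1))
  data.frame(node = igraph::V(g)$name, dc = as.numeric(deg),
             bc = as.numeric(bc), cc = cc, ec = as.numeric(ec),
             lac = lac, nc = nc, stringsAsFactors = FALSE, row.names = NULL)
}

centrality_indices <- c("dc", "bc", "cc", "ec", "lac", "nc")

#' One median-filtering round
#'
#' Computes the six-index centrality table and retains the nodes whose score
#' passes the per-index median on all six indices. With the default `strict`
#' comparator "passes" means strictly greater than the median; `inclusive`
#' means greater than or equal.
#'
#' @param g an igraph with at least 2 nodes.
#' @param comparator `"strict"` or `"inclusive"`.
#' @return list with `survivors` (node names, possibly empty), `medians`
#'   (named numeric of the six per-index medians), and `table` (the
#'   centrality table).
#' @export
median_filter_step <- function(g, comparator = c("strict", "inclusive")) {
  comparator <- match.arg(comparator)
  stopifnot(igraph::vcount(g) >= 2L)
  tab <- compute_centralities(g)
  med <- vapply(centrality_indices, function(j) stats::median(tab[[j]]),
                numeric(1))
  # tolerance so numerically tied scores (e.g. ARPACK eigenvector jitter on
  # symmetric graphs) compare as equal to the median
  pass <- vapply(centrality_indices, function(j) {
    tol <- 1e-8 * max(1, abs(med[[j]]))
    if (comparator == "strict") tab[[j]] > med[[j]] + tol
    else tab[[j]] >= med[[j]] - tol
  }, logical(nrow(tab)))
  if (nrow(tab) == 1L) pass <- matrix(pass, nrow = 1L)
  keep <- rowSums(pass) == length(centrality_indices)
  list(survivors = tab$node[keep], medians = med, table = tab)
}

#' Iterative hub-subnetwork extraction
#'
#' Repeats [median_filter_step()] for up to `rounds` rounds (three in the
#' standard protocol), each time inducing the subgraph on the survivors and
#' re-removing isolated nodes, and recomputing centralities on that subgraph.
#' Stops early -- returning the last valid subnetwork -- when the survivor
#' set is empty, unchanged from the previous round, or smaller than
#' `min_size`.
#'
#' @param g an igraph, e.g. from [build_ppi_graph()].
#' @param rounds number of filtering rounds. Default 3.
#' @param min_size smallest admissible subnetwork. Default 3.
#' @param comparator passed to [median_filter_step()].
#' @return list with `subnetwork` (igraph) and `trace` (class `hub_trace`):
#'   one element per executed round holding `input_nodes`, `medians`,
#'   `survivors`; plus `stop_reason` in
#'   completed/empty-result/unchanged/below-min-size.
#' @export
extract_hub_subnetwork <- function(g, rounds = 3L, min_size = 3L,
                                   comparator = c("strict", "inclusive")) {
  comparator <- match.arg(comparator)
  stopifnot(rounds >= 1L)
  if (igraph::vcount(g) < 2L) stop("graph must have at least 2 nodes")
  cur <- g
  iterations <- list()
  stop_reason <- "completed"
  for (r in seq_len(rounds)) {
    step <- median_filter_step(cur, comparator)
    surv <- step$survivors
    iterations[[r]] <- list(round = r,
                            input_nodes = igraph::V(cur)$name,
                            medians = step$medians,
                            survivors = surv)
    if (length(surv) == 0L) {
      stop_reason <- "empty-result"
      break
    }
    nxt <- igraph::induced_subgraph(cur, surv)
    iso <- igraph::V(nxt)[igraph::degree(nxt) == 0]
    if (length(iso) > 0L) nxt <- igraph::delete_vertices(nxt, iso)
    if (igraph::vcount(nxt) < min_size) {
      stop_reason <- "below-min-size"
      break
    }
    if (setequal(igraph::V(nxt)$name, igraph::V(cur)$name)) {
      cur <- nxt
      stop_reason <- "unchanged"
      break
    }
    cur <- nxt
    if (igraph::vcount(cur) < 2L) break  # next round infeasible
  }
  trace <- structure(list(iterations = iterations, stop_reason = stop_reason,
                          comparator = comparator, rounds = rounds,
                          min_size = min_size),
                     class = "hub_trace")
  list(subnetwork = cur, trace = trace)
}

#' @export
print.hub_trace <- function(x, ...) {
  cat(sprintf("Hub extraction trace: %d round(s), stop reason '%s'\n",
              length(x$iterations), x$stop_reason))
  for (it in x$iterations) {
    cat(sprintf("  round %d: %d nodes -> %d survivors\n", it$round,
                length(it$input_nodes), length(it$survivors)))
  }
  invisible(x)
}

#' Read a STRING-style PPI edge list
#'
#' Tab-separated `protein1 protein2 combined_score`. STRING exports scores on
#' a 0--1000 scale; any file whose maximum score exceeds 1 is auto-detected
#' as that dialect and divided by 1000.
#'
#' @param path TSV file path.
#' @return data.frame `from`, `to`, `confidence` in \[0, 1\].
#' @export
read_ppi_edges <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(ncol(df) >= 3L)
  df <- df[, 1:3]
  names(df) <- c("from", "to", "confidence")
  df$confidence <- as.numeric(df$confidence)
  if (any(df$confidence > 1, na.rm = TRUE))
    df$confidence <- df$confidence / 1000
  df
}
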