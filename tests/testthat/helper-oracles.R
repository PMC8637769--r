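# Independent brute-force oracles, written directly against the adjacency
# matrix (explicit BFS path counting, triangle enumeration, power iteration)
# so they share no code path with the package's graph machinery.

# adjacency matrix of a random connected graph: random spanning path + ER
random_connected_adjacency <- function(n, p) {
  A <- matrix(0, n, n)
  perm <- sample(n)
  for (i in seq_len(n - 1)) A[perm[i], perm[i + 1]] <- 1
  extra <- matrix(runif(n * n) < p, n, n)
  A <- pmax(A, extra * upper.tri(extra))
  A <- pmax(A, t(A))
  diag(A) <- 0
  dimnames(A) <- list(paste0("v", 1:n), paste0("v", 1:n))
  A
}

# BFS distances and shortest-path counts from every source
oracle_paths <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  Sig <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); sig <- rep(0, n)
    dist[s] <- 0; sig[s] <- 1
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (u in frontier) {
        for (v in which(A[u, ] > 0)) {
          if (is.infinite(dist[v])) {
            dist[v] <- dist[u] + 1
            nxt <- c(nxt, v)
          }
          if (dist[v] == dist[u] + 1) sig[v] <- sig[v] + sig[u]
        }
      }
      frontier <- unique(nxt)
    }
    D[s, ] <- dist
    Sig[s, ] <- sig
  }
  list(D = D, Sig = Sig)
}

# all six indices by enumeration / power iteration
oracle_centralities <- function(A) {
  n <- nrow(A)
  deg <- rowSums(A)
  pp <- oracle_paths(A)
  D <- pp$D; Sig <- pp$Sig
  bc <- numeric(n)
  for (v in seq_len(n)) {
    # pair (s, t) contributes Sig[s,v] * Sig[v,t] / Sig[s,t] when v lies on
    # a shortest s-t path (D[s,v] + D[v,t] == D[s,t])
    on_path <- outer(D[, v], D[v, ], "+") == D & is.finite(D)
    contrib <- outer(Sig[, v], Sig[v, ]) / ifelse(Sig > 0, Sig, 1)
    contrib[!on_path] <- 0
    contrib[v, ] <- 0; contrib[, v] <- 0
    bc[v] <- sum(contrib[upper.tri(contrib)])
  }
  cc <- vapply(seq_len(n), function(v) {
    d <- D[v, -v]; d <- d[is.finite(d)]
    if (length(d) == 0) 0 else length(d) / sum(d)
  }, numeric(1))
  # power iteration for the principal adjacency eigenvector; iterate on
  # A + cI (same Perron vector) so near-bipartite spectra still converge
  shift <- max(deg) + 1
  As <- A + diag(shift, n)
  x <- rep(1, n)
  for (i in 1:10000) {
    xn <- As %*% x
    nrm <- sqrt(sum(xn^2))
    if (nrm == 0) { x <- rep(0, n); break }
    xn <- xn / nrm
    if (max(abs(xn - x)) < 1e-14) { x <- xn; break }
    x <- xn
  }
  ec <- abs(as.numeric(x))
  if (max(ec) > 0) ec <- ec / max(ec)
  lac <- vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] > 0)
    if (length(nb) == 0) return(0)
    sub <- A[nb, nb, drop = FALSE]
    mean(rowSums(sub))
  }, numeric(1))
  nc <- vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] > 0)
    acc <- 0
    for (w in nb) {
      tri <- sum(A[v, ] * A[w, ])
      den <- min(deg[v] - 1, deg[w] - 1)
      if (den > 0) acc <- acc + tri / den
    }
    acc
  }, numeric(1))
  data.frame(node = rownames(A), dc = deg, bc = bc, cc = cc, ec = ec,
             lac = lac, nc = nc, stringsAsFactors = FALSE, row.names = NULL)
}

igraph_from_adjacency <- function(A) {
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

# hand step-up BH
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  cummin_rev <- rev(cummin(rev(p[o] * n / seq_len(n))))
  adj[o] <- pmin(cummin_rev, 1)
  adj
}

# exhaustive hypergeometric upper tail by enumerating all C(N, n) draws
oracle_hyper <- function(k, K, n, N) {
  marked <- seq_len(K)
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  hits <- apply(draws, 2, function(dr) sum(dr %in% marked))
  mean(hits >= k)
}

make_graph_named <- function(el) {
  igraph::graph_from_edgelist(el, directed = FALSE)
}
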