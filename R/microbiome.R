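# Downstream statistics on OTU/ASV count tables: low-abundance filtration,
# composition profiles, alpha diversity (coverage, Chao1, ACE, Shannon,
# Simpson), rarefaction, binary-Jaccard beta diversity, PCoA, NMDS, UPGMA
# and a two-class LEfSe-style biomarker screen.

#' Construct a feature table
#'
#' Container for a samples x features count matrix with per-feature taxonomy
#' and per-sample group labels.
#'
#' @param counts samples x features matrix of non-negative integers with
#'   dimnames (rows samples, columns features).
#' @param taxonomy optional: either a data.frame of ranked lineages (rownames
#'   or a `feature` column matching feature ids; columns among kingdom,
#'   phylum, class, order, family, genus) or a character vector of
#'   `k__...;p__...;c__...;o__...;f__...;g__...` lineage strings named by
#'   feature.
#' @param groups named character/factor of group labels, one per sample.
#' @return object of class `feature_table`.
#' @export
feature_table <- function(counts, taxonomy = NULL, groups = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) && nrow(counts) > 0)
    rownames(counts) <- paste0("S", seq_len(nrow(counts)))
  if (is.null(colnames(counts)) && ncol(counts) > 0)
    colnames(counts) <- paste0("OTU", seq_len(ncol(counts)))
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  if (!is.null(taxonomy)) {
    if (is.character(taxonomy)) taxonomy <- parse_taxonomy(taxonomy)
    if ("feature" %in% names(taxonomy)) {
      rownames(taxonomy) <- taxonomy$feature
      taxonomy$feature <- NULL
    }
    taxonomy <- taxonomy[colnames(counts), , drop = FALSE]
    rownames(taxonomy) <- colnames(counts)
  }
  if (!is.null(groups)) {
    groups <- stats::setNames(as.character(groups),
                              names(groups) %||% rownames(counts))
    if (!all(rownames(counts) %in% names(groups)))
      stop("every sample needs a group label")
    groups <- groups[rownames(counts)]
  }
  structure(list(counts = counts, taxonomy = taxonomy, groups = groups),
            class = "feature_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("Feature table: %d samples x %d features, %s total reads\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  if (!is.null(x$groups))
    cat("  groups:", paste(sprintf("%s (n=%d)", names(table(x$groups)),
                                   table(x$groups)), collapse = ", "), "\n")
  invisible(x)
}

#' Parse greengenes-style lineage strings
#'
#' @param lineages character vector like
#'   `"k__Bacteria;p__Firmicutes;c__;o__;f__;g__Roseburia"`.
#' @return data.frame with columns kingdom, phylum, class, order, family,
#'   genus (`NA` where the rank is empty).
#' @export
parse_taxonomy <- function(lineages) {
  ranks <- c(k = "kingdom", p = "phylum", c = "class", o = "order",
             f = "family", g = "genus")
  parts <- strsplit(as.character(lineages), ";", fixed = TRUE)
  out <- lapply(parts, function(p) {
    p <- trimws(p)
    vals <- stats::setNames(rep(NA_character_, length(ranks)), ranks)
    for (piece in p) {
      m <- regmatches(piece, regexec("^([kpcofg])__(.*)$", piece))[[1]]
      if (length(m) == 3L && m[2] %in% names(ranks) && nzchar(m[3]))
        vals[ranks[[m[2]]]] <- m[3]
    }
    vals
  })
  df <- as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE)
  rownames(df) <- names(lineages) %||% NULL
  df
}

#' Remove low-abundance features
#'
#' Drops features whose total count across all samples falls below
#' `min_fraction` of the table's grand total (the conventional conservative
#' 0.005% OTU filtration). The boundary is inclusive: a feature at exactly
#' the threshold is kept.
#'
#' @param t a `feature_table` with at least one read.
#' @param min_fraction fraction of the grand total. Default `5e-5` (0.005%).
#' @return filtered `feature_table`.
#' @export
filter_low_abundance <- function(t, min_fraction = 5e-5) {
  stopifnot(inherits(t, "feature_table"))
  grand <- sum(t$counts)
  if (grand <= 0) stop("feature table has no reads")
  keep <- colSums(t$counts) >= min_fraction * grand
  if (!any(keep))
    warning("all features fall below the abundance threshold")
  feature_table(t$counts[, keep, drop = FALSE],
                taxonomy = if (is.null(t$taxonomy)) NULL else
                  t$taxonomy[keep, , drop = FALSE],
                groups = t$groups)
}

#' Taxonomic composition profile
#'
#' Aggregates relative abundances at a taxonomic rank, keeps the `top_n`
#' taxa by mean relative abundance and pools the remainder into `"Others"`.
#' Features unassigned at the rank are labelled `"Unclassified"` and compete
#' for the top slots like any taxon.
#'
#' @param t a `feature_table` with taxonomy.
#' @param rank `"phylum"` or `"genus"` (any taxonomy column works).
#' @param top_n number of named taxa to keep. Default 10.
#' @return taxa x samples matrix of relative abundances; every column sums
#'   to 1.
#' @export
composition_profile <- function(t, rank = c("phylum", "genus"), top_n = 10) {
  rank <- match.arg(rank, choices = c("phylum", "genus", "kingdom", "class",
                                      "order", "family"))
  stopifnot(inherits(t, "feature_table"))
  if (is.null(t$taxonomy) || !(rank %in% names(t$taxonomy)))
    stop("taxonomy at rank '", rank, "' is not available")
  taxa <- t$taxonomy[[rank]]
  if (all(is.na(taxa))) stop("taxonomy at rank '", rank, "' is empty")
  taxa[is.na(taxa) | !nzchar(taxa)] <- "Unclassified"
  rel <- t$counts / rowSums(t$counts)
  agg <- rowsum(base::t(rel), group = taxa)  # taxa x samples
  ord <- order(rowMeans(agg), decreasing = TRUE)
  agg <- agg[ord, , drop = FALSE]
  if (nrow(agg) > top_n) {
    head_m <- agg[seq_len(top_n), , drop = FALSE]
    others <- colSums(agg[-seq_len(top_n), , drop = FALSE])
    agg <- rbind(head_m, Others = others)
  }
  agg
}

#' Alpha-diversity indices for one sample
#'
#' Computes Good's coverage, Chao1, ACE, Shannon and Simpson from a single
#' sample's feature counts.
#'
#' Formulas (with `S` observed taxa, `N` reads, `F_i` taxa seen `i` times):
#' coverage `1 - F1/N`; Chao1 bias-corrected `S + F1(F1-1)/(2(F2+1))`
#' (classic `S + F1^2/(2 F2)` by flag, falling back to the bias-corrected
#' form when `F2 = 0`); ACE with rare/abundant cutoff `ace_cutoff` reads,
#' `C_ACE = 1 - F1/N_rare`,
#' `gamma^2 = max(S_rare * sum(i(i-1)F_i) / (C_ACE N_rare (N_rare-1)) - 1, 0)`,
#' `ACE = S_abund + S_rare/C_ACE + F1 gamma^2 / C_ACE`; Shannon
#' `-sum(p_i ln p_i)` (natural log); Simpson as Gini-Simpson
#' `1 - sum(p_i^2)` so that larger means more diverse (classic dominance
#' `sum(p_i^2)` by flag).
#'
#' @param counts non-negative count vector for one sample (zeros allowed).
#' @param chao1_form `"bc"` (bias-corrected, default) or `"classic"`.
#' @param simpson_form `"gini"` (default) or `"classic"`.
#' @param ace_cutoff rare/abundant boundary in reads. Default 10.
#' @return named numeric: `coverage`, `chao1`, `ace`, `shannon`, `simpson`.
#' @export
alpha_diversity <- function(counts, chao1_form = c("bc", "classic"),
                            simpson_form = c("gini", "classic"),
                            ace_cutoff = 10) {
  chao1_form <- match.arg(chao1_form)
  simpson_form <- match.arg(simpson_form)
  counts <- as.numeric(counts)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  x <- counts[counts > 0]
  if (length(x) == 0L) stop("sample has no reads")
  N <- sum(x); S <- length(x)
  F1 <- sum(x == 1); F2 <- sum(x == 2)
  coverage <- 1 - F1 / N
  chao1 <- if (chao1_form == "classic" && F2 > 0) {
    S + F1^2 / (2 * F2)
  } else {
    S + F1 * (F1 - 1) / (2 * (F2 + 1))
  }
  rare <- x[x <= ace_cutoff]
  S_abund <- sum(x > ace_cutoff)
  S_rare <- length(rare)
  N_rare <- sum(rare)
  if (S_rare == 0L) {
    ace <- S_abund
  } else {
    C_ace <- 1 - F1 / N_rare
    if (C_ace <= 0) {
      warning("ACE sample coverage is 0 (all rare reads are singletons); ",
              "falling back to Chao1")
      ace <- chao1
    } else {
      Fi <- tabulate(rare, nbins = ace_cutoff)
      i <- seq_len(ace_cutoff)
      gamma2 <- if (N_rare > 1) {
        max(S_rare * sum(i * (i - 1) * Fi) /
              (C_ace * N_rare * (N_rare - 1)) - 1, 0)
      } else 0
      ace <- S_abund + S_rare / C_ace + F1 * gamma2 / C_ace
    }
  }
  p <- x / N
  shannon <- -sum(p * log(p))
  simpson <- if (simpson_form == "gini") 1 - sum(p^2) else sum(p^2)
  c(coverage = coverage, chao1 = chao1, ace = ace, shannon = shannon,
    simpson = simpson)
}

#' Exact rarefaction curve
#'
#' Expected richness when subsampling a sample without replacement:
#' `E[S_n] = S - sum_i C(N - N_i, n) / C(N, n)`, evaluated in log space.
#'
#' @param counts non-negative count vector for one sample.
#' @param depths subsampling depths, each between 1 and `sum(counts)`.
#' @return data.frame `depth`, `richness`.
#' @export
rarefaction_curve <- function(counts, depths) {
  x <- as.numeric(counts)
  x <- x[x > 0]
  if (length(x) == 0L) stop("sample has no reads")
  N <- sum(x); S <- length(x)
  depths <- as.numeric(depths)
  if (any(depths > N)) stop("depth exceeds the sample's read count")
  if (any(depths < 1)) stop("depths must be >= 1")
  rich <- vapply(depths, function(n) {
    S - sum(exp(lchoose(N - x, n) - lchoose(N, n)))
  }, numeric(1))
  data.frame(depth = depths, richness = rich)
}

#' Binary Jaccard distance matrix
#'
#' Presence/absence Jaccard dissimilarity between samples:
#' `d = 1 - |A intersect B| / |A union B|`; two samples with no features at
#' all are at distance 0.
#'
#' @param t a `feature_table` (or samples x features matrix) with >= 2
#'   samples.
#' @return a [stats::dist] object.
#' @export
jaccard_distance_matrix <- function(t) {
  m <- if (inherits(t, "feature_table")) t$counts else as.matrix(t)
  if (nrow(m) < 2L) stop("need at least 2 samples")
  P <- (m > 0) * 1
  inter <- P %*% base::t(P)
  sz <- rowSums(P)
  uni <- outer(sz, sz, "+") - inter
  d <- 1 - ifelse(uni > 0, inter / uni, 1)  # both-empty pairs -> d = 0
  diag(d) <- 0
  stats::as.dist(d)
}

#' Principal coordinates analysis (classical MDS)
#'
#' Gower double-centering of `-0.5 * D^2` followed by eigendecomposition.
#' Coordinates are eigenvectors scaled by the square root of their (positive)
#' eigenvalues; negative eigenvalues are reported but contribute no axis.
#'
#' @param d a [stats::dist] or symmetric zero-diagonal matrix.
#' @return object of class `pcoa`: list with `coordinates` (samples x axes),
#'   `eigenvalues` (all, non-increasing), `labels`.
#' @export
pcoa <- function(d) {
  D <- as.matrix(d)
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (any(abs(diag(D)) > 1e-8)) stop("distance matrix must have zero diagonal")
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  e <- eigen((B + base::t(B)) / 2, symmetric = TRUE)
  vals <- e$values
  tol <- 1e-9 * max(abs(vals), 1)
  pos <- which(vals > tol)
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(vals[pos]), nrow = length(pos))
  labels <- rownames(D) %||% paste0("S", seq_len(n))
  rownames(coords) <- labels
  colnames(coords) <- paste0("Axis", seq_along(pos))
  structure(list(coordinates = coords, eigenvalues = vals, labels = labels),
            class = "pcoa")
}

#' Non-metric multidimensional scaling (Kruskal stress-1)
#'
#' Minimizes Kruskal stress-1 by alternating monotone (isotonic) regression
#' of configuration distances on dissimilarity ranks with a Guttman
#' (majorization) configuration update. Ties in the dissimilarities are
#' handled by the primary approach (tied blocks ordered by current
#' configuration distance before the isotonic fit). The best of one
#' metric-scaling (PCoA) start and `n_starts` random starts is returned;
#' within a run the recorded stress sequence is non-increasing (an update
#' that fails to decrease stress ends the run).
#'
#' @param d distance matrix ([stats::dist] or symmetric matrix), >= 4
#'   samples for the default `k = 2`.
#' @param k embedding dimension. Default 2.
#' @param n_starts number of random starts in addition to the metric start.
#' @param seed optional integer seed for the random starts.
#' @param maxit maximum iterations per start. Default 200.
#' @param tol relative stress-improvement convergence tolerance.
#' @return object of class `nmds`: `points` (samples x k), `stress`,
#'   `stress_trace` (of the best run), `converged`, `valid`
#'   (stress < 0.2), `labels`.
#' @export
nmds <- function(d, k = 2, n_starts = 20, seed = NULL, maxit = 200,
                 tol = 1e-7) {
  D <- as.matrix(d)
  n <- nrow(D)
  if (n < k + 2) stop("need at least k + 2 samples")
  labels <- rownames(D) %||% paste0("S", seq_len(n))
  delta <- D[lower.tri(D)]
  pair_i <- row(D)[lower.tri(D)]
  pair_j <- col(D)[lower.tri(D)]

  run <- function(X) {
    X <- scale(X, scale = FALSE)
    trace <- numeric(0)
    converged <- FALSE
    cfg_dist <- function(X) {
      dd <- as.matrix(stats::dist(X))
      dd[lower.tri(dd)]
    }
    fit_stress <- function(dv) {
      ord <- order(delta, dv)  # primary approach to ties
      yf <- stats::isoreg(seq_along(dv), dv[ord])$yf
      dhat <- numeric(length(dv))
      dhat[ord] <- yf
      denom <- sum(dv^2)
      s <- if (denom > 0) sqrt(sum((dv - dhat)^2) / denom) else 0
      list(dhat = dhat, stress = s)
    }
    dv <- cfg_dist(X)
    fs <- fit_stress(dv)
    s_prev <- fs$stress
    trace <- s_prev
    for (it in seq_len(maxit)) {
      # Guttman transform toward the isotonic targets
      ratio <- ifelse(dv > 0, fs$dhat / dv, 0)
      B <- matrix(0, n, n)
      B[cbind(pair_i, pair_j)] <- -ratio
      B[cbind(pair_j, pair_i)] <- -ratio
      diag(B) <- -rowSums(B)
      Xn <- (B %*% X) / n
      dvn <- cfg_dist(Xn)
      fsn <- fit_stress(dvn)
      if (fsn$stress > s_prev - 1e-12) {
        converged <- TRUE  # majorization stalled; stress cannot decrease
        break
      }
      X <- Xn; dv <- dvn; fs <- fsn
      trace <- c(trace, fs$stress)
      if (s_prev - fs$stress < tol * max(s_prev, 1e-12)) {
        s_prev <- fs$stress
        converged <- TRUE
        break
      }
      s_prev <- fs$stress
    }
    list(X = X, stress = s_prev, trace = trace, converged = converged)
  }

  starts <- list(pcoa_start(D, k))
  extra <- with_seed(seed, {
    lapply(seq_len(n_starts), function(i)
      matrix(stats::runif(n * k, -0.5, 0.5), n, k))
  })
  starts <- c(starts, extra)
  runs <- lapply(starts, run)
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "stress"))]]
  if (!best$converged)
    warning("NMDS did not converge within maxit; returning best-so-far")
  pts <- scale(best$X, scale = FALSE)
  pr <- stats::prcomp(pts, center = FALSE)          # rotate to principal axes
  pts <- pr$x[, seq_len(k), drop = FALSE]
  rownames(pts) <- labels
  colnames(pts) <- paste0("NMDS", seq_len(k))
  structure(list(points = pts, stress = best$stress,
                 stress_trace = best$trace, converged = best$converged,
                 valid = best$stress < 0.2, labels = labels),
            class = "nmds")
}

# metric-scaling initial configuration, padded with jitter when the distance
# matrix yields fewer than k positive axes
pcoa_start <- function(D, k) {
  co <- pcoa(stats::as.dist(D))$coordinates
  n <- nrow(D)
  X <- matrix(0, n, k)
  take <- min(k, ncol(co))
  if (take > 0) X[, seq_len(take)] <- co[, seq_len(take)]
  if (take < k)
    X[, (take + 1):k] <- matrix(stats::rnorm(n * (k - take), sd = 1e-4),
                                n, k - take)
  X
}

#' @export
print.nmds <- function(x, ...) {
  cat(sprintf("NMDS (k = %d): stress-1 = %.4f (%s; %s)\n", ncol(x$points),
              x$stress, if (x$valid) "valid, stress < 0.2" else "stress >= 0.2",
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' UPGMA hierarchical clustering
#'
#' Average-linkage agglomeration with cluster-size weighting. At every step
#' the closest pair of clusters is merged (ties broken deterministically in
#' favor of the pair containing the earliest label) at a height equal to
#' their average distance; leaf-to-root depth is half the merge height, so
#' cophenetic distances reproduce ultrametric inputs exactly.
#'
#' @param d a [stats::dist] or symmetric distance matrix, >= 2 samples.
#' @return object of class `upgma`: `hclust` (a [stats::hclust]-compatible
#'   object), `newick` (Newick string with branch lengths), `merge`,
#'   `height`, `labels`.
#' @export
upgma <- function(d) {
  D <- as.matrix(d)
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 samples")
  labels <- rownames(D) %||% paste0("S", seq_len(n))
  size <- rep(1L, n)
  id <- -seq_len(n)              # hclust convention: negatives are leaves
  minleaf <- seq_len(n)          # earliest original leaf per cluster
  active <- rep(TRUE, n)
  Dw <- D
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  node_h <- c(rep(0, n), numeric(n - 1L))   # heights/2 later for branches
  children <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    act <- which(active)
    best <- NULL
    best_d <- Inf
    for (ii in seq_along(act)) for (jj in seq_along(act)) {
      if (jj <= ii) next
      a <- act[ii]; b <- act[jj]
      dd <- Dw[a, b]
      pick <- dd < best_d - 1e-12 ||
        (abs(dd - best_d) <= 1e-12 && !is.null(best) &&
           (min(minleaf[a], minleaf[b]) <
              min(minleaf[best[1]], minleaf[best[2]]) ||
            (min(minleaf[a], minleaf[b]) ==
               min(minleaf[best[1]], minleaf[best[2]]) &&
             max(minleaf[a], minleaf[b]) <
               max(minleaf[best[1]], minleaf[best[2]]))))
      if (pick) { best <- c(a, b); best_d <- dd }
    }
    a <- best[1]; b <- best[2]
    merge[s, ] <- sort(c(id[a], id[b]))
    height[s] <- best_d
    children[[s]] <- c(id[a], id[b])
    # size-weighted average update into slot a
    for (kk in act) {
      if (kk == a || kk == b) next
      Dw[a, kk] <- Dw[kk, a] <-
        (size[a] * Dw[a, kk] + size[b] * Dw[b, kk]) / (size[a] + size[b])
    }
    size[a] <- size[a] + size[b]
    active[b] <- FALSE
    minleaf[a] <- min(minleaf[a], minleaf[b])
    id[a] <- s
  }
  hc <- structure(list(merge = merge, height = height,
                       order = upgma_leaf_order(merge, n),
                       labels = labels, method = "average",
                       call = match.call(), dist.method = "user"),
                  class = "hclust")
  nwk <- paste0(upgma_newick(n - 1L, merge, height, labels), ";")
  structure(list(hclust = hc, newick = nwk, merge = merge, height = height,
                 labels = labels), class = "upgma")
}

upgma_leaf_order <- function(merge, n) {
  rec <- function(node) {
    if (node < 0) return(-node)
    c(rec(merge[node, 1]), rec(merge[node, 2]))
  }
  rec(nrow(merge))
}

upgma_newick <- function(node, merge, height, labels) {
  node_height <- function(nd) if (nd < 0) 0 else height[nd] / 2
  min_leaf <- function(nd) {
    if (nd < 0) return(-nd)
    min(min_leaf(merge[nd, 1]), min_leaf(merge[nd, 2]))
  }
  rec <- function(nd) {
    if (nd < 0) return(labels[-nd])
    kids <- merge[nd, ]
    kids <- kids[order(vapply(kids, min_leaf, numeric(1)))]
    h <- height[nd] / 2
    parts <- vapply(kids, function(ch) {
      bl <- h - node_height(ch)
      paste0(rec(ch), ":", sprintf("%.10g", bl))
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  rec(node)
}

#' @export
print.upgma <- function(x, ...) {
  cat("UPGMA clustering of", length(x$labels), "samples\n")
  cat(" ", x$newick, "\n")
  invisible(x)
}

#' Two-class LEfSe-style biomarker screen
#'
#' A documented reimplementation variant of the LEfSe procedure for exactly
#' two groups. Per feature, on relative abundances scaled to 1e6: (1) a
#' Kruskal-Wallis test keeps features with `p < alpha`; (2) over `n_boot`
#' bootstrap resamples (drawn within each group) a one-dimensional two-class
#' linear discriminant reduces to the absolute difference of class means
#' along the feature axis; each bootstrap effect is averaged with the
#' feature's full-sample class-mean difference and the bootstrap mean is the
#' effect size. `lda_effect = max(1, log10(effect))`; a feature is a
#' biomarker when `kw_p < alpha` and `lda_effect >= lda_min`.
#'
#' @param t a `feature_table` with exactly two groups, >= 3 samples each.
#' @param alpha Kruskal-Wallis significance gate. Default 0.05.
#' @param lda_min log10 effect-size threshold. Default 2.
#' @param n_boot bootstrap resamples. Default 30.
#' @param seed optional integer seed.
#' @return data.frame of class `lefse_result`: `feature`, `kw_p`,
#'   `lda_effect` (NA when the KW gate fails), `enriched_group`,
#'   `significant`.
#' @export
lefse <- function(t, alpha = 0.05, lda_min = 2.0, n_boot = 30, seed = NULL) {
  stopifnot(inherits(t, "feature_table"))
  if (is.null(t$groups)) stop("feature table has no group labels")
  grp <- factor(t$groups)
  if (nlevels(grp) != 2L)
    stop("lefse requires exactly 2 groups, got ", nlevels(grp))
  if (any(table(grp) < 3L)) stop("need >= 3 samples per group")
  X <- t$counts / rowSums(t$counts) * 1e6
  ia <- which(grp == levels(grp)[1])
  ib <- which(grp == levels(grp)[2])
  kw_p <- apply(X, 2L, function(x) {
    if (stats::var(x) == 0) return(1)
    stats::kruskal.test(x, grp)$p.value
  })
  res <- data.frame(feature = colnames(X), kw_p = as.numeric(kw_p),
                    lda_effect = NA_real_,
                    enriched_group = NA_character_,
                    significant = FALSE, stringsAsFactors = FALSE,
                    row.names = NULL)
  mean_a <- colMeans(X[ia, , drop = FALSE])
  mean_b <- colMeans(X[ib, , drop = FALSE])
  res$enriched_group <- ifelse(mean_a >= mean_b, levels(grp)[1],
                               levels(grp)[2])
  pass <- which(res$kw_p < alpha)
  if (length(pass) > 0L) {
    raw_diff <- abs(mean_a - mean_b)
    boot_eff <- with_seed(seed, {
      acc <- matrix(0, nrow = n_boot, ncol = length(pass))
      for (b in seq_len(n_boot)) {
        sa <- sample(ia, length(ia), replace = TRUE)
        sb <- sample(ib, length(ib), replace = TRUE)
        db <- abs(colMeans(X[sa, pass, drop = FALSE]) -
                    colMeans(X[sb, pass, drop = FALSE]))
        acc[b, ] <- (db + raw_diff[pass]) / 2
      }
      colMeans(acc)
    })
    res$lda_effect[pass] <- ifelse(boot_eff > 0,
                                   pmax(1, log10(boot_eff)), 1)
    res$significant <- !is.na(res$lda_effect) & res$kw_p < alpha &
      res$lda_effect >= lda_min
  }
  class(res) <- c("lefse_result", "data.frame")
  res
}
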