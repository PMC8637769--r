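# Seeded generators for every pipeline input, each emitting planted ground
# truth alongside the data. A master seed fans out to independent
# per-generator substreams, so adding a generator never perturbs another.
#
# Default scenarios state a "paper-like" world: a six-herb formula, five
# disease-gene databases, a STRING-like PPI graph with a dense planted
# module, Dirichlet-multinomial 16S count tables with a multiplicative
# group effect, and three DAI cohorts of 15 mice.

default_herb_ids <- c("Mf", "Zr", "Ar", "CRr", "CPr", "Pp")

#' Generate herb-compound and compound-target tables
#'
#' OB is drawn from a right-skewed lognormal on \[0, 100\] (most compounds
#' fail the 20% cutoff, as in typical TCMSP exports) and DL from a
#' Beta(1.2, 5) on \[0, 1\]. A fraction of compound slots reuse a compound
#' already assigned to another herb (shared constituents such as quercetin).
#' Ground truth records which herb-compound records pass the ADME cutoffs.
#'
#' @param n_herbs number of herbs. Default 6.
#' @param compounds_per_herb compound slots per herb. Default 15.
#' @param target_universe_size size of the target gene pool. Default 300.
#' @param shared_compound_rate probability a slot reuses an existing
#'   compound. Default 0.15.
#' @param targets_per_compound Poisson mean of targets per compound.
#' @param ob_meanlog,ob_sdlog lognormal parameters of OB (percent).
#' @param dl_shape1,dl_shape2 Beta parameters of DL.
#' @param seed integer seed.
#' @return list: `compounds` (herb_id, compound_id, compound_name, ob, dl),
#'   `targets` (compound_id, gene_symbol), `truth` (per record, `kept` under
#'   the 20% / 0.18 cutoffs).
#' @export
gen_hit_tables <- function(n_herbs = 6, compounds_per_herb = 15,
                           target_universe_size = 300,
                           shared_compound_rate = 0.15,
                           targets_per_compound = 8,
                           ob_meanlog = log(15), ob_sdlog = 0.8,
                           dl_shape1 = 1.2, dl_shape2 = 5, seed = 1) {
  stopifnot(n_herbs >= 1, compounds_per_herb >= 1, target_universe_size >= 1)
  herbs <- if (n_herbs <= length(default_herb_ids))
    default_herb_ids[seq_len(n_herbs)]
  else c(default_herb_ids, paste0("H", seq_len(n_herbs -
                                                 length(default_herb_ids))))
  genes <- sprintf("TGT%04d", seq_len(target_universe_size))
  with_seed(substream_seed(seed, "hit_tables"), {
    pool <- list()  # compound_id -> list(ob, dl, targets)
    rows <- list()
    for (h in herbs) {
      in_herb <- character(0)
      for (slot in seq_len(compounds_per_herb)) {
        reusable <- setdiff(names(pool), in_herb)
        if (length(reusable) > 0L &&
            stats::runif(1) < shared_compound_rate) {
          cid <- sample(reusable, 1L)
        } else {
          cid <- sprintf("CMP%04d", length(pool) + 1L)
          ob <- min(stats::rlnorm(1, ob_meanlog, ob_sdlog), 100)
          dl <- stats::rbeta(1, dl_shape1, dl_shape2)
          ntg <- stats::rpois(1, targets_per_compound) + 1L
          pool[[cid]] <- list(ob = ob, dl = dl,
                              targets = sample(genes,
                                               min(ntg, length(genes))))
        }
        in_herb <- c(in_herb, cid)
        rows[[length(rows) + 1L]] <- data.frame(
          herb_id = h, compound_id = cid, stringsAsFactors = FALSE)
      }
    }
    compounds <- do.call(rbind, rows)
    compounds$compound_name <- paste0("compound_",
                                      sub("CMP", "", compounds$compound_id))
    compounds$ob <- vapply(compounds$compound_id,
                           function(i) pool[[i]]$ob, numeric(1))
    compounds$dl <- vapply(compounds$compound_id,
                           function(i) pool[[i]]$dl, numeric(1))
    targets <- do.call(rbind, lapply(names(pool), function(i)
      data.frame(compound_id = i, gene_symbol = pool[[i]]$targets,
                 stringsAsFactors = FALSE)))
    truth <- compounds[, c("herb_id", "compound_id")]
    truth$kept <- compounds$ob >= 20 & compounds$dl >= 0.18
    rownames(compounds) <- rownames(targets) <- rownames(truth) <- NULL
    list(compounds = compounds, targets = targets, truth = truth)
  })
}

#' Generate disease-gene sources with planted Venn regions
#'
#' Builds the sources from an explicit region plan: by default one region of
#' genes shared by all sources (a fraction `overlap` of the smallest source)
#' plus one private region per source. Arbitrary region plans can be passed
#' directly.
#'
#' @param n_sources number of sources. Default 5.
#' @param per_source_size source sizes, recycled. Default 800.
#' @param overlap fraction of the smallest source shared by all sources.
#' @param source_names defaults to GeneCards, DrugBank, OMIM, PharmGkb, TTD.
#' @param region_counts optional named vector of planted exact-membership
#'   counts; names are `&`-joined source-name combinations. Overrides
#'   `overlap`.
#' @param gene_pool optional symbol pool to draw from (so disease genes can
#'   share a namespace with formula targets); defaults to fresh `UCG*`
#'   symbols.
#' @param seed integer seed (shuffles symbols only).
#' @return list: `sources` (named list of symbol vectors), `table`
#'   (source_name, gene_symbol), `truth` (`union_size`, `region_counts`
#'   over every non-empty source combination).
#' @export
gen_disease_sources <- function(n_sources = 5, per_source_size = 800,
                                overlap = 0.15, source_names = NULL,
                                region_counts = NULL, gene_pool = NULL,
                                seed = 1) {
  if (is.null(source_names)) {
    base_names <- c("GeneCards", "DrugBank", "OMIM", "PharmGkb", "TTD")
    source_names <- if (n_sources <= 5) base_names[seq_len(n_sources)]
    else c(base_names, paste0("Source", seq_len(n_sources - 5)))
  }
  stopifnot(length(source_names) == n_sources)
  sizes <- rep_len(per_source_size, n_sources)
  if (is.null(region_counts)) {
    core <- round(overlap * min(sizes))
    priv <- sizes - core
    if (any(priv < 0) || core < 0)
      stop("infeasible overlap specification")
    region_counts <- stats::setNames(priv, source_names)
    if (core > 0)
      region_counts[paste(source_names, collapse = "&")] <- core
    region_counts <- region_counts[region_counts > 0]
  }
  members <- strsplit(names(region_counts), "&", fixed = TRUE)
  if (!all(unlist(members) %in% source_names))
    stop("region plan names an unknown source")
  total <- sum(region_counts)
  if (!is.null(gene_pool) && length(gene_pool) < total)
    stop("gene_pool smaller than the planted union (", total, " genes)")
  with_seed(substream_seed(seed, "disease_sources"), {
    genes <- if (is.null(gene_pool)) sample(sprintf("UCG%05d", seq_len(total)))
             else sample(gene_pool, total)
    idx <- rep(seq_along(region_counts), region_counts)
    sources <- stats::setNames(
      lapply(source_names, function(s) {
        in_region <- vapply(members, function(m) s %in% m, logical(1))
        genes[idx %in% which(in_region)]
      }), source_names)
    # full planted region vector in collate_disease_genes naming order
    combos <- expand.grid(rep(list(c(FALSE, TRUE)),
                              n_sources))[-1L, , drop = FALSE]
    full <- stats::setNames(integer(nrow(combos)),
                            apply(combos, 1L, function(z)
                              paste(source_names[as.logical(z)],
                                    collapse = "&")))
    full[names(region_counts)] <- as.integer(region_counts)
    tab <- do.call(rbind, lapply(source_names, function(s)
      data.frame(source_name = s, gene_symbol = sources[[s]],
                 stringsAsFactors = FALSE)))
    rownames(tab) <- NULL
    list(sources = sources, table = tab,
         truth = list(union_size = total, region_counts = full))
  })
}

#' Generate a PPI edge list with a planted dense module
#'
#' Erdos-Renyi background on `n` proteins plus a planted module whose pairs
#' are connected with probability `module_density` (1 = clique). Module-edge
#' confidences are drawn above the 0.7 STRING-style cutoff so the module
#' survives confidence filtering; background confidences straddle it.
#'
#' @param n number of proteins. Default 200.
#' @param p_background background edge probability. Default 0.03.
#' @param module_size planted module size. Default 12.
#' @param module_density within-module edge probability. Default 1.
#' @param conf_background,conf_module confidence ranges (uniform).
#' @param nodes optional node names (length `n` is then taken from it);
#'   defaults to `GENE001...`.
#' @param seed integer seed.
#' @return list: `edges` (from, to, confidence), `planted` (module node
#'   names).
#' @export
gen_ppi_with_planted_module <- function(n = 200, p_background = 0.03,
                                        module_size = 12,
                                        module_density = 1.0,
                                        conf_background = c(0.4, 0.95),
                                        conf_module = c(0.75, 0.99),
                                        nodes = NULL, seed = 1) {
  if (!is.null(nodes)) n <- length(nodes)
  stopifnot(module_size <= n, module_size >= 0, n >= 2)
  if (is.null(nodes)) nodes <- sprintf("GENE%03d", seq_len(n))
  with_seed(substream_seed(seed, "ppi_module"), {
    planted <- if (module_size > 0) sort(sample(nodes, module_size))
               else character(0)
    pairs <- utils::combn(n, 2)
    i <- pairs[1, ]; j <- pairs[2, ]
    in_mod <- nodes[i] %in% planted & nodes[j] %in% planted
    keep_bg <- !in_mod & stats::runif(length(i)) < p_background
    keep_mod <- in_mod & stats::runif(length(i)) < module_density
    conf <- numeric(length(i))
    conf[keep_bg] <- stats::runif(sum(keep_bg), conf_background[1],
                                  conf_background[2])
    conf[keep_mod] <- stats::runif(sum(keep_mod), conf_module[1],
                                   conf_module[2])
    keep <- keep_bg | keep_mod
    list(edges = data.frame(from = nodes[i][keep], to = nodes[j][keep],
                            confidence = conf[keep],
                            stringsAsFactors = FALSE),
         planted = planted)
  })
}

taxonomy_pool <- list(
  Firmicutes = c("Lachnospiraceae_NK4A136", "Lactobacillus",
                 "Ruminiclostridium", "Clostridium"),
  Bacteroidetes = c("Muribaculum", "Bacteroides", "Alistipes", "Prevotella"),
  Proteobacteria = c("Escherichia"),
  Actinobacteria = c("Bifidobacterium"),
  Verrucomicrobia = c("Akkermansia"),
  Fusobacteria = c("Fusobacterium"))

#' Generate a Dirichlet-multinomial feature table with planted effects
#'
#' Base proportions are lognormal (uneven, a few dominant taxa); per-sample
#' compositions follow a Dirichlet with total concentration `concentration`
#' (overdispersed counts, as fitted to real 16S data); the second group's
#' concentrations are multiplied by `fold_change` on `n_diff_features`
#' planted features. Library sizes are lognormal. Taxonomy strings are
#' synthesized over 6 phyla / 12 genera.
#'
#' @param n_samples_per_group samples per group. Default 10.
#' @param n_features OTUs. Default 120.
#' @param concentration total Dirichlet concentration. Default 60.
#' @param base_sdlog lognormal sd of base proportions. Default 1.5.
#' @param n_diff_features planted differential features. Default 5.
#' @param fold_change multiplicative concentration shift in group 2.
#' @param lib_meanlog,lib_sdlog lognormal library-size parameters
#'   (default around 20k reads).
#' @param group_names two group labels.
#' @param seed integer seed.
#' @return list: `table` (a [feature_table()]), `diff_features` (planted
#'   feature ids), `group_names`.
#' @export
gen_feature_table <- function(n_samples_per_group = 10, n_features = 120,
                              concentration = 60, base_sdlog = 1.5,
                              n_diff_features = 5, fold_change = 5,
                              lib_meanlog = log(20000), lib_sdlog = 0.2,
                              group_names = c("DSS", "DSS_GCZX"),
                              seed = 1) {
  stopifnot(n_diff_features <= n_features, length(group_names) == 2L,
            n_samples_per_group >= 1, fold_change > 0)
  with_seed(substream_seed(seed, "feature_table"), {
    w <- stats::rlnorm(n_features, 0, base_sdlog)
    alpha_a <- concentration * w / sum(w)
    diff <- if (n_diff_features > 0)
      sort(sample(n_features, n_diff_features)) else integer(0)
    alpha_b <- alpha_a
    alpha_b[diff] <- alpha_b[diff] * fold_change
    n_tot <- 2L * n_samples_per_group
    libs <- round(stats::rlnorm(n_tot, lib_meanlog, lib_sdlog))
    if (any(libs <= 0)) stop("generated library size of 0; increase ",
                             "lib_meanlog or reduce lib_sdlog")
    counts <- matrix(0L, nrow = n_tot, ncol = n_features)
    for (s in seq_len(n_tot)) {
      alpha <- if (s <= n_samples_per_group) alpha_a else alpha_b
      g <- stats::rgamma(n_features, shape = alpha, rate = 1)
      if (sum(g) == 0) g <- rep(1, n_features)
      counts[s, ] <- stats::rmultinom(1, libs[s], g / sum(g))
    }
    feats <- sprintf("OTU%04d", seq_len(n_features))
    colnames(counts) <- feats
    rownames(counts) <- paste0(rep(group_names, each = n_samples_per_group),
                               "_", rep(seq_len(n_samples_per_group), 2))
    phyla <- rep(names(taxonomy_pool),
                 vapply(taxonomy_pool, length, integer(1)))
    genera <- unlist(taxonomy_pool, use.names = FALSE)
    gi <- sample(length(genera), n_features, replace = TRUE)
    lineage <- sprintf("k__Bacteria;p__%s;c__;o__;f__;g__%s",
                       phyla[gi], genera[gi])
    names(lineage) <- feats
    groups <- stats::setNames(rep(group_names, each = n_samples_per_group),
                              rownames(counts))
    list(table = feature_table(counts, taxonomy = lineage, groups = groups),
         diff_features = feats[diff], group_names = group_names)
  })
}

default_dai_profiles <- function() {
  list(
    control = list(stool = c(0.9, 0.1, 0, 0), weight_mean = 0,
                   weight_sd = 0.5, blood = c(0.95, 0.05, 0, 0),
                   histology = c(0.8, 0.2, 0, 0)),
    DSS = list(stool = c(0.05, 0.15, 0.3, 0.5), weight_mean = 12,
               weight_sd = 4, blood = c(0.05, 0.15, 0.3, 0.5),
               histology = c(0.05, 0.2, 0.4, 0.35)),
    DSS_GCZX = list(stool = c(0.3, 0.4, 0.2, 0.1), weight_mean = 6,
                    weight_sd = 3, blood = c(0.3, 0.4, 0.2, 0.1),
                    histology = c(0.3, 0.4, 0.2, 0.1)))
}

#' Generate a DAI cohort with planted severity profiles
#'
#' Samples categorical DAI fields from per-group probability profiles
#' (defaults: a healthy control group, a severe DSS group and an
#' intermediate treated group, 15 mice each, as in the standard DSS-colitis
#' design). Weight loss is `max(0, Normal(mean, sd))`. The planted truth is
#' each group's expected total score, computed exactly from the profile.
#'
#' @param n_per_group mice per group. Default 15.
#' @param profiles named list of group profiles, each with `stool` (4
#'   probabilities), `weight_mean`, `weight_sd`, `blood` (4 probabilities),
#'   `histology` (4 probabilities over subscores 0--3, shared by the four
#'   criteria).
#' @param seed integer seed.
#' @return list: `observations` (mouse_id, group, stool, weight_loss, blood,
#'   four histology subscores), `truth` (group, expected_total).
#' @export
gen_dai_cohort <- function(n_per_group = 15, profiles = NULL, seed = 1) {
  if (is.null(profiles)) profiles <- default_dai_profiles()
  for (g in names(profiles)) {
    p <- profiles[[g]]
    for (f in c("stool", "blood", "histology")) {
      v <- p[[f]]
      if (length(v) != 4L || any(v < 0) || sum(v) <= 0)
        stop("invalid ", f, " profile for group ", g)
      profiles[[g]][[f]] <- v / sum(v)
    }
    if (p$weight_sd < 0) stop("invalid weight_sd for group ", g)
  }
  with_seed(substream_seed(seed, "dai_cohort"), {
    obs <- do.call(rbind, lapply(names(profiles), function(g) {
      p <- profiles[[g]]
      wl <- pmax(0, stats::rnorm(n_per_group, p$weight_mean, p$weight_sd))
      df <- data.frame(
        mouse_id = paste0(g, "_", seq_len(n_per_group)), group = g,
        stool = sample(names(dai_stool_levels), n_per_group, replace = TRUE,
                       prob = p$stool),
        weight_loss = round(wl, 2),
        blood = sample(names(dai_blood_levels), n_per_group, replace = TRUE,
                       prob = p$blood), stringsAsFactors = FALSE)
      for (f in dai_histology_fields)
        df[[f]] <- sample(0:3, n_per_group, replace = TRUE,
                          prob = p$histology)
      df
    }))
    rownames(obs) <- NULL
    truth <- data.frame(
      group = names(profiles),
      expected_total = vapply(profiles, function(p) {
        e_stool <- sum(p$stool * 0:3)
        e_blood <- sum(p$blood * 0:3)
        e_hist <- 4 * sum(p$histology * 0:3)
        # weight bins of max(0, Normal): mass at 0 plus half-open bins
        br <- c(0, 5, 10, 20, Inf)
        pb <- stats::pnorm(br, p$weight_mean, p$weight_sd)
        probs <- c(pb[1], diff(pb))     # P(<=0), (0,5), [5,10), [10,20), >=20
        e_weight <- sum(probs * 0:4)
        e_stool + e_blood + e_hist + e_weight
      }, numeric(1)), stringsAsFactors = FALSE)
    rownames(truth) <- NULL
    list(observations = obs, truth = truth)
  })
}

#' Generate a GMT-style gene-set collection
#'
#' Random term memberships drawn from a gene universe, split across the four
#' ontology categories (BP, CC, MF, pathway).
#'
#' @param universe gene symbols to draw members from.
#' @param n_terms number of terms. Default 40.
#' @param term_size_range inclusive member-count range. Default c(10, 80).
#' @param categories category labels cycled over terms.
#' @param seed integer seed.
#' @return a [gene_set_collection()].
#' @export
gen_gene_sets <- function(universe, n_terms = 40,
                          term_size_range = c(10, 80),
                          categories = c("BP", "CC", "MF", "pathway"),
                          seed = 1) {
  stopifnot(length(universe) >= max(term_size_range), n_terms >= 1)
  with_seed(substream_seed(seed, "gene_sets"), {
    sizes <- sample(term_size_range[1]:term_size_range[2], n_terms,
                    replace = TRUE)
    genes <- lapply(sizes, function(s) sample(universe, s))
    names(genes) <- sprintf("TERM%04d", seq_len(n_terms))
    gene_set_collection(genes,
                        categories = rep_len(categories, n_terms))
  })
}

#' Write a gene-set collection as GMT
#'
#' @param collection a `gene_set_collection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection), function(id) {
    term <- collection[[id]]
    paste(c(id, term$category, term$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
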