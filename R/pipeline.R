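# Pipeline orchestration: a validated config object, a paper-like synthetic
# input preset, and a deterministic end-to-end run writing stage outputs, a
# JSON manifest with input/output checksums, and a human-readable summary.
#
# Two independent branches mirror the study design: network pharmacology
# (ADME filter -> HIT network -> PPI hub extraction -> enrichment) and the
# animal-study statistics (16S feature-table analyses; DAI scoring).

#' Build and validate a pipeline configuration
#'
#' All thresholds default to the study's printed values: OB >= 20%,
#' DL >= 0.18, PPI confidence >= 0.7, three median-filter rounds,
#' 0.005% feature filtration, adjusted p < 0.05.
#'
#' @param compounds,targets,disease_sources,ppi_edges input file paths (any
#'   may be NULL; the corresponding stage is skipped).
#' @param gene_sets,feature_table,group_map,dai_observations further input
#'   file paths, NULL to skip.
#' @param ob_min,dl_min ADME cutoffs.
#' @param conf_min PPI confidence cutoff.
#' @param rounds,min_size,comparator hub-extraction settings.
#' @param alpha significance level (enrichment and LEfSe gate).
#' @param lda_min LEfSe effect-size threshold.
#' @param min_fraction low-abundance filtration fraction.
#' @param top_n composition-profile taxa to keep.
#' @param nmds_k,nmds_starts NMDS settings.
#' @param seed integer seed for the stochastic stages.
#' @param out_dir output directory.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(compounds = NULL, targets = NULL,
                            disease_sources = NULL, ppi_edges = NULL,
                            gene_sets = NULL, feature_table = NULL,
                            group_map = NULL, dai_observations = NULL,
                            ob_min = 20, dl_min = 0.18, conf_min = 0.7,
                            rounds = 3, min_size = 3, comparator = "strict",
                            alpha = 0.05, lda_min = 2.0,
                            min_fraction = 5e-5, top_n = 10, nmds_k = 2,
                            nmds_starts = 20, seed = 1,
                            out_dir = "pipeline_out") {
  cfg <- list(inputs = list(compounds = compounds, targets = targets,
                            disease_sources = disease_sources,
                            ppi_edges = ppi_edges, gene_sets = gene_sets,
                            feature_table = feature_table,
                            group_map = group_map,
                            dai_observations = dai_observations),
              ob_min = ob_min, dl_min = dl_min, conf_min = conf_min,
              rounds = rounds, min_size = min_size, comparator = comparator,
              alpha = alpha, lda_min = lda_min, min_fraction = min_fraction,
              top_n = top_n, nmds_k = nmds_k, nmds_starts = nmds_starts,
              seed = seed, out_dir = out_dir)
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  stopifnot(cfg$ob_min >= 0, cfg$ob_min <= 100, cfg$dl_min >= 0,
            cfg$conf_min >= 0, cfg$conf_min <= 1, cfg$rounds >= 1,
            cfg$min_size >= 1, cfg$alpha > 0, cfg$alpha < 1,
            cfg$lda_min >= 0, cfg$min_fraction >= 0, cfg$min_fraction < 1,
            cfg$top_n >= 1, cfg$nmds_k >= 1, cfg$nmds_starts >= 1)
  stopifnot(cfg$comparator %in% c("strict", "inclusive"))
  invisible(cfg)
}

#' Save / load a pipeline configuration
#'
#' JSON serialization; a loaded config validates and round-trips losslessly.
#'
#' @param cfg a `pipeline_config`.
#' @param path JSON file path.
#' @return `write_pipeline_config`: `path` invisibly;
#'   `read_pipeline_config`: a `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  raw$inputs <- lapply(raw$inputs, function(x)
    if (is.null(x) || length(x) == 0L) NULL else x)
  do.call(pipeline_config, c(raw$inputs, raw[setdiff(names(raw), "inputs")]))
}

#' Write the paper-like synthetic input preset
#'
#' Generates every pipeline input into `dir` with one master seed: a
#' six-herb compound/target table, five disease-gene sources sharing a gene
#' namespace with the formula targets, a PPI edge list over the
#' formula-disease shared genes with a planted dense module, a GMT gene-set
#' collection, a two-group Dirichlet-multinomial 16S table with planted
#' differential taxa, and a three-group DAI cohort of 15 mice. Planted
#' ground truth is written alongside each input.
#'
#' @param dir output directory (created if needed).
#' @param seed master seed.
#' @return a [pipeline_config()] pointing at the generated files (out_dir
#'   set to `file.path(dir, "results")`), invisibly returned with attribute
#'   `truth_files`.
#' @export
simulate_preset <- function(dir, seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)

  hit <- gen_hit_tables(seed = seed)
  write_tsv(hit$compounds, p("compounds.tsv"))
  write_tsv(hit$targets, p("compound_targets.tsv"))
  write_tsv(hit$truth, p("truth_adme.tsv"))

  target_pool <- unique(hit$targets$gene_symbol)
  pool <- c(target_pool, sprintf("UCG%05d", seq_len(4000)))
  dis <- gen_disease_sources(gene_pool = pool, seed = seed)
  write_tsv(dis$table, p("disease_sources.tsv"))
  jsonlite::write_json(as.list(dis$truth$region_counts),
                       p("truth_disease_regions.json"),
                       auto_unbox = TRUE, digits = NA)

  # shared genes drive the PPI input, as in the study workflow
  kept <- filter_adme(hit$compounds)
  kept_targets <- normalize_gene_symbols(
    hit$targets$gene_symbol[hit$targets$compound_id %in% kept$compound_id])
  shared <- intersect_targets(kept_targets,
                              normalize_gene_symbols(unlist(dis$sources)))
  ppi <- gen_ppi_with_planted_module(nodes = shared,
                                     module_size = min(12, length(shared)),
                                     seed = seed)
  write_tsv(stats::setNames(ppi$edges,
                            c("protein1", "protein2", "combined_score")),
            p("ppi_edges.tsv"))
  writeLines(ppi$planted, p("truth_ppi_module.txt"))

  gmt <- gen_gene_sets(universe = pool, seed = seed)
  write_gmt(gmt, p("gene_sets.gmt"))

  ft <- gen_feature_table(seed = seed)
  write_feature_table_tsv(ft$table, p("feature_table.tsv"))
  write_tsv(data.frame(sample = names(ft$table$groups),
                       group = unname(ft$table$groups)), p("group_map.tsv"))
  writeLines(ft$diff_features, p("truth_diff_features.txt"))

  dai <- gen_dai_cohort(seed = seed)
  write_tsv(dai$observations, p("dai_observations.tsv"))
  write_tsv(dai$truth, p("truth_dai_expected.tsv"))

  cfg <- pipeline_config(
    compounds = p("compounds.tsv"), targets = p("compound_targets.tsv"),
    disease_sources = p("disease_sources.tsv"),
    ppi_edges = p("ppi_edges.tsv"), gene_sets = p("gene_sets.gmt"),
    feature_table = p("feature_table.tsv"), group_map = p("group_map.tsv"),
    dai_observations = p("dai_observations.tsv"), seed = seed,
    out_dir = file.path(dir, "results"))
  attr(cfg, "truth_files") <- p(c("truth_adme.tsv",
                                  "truth_disease_regions.json",
                                  "truth_ppi_module.txt",
                                  "truth_diff_features.txt",
                                  "truth_dai_expected.tsv"))
  invisible(cfg)
}

#' Write a feature table as features x samples TSV
#'
#' @param t a `feature_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table_tsv <- function(t, path) {
  stopifnot(inherits(t, "feature_table"))
  df <- data.frame(feature = colnames(t$counts),
                   base::t(t$counts), check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(t$taxonomy)) {
    lineage <- apply(t$taxonomy, 1L, function(r) {
      r[is.na(r)] <- ""
      sprintf("k__%s;p__%s;c__%s;o__%s;f__%s;g__%s", r["kingdom"],
              r["phylum"], r["class"], r["order"], r["family"], r["genus"])
    })
    df$taxonomy <- lineage
  }
  write_tsv(df, path)
}

#' Run the full pipeline
#'
#' Executes the network-pharmacology branch (ADME filter, disease-gene
#' collation, HIT network, PPI hub extraction, enrichment) and the
#' animal-study branch (16S statistics, DAI scoring) on the inputs named in
#' the config, writing all stage outputs plus `manifest.json` (thresholds,
#' seed, input/output checksums) and `summary.txt` under `cfg$out_dir`.
#' Identical config and inputs produce byte-identical outputs. A stage
#' failure writes a `FAILED` marker naming the stage and aborts; earlier
#' stage outputs are preserved.
#'
#' @param cfg a [pipeline_config()].
#' @return list with the per-stage results (invisible); side effect: files
#'   under `cfg$out_dir`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  validate_pipeline_config(cfg)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  o <- function(f) file.path(out, f)
  results <- list()
  stages_run <- character(0)
  summary_lines <- character(0)
  note <- function(...) summary_lines <<- c(summary_lines, sprintf(...))

  run_stage <- function(name, expr) {
    stages_run <<- c(stages_run, name)
    tryCatch(expr, error = function(e) {
      writeLines(sprintf("stage %s failed: %s", name, conditionMessage(e)),
                 o("FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  need <- function(input, stage) {
    path <- cfg$inputs[[input]]
    if (is.null(path)) return(NULL)
    if (!file.exists(path)) {
      writeLines(sprintf("stage %s failed: missing input '%s' (%s)",
                         stage, input, path), o("FAILED"))
      stop("pipeline stage '", stage, "': missing input '", input, "' (",
           path, ")", call. = FALSE)
    }
    path
  }
  if (file.exists(o("FAILED"))) unlink(o("FAILED"))

  # ---- network pharmacology branch --------------------------------------
  shared <- NULL
  if (!is.null(cfg$inputs$compounds)) {
    results$hit <- run_stage("hit_assembly", {
      comp <- read_compound_table(need("compounds", "hit_assembly"))
      tgt <- read_target_table(need("targets", "hit_assembly"))
      kept <- filter_adme(comp, cfg$ob_min, cfg$dl_min)
      write_tsv(kept, o("adme_kept_compounds.tsv"))
      note("ADME filter: %d / %d herb-compound records kept", nrow(kept),
           nrow(comp))
      pooled <- normalize_gene_symbols(
        tgt$gene_symbol[tgt$compound_id %in% kept$compound_id])
      keep_set <- pooled
      venn <- NULL
      if (!is.null(cfg$inputs$disease_sources)) {
        src <- read_disease_sources(need("disease_sources", "hit_assembly"))
        venn <- collate_disease_genes(src)
        keep_set <- intersect_targets(pooled, venn$union)
        note("Disease genes: %d pooled from %d sources; %d shared with the formula",
             length(venn$union), length(src), length(keep_set))
      }
      net <- build_hit_network(kept, tgt, keep_set)
      write_tsv(net$nodes, o("hit_nodes.tsv"))
      write_tsv(net$edges, o("hit_edges.tsv"))
      share <- herb_target_share(net)
      jsonlite::write_json(
        list(per_herb = share$per_herb, n_union = share$n_union,
             venn_regions = if (is.null(venn)) NULL else
               as.list(venn$region_counts)),
        o("hit_summary.json"), auto_unbox = TRUE, digits = NA)
      list(kept = kept, network = net, share = share, venn = venn,
           shared_genes = keep_set)
    })
    shared <- results$hit$shared_genes
  }

  if (!is.null(cfg$inputs$ppi_edges)) {
    results$ppi <- run_stage("ppi_hub", {
      edges <- read_ppi_edges(need("ppi_edges", "ppi_hub"))
      if (!is.null(shared))
        edges <- edges[edges$from %in% shared & edges$to %in% shared, ,
                       drop = FALSE]
      g <- build_ppi_graph(edges, cfg$conf_min)
      ext <- extract_hub_subnetwork(g, rounds = cfg$rounds,
                                    min_size = cfg$min_size,
                                    comparator = cfg$comparator)
      write_tsv(compute_centralities(g), o("ppi_centralities.tsv"))
      sub_edges <- igraph::as_data_frame(ext$subnetwork, what = "edges")
      write_tsv(sub_edges, o("hub_subnetwork_edges.tsv"))
      writeLines(sort(igraph::V(ext$subnetwork)$name), o("hub_genes.txt"))
      jsonlite::write_json(
        list(stop_reason = ext$trace$stop_reason,
             rounds = lapply(ext$trace$iterations, function(it)
               list(round = it$round, n_input = length(it$input_nodes),
                    medians = as.list(it$medians),
                    n_survivors = length(it$survivors)))),
        o("hub_trace.json"), auto_unbox = TRUE, digits = NA)
      note("PPI: %d nodes / %d edges at confidence >= %g; hub subnetwork %d genes (%s)",
           igraph::vcount(g), igraph::ecount(g), cfg$conf_min,
           igraph::vcount(ext$subnetwork), ext$trace$stop_reason)
      list(graph = g, extraction = ext)
    })
  }

  if (!is.null(cfg$inputs$gene_sets) && !is.null(shared)) {
    results$enrichment <- run_stage("enrichment", {
      coll <- read_gmt(need("gene_sets", "enrichment"))
      enr <- suppressWarnings(
        enrich_gene_set(shared, coll, alpha = cfg$alpha))
      write_tsv(enr, o("enrichment.tsv"))
      note("Enrichment: %d terms hit, %d significant at adjusted p < %g",
           nrow(enr), sum(enr$significant), cfg$alpha)
      enr
    })
  }

  # ---- microbiome / DAI branch ------------------------------------------
  if (!is.null(cfg$inputs$feature_table)) {
    results$microbiome <- run_stage("microbiome_stats", {
      ft <- read_feature_table(need("feature_table", "microbiome_stats"),
                               need("group_map", "microbiome_stats"))
      if (is.null(ft$groups))
        stop("microbiome_stats requires a group map")
      filt <- filter_low_abundance(ft, cfg$min_fraction)
      note("Feature table: %d / %d features pass the %.4g%% filtration",
           ncol(filt$counts), ncol(ft$counts), cfg$min_fraction * 100)
      for (rk in c("phylum", "genus")) {
        prof <- composition_profile(filt, rk, cfg$top_n)
        write_tsv(data.frame(taxon = rownames(prof), prof,
                             check.names = FALSE), o(paste0(
                               "composition_", rk, ".tsv")))
      }
      adiv <- base::t(apply(filt$counts, 1L, alpha_diversity))
      write_tsv(data.frame(sample = rownames(adiv), adiv,
                           check.names = FALSE), o("alpha_diversity.tsv"))
      d <- jaccard_distance_matrix(filt)
      dm <- as.matrix(d)
      write_tsv(data.frame(sample = rownames(dm), dm, check.names = FALSE),
                o("jaccard_distance.tsv"))
      pc <- pcoa(d)
      write_tsv(data.frame(sample = rownames(pc$coordinates),
                           pc$coordinates[, seq_len(min(2,
                             ncol(pc$coordinates))), drop = FALSE],
                           check.names = FALSE), o("pcoa_coordinates.tsv"))
      nm <- nmds(d, k = cfg$nmds_k, n_starts = cfg$nmds_starts,
                 seed = substream_seed(cfg$seed, "nmds"))
      write_tsv(data.frame(sample = rownames(nm$points), nm$points,
                           stress = nm$stress, check.names = FALSE),
                o("nmds_points.tsv"))
      note("Ordination: NMDS stress %.4f (%s)", nm$stress,
           if (nm$valid) "valid, < 0.2" else ">= 0.2")
      up <- upgma(d)
      writeLines(up$newick, o("upgma.nwk"))
      lf <- lefse(filt, alpha = cfg$alpha, lda_min = cfg$lda_min,
                  seed = substream_seed(cfg$seed, "lefse"))
      write_tsv(lf, o("lefse.tsv"))
      note("LEfSe: %d biomarker feature(s) at KW p < %g and effect >= %g",
           sum(lf$significant), cfg$alpha, cfg$lda_min)
      list(filtered = filt, alpha = adiv, dist = d, pcoa = pc, nmds = nm,
           upgma = up, lefse = lf)
    })
  }

  if (!is.null(cfg$inputs$dai_observations)) {
    results$dai <- run_stage("dai_score", {
      obs <- utils::read.delim(need("dai_observations", "dai_score"),
                               sep = "\t", stringsAsFactors = FALSE)
      sc <- score_components(obs)
      write_tsv(sc, o("dai_scores.tsv"))
      summ <- cohort_summary(sc)
      write_tsv(summ, o("dai_summary.tsv"))
      note("DAI: group means %s",
           paste(sprintf("%s=%.2f", summ$group, summ$total_mean),
                 collapse = ", "))
      list(scores = sc, summary = summ)
    })
  }

  # ---- manifest + summary -----------------------------------------------
  inputs <- Filter(Negate(is.null), cfg$inputs)
  in_md5 <- vapply(inputs, function(pp) unname(tools::md5sum(pp)),
                   character(1))
  out_files <- setdiff(list.files(out), c("manifest.json", "summary.txt"))
  out_md5 <- vapply(file.path(out, out_files),
                    function(pp) unname(tools::md5sum(pp)), character(1))
  names(out_md5) <- out_files
  manifest <- list(package = "netpharmbiome",
                   version = as.character(utils::packageVersion(
                     "netpharmbiome")),
                   seed = cfg$seed,
                   thresholds = cfg[c("ob_min", "dl_min", "conf_min",
                                      "rounds", "min_size", "comparator",
                                      "alpha", "lda_min", "min_fraction",
                                      "top_n")],
                   stages = stages_run,
                   input_md5 = as.list(in_md5),
                   output_md5 = as.list(out_md5))
  jsonlite::write_json(manifest, o("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(summary_lines, o("summary.txt"))
  invisible(results)
}
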