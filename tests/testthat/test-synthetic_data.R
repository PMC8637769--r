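# Synthetic-data generators: determinism, planted ground truth, edge cases.

test_that("generators are pure functions of their config", {
  expect_identical(gen_hit_tables(seed = 7), gen_hit_tables(seed = 7))
  expect_identical(gen_disease_sources(seed = 3), gen_disease_sources(seed = 3))
  expect_identical(gen_ppi_with_planted_module(seed = 5),
                   gen_ppi_with_planted_module(seed = 5))
  expect_identical(gen_feature_table(seed = 2), gen_feature_table(seed = 2))
  expect_identical(gen_dai_cohort(seed = 4), gen_dai_cohort(seed = 4))
  # different master seeds give different data
  expect_false(identical(gen_feature_table(seed = 1),
                         gen_feature_table(seed = 2)))
})

test_that("ADME ground-truth labels match the filter exactly", {
  ht <- gen_hit_tables(seed = 7)
  kept <- filter_adme(ht$compounds)
  key <- function(df) paste(df$herb_id, df$compound_id)
  expect_setequal(key(kept), key(ht$truth[ht$truth$kept, ]))
  # degenerate OB mass below the cutoff keeps nothing
  low <- gen_hit_tables(ob_meanlog = log(2), ob_sdlog = 0.1, seed = 1)
  expect_equal(nrow(filter_adme(low$compounds)), 0L)
})

test_that("disease-source collation reproduces the planted Venn regions", {
  ds <- gen_disease_sources(seed = 3)
  out <- collate_disease_genes(ds$sources)
  expect_equal(length(out$union), ds$truth$union_size)
  expect_equal(out$region_counts[names(ds$truth$region_counts)],
               ds$truth$region_counts)
  # overlap 0 -> disjoint sources
  dj <- gen_disease_sources(per_source_size = 50, overlap = 0, seed = 2)
  expect_equal(length(collate_disease_genes(dj$sources)$union), 250L)
  # full overlap -> union equals one source
  fo <- gen_disease_sources(per_source_size = 50, overlap = 1, seed = 2)
  expect_equal(length(collate_disease_genes(fo$sources)$union), 50L)
  expect_error(gen_disease_sources(per_source_size = 10, overlap = 2),
               "infeasible")
})

test_that("planted PPI module edge cases behave as configured", {
  pure <- gen_ppi_with_planted_module(n = 30, p_background = 0,
                                      module_size = 6, seed = 1)
  g <- build_ppi_graph(pure$edges)
  expect_setequal(igraph::V(g)$name, pure$planted)   # graph = module only
  expect_equal(igraph::ecount(g), choose(6, 2))
  nomod <- gen_ppi_with_planted_module(n = 30, module_size = 0, seed = 1)
  expect_length(nomod$planted, 0)
  # module confidences survive the 0.7 cutoff by construction
  mod <- gen_ppi_with_planted_module(n = 50, module_size = 8, seed = 2)
  gg <- build_ppi_graph(mod$edges)
  sub <- igraph::induced_subgraph(gg, mod$planted)
  expect_equal(igraph::ecount(sub), choose(8, 2))
})

test_that("feature tables carry taxonomy, groups and planted features", {
  ft <- gen_feature_table(seed = 2)
  expect_s3_class(ft$table, "feature_table")
  expect_equal(dim(ft$table$counts), c(20, 120))
  expect_length(ft$diff_features, 5)
  expect_true(all(ft$diff_features %in% colnames(ft$table$counts)))
  expect_equal(unname(table(ft$table$groups)), c(10L, 10L),
               ignore_attr = TRUE)
  expect_false(any(is.na(ft$table$taxonomy$phylum)))
  expect_error(gen_feature_table(lib_meanlog = log(0.4), lib_sdlog = 0.01,
                                 seed = 1), "library size")
  # fold_change = 1 plants no signal: KW hit rate stays near alpha
  null_ft <- gen_feature_table(n_features = 300, n_diff_features = 0,
                               fold_change = 1, seed = 8)
  lf <- lefse(null_ft$table, seed = 1)
  expect_lt(mean(lf$kw_p < 0.05), 0.12)
})

test_that("DAI cohorts honour their severity profiles", {
  prof <- default_profiles <- list(
    zero = list(stool = c(1, 0, 0, 0), weight_mean = 0, weight_sd = 0,
                blood = c(1, 0, 0, 0), histology = c(1, 0, 0, 0)))
  coh0 <- gen_dai_cohort(n_per_group = 5, profiles = prof, seed = 1)
  expect_true(all(score_components(coh0$observations)$total == 0))
  expect_equal(coh0$truth$expected_total, 0)
  coh <- gen_dai_cohort(seed = 5)
  expect_equal(nrow(coh$observations), 45L)  # 15 mice x 3 groups
  sc <- score_components(coh$observations)
  ms <- tapply(sc$total, coh$observations$group, mean)
  expect_gt(ms[["DSS"]], ms[["control"]])
})
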