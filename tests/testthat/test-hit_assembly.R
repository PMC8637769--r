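# Herb-compound ADME filtering, disease-gene collation, and HIT network
# construction.

recs <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  if (is.null(df$compound_name)) df$compound_name <- df$compound_id
  df
}

test_that("ADME filter keeps boundary records, preserves order, is idempotent", {
  r <- recs(herb_id = "Mf", compound_id = c("C1", "C2", "C3", "C4"),
            ob = c(20.0, 19.9, 80, 35), dl = c(0.18, 0.90, 0.17, 0.5))
  kept <- filter_adme(r)
  expect_equal(kept$compound_id, c("C1", "C4"))   # boundary inclusive
  expect_equal(filter_adme(kept), kept)           # idempotent
  expect_true(all(kept$compound_id %in% r$compound_id))
  expect_equal(nrow(filter_adme(r[0, ])), 0L)
  bad <- recs(herb_id = "Zr", compound_id = "X", ob = -1, dl = 0.5)
  expect_error(filter_adme(bad), "Zr/X")
})

test_that("gene symbol normalization collapses case and whitespace", {
  expect_setequal(normalize_gene_symbols(c("Tnf", "TNF", " il6 ")),
                  c("TNF", "IL6"))
  expect_equal(normalize_gene_symbols(character(0)), character(0))
  expect_equal(normalize_gene_symbols("PTGS2"), "PTGS2")
  expect_equal(normalize_gene_symbols(c("", "  ", NA, "a")), "A")
})

test_that("disease-gene collation computes exact Venn regions", {
  out <- collate_disease_genes(list(A = c("g1", "g2"), B = c("g2", "g3")))
  expect_setequal(out$union, c("G1", "G2", "G3"))
  expect_equal(unname(out$region_counts[c("A", "B", "A&B")]), c(1L, 1L, 1L))
  expect_equal(sum(out$region_counts), length(out$union))

  single <- collate_disease_genes(list(S = "g1"))
  expect_equal(single$union, "G1")
  expect_equal(sum(single$region_counts), 1L)

  expect_error(collate_disease_genes(list(A = "g1", A = "g2")), "duplicate")
})

test_that("region counts sum to the union size on random sources", {
  set.seed(41)
  for (rep in 1:10) {
    srcs <- lapply(1:5, function(i)
      sample(sprintf("g%02d", 1:60), 50, replace = FALSE))
    names(srcs) <- LETTERS[1:5]
    out <- collate_disease_genes(srcs)
    # brute-force membership tabulation
    uni <- unique(toupper(unlist(srcs)))
    expect_equal(sum(out$region_counts), length(uni))
    # spot-check one region against direct membership counting
    pat <- vapply(uni, function(g)
      paste(names(srcs)[vapply(srcs, function(s) g %in% toupper(s),
                               logical(1))], collapse = "&"), character(1))
    tab <- table(pat)
    for (nm in names(tab))
      expect_equal(unname(out$region_counts[nm]), unname(as.integer(tab[nm])))
  }
})

test_that("target intersection is exact set intersection", {
  expect_setequal(intersect_targets(c("a", "b", "c"), c("b", "c", "d")),
                  c("b", "c"))
  expect_length(intersect_targets(c("a"), c("b")), 0)
  x <- c("p", "q")
  expect_setequal(intersect_targets(x, x), x)
})

test_that("HIT network is tripartite with closed pruning", {
  r <- recs(herb_id = c("H1", "H1", "H2"),
            compound_id = c("C1", "C2", "C1"),
            ob = 50, dl = 0.5)
  tg <- data.frame(compound_id = c("C1", "C1", "C2"),
                   gene_symbol = c("T1", "T2", "T3"),
                   stringsAsFactors = FALSE)
  net <- build_hit_network(r, tg, keep_targets = c("T1"))
  # C2 loses its only target -> dropped; C1 kept with one target
  expect_setequal(net$nodes$id[net$nodes$type == "compound"], "C1")
  expect_setequal(net$nodes$id[net$nodes$type == "target"], "T1")
  # C1 shared by two herbs -> two herb parents
  hc <- net$edges[net$edges$type == "herb-compound", ]
  expect_setequal(hc$from, c("H1", "H2"))
  # no within-layer or herb-target edges
  types <- net$nodes$type[match(net$edges$from, net$nodes$id)]
  totypes <- net$nodes$type[match(net$edges$to, net$nodes$id)]
  expect_true(all(paste(types, totypes) %in%
                    c("herb compound", "compound target")))
  # single herb+compound with 2 kept targets -> 3 edges pattern
  net2 <- build_hit_network(recs(herb_id = "H", compound_id = "C",
                                 ob = 50, dl = 0.5),
                            data.frame(compound_id = "C",
                                       gene_symbol = c("T1", "T2")),
                            keep_targets = c("T1", "T2"))
  expect_equal(nrow(net2$edges), 3L)
  expect_warning(build_hit_network(r, tg, keep_targets = "ZZZ"), "empty")
})

test_that("per-herb target shares match set arithmetic", {
  r <- recs(herb_id = c("H1", "H2"), compound_id = c("C1", "C2"),
            ob = 50, dl = 0.5)
  tg <- data.frame(compound_id = c("C1", "C1", "C2", "C2"),
                   gene_symbol = c("a", "b", "b", "c"),
                   stringsAsFactors = FALSE)
  net <- build_hit_network(r, tg)
  sh <- herb_target_share(net, subsets = list(c("H1", "H2"), "H1"))
  expect_equal(sh$n_union, 3L)
  ph <- sh$per_herb
  expect_equal(ph$fraction[ph$herb_id == "H1"], 2 / 3)
  expect_equal(ph$fraction[ph$herb_id == "H2"], 2 / 3)
  expect_equal(sh$combined$fraction[1], 1.0)  # all herbs cover the union
  expect_equal(sh$combined$fraction[2], 2 / 3)
})
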