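# PPI graph construction and six-centrality hub extraction.

test_that("PPI graph filtering: threshold, self-loops, duplicates, isolates", {
  e <- data.frame(from = c("a", "b", "a", "a", "x"),
                  to = c("b", "c", "a", "b", "y"),
                  confidence = c(0.9, 0.6, 0.95, 0.75, 0.7))
  g <- build_ppi_graph(e)
  expect_setequal(igraph::V(g)$name, c("a", "b", "x", "y"))  # c dropped
  expect_equal(igraph::ecount(g), 2L)
  ab <- igraph::E(g)[igraph::V(g)["a"] %--% igraph::V(g)["b"]]
  expect_equal(ab$confidence, 0.9)  # duplicate kept at max confidence
  # boundary 0.7 retained
  expect_true("x" %in% igraph::V(g)$name)
  expect_error(build_ppi_graph(data.frame(from = "a", to = "b",
                                          confidence = 1.2)), "\\[0, 1\\]")
})

test_that("centralities match hand-enumerated values on K3, star, K4+pendant", {
  t3 <- make_graph_named(rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  tab <- compute_centralities(t3)
  for (j in c("dc", "bc", "cc", "ec", "lac", "nc"))
    expect_equal(tab[[j]], rep(c(dc = 2, bc = 0, cc = 1, ec = 1, lac = 1,
                                 nc = 2)[[j]], 3), tolerance = 1e-7)

  st <- make_graph_named(rbind(c("c", "a"), c("c", "b"), c("c", "d")))
  tab <- compute_centralities(st)
  ctr <- tab[tab$node == "c", ]
  expect_equal(unlist(ctr[c("dc", "bc", "cc", "lac", "nc")]),
               c(dc = 3, bc = 3, cc = 1, lac = 0, nc = 0))
  expect_equal(tab$cc[tab$node == "a"], 0.6)

  k4p <- make_graph_named(rbind(c("1", "2"), c("1", "3"), c("1", "4"),
                                c("2", "3"), c("2", "4"), c("3", "4"),
                                c("1", "p")))
  tab <- compute_centralities(k4p)
  n1 <- tab[tab$node == "1", ]
  expect_equal(unlist(n1[c("dc", "bc", "cc", "lac", "nc")]),
               c(dc = 4, bc = 3, cc = 1, lac = 1.5, nc = 3))
  n2 <- tab[tab$node == "2", ]
  expect_equal(unlist(n2[c("dc", "bc", "cc", "lac", "nc")]),
               c(dc = 3, bc = 0, cc = 0.8, lac = 2, nc = 3))
  expect_error(compute_centralities(igraph::make_empty_graph(0)), "empty")
})

test_that("centralities are invariant under node relabeling", {
  set.seed(7)
  A <- random_connected_adjacency(15, 0.15)
  g <- igraph_from_adjacency(A)
  perm <- sample(15)
  Ap <- A[perm, perm]
  gp <- igraph_from_adjacency(Ap)
  t1 <- compute_centralities(g)
  t2 <- compute_centralities(gp)
  t2 <- t2[match(t1$node, t2$node), ]
  for (j in c("dc", "bc", "cc", "lac", "nc"))
    expect_equal(t2[[j]], t1[[j]], tolerance = 1e-9)
  expect_equal(t2$ec, t1$ec, tolerance = 1e-6)
})

test_that("median filtering: P5 empties, symmetric graphs split by comparator", {
  p5 <- make_graph_named(rbind(c("a", "b"), c("b", "c"), c("c", "d"),
                               c("d", "e")))
  st <- median_filter_step(p5)
  expect_length(st$survivors, 0)
  expect_equal(unname(st$medians["dc"]), 2)

  c6 <- igraph::make_ring(6)
  igraph::V(c6)$name <- letters[1:6]
  expect_length(median_filter_step(c6, "strict")$survivors, 0)
  expect_length(median_filter_step(c6, "inclusive")$survivors, 6)
})

test_that("hub extraction: early stops, trace consistency, monotone shrink", {
  k3 <- make_graph_named(rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  ex <- extract_hub_subnetwork(k3)
  expect_equal(ex$trace$stop_reason, "empty-result")
  expect_setequal(igraph::V(ex$subnetwork)$name, c("a", "b", "c"))

  ppi <- gen_ppi_with_planted_module(seed = 3)
  g <- build_ppi_graph(ppi$edges)
  ex <- extract_hub_subnetwork(g)
  prev <- igraph::V(g)$name
  for (it in ex$trace$iterations) {
    expect_true(all(it$input_nodes %in% prev))       # monotone shrink
    expect_true(all(it$survivors %in% it$input_nodes))
    # trace medians are the medians of the recomputed table
    sub <- igraph::induced_subgraph(g, it$input_nodes)
    tab <- compute_centralities(sub)
    med <- vapply(c("dc", "bc", "cc", "ec", "lac", "nc"),
                  function(j) stats::median(tab[[j]]), numeric(1))
    expect_equal(it$medians, med, tolerance = 1e-9)
    prev <- it$input_nodes
  }
  # rounds = 1 equals a single median step (same survivor set)
  one <- extract_hub_subnetwork(g, rounds = 1)
  st <- median_filter_step(g)
  surv_graph <- igraph::induced_subgraph(g, st$survivors)
  surv_graph <- igraph::delete_vertices(
    surv_graph, igraph::V(surv_graph)[igraph::degree(surv_graph) == 0])
  expect_setequal(igraph::V(one$subnetwork)$name,
                  igraph::V(surv_graph)$name)
})

test_that("one median round on a planted clique keeps >= 10 of 12 members", {
  ppi <- gen_ppi_with_planted_module(n = 200, p_background = 0.03,
                                     module_size = 12,
                                     conf_background = c(0.7, 1),
                                     conf_module = c(0.7, 1), seed = 1)
  g <- build_ppi_graph(ppi$edges)
  st <- median_filter_step(g)
  expect_gte(length(intersect(st$survivors, ppi$planted)), 10)
})

test_that("STRING dialect edge lists auto-scale 0-1000 scores", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein1\tprotein2\tcombined_score",
               "TP53\tMDM2\t950", "TP53\tEP300\t400"), f)
  e <- read_ppi_edges(f)
  expect_equal(e$confidence, c(0.95, 0.4))
  g <- build_ppi_graph(e)
  expect_equal(igraph::ecount(g), 1L)
})
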