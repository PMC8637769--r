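# Feature-table filtration, composition profiles, alpha diversity and
# rarefaction.

toy_table <- function(counts, groups = NULL, tax = NULL) {
  feature_table(counts, taxonomy = tax, groups = groups)
}

test_that("low-abundance filtration is boundary inclusive on the grand total", {
  # grand total 1e6: a 49-read feature is removed, a 50-read feature kept
  m <- matrix(c(999901, 49, 50), nrow = 1,
              dimnames = list("S1", c("big", "f49", "f50")))
  ft <- filter_low_abundance(toy_table(m))
  expect_setequal(colnames(ft$counts), c("big", "f50"))
  # min_fraction = 0 is the identity
  ft0 <- filter_low_abundance(toy_table(m), min_fraction = 0)
  expect_equal(ncol(ft0$counts), 3L)
  # everything below threshold -> empty table with warning
  m2 <- matrix(c(1, 1), 1, dimnames = list("S1", c("a", "b")))
  expect_warning(out <- filter_low_abundance(toy_table(m2),
                                             min_fraction = 0.9), "below")
  expect_equal(ncol(out$counts), 0L)
})

test_that("composition profiles keep top taxa, pool Others, and sum to 1", {
  set.seed(2)
  n_feat <- 24
  m <- matrix(rpois(3 * n_feat, 40) + 1, nrow = 3,
              dimnames = list(paste0("S", 1:3), paste0("F", 1:n_feat)))
  tax <- sprintf("k__Bacteria;p__P%d;c__;o__;f__;g__G%d",
                 rep(1:4, each = 6), 1:12)
  names(tax) <- colnames(m)
  t <- toy_table(m, tax = tax)
  prof <- composition_profile(t, "genus", top_n = 10)
  expect_equal(nrow(prof), 11L)                  # 12 genera -> 10 + Others
  expect_true("Others" %in% rownames(prof))
  expect_equal(unname(colSums(prof)), rep(1, 3), tolerance = 1e-12)
  # <= top_n taxa: no Others row
  prof_p <- composition_profile(t, "phylum", top_n = 10)
  expect_false("Others" %in% rownames(prof_p))
  expect_equal(nrow(prof_p), 4L)
  # single taxon -> all mass on it
  t1 <- toy_table(m[, 1, drop = FALSE],
                  tax = tax[1])
  prof1 <- composition_profile(t1, "genus")
  expect_equal(unname(prof1[1, ]), rep(1, 3))
  expect_error(composition_profile(toy_table(m), "genus"), "taxonomy")
})

test_that("alpha diversity matches the closed-form worked examples", {
  a <- alpha_diversity(c(5, 3, 1, 1, 1, 2, 2), chao1_form = "classic")
  expect_equal(unname(a["chao1"]), 9.25, tolerance = 1e-9)  # 7 + 9/4
  expect_equal(unname(a["coverage"]), 1 - 3 / 15, tolerance = 1e-12)

  u <- alpha_diversity(rep(10, 4))
  expect_equal(unname(u["shannon"]), log(4), tolerance = 1e-9)
  expect_equal(unname(u["simpson"]), 0.75, tolerance = 1e-12)

  w <- alpha_diversity(c(1, 1, 2, 12))
  expect_equal(unname(w["ace"]), 7, tolerance = 1e-9)

  nosing <- alpha_diversity(c(3, 4, 5), chao1_form = "classic")
  expect_equal(unname(nosing["coverage"]), 1.0)
  expect_equal(unname(nosing["chao1"]), 3)       # classic reduces to S

  expect_error(alpha_diversity(c(0, 0)), "no reads")
})

test_that("alpha diversity invariants and vegan cross-checks hold", {
  skip_if_not_installed("vegan")
  set.seed(31)
  for (i in 1:10) {
    x <- rpois(30, 3)
    if (sum(x) == 0) x[1] <- 1
    a <- alpha_diversity(x)
    S <- sum(x > 0)
    expect_gte(a[["chao1"]], S)
    expect_true(a[["simpson"]] >= 0 && a[["simpson"]] < 1)
    expect_true(a[["coverage"]] >= 0 && a[["coverage"]] <= 1)
    expect_equal(a[["shannon"]], vegan::diversity(x, "shannon"),
                 tolerance = 1e-9)
    expect_equal(a[["simpson"]], vegan::diversity(x, "simpson"),
                 tolerance = 1e-9)
    est <- vegan::estimateR(x)
    expect_equal(a[["chao1"]], unname(est["S.chao1"]), tolerance = 1e-6)
  }
  # shannon maximal at uniform composition
  expect_gt(alpha_diversity(rep(5, 10))[["shannon"]],
            alpha_diversity(c(41, rep(1, 9)))[["shannon"]])
})

test_that("rarefaction is exact, monotone, and agrees with vegan", {
  rc <- rarefaction_curve(c(2, 2), 2)
  expect_equal(rc$richness, 5 / 3, tolerance = 1e-9)
  x <- c(10, 5, 3, 1, 1)
  expect_equal(rarefaction_curve(x, 1)$richness, 1, tolerance = 1e-12)
  expect_equal(rarefaction_curve(x, sum(x))$richness, 5, tolerance = 1e-12)
  curve <- rarefaction_curve(x, 1:20)
  expect_true(all(diff(curve$richness) >= -1e-12))
  expect_error(rarefaction_curve(x, 21), "exceeds")
  skip_if_not_installed("vegan")
  expect_equal(curve$richness[10], as.numeric(vegan::rarefy(x, 10)),
               tolerance = 1e-9)
})
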