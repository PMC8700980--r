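test_that("pearson matches hand computation and its invariances", {
  expect_equal(pearson(1:4, c(2, 1, 4, 3)), 0.6)
  expect_equal(pearson(1:5, 2 * (1:5) + 1), 1)
  expect_equal(pearson(1:5, -(1:5)), -1)
  expect_true(is.na(pearson(c(1, 1, 1), c(1, 2, 3))))
  expect_error(pearson(1:2, 1:2), "n >= 3")
  set.seed(61)
  for (i in 1:25) {
    x <- rnorm(8); y <- rnorm(8)
    expect_equal(pearson(x, y), pearson(y, x))
    expect_equal(pearson(3 * x + 2, y), pearson(x, y), tolerance = 1e-12)
    expect_equal(pearson(-x, y), -pearson(x, y), tolerance = 1e-12)
    expect_lte(abs(pearson(x, y)), 1 + 1e-12)
  }
})

test_that("correlation annotation handles tiny groups and missing genes", {
  net <- data.frame(regulator = c("a", "a", "L"), target = c("b", "zz", "c"),
                    edge_type = c("tf_gene", "tf_gene", "lncrna_gene"),
                    evidence = c("reference_network", "reference_network",
                                 "enhancer_overlap"))
  expr <- matrix(rnorm(20), 4, 5,
                 dimnames = list(c("a", "b", "L", "c"), paste0("s", 1:5)))
  expr["b", ] <- expr["a", ] * 2          # perfectly coupled
  sheet <- data.frame(sample_id = paste0("s", 1:5),
                      cell_type = c(rep("NPC", 3), rep("iPSC", 2)),
                      condition = "normal")
  act <- annotate_correlations(net, expr, sheet, cutoff = 0.75)
  npc <- act[act$cell_type == "NPC", ]
  expect_equal(npc$r[npc$target == "b"], 1)
  expect_true(npc$active[npc$target == "b"])
  expect_true(is.na(npc$r[npc$target == "zz"]))   # gene absent
  expect_false(npc$active[npc$target == "zz"])
  expect_true(npc$active[npc$edge_type == "lncrna_gene"])  # exempt
  ipsc <- act[act$cell_type == "iPSC", ]           # n = 2 group
  expect_true(all(is.na(ipsc$r)))
  expect_false(any(ipsc$active[ipsc$edge_type != "lncrna_gene"]))
  # permuting samples within the group leaves r unchanged
  perm <- c(3, 1, 2, 5, 4)
  act2 <- annotate_correlations(net, expr[, perm], sheet[perm, ],
                                cutoff = 0.75)
  expect_equal(act$r, act2$r[match(paste(act$regulator, act$target,
                                         act$cell_type),
                                   paste(act2$regulator, act2$target,
                                         act2$cell_type))])
})

test_that("broken edges are active in normal samples only", {
  study <- default_study()
  lc <- normalize_cpm_log(filter_unexpressed(study$counts))
  act <- annotate_correlations(
    study$truth$broken_edges[, c("regulator", "target", "edge_type")] |>
      transform(evidence = "reference_network"),
    lc, study$sheet, cutoff = 0.75)
  npc <- act[act$cell_type == "NPC", ]
  expect_true(all(npc$active[npc$condition == "normal"]))
  expect_false(any(npc$active[npc$condition == "ASD"]))
})

test_that("condition-unique targets equal the brute-force set difference", {
  mk <- function(targets, active) {
    data.frame(regulator = "T", target = targets, edge_type = "tf_gene",
               cell_type = "NPC", condition = "x", r = 0.9, active = active)
  }
  a <- mk(c("g1", "g2", "g3", "g4"), c(TRUE, TRUE, FALSE, TRUE))
  b <- mk(c("g1", "g2", "g3", "g4"), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(condition_unique_targets(a, b), c("g2", "g4"))
  expect_equal(condition_unique_targets(a, a), character(0))
  set.seed(62)
  for (i in 1:20) {
    ta <- sample(sprintf("g%d", 1:10), 8, TRUE)
    tb <- sample(sprintf("g%d", 1:10), 8, TRUE)
    aa <- mk(ta, runif(8) < 0.6)
    bb <- mk(tb, runif(8) < 0.6)
    want <- sort(setdiff(unique(ta[aa$active]), unique(tb[bb$active])))
    expect_equal(condition_unique_targets(aa, bb), want)
  }
})

test_that("raising the cutoff never adds active edges", {
  study <- default_study()
  lc <- normalize_cpm_log(filter_unexpressed(study$counts))
  net <- study$truth$edges[, c("regulator", "target", "edge_type")]
  net$evidence <- "reference_network"
  sheet <- study$sheet[study$sheet$cell_type == "NPC", ]
  lo <- annotate_correlations(net, lc, sheet, cutoff = 0.6)
  hi <- annotate_correlations(net, lc, sheet, cutoff = 0.9)
  expect_true(all(!hi$active | lo$active))
})
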