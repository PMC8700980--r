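test_that("annotation places every promoter in bounds without overlaps", {
  d <- small_design()
  ann <- generate_genome_and_annotation(d, seed = 3)
  genes <- ann$genes
  # 2 TFs + cascade PCGs (2*(2+4)) + 2 lncRNAs + 2 enhancer targets +
  # 2 distractor regs + 6 distractor targets + 10 DE + 4 unexpressed
  expect_equal(nrow(genes), 2 + 12 + 2 + 2 + 2 + 6 + 10 + 4)
  chrlen <- nchar(ann$genome[["chr1"]])
  wins <- t(sapply(seq_len(nrow(genes)), function(i) {
    w <- regcascade:::promoter_window(genes[i, ], 1000, 200)
    c(w[["start"]], w[["end"]])
  }))
  expect_true(all(wins[, 1] >= 0 & wins[, 2] <= chrlen))
  expect_true(all(wins[, 2] - wins[, 1] == 1200))
  # pairwise non-overlap of promoter windows
  ord <- order(wins[, 1])
  expect_true(all(wins[ord[-1], 1] >= wins[ord[-nrow(wins)], 2]))
})

test_that("minus-strand promoter windows are strand-reflected", {
  bed_row <- data.frame(chrom = "chr1", start = 4401L, end = 5001L,
                        name = "g", score = 0L, strand = "-",
                        class = "PCG", stringsAsFactors = FALSE)
  t <- 5000L  # TSS = end - 1
  w <- regcascade:::promoter_window(bed_row, 1000, 200)
  expect_equal(unname(w[["start"]]), t - 200 + 1)
  expect_equal(unname(w[["end"]]), t + 1000 + 1)
})

test_that("every lncRNA locus intersects an enhancer at overlap fraction 1", {
  d <- small_design()
  ann <- generate_genome_and_annotation(d, seed = 3)
  lnc <- ann$genes[ann$genes$class %in% c("lncRNA", "antisense"), ]
  expect_equal(nrow(lnc), 2)
  for (i in seq_len(nrow(lnc))) {
    hits <- vapply(seq_len(nrow(ann$enhancers)), function(j) {
      oracle_overlap(lnc[i, ], ann$enhancers[j, ])
    }, TRUE)
    expect_true(any(hits))
  }
})

test_that("the reference cascade forest has the planted shape and no cycles", {
  d <- sim_design(n_tfs = 1, branching = 2, depth = 3, n_lncrnas = 1,
                  n_antisense = 0, n_distractor_regulators = 0,
                  distractor_edges_per_regulator = 1,
                  n_de_genes = 1, n_unexpressed = 1)
  st <- regcascade:::sim_structure(d)
  ref <- st$edges[st$edges$in_reference, ]
  expect_equal(nrow(ref), 2 + 4 + 8)
  expect_true(all(ref$beta > 0))           # no distractors requested
  expect_true(oracle_is_acyclic(st$edges))

  d2 <- small_design()
  st2 <- regcascade:::sim_structure(d2)
  expect_true(oracle_is_acyclic(st2$edges))
  expect_true(all(st2$edges$beta[st2$edges$distractor] == 0))
})

test_that("planted motif sites put the consensus into the promoter", {
  study <- default_study()
  cfg <- default_config()
  lnc <- study$genes[study$genes$class %in% c("lncRNA", "antisense"), ]
  promoters <- extract_promoters(lnc, study$genome,
                                 cfg$promoter_upstream,
                                 cfg$promoter_downstream)
  sites <- study$truth$motif_sites
  expect_gt(nrow(sites), 0)
  for (i in seq_len(nrow(sites))) {
    pwm <- study$motifs[[sites$tf[i]]]
    consensus <- attr(pwm, "consensus")
    expected <- if (sites$strand[i] == "+") consensus else
      regcascade:::rc_revcomp(consensus)
    window <- substr(promoters[[sites$lncrna[i]]], sites$offset[i] + 1,
                     sites$offset[i] + pwm$length)
    expect_identical(window, expected)
  }
})

test_that("zero planted sites leave the genome untouched", {
  d <- small_design(sites_per_lncrna = 0)
  ann <- generate_genome_and_annotation(d, seed = 9)
  set.seed(9)
  motifs <- generate_motifs(d)
  st <- ann$structure
  planted <- plant_motif_sites(ann$genome, ann$genes,
                               data.frame(lncrna = st$lnc_ids,
                                          tf = st$lnc_tf),
                               motifs, sites_per_lncrna = 0)
  expect_identical(planted$genome, ann$genome)
  expect_equal(nrow(planted$motif_sites), 0)
})

test_that("decoupled regulators and targets are uncorrelated", {
  # beta = 0 everywhere: sample correlations collapse to ~0 at n = 200
  d <- small_design(coupling_strength = 0,
                    samples = list(iPSC = c(normal = 200, ASD = 2),
                                   NPC = c(normal = 2, ASD = 2),
                                   neuron = c(normal = 2, ASD = 2)))
  study <- simulate_study(d, seed = 42)
  # log counts without per-library scaling: scaling by the (random) library
  # size would couple otherwise independent genes through a common factor
  lc <- log2(study$counts + 1)
  ids <- study$sheet$sample_id[study$sheet$cell_type == "iPSC" &
                                 study$sheet$condition == "normal"]
  planted <- study$truth$edges[!study$truth$edges$distractor, ]
  rs <- vapply(seq_len(nrow(planted)), function(i) {
    pearson(lc[planted$regulator[i], ids], lc[planted$target[i], ids])
  }, 0.0)
  expect_true(all(abs(rs) <= 3 / sqrt(200)))
})

test_that("planted fold changes are recovered on the count scale", {
  d <- small_design(nb_dispersion = 0.05, planted_lfc = 2,
                    samples = list(iPSC = c(normal = 2, ASD = 2),
                                   NPC = c(normal = 20, ASD = 20),
                                   neuron = c(normal = 2, ASD = 2)))
  study <- simulate_study(d, seed = 7)
  sheet <- study$sheet
  de <- study$truth$de_genes$NPC$gene
  asd <- sheet$sample_id[sheet$cell_type == "NPC" & sheet$condition == "ASD"]
  nrm <- sheet$sample_id[sheet$cell_type == "NPC" & sheet$condition == "normal"]
  obs <- log2(rowMeans(study$counts[de, asd]) /
                rowMeans(study$counts[de, nrm]))
  expect_true(all(abs(obs - 2) < 0.3 + 3 * sd(obs)))
  expect_lt(abs(mean(obs) - 2), 0.3)
})

test_that("identical design and seed give byte-identical studies", {
  d <- small_design()
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  write_study(simulate_study(d, seed = 13), dir1)
  write_study(simulate_study(d, seed = 13), dir2)
  files <- list.files(dir1)
  expect_true(length(files) >= 8)
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(dir1, f))),
                     unname(tools::md5sum(file.path(dir2, f))),
                     label = f)
  }
})

test_that("correlation separation holds in the normal NPC group", {
  study <- default_study()
  lc <- normalize_cpm_log(filter_unexpressed(study$counts))
  sheet <- study$sheet
  ids <- sheet$sample_id[sheet$cell_type == "NPC" &
                           sheet$condition == "normal"]
  edges <- study$truth$edges
  rs <- function(sub) {
    vapply(seq_len(nrow(sub)), function(i) {
      abs(pearson(lc[sub$regulator[i], ids], lc[sub$target[i], ids]))
    }, 0.0)
  }
  active <- edges[!edges$distractor & edges$beta > 0, ]
  distract <- edges[edges$distractor, ]
  expect_gte(median(rs(active)), 0.8)
  expect_lte(median(rs(distract)), 0.3)
})
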