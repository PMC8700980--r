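test_that("reference loading dedupes, drops self-loops, tolerates empties", {
  df <- data.frame(regulator = c("A", "A", "A", "B"),
                   target = c("B", "B", "A", "C"),
                   weight = 1)
  net <- load_reference_network(df)
  expect_equal(nrow(net), 2)
  expect_false(any(net$regulator == net$target))
  expect_warning(empty <- load_reference_network(df[0, ]), "empty")
  expect_equal(nrow(empty), 0)
})

test_that("expression filtering equals brute-force endpoint membership", {
  set.seed(51)
  genes <- sprintf("g%02d", 1:10)
  net <- data.frame(regulator = sample(genes, 30, TRUE),
                    target = sample(genes, 30, TRUE),
                    edge_type = "tf_gene", evidence = "reference_network")
  net <- net[net$regulator != net$target, ]
  expressed <- sample(genes, 6)
  got <- filter_by_expression(net, expressed)
  want <- net[vapply(seq_len(nrow(net)), function(i) {
    net$regulator[i] %in% expressed && net$target[i] %in% expressed
  }, TRUE), ]
  expect_equal(got, want, ignore_attr = TRUE)
  expect_equal(filter_by_expression(net, genes), net, ignore_attr = TRUE)
})

test_that("interval overlap follows half-open semantics and matches oracles", {
  a <- list(chrom = "chr1", start = 0, end = 10)
  expect_false(interval_overlap(a, list(chrom = "chr1", start = 10, end = 20)))
  expect_true(interval_overlap(a, list(chrom = "chr1", start = 9, end = 20)))
  expect_false(interval_overlap(a, list(chrom = "chr2", start = 0, end = 10)))

  set.seed(52)
  has_gr <- requireNamespace("GenomicRanges", quietly = TRUE)
  for (i in 1:1000) {
    s1 <- sample(0:60, 1); e1 <- s1 + sample(1:15, 1)
    s2 <- sample(0:60, 1); e2 <- s2 + sample(1:15, 1)
    c1 <- sample(c("chr1", "chr2"), 1); c2 <- sample(c("chr1", "chr2"), 1)
    A <- list(chrom = c1, start = s1, end = e1)
    B <- list(chrom = c2, start = s2, end = e2)
    expect_identical(interval_overlap(A, B), oracle_overlap(A, B))
    expect_identical(interval_overlap(A, B), interval_overlap(B, A))
    if (has_gr && i <= 200) {
      gr <- suppressWarnings(GenomicRanges::countOverlaps(
        GenomicRanges::GRanges(c1, IRanges::IRanges(s1 + 1, e1)),
        GenomicRanges::GRanges(c2, IRanges::IRanges(s2 + 1, e2)))) > 0
      expect_identical(interval_overlap(A, B), unname(gr))
    }
  }
})

test_that("enhancer targets dedupe and recover the planted links exactly", {
  lnc <- data.frame(chrom = "chr1", start = c(100L, 500L), end = c(200L, 600L),
                    name = c("L1", "L2"), score = 0L, strand = c("+", "-"),
                    class = "lncRNA")
  enh <- data.frame(chrom = "chr1",
                    start = c(150L, 180L, 1000L, 510L),
                    end = c(170L, 210L, 1100L, 540L),
                    name = c("G1", "G1", "G2", ""),
                    score = 0L, strand = ".", class = "enhancer")
  got <- lncrna_enhancer_targets(lnc, enh)
  # two enhancers of the same gene overlap L1 -> one edge; unnamed skipped
  expect_equal(nrow(got), 1)
  expect_equal(got$regulator, "L1")
  expect_equal(got$target, "G1")
  expect_equal(got$evidence, "enhancer_overlap")
  expect_equal(nrow(lncrna_enhancer_targets(lnc, enh[3, ])), 0)

  study <- default_study()
  lnc_all <- study$genes[study$genes$class %in% c("lncRNA", "antisense"), ]
  edges <- lncrna_enhancer_targets(lnc_all, study$enhancers)
  truth <- study$truth$enhancer_links
  expect_setequal(paste(edges$regulator, edges$target),
                  paste(truth$lncrna, truth$target))
})

test_that("assembly is a deduplicating union and is idempotent", {
  a <- data.frame(regulator = c("T1", "T1"), target = c("g1", "g2"),
                  edge_type = "tf_gene", evidence = "reference_network")
  b <- data.frame(regulator = "T1", target = "L1", edge_type = "tf_lncrna",
                  evidence = "motif")
  c_ <- data.frame(regulator = c("L1", "T1"), target = c("g3", "g1"),
                   edge_type = c("lncrna_gene", "tf_gene"),
                   evidence = c("enhancer_overlap", "reference_network"))
  net <- assemble_network(a, b, c_)
  expect_equal(nrow(net), 4)  # duplicate (T1,g1,tf_gene) collapsed
  expect_equal(net, assemble_network(net, a[0, ]), ignore_attr = TRUE)
  # disjoint unions add sizes; brute-force set union agreement
  key <- function(d) sort(paste(d$regulator, d$target, d$edge_type))
  expect_identical(key(net), unique(sort(c(key(a), key(b), key(c_)))))
  # same pair under two types is kept twice
  d <- data.frame(regulator = "T1", target = "L1", edge_type = "lncrna_gene",
                  evidence = "enhancer_overlap")
  expect_equal(nrow(assemble_network(b, d)), 2)
})
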