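sharp_pwm <- function(L, name = "toy", seed = 1) {
  set.seed(seed)
  consensus <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  counts <- matrix(5, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_len(L)) counts[consensus[j], j] <- 85
  p <- pwm_record(name, counts)
  attr(p, "consensus") <- paste(consensus, collapse = "")
  p
}

soft_pwm <- function(L, name = "soft", seed = 2) {
  set.seed(seed)
  counts <- replicate(L, sample(c(35, 28, 22, 15)))
  rownames(counts) <- c("A", "C", "G", "T")
  pwm_record(name, counts)
}

test_that("JASPAR parsing normalizes row order and validates counts", {
  lines <- c(">M1 TFA",
             "T  [ 1 2 3 ]",
             "G  [ 4 5 6 ]",
             "C  [ 7 8 9 ]",
             "A  [ 10 11 12 ]",
             ">M2 TFB",
             "A [ 1 1 ]", "C [ 2 2 ]", "G [ 3 3 ]", "T [ 4 4 ]")
  f <- withr::local_tempfile(lines = lines)
  pwms <- parse_jaspar(f)
  expect_length(pwms, 2)
  expect_equal(pwms$TFA$length, 3)
  expect_equal(unname(pwms$TFA$counts["A", ]), c(10, 11, 12))
  expect_equal(unname(pwms$TFA$counts["T", ]), c(1, 2, 3))
  expect_equal(pwms$TFB$length, 2)

  bad <- withr::local_tempfile(lines = c(">M3 TFC", "A [ 1 ]", "C [ -2 ]",
                                         "G [ 3 ]", "T [ 4 ]"))
  expect_error(parse_jaspar(bad), "negative count")
  short <- withr::local_tempfile(lines = c(">M4 TFD", "A [ 1 2 ]", "C [ 3 ]",
                                           "G [ 4 5 ]", "T [ 6 7 ]"))
  expect_error(parse_jaspar(short), "length mismatch")
})

test_that("JASPAR files round trip through write and parse", {
  pwms <- list(A1 = sharp_pwm(6, "A1", 11), B2 = soft_pwm(4, "B2", 12))
  f <- withr::local_tempfile()
  write_jaspar(pwms, f)
  back <- parse_jaspar(f)
  expect_equal(back$A1$counts, pwms$A1$counts, ignore_attr = TRUE)
  expect_equal(back$B2$counts, pwms$B2$counts, ignore_attr = TRUE)
})

test_that("threshold computation is exact on enumerable cases", {
  # L = 1, uniform background: best base has probability exactly 0.25
  one <- pwm_record("one", matrix(c(97, 1, 1, 1), 4, 1))
  thr <- score_threshold_from_pvalue(one, 0.25)
  expect_equal(thr$threshold_int, max(floor(one$log_odds / 1e-3)))
  expect_equal(thr$tail_mass, 0.25)
  # pvalue = 1 admits every score
  all_thr <- score_threshold_from_pvalue(one, 1)
  expect_equal(all_thr$threshold_int, min(floor(one$log_odds / 1e-3)))
  expect_equal(all_thr$tail_mass, 1)
  # pvalue below the best word's probability falls back to the max score
  expect_warning(
    thr_max <- score_threshold_from_pvalue(one, 0.1),
    "best word")
  expect_equal(thr_max$threshold_int, max(floor(one$log_odds / 1e-3)))
})

test_that("DP threshold equals brute-force enumeration for short motifs", {
  for (L in 2:6) {
    for (mk in list(sharp_pwm, soft_pwm)) {
      pwm <- mk(L, seed = 100 + L)
      for (pv in c(0.25, 1e-2, 5e-5)) {
        got <- suppressWarnings(score_threshold_from_pvalue(pwm, pv))
        want <- oracle_pwm_threshold(pwm, pv)
        expect_equal(got$threshold_int, want$threshold_int,
                     label = sprintf("L=%d p=%g", L, pv))
        expect_equal(got$tail_mass, want$tail_mass, tolerance = 1e-12)
      }
    }
  }
})

test_that("thresholds are monotone in the p-value", {
  pwm <- soft_pwm(8, seed = 5)
  pvs <- c(0.5, 0.1, 1e-2, 1e-3, 5e-5)
  thr <- vapply(pvs, function(p) {
    score_threshold_from_pvalue(pwm, p)$threshold_int
  }, 0L)
  expect_true(all(diff(thr) >= 0))
})

test_that("promoter extraction follows the stated window arithmetic", {
  set.seed(21)
  genome <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 8000, TRUE),
                           collapse = ""))
  plus <- data.frame(chrom = "chr1", start = 5000L, end = 5600L, name = "gp",
                     score = 0L, strand = "+", class = "lncRNA")
  got <- extract_promoters(plus, genome, 1000, 200)
  expect_equal(nchar(got[["gp"]]), 1200)
  expect_identical(got[["gp"]], unname(substring(genome, 4001, 5200)))

  minus <- data.frame(chrom = "chr1", start = 4400L, end = 5001L, name = "gm",
                      score = 0L, strand = "-", class = "lncRNA")
  gotm <- extract_promoters(minus, genome, 1000, 200)
  # TSS = 5000; reflected window [4801, 6001), reverse complemented
  expect_identical(gotm[["gm"]],
                   unname(regcascade:::rc_revcomp(substring(genome, 4802, 6001))))

  near <- data.frame(chrom = "chr1", start = 100L, end = 700L, name = "gc",
                     score = 0L, strand = "+", class = "lncRNA")
  expect_warning(clip <- extract_promoters(near, genome, 1000, 200),
                 "clipped")
  expect_identical(clip[["gc"]], unname(substring(genome, 1, 300)))
  bad <- data.frame(chrom = "chrX", start = 100L, end = 700L, name = "gx",
                    score = 0L, strand = "+", class = "lncRNA")
  expect_error(extract_promoters(bad, genome), "unknown chromosome")
})

test_that("scanning finds a planted consensus at its offset and strand", {
  pwm <- sharp_pwm(10, "TFX", seed = 31)
  set.seed(32)
  prom <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  consensus <- attr(pwm, "consensus")
  fwd <- prom
  substr(fwd, 101, 110) <- consensus
  rev <- prom
  substr(rev, 201, 210) <- regcascade:::rc_revcomp(consensus)
  hits <- scan_promoters(list(pwm), c(pf = fwd, pr = rev), pvalue = 5e-5)
  expect_true(any(hits$sequence_id == "pf" & hits$offset == 100 &
                    hits$strand == "+"))
  expect_true(any(hits$sequence_id == "pr" & hits$offset == 200 &
                    hits$strand == "-"))
  expect_true(all(hits$pvalue_bound <= 5e-5))
  # empty motif list gives an empty, well-formed table
  none <- scan_promoters(list(), c(pf = fwd))
  expect_equal(nrow(none), 0)
})

test_that("scanning a sequence equals scanning its reverse complement", {
  pwm <- soft_pwm(7, seed = 41)
  set.seed(42)
  s <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  rc <- regcascade:::rc_revcomp(s)
  h1 <- scan_promoters(list(pwm), c(x = s), pvalue = 1e-2)
  h2 <- scan_promoters(list(pwm), c(x = rc), pvalue = 1e-2)
  # hits map 1:1 under offset -> len - L - offset with flipped strand
  key1 <- sort(paste(500 - 7 - h1$offset, ifelse(h1$strand == "+", "-", "+")))
  key2 <- sort(paste(h2$offset, h2$strand))
  expect_identical(key1, key2)
})

test_that("hit collapse produces distinct, ordered TF-target edges", {
  hits <- data.frame(tf = c("T1", "T1", "T2"),
                     sequence_id = c("L1", "L1", "L1"),
                     offset = c(3L, 50L, 7L), strand = c("+", "-", "+"),
                     score = 1, pvalue_bound = 1e-6)
  edges <- motif_hits_to_edges(hits)
  expect_equal(nrow(edges), 2)
  expect_equal(edges$regulator, c("T1", "T2"))
  expect_true(all(edges$edge_type == "tf_lncrna"))
})
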