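# Expression module: count filtering, log-CPM normalization, a calibrated
# negative-binomial Wald test for differential expression, and FDR control.

#' Remove unexpressed genes
#'
#' A gene is retained iff its median count across ALL samples is at least
#' `min_median`; genes with median strictly below the threshold are removed,
#' so a median exactly at the threshold survives. Gene order is preserved and
#' the operation is idempotent.
#'
#' @param cm an `rc_counts` object or counts matrix.
#' @param min_median minimum median read count (default 20).
#' @return filtered object of the same type as the input.
#' @export
filter_unexpressed <- function(cm, min_median = 20) {
  m <- if (inherits(cm, "rc_counts")) cm$counts else cm
  med <- apply(m, 1, stats::median)
  keep <- med >= min_median
  rc_log("filter_unexpressed: %d/%d genes retained (median >= %g)",
         sum(keep), nrow(m), min_median)
  if (!any(keep)) rc_warn("filter_unexpressed removed every gene")
  if (inherits(cm, "rc_counts")) {
    count_matrix(m[keep, , drop = FALSE],
                 gene_class = cm$gene_class[keep])
  } else {
    m[keep, , drop = FALSE]
  }
}

#' Log2 counts-per-million normalization
#'
#' `value = log2(count / librarySize * 1e6 + 1)`. A zero count maps to 0
#' exactly and a CPM of 1 to 1; the transform is monotone within each sample.
#' Used as the input to correlations and pathway activity scoring.
#'
#' @param cm an `rc_counts` object or counts matrix.
#' @return real matrix of the same shape.
#' @export
normalize_cpm_log <- function(cm) {
  m <- if (inherits(cm, "rc_counts")) cm$counts else cm
  lib <- colSums(m)
  if (any(lib <= 0)) {
    rc_stop("zero library size for sample(s): %s",
            paste(colnames(m)[lib <= 0], collapse = ", "))
  }
  log2(sweep(m, 2, lib, "/") * 1e6 + 1)
}

#' DESeq-style median-of-ratios size factors
#'
#' Falls back to library-size ratios when fewer than 50 genes have all-positive
#' counts (the geometric-mean reference is undefined on sparse toy matrices).
#' @param counts integer matrix.
#' @return numeric vector of per-sample size factors, geometric mean 1.
#' @export
size_factors <- function(counts) {
  allpos <- rowSums(counts == 0) == 0
  if (sum(allpos) < 50) {
    lib <- colSums(counts)
    sf <- lib / exp(mean(log(lib)))
    rc_log("size_factors: library-size fallback (%d all-positive genes)",
           sum(allpos))
    return(sf)
  }
  sub <- counts[allpos, , drop = FALSE]
  logref <- rowMeans(log(sub))
  sf <- apply(sub, 2, function(col) exp(stats::median(log(col) - logref)))
  sf / exp(mean(log(sf)))
}

trimmed_mean <- function(x, trim = 0.2) {
  x <- x[is.finite(x)]
  if (length(x) == 0) return(0)
  mean(x, trim = trim)
}

#' Negative-binomial Wald test for differential expression
#'
#' A fully specified count-based two-group test:
#' \enumerate{
#'   \item size factors by median-of-ratios ([size_factors()]);
#'   \item normalized group means `m_A`, `m_B`;
#'     `log2FC = log2((m_A + 0.5)/(m_B + 0.5))`;
#'   \item gene-wise dispersion by method of moments on normalized counts,
#'     shrunk 50/50 toward the 20%-trimmed mean of all gene-wise estimates and
#'     floored at 1e-8;
#'   \item Wald test on the log-mean difference with variance
#'     `sum over groups of (m + phi m^2) / (n m^2)`; two-sided normal p-value.
#' }
#' An all-zero gene gets `p = 1`, `log2FC = 0`. Swapping the groups negates
#' every log2FC and leaves p-values unchanged.
#'
#' @param cm an `rc_counts` object or counts matrix.
#' @param groupA,groupB sample ids of the two groups (each >= 2 samples);
#'   log2FC is reported as A over B.
#' @param lfc_threshold,fdr_threshold significance criteria
#'   (`|log2FC| > lfc_threshold` strictly, `fdr < fdr_threshold`).
#' @return data.frame with columns gene, log2FC, pvalue, fdr, significant.
#' @export
nb_differential_test <- function(cm, groupA, groupB,
                                 lfc_threshold = 1, fdr_threshold = 0.05) {
  m <- if (inherits(cm, "rc_counts")) cm$counts else cm
  if (length(groupA) < 2 || length(groupB) < 2) {
    rc_stop("both groups need at least 2 samples (got %d and %d)",
            length(groupA), length(groupB))
  }
  missing <- setdiff(c(groupA, groupB), colnames(m))
  if (length(missing) > 0) {
    rc_stop("samples absent from count matrix: %s",
            paste(missing, collapse = ", "))
  }
  sub <- m[, c(groupA, groupB), drop = FALSE]
  sf <- size_factors(sub)
  y <- sweep(sub, 2, sf, "/")
  ia <- seq_along(groupA)
  ib <- length(groupA) + seq_along(groupB)
  nA <- length(ia); nB <- length(ib)

  mA <- rowMeans(y[, ia, drop = FALSE])
  mB <- rowMeans(y[, ib, drop = FALSE])
  log2fc <- log2((mA + 0.5) / (mB + 0.5))

  # method-of-moments dispersion on normalized counts, pooled within groups
  ssA <- rowSums((y[, ia, drop = FALSE] - mA)^2)
  ssB <- rowSums((y[, ib, drop = FALSE] - mB)^2)
  s2 <- (ssA + ssB) / (nA + nB - 2)
  mbar <- (nA * mA + nB * mB) / (nA + nB)
  phi_raw <- ifelse(mbar > 0, pmax((s2 - mbar) / mbar^2, 0), 0)
  phi <- pmax(0.5 * phi_raw + 0.5 * trimmed_mean(phi_raw), 1e-8)

  mA5 <- mA + 0.5
  mB5 <- mB + 0.5
  se2 <- (mA5 + phi * mA5^2) / (nA * mA5^2) + (mB5 + phi * mB5^2) / (nB * mB5^2)
  wald <- log(mA5 / mB5) / sqrt(se2)
  pval <- 2 * stats::pnorm(-abs(wald))

  zero <- mA == 0 & mB == 0
  pval[zero] <- 1
  log2fc[zero] <- 0

  fdr <- benjamini_hochberg(pval)
  res <- data.frame(gene = rownames(m),
                    log2FC = log2fc,
                    pvalue = pval,
                    fdr = fdr,
                    significant = abs(log2fc) > lfc_threshold &
                      fdr < fdr_threshold,
                    stringsAsFactors = FALSE, row.names = NULL)
  rc_log("nb_differential_test: %d genes, %d/%d samples, %d significant",
         nrow(res), nA, nB, sum(res$significant))
  res
}

#' Benjamini-Hochberg step-up FDR
#'
#' Standard step-up adjustment, restored to input order and clipped to 1.
#' @param pvalues numeric vector in \[0,1\]; NaN is an error.
#' @return adjusted values in the input order.
#' @export
benjamini_hochberg <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(is.na(pvalues))) rc_stop("benjamini_hochberg: NA/NaN p-value input")
  if (any(pvalues < 0 | pvalues > 1)) {
    rc_stop("benjamini_hochberg: p-values must lie in [0,1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Call differentially expressed genes, split by gene class
#'
#' Returns the significant genes partitioned into protein-coding and
#' non-coding (lncRNA + antisense) sets, logging counts in the usual
#' "n DEGs (x PCGs, y lncRNAs)" reporting style.
#'
#' @param results data.frame from [nb_differential_test()].
#' @param gene_class named character vector mapping gene to class
#'   (`PCG`, `lncRNA`, `antisense`); unknown genes count as PCG.
#' @return list with elements `pcg`, `noncoding` and `all`.
#' @export
call_degs <- function(results, gene_class = NULL) {
  sig <- results$gene[results$significant]
  cls <- if (is.null(gene_class)) {
    rep("PCG", length(sig))
  } else {
    cl <- gene_class[sig]
    cl[is.na(cl)] <- "PCG"
    cl
  }
  out <- list(pcg = sig[cls == "PCG"],
              noncoding = sig[cls %in% c("lncRNA", "antisense")],
              all = sig)
  rc_log("call_degs: %d significant DEGs (%d PCGs, %d lncRNAs/antisense)",
         length(out$all), length(out$pcg), length(out$noncoding))
  out
}

#' Simulate a two-group negative-binomial count experiment
#'
#' Calibration utility for the differential-expression test: genes are NB with
#' common mean `mu` and dispersion `phi`; the first `n_de` genes carry a
#' multiplicative `2^lfc` shift in group A.
#'
#' @param n_genes,n_per_group problem size.
#' @param mu baseline mean count.
#' @param phi NB dispersion.
#' @param n_de number of shifted genes (may be 0 for a null simulation).
#' @param lfc planted log2 fold change for the shifted genes.
#' @return list with `counts` (matrix), `groupA`, `groupB`, `de_genes`.
#' @export
simulate_nb_counts <- function(n_genes, n_per_group, mu = 100, phi = 0.1,
                               n_de = 0, lfc = 0) {
  ids <- sprintf("g%05d", seq_len(n_genes))
  samples <- c(sprintf("A%03d", seq_len(n_per_group)),
               sprintf("B%03d", seq_len(n_per_group)))
  mu_mat <- matrix(mu, n_genes, 2 * n_per_group)
  if (n_de > 0) {
    mu_mat[seq_len(n_de), seq_len(n_per_group)] <- mu * 2^lfc
  }
  counts <- matrix(stats::rnbinom(length(mu_mat), mu = mu_mat, size = 1 / phi),
                   n_genes, 2 * n_per_group, dimnames = list(ids, samples))
  list(counts = counts,
       groupA = samples[seq_len(n_per_group)],
       groupB = samples[n_per_group + seq_len(n_per_group)],
       de_genes = if (n_de > 0) ids[seq_len(n_de)] else character(0))
}
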