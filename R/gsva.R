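# Pathway activity: a fully specified, rank-based gene-set variation score
# per sample (weighted random walk over expression ranks), group medians, and
# between-stage comparisons.

# (1) per-gene ECDF across samples, evaluated at each sample's value:
# F_i(x_ik) = (1/n) * #{k': x_ik' <= x_ik}, i.e. max-ties rank / n
gsva_ecdf <- function(expr_log) {
  Fm <- t(apply(expr_log, 1, rank, ties.method = "max")) / ncol(expr_log)
  dimnames(Fm) <- dimnames(expr_log)
  Fm
}

# walk underlying the score; expr_log is genes x samples
gsva_walk_stats <- function(expr_log, set_genes, Fm = NULL) {
  p <- nrow(expr_log)
  n <- ncol(expr_log)
  genes <- rownames(expr_log)
  set_genes <- intersect(set_genes, genes)
  m <- length(set_genes)
  if (m == 0) rc_stop("gene set has no member among the expressed genes")
  if (m >= p) rc_stop("gene set covers all %d genes; the walk is undefined", p)

  if (is.null(Fm)) Fm <- gsva_ecdf(expr_log)

  inset <- genes %in% set_genes
  scores <- stats::setNames(numeric(n), colnames(expr_log))
  for (k in seq_len(n)) {
    # (2) rank genes by ECDF value, descending; ties broken by gene id
    ord <- order(-Fm[, k], genes)
    r <- integer(p); r[ord] <- seq_len(p)
    # (3) distance-from-middle weights
    w <- abs(p / 2 - r)
    wset <- sum(w[inset])
    inc_in <- if (wset > 0) w / wset else rep(1 / m, p)
    # (4) walk over genes in rank order
    step <- ifelse(inset, inc_in, -1 / (p - m))[ord]
    v <- cumsum(step)
    # (5) largest positive plus largest negative deviation
    scores[k] <- max(0, max(v)) + min(0, min(v))
  }
  scores
}

#' Per-sample gene-set activity score
#'
#' A rank random-walk statistic over one sample's expression profile:
#' per-gene ECDFs across samples are ranked within the sample (ties broken by
#' gene id), each gene is weighted by its distance `|p/2 - rank|` from the
#' middle rank, and the walk accumulates in-set weight against a uniform
#' out-of-set penalty. The score is the largest positive deviation plus the
#' largest negative deviation of the walk and always lies in \[-1, 1\]. It is
#' invariant under strictly increasing transforms of any gene's values.
#'
#' @param expr_log real matrix (genes x samples), typically log2-CPM.
#' @param set_genes character vector of member gene ids; must hit at least one
#'   expressed gene and not all of them.
#' @param sample sample id or column index.
#' @return a single score in \[-1, 1\].
#' @export
gsva_score <- function(expr_log, set_genes, sample) {
  gsva_walk_stats(expr_log, set_genes)[[sample]]
}

#' Activity matrix over a gene-set collection
#'
#' @param expr_log real matrix (genes x samples).
#' @param sets named list of gene id vectors; sets with no expressed member
#'   are dropped with a log line.
#' @return real matrix, sets x samples, every entry in \[-1, 1\].
#' @export
gsva_scores <- function(expr_log, sets) {
  keep <- vapply(sets, function(s) {
    k <- length(intersect(s, rownames(expr_log)))
    k >= 1 && k < nrow(expr_log)
  }, TRUE)
  if (!all(keep)) {
    rc_log("gsva_scores: dropping %d set(s) with no usable member: %s",
           sum(!keep), paste(names(sets)[!keep], collapse = ", "))
  }
  sets <- sets[keep]
  if (length(sets) == 0) rc_stop("no usable gene set")
  Fm <- gsva_ecdf(expr_log)
  out <- t(vapply(sets, function(s) gsva_walk_stats(expr_log, s, Fm = Fm),
                  numeric(ncol(expr_log))))
  rownames(out) <- names(sets)
  out
}

#' Median activity per set per (cell type, condition) group
#'
#' Exact sample median (midpoint convention for even group size).
#' @param am activity matrix (sets x samples) from [gsva_scores()].
#' @param sheet sample sheet.
#' @return data.frame with columns set, cell_type, condition, median_score.
#' @export
median_activity <- function(am, sheet) {
  groups <- unique(sheet[, c("cell_type", "condition")])
  out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    ids <- sheet_group(sheet, groups$cell_type[i], groups$condition[i])
    data.frame(set = rownames(am),
               cell_type = groups$cell_type[i],
               condition = groups$condition[i],
               median_score = apply(am[, ids, drop = FALSE], 1, stats::median),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  out
}

#' Compare pathway activity between two stages
#'
#' Classical pooled-variance two-sample Student t-test on per-pathway score
#' vectors (two-sided); set `paired = TRUE` to pair scores by pathway. With
#' zero pooled variance the degenerate limit is reported: p = 1 when the means
#' are equal, p = 0 otherwise.
#'
#' @param scoresA,scoresB numeric vectors of per-pathway scores (>= 2 values
#'   each; equal length when paired).
#' @param paired whether to pair scores by pathway.
#' @return list with elements `t` and `pvalue`.
#' @export
compare_stage_activity <- function(scoresA, scoresB, paired = FALSE) {
  if (length(scoresA) < 2 || length(scoresB) < 2) {
    rc_stop("each group needs >= 2 scores")
  }
  if (paired && length(scoresA) != length(scoresB)) {
    rc_stop("paired comparison requires equal-length score vectors")
  }
  degenerate <- if (paired) {
    stats::var(scoresA - scoresB) == 0
  } else {
    stats::var(scoresA) == 0 && stats::var(scoresB) == 0
  }
  if (degenerate) {
    eq <- isTRUE(all.equal(mean(scoresA), mean(scoresB)))
    rc_log("compare_stage_activity: zero pooled variance, degenerate p = %d",
           as.integer(eq))
    return(list(t = if (eq) 0 else Inf * sign(mean(scoresA) - mean(scoresB)),
                pvalue = if (eq) 1 else 0))
  }
  ht <- stats::t.test(scoresA, scoresB, var.equal = TRUE, paired = paired)
  list(t = unname(ht$statistic), pvalue = ht$p.value)
}
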