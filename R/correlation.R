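# Edge correlation: per-(cell type, condition) Pearson coefficients for every
# edge, activation at the pair cutoff, and condition-unique target sets.

#' Pearson product-moment correlation with explicit degenerate handling
#'
#' Standard formula via [stats::cor()]; requires n >= 3 paired values and
#' returns NA (not NaN propagation) when either vector is constant — callers
#' treat such edges as inactive.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in \[-1, 1\], or NA for a constant input.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) rc_stop("pearson: length mismatch (%d vs %d)",
                                      length(x), length(y))
  if (length(x) < 3) rc_stop("pearson: need n >= 3, got %d", length(x))
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  r <- stats::cor(x, y)
  max(min(r, 1), -1)
}

#' Annotate network edges with per-group correlations and activation calls
#'
#' For every edge and every (cell type, condition) group, the Pearson
#' correlation of regulator and target log-CPM profiles across the group's
#' samples is computed. An edge is active in a group when `|r| >= cutoff`
#' (absolute value: negative regulation counts), except that `lncrna_gene`
#' edges — supported by physical enhancer overlap — are active unconditionally
#' whenever both genes are in the expression matrix (their r is still reported).
#' Groups with fewer than 3 samples, or genes absent from the matrix, yield
#' undefined r and an inactive edge.
#'
#' @param network edge data.frame from [assemble_network()].
#' @param expr_log log-CPM matrix (genes x samples) of expressed genes.
#' @param sheet sample sheet.
#' @param cutoff pair activation cutoff on `|r|` (default 0.75).
#' @return data.frame: regulator, target, edge_type, cell_type, condition,
#'   r, active.
#' @export
annotate_correlations <- function(network, expr_log, sheet, cutoff = 0.75) {
  groups <- unique(sheet[, c("cell_type", "condition")])
  res <- list()
  for (g in seq_len(nrow(groups))) {
    ct <- groups$cell_type[g]
    cond <- groups$condition[g]
    ids <- sheet_group(sheet, ct, cond)
    sub <- expr_log[, ids, drop = FALSE]
    have <- rownames(sub)
    n_ok <- length(ids) >= 3
    r <- rep(NA_real_, nrow(network))
    for (i in seq_len(nrow(network))) {
      reg <- network$regulator[i]
      tgt <- network$target[i]
      if (!n_ok || !(reg %in% have) || !(tgt %in% have)) next
      r[i] <- pearson(sub[reg, ], sub[tgt, ])
    }
    exempt <- network$edge_type == "lncrna_gene" &
      network$regulator %in% have & network$target %in% have
    active <- (!is.na(r) & abs(r) >= cutoff) | exempt
    res[[g]] <- data.frame(regulator = network$regulator,
                           target = network$target,
                           edge_type = network$edge_type,
                           cell_type = ct, condition = cond,
                           r = r, active = active,
                           stringsAsFactors = FALSE)
    rc_log("annotate_correlations: group (%s, %s): %d/%d edges active at |r| >= %g",
           ct, cond, sum(active), nrow(network), cutoff)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Target genes unique to one condition
#'
#' The targets of at least one active edge in activation table A, minus those
#' with an active edge in table B (same cell type, conditions differ).
#'
#' @param activationsA,activationsB activation tables restricted to one group
#'   each (rows of [annotate_correlations()] output).
#' @return character vector of condition-unique target gene ids.
#' @export
condition_unique_targets <- function(activationsA, activationsB) {
  ta <- unique(activationsA$target[activationsA$active])
  tb <- unique(activationsB$target[activationsB$active])
  sort(setdiff(ta, tb))
}
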