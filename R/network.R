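# Network assembly: reference TF->gene edges filtered by expression, motif
# TF->lncRNA edges, and lncRNA->gene edges by enhancer interval overlap,
# merged into one deduplicated regulator->target table.

empty_edges <- function() {
  data.frame(regulator = character(), target = character(),
             edge_type = character(), evidence = character(),
             stringsAsFactors = FALSE)
}

#' Load a reference regulator -> target edge list
#'
#' TSV with columns `regulator` and `target` (an optional `weight` column is
#' only used to drop non-positive rows). Self-loops are dropped with a count
#' logged; duplicate pairs are collapsed.
#'
#' @param path TSV path, or a data.frame with the same columns.
#' @return edge data.frame (regulator, target, edge_type = "tf_gene",
#'   evidence = "reference_network").
#' @export
load_reference_network <- function(path) {
  df <- if (is.data.frame(path)) path else rc_read_tsv(path)
  if (nrow(df) == 0) {
    rc_warn("reference network is empty")
    return(empty_edges())
  }
  if (!all(c("regulator", "target") %in% names(df))) {
    rc_stop("reference network needs columns regulator, target")
  }
  if ("weight" %in% names(df)) df <- df[df$weight > 0 | is.na(df$weight), ]
  self <- df$regulator == df$target
  if (any(self)) {
    rc_log("load_reference_network: dropped %d self-loop row(s)", sum(self))
    df <- df[!self, , drop = FALSE]
  }
  df <- unique(df[, c("regulator", "target")])
  out <- data.frame(regulator = df$regulator, target = df$target,
                    edge_type = "tf_gene", evidence = "reference_network",
                    stringsAsFactors = FALSE)
  out <- out[order(out$regulator, out$target), , drop = FALSE]
  rownames(out) <- NULL
  rc_log("load_reference_network: %d unique directed edge(s)", nrow(out))
  out
}

#' Keep only edges whose both endpoints are expressed
#' @param edges edge data.frame.
#' @param expressed_genes character vector of expressed gene ids (survivors of
#'   [filter_unexpressed()]).
#' @return filtered edge data.frame.
#' @export
filter_by_expression <- function(edges, expressed_genes) {
  keep <- edges$regulator %in% expressed_genes &
    edges$target %in% expressed_genes
  rc_log("filter_by_expression: %d/%d edges retained", sum(keep), nrow(edges))
  out <- edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genomic interval overlap (0-based half-open)
#'
#' True iff the intervals share a chromosome and `a.start < b.end` and
#' `b.start < a.end`; touching intervals do not overlap and strand is ignored.
#'
#' @param a,b lists or one-row data.frames with fields chrom, start, end.
#' @return logical scalar.
#' @export
interval_overlap <- function(a, b) {
  a$chrom == b$chrom && a$start < b$end && b$start < a$end
}

#' Infer lncRNA -> gene edges by enhancer overlap
#'
#' A lncRNA is declared a regulator of gene G when its locus overlaps an
#' enhancer interval assigned to G (the enhancer's `name` field carries the
#' target gene id). Edges are deduplicated; enhancers without a target name
#' are skipped with a log line. These edges are exempt from correlation
#' gating downstream.
#'
#' @param lncrna_loci BED data.frame of lncRNA gene bodies.
#' @param enhancers BED data.frame; `name` = target gene id.
#' @return edge data.frame (regulator = lncRNA, target, edge_type =
#'   "lncrna_gene", evidence = "enhancer_overlap").
#' @export
lncrna_enhancer_targets <- function(lncrna_loci, enhancers) {
  if (nrow(lncrna_loci) == 0 || nrow(enhancers) == 0) return(empty_edges())
  unnamed <- is.na(enhancers$name) | enhancers$name == "" |
    enhancers$name == "."
  if (any(unnamed)) {
    rc_log("lncrna_enhancer_targets: skipped %d enhancer(s) without target",
           sum(unnamed))
    enhancers <- enhancers[!unnamed, , drop = FALSE]
  }
  rows <- list()
  for (i in seq_len(nrow(lncrna_loci))) {
    for (j in seq_len(nrow(enhancers))) {
      if (interval_overlap(lncrna_loci[i, ], enhancers[j, ])) {
        rows[[length(rows) + 1L]] <- c(lncrna_loci$name[i], enhancers$name[j])
      }
    }
  }
  if (length(rows) == 0) return(empty_edges())
  pairs <- unique(do.call(rbind, rows))
  out <- data.frame(regulator = pairs[, 1], target = pairs[, 2],
                    edge_type = "lncrna_gene", evidence = "enhancer_overlap",
                    stringsAsFactors = FALSE)
  out <- out[out$regulator != out$target, , drop = FALSE]
  out <- out[order(out$regulator, out$target), , drop = FALSE]
  rownames(out) <- NULL
  rc_log("lncrna_enhancer_targets: %d edge(s)", nrow(out))
  out
}

#' Assemble the unified regulatory network
#'
#' Concatenates edge tables with a global deduplication on
#' (regulator, target, edge_type) — the same pair under distinct edge types is
#' distinct evidence and both rows are kept — and a stable lexicographic
#' ordering. Assembling an output with empty additions is the identity.
#'
#' @param ... edge data.frames (any of which may be empty).
#' @return unified edge data.frame.
#' @export
assemble_network <- function(...) {
  parts <- Filter(function(d) !is.null(d) && nrow(d) > 0, list(...))
  if (length(parts) == 0) return(empty_edges())
  all <- do.call(rbind, lapply(parts, function(d) {
    d[, c("regulator", "target", "edge_type", "evidence")]
  }))
  key <- paste(all$regulator, all$target, all$edge_type, sep = "\r")
  out <- all[!duplicated(key), , drop = FALSE]
  out <- out[order(out$regulator, out$target, out$edge_type), , drop = FALSE]
  rownames(out) <- NULL
  rc_log("assemble_network: %d unique edge(s) from %d input table(s)",
         nrow(out), length(parts))
  out
}
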