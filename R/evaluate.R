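# Comparison of pipeline output against the generator's planted truth.

#' Expected cascade implied by the planted truth
#'
#' Breadth-first reachability over the planted active edges of the requested
#' condition (broken edges, and therefore their whole subtrees, drop out in
#' ASD), depth-capped like the real cascade growth.
#'
#' @param truth an `rc_sim_truth`.
#' @param root root TF id.
#' @param condition "normal" or "ASD".
#' @param max_layers depth cap.
#' @return list with `nodes` (ids incl. root) and `edges` (data.frame
#'   regulator, target, edge_type).
#' @export
truth_expected_cascade <- function(truth, root, condition, max_layers = 3L) {
  act <- truth_active_edges(truth, condition)
  nodes <- root
  edges <- act[0, c("regulator", "target", "edge_type"), drop = FALSE]
  frontier <- root
  for (l in seq_len(max_layers)) {
    sub <- act[act$regulator %in% frontier &
                 !(act$target %in% nodes), , drop = FALSE]
    if (nrow(sub) == 0) break
    edges <- rbind(edges, sub[, c("regulator", "target", "edge_type")])
    frontier <- unique(sub$target)
    nodes <- c(nodes, frontier)
  }
  rownames(edges) <- NULL
  list(nodes = nodes, edges = edges)
}

#' Fraction of planted motif sites recovered by a scan
#'
#' A site counts as recovered when a hit matches its (lncRNA, TF, offset,
#' strand) exactly.
#' @param hits data.frame from [scan_promoters()].
#' @param motif_sites truth data.frame.
#' @return list with `recovered`, `total`, `fraction`.
#' @export
evaluate_motif_recovery <- function(hits, motif_sites) {
  if (nrow(motif_sites) == 0) {
    return(list(recovered = 0L, total = 0L, fraction = NA_real_))
  }
  hit_keys <- paste(hits$tf, hits$sequence_id, hits$offset, hits$strand)
  site_keys <- paste(motif_sites$tf, motif_sites$lncrna, motif_sites$offset,
                     motif_sites$strand)
  rec <- sum(site_keys %in% hit_keys)
  list(recovered = rec, total = nrow(motif_sites),
       fraction = rec / nrow(motif_sites))
}

#' Compare a grown cascade against its planted counterpart
#'
#' @param cascade an `rc_cascade`.
#' @param truth an `rc_sim_truth`.
#' @param condition condition the cascade was grown in.
#' @param max_layers depth cap used for the expected tree.
#' @return list: `exact` (node and edge sets match), `missing_nodes`,
#'   `spurious_nodes`, `expected_size`, `observed_size`.
#' @export
evaluate_cascade_recovery <- function(cascade, truth, condition,
                                      max_layers = 3L) {
  exp <- truth_expected_cascade(truth, cascade$root, condition, max_layers)
  obs_nodes <- cascade$nodes$id
  obs_edges <- paste(cascade$edges$parent, cascade$edges$child, sep = "->")
  exp_edges <- paste(exp$edges$regulator, exp$edges$target, sep = "->")
  list(exact = setequal(obs_nodes, exp$nodes) &&
         setequal(obs_edges, exp_edges),
       missing_nodes = setdiff(exp$nodes, obs_nodes),
       spurious_nodes = setdiff(obs_nodes, exp$nodes),
       expected_size = length(exp$nodes),
       observed_size = length(obs_nodes))
}
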