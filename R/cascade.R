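# Cascade module: rooted regulatory trees grown breadth-first from TF roots
# under a strict correlation gate, with disease-versus-control comparison.

#' Construct a cascade object
#'
#' @param root root TF id.
#' @param cell_type,condition the (cell type, condition) group the cascade was
#'   grown in.
#' @param nodes data.frame (id, layer, type); root at layer 0.
#' @param edges data.frame (parent, child, edge_type, r).
#' @return an `rc_cascade` object.
#' @export
new_cascade <- function(root, cell_type, condition, nodes, edges) {
  structure(list(root = root, cell_type = cell_type, condition = condition,
                 nodes = nodes, edges = edges),
            class = "rc_cascade")
}

#' @export
print.rc_cascade <- function(x, ...) {
  cat(sprintf("<rc_cascade> root %s (%s, %s): %d nodes, %d edges, depth %d\n",
              x$root, x$cell_type, x$condition, nrow(x$nodes), nrow(x$edges),
              max(x$nodes$layer)))
  invisible(x)
}

#' Validate cascade invariants
#'
#' Checks tree-ness (every non-root node has exactly one parent, child layer =
#' parent layer + 1), the depth cap, node uniqueness, and the correlation gate
#' (`|r| > cutoff` strictly for tf_gene / tf_lncrna edges; lncrna_gene edges
#' exempt).
#'
#' @param cs an `rc_cascade`.
#' @param max_layers depth cap.
#' @param cascade_corr_cutoff gate checked on stored edge correlations; NULL
#'   skips the gate check (e.g. for deserialized cascades without context).
#' @return the cascade, invisibly; errors on violation.
#' @export
validate_cascade <- function(cs, max_layers = 3L, cascade_corr_cutoff = NULL) {
  nodes <- cs$nodes
  edges <- cs$edges
  if (anyDuplicated(nodes$id)) rc_stop("cascade %s: duplicate node", cs$root)
  if (!cs$root %in% nodes$id || nodes$layer[nodes$id == cs$root] != 0) {
    rc_stop("cascade %s: root must be a layer-0 node", cs$root)
  }
  if (any(nodes$layer > max_layers)) {
    rc_stop("cascade %s: node beyond depth cap %d", cs$root, max_layers)
  }
  nonroot <- setdiff(nodes$id, cs$root)
  parent_count <- table(factor(edges$child, levels = nonroot))
  if (length(nonroot) > 0 && any(parent_count != 1)) {
    rc_stop("cascade %s: non-root node without exactly one parent", cs$root)
  }
  layer_of <- stats::setNames(nodes$layer, nodes$id)
  if (nrow(edges) > 0 &&
      any(layer_of[edges$child] != layer_of[edges$parent] + 1L)) {
    rc_stop("cascade %s: child layer must be parent layer + 1", cs$root)
  }
  if (!is.null(cascade_corr_cutoff) && nrow(edges) > 0) {
    gated <- edges$edge_type != "lncrna_gene"
    bad <- gated & (is.na(edges$r) | abs(edges$r) <= cascade_corr_cutoff)
    if (any(bad)) {
      rc_stop("cascade %s: gated edge with |r| <= %g", cs$root,
              cascade_corr_cutoff)
    }
  }
  invisible(cs)
}

#' Grow a regulatory cascade from a root TF
#'
#' Breadth-first growth in one (cell type, condition) group: layer l+1
#' candidates are network targets of layer-l nodes whose edge passes the gate
#' — `|r|` strictly greater than `cascade_corr_cutoff` for tf_gene/tf_lncrna
#' edges, while lncrna_gene (enhancer-evidence) edges pass whenever active.
#' A gene already in the cascade is never re-added (first encounter wins;
#' parents, and each parent's candidate targets, are processed in
#' lexicographic order for determinism). Growth stops at `max_layers`.
#'
#' @param root root TF id.
#' @param activations one group's slice of [annotate_correlations()] output
#'   (carries the network edges plus their r and active flags).
#' @param cascade_corr_cutoff strict gate (default 0.8).
#' @param max_layers depth cap (default 3).
#' @param gene_class optional named class map used to fill node types.
#' @return an `rc_cascade`; root-only when the root regulates nothing that
#'   passes the gate.
#' @export
grow_cascade <- function(root, activations, cascade_corr_cutoff = 0.8,
                         max_layers = 3L, gene_class = NULL) {
  gate <- ifelse(activations$edge_type == "lncrna_gene",
                 activations$active,
                 !is.na(activations$r) &
                   abs(activations$r) > cascade_corr_cutoff)
  ed <- activations[gate, , drop = FALSE]
  if (!root %in% activations$regulator) {
    rc_log("grow_cascade: root %s is not a regulator in the network", root)
  }
  node_ids <- root
  node_layer <- 0L
  edges <- list()
  frontier <- root
  layer <- 0L
  while (layer < max_layers && length(frontier) > 0) {
    nxt <- character(0)
    for (p in sort(frontier)) {
      cand <- ed[ed$regulator == p, , drop = FALSE]
      cand <- cand[order(cand$target), , drop = FALSE]
      for (i in seq_len(nrow(cand))) {
        tgt <- cand$target[i]
        if (tgt %in% node_ids) next
        node_ids <- c(node_ids, tgt)
        node_layer <- c(node_layer, layer + 1L)
        edges[[length(edges) + 1L]] <- data.frame(
          parent = p, child = tgt, edge_type = cand$edge_type[i],
          r = cand$r[i], stringsAsFactors = FALSE)
        nxt <- c(nxt, tgt)
      }
    }
    frontier <- nxt
    layer <- layer + 1L
  }
  type <- if (is.null(gene_class)) {
    rep("PCG", length(node_ids))
  } else {
    tp <- unname(gene_class[node_ids])
    tp[is.na(tp)] <- "PCG"
    tp
  }
  nodes <- data.frame(id = node_ids, layer = node_layer, type = type,
                      stringsAsFactors = FALSE)
  edges <- if (length(edges) == 0) {
    data.frame(parent = character(), child = character(),
               edge_type = character(), r = numeric(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, edges)
  }
  ct <- if (nrow(activations) > 0) activations$cell_type[1] else NA_character_
  cond <- if (nrow(activations) > 0) activations$condition[1] else NA_character_
  cs <- new_cascade(root, ct, cond, nodes, edges)
  validate_cascade(cs, max_layers = max_layers,
                   cascade_corr_cutoff = cascade_corr_cutoff)
  cs
}

#' Cascade size (node count including the root)
#' @param cs an `rc_cascade`.
#' @return integer node count, always >= 1.
#' @export
cascade_size <- function(cs) nrow(cs$nodes)

#' Grow cascades for every root in every group
#'
#' One cascade per root TF per (cell type, condition) group. Cascades with no
#' passing regulation (root only) are excluded from the counted set — a
#' cascade requires at least one regulation — but returned for inspection.
#'
#' @param tf_list character vector of root TF ids.
#' @param activations full [annotate_correlations()] table.
#' @param cascade_corr_cutoff,max_layers growth parameters.
#' @param gene_class optional class map for node types.
#' @return nested list: `result[[cell_type]][[condition]]` is a list with
#'   `cascades` (all, named by root) and `counted` (roots with >= 1 edge).
#' @export
build_all_cascades <- function(tf_list, activations, cascade_corr_cutoff = 0.8,
                               max_layers = 3L, gene_class = NULL) {
  groups <- unique(activations[, c("cell_type", "condition")])
  out <- list()
  for (g in seq_len(nrow(groups))) {
    ct <- groups$cell_type[g]
    cond <- groups$condition[g]
    sub <- activations[activations$cell_type == ct &
                         activations$condition == cond, , drop = FALSE]
    cascades <- lapply(sort(tf_list), grow_cascade, activations = sub,
                       cascade_corr_cutoff = cascade_corr_cutoff,
                       max_layers = max_layers, gene_class = gene_class)
    names(cascades) <- sort(tf_list)
    counted <- names(cascades)[vapply(cascades,
                                      function(c) nrow(c$edges) > 0, TRUE)]
    out[[ct]][[cond]] <- list(cascades = cascades, counted = counted)
    rc_log("build_all_cascades: (%s, %s): %d/%d roots form a cascade, total size %d",
           ct, cond, length(counted), length(tf_list),
           sum(vapply(cascades[counted], cascade_size, 0L)))
  }
  out
}

#' Compare normal versus disease cascades of one cell type
#'
#' Per root TF: status `lost` (counted in normal, absent in disease), `shrunk`
#' (size ratio < 1), `grown`, `stable`, or `gained` (disease only). Also
#' reports the lost cascades whose normal size exceeds `size_threshold` and,
#' per root, the edges present in the normal cascade but not the disease one.
#'
#' @param normal,asd group results (`list(cascades, counted)`) from
#'   [build_all_cascades()] for the same cell type.
#' @param size_threshold size for the "lost over threshold" list (default 20).
#' @return list with `report` (data.frame root, size_normal, size_asd,
#'   status), `lost_over_threshold` (roots), and `lost_edges` (named list of
#'   edge data.frames).
#' @export
compare_cascades <- function(normal, asd, size_threshold = 20) {
  roots <- sort(union(normal$counted, asd$counted))
  edge_key <- function(cs) {
    if (nrow(cs$edges) == 0) return(character(0))
    paste(cs$edges$parent, cs$edges$child, sep = "->")
  }
  rows <- lapply(roots, function(rt) {
    in_n <- rt %in% normal$counted
    in_a <- rt %in% asd$counted
    sn <- if (in_n) cascade_size(normal$cascades[[rt]]) else 0L
    sa <- if (in_a) cascade_size(asd$cascades[[rt]]) else 0L
    status <- if (in_n && !in_a) "lost"
      else if (!in_n && in_a) "gained"
      else if (sa < sn) "shrunk"
      else if (sa > sn) "grown"
      else "stable"
    data.frame(root = rt, size_normal = sn, size_asd = sa, status = status,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows) %||%
    data.frame(root = character(), size_normal = integer(),
               size_asd = integer(), status = character(),
               stringsAsFactors = FALSE)
  lost_over <- report$root[report$status == "lost" &
                             report$size_normal > size_threshold]
  lost_edges <- list()
  for (rt in intersect(roots, normal$counted)) {
    ne <- normal$cascades[[rt]]$edges
    ak <- if (rt %in% asd$counted) edge_key(asd$cascades[[rt]]) else character(0)
    miss <- ne[!(paste(ne$parent, ne$child, sep = "->") %in% ak), ,
               drop = FALSE]
    if (nrow(miss) > 0) {
      rownames(miss) <- NULL
      lost_edges[[rt]] <- miss
    }
  }
  rc_log("compare_cascades: %d roots, %d lost (%d over size %d)",
         nrow(report), sum(report$status == "lost"), length(lost_over),
         size_threshold)
  list(report = report, lost_over_threshold = lost_over,
       lost_edges = lost_edges)
}
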