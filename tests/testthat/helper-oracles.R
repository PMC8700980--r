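# Independent oracles: deliberately naive re-derivations of each statistic,
# kept structurally different from the package implementations they check.

# literal five-step evaluation of the rank random-walk score
oracle_gsva <- function(expr, set_genes, sample_k) {
  p <- nrow(expr)
  n <- ncol(expr)
  genes <- rownames(expr)
  Fm <- matrix(0, p, n)
  for (i in 1:p) {
    for (k in 1:n) Fm[i, k] <- sum(expr[i, ] <= expr[i, k]) / n
  }
  if (is.character(sample_k)) sample_k <- match(sample_k, colnames(expr))
  ord <- order(-Fm[, sample_k], genes)
  r <- integer(p)
  for (pos in 1:p) r[ord[pos]] <- pos
  w <- abs(p / 2 - r)
  inset <- genes %in% set_genes
  m <- sum(inset)
  W <- sum(w[inset])
  acc <- 0
  vmax <- -Inf
  vmin <- Inf
  for (pos in 1:p) {
    g <- ord[pos]
    if (inset[g]) {
      acc <- acc + if (W > 0) w[g] / W else 1 / m
    } else {
      acc <- acc - 1 / (p - m)
    }
    vmax <- max(vmax, acc)
    vmin <- min(vmin, acc)
  }
  max(0, vmax) + min(0, vmin)
}

# exhaustive enumeration of all 4^L words: discretized score distribution,
# tail masses, and the smallest score with tail <= pvalue
oracle_pwm_threshold <- function(pwm, pvalue, granularity = 1e-3) {
  L <- pwm$length
  im <- floor(pwm$log_odds / granularity)
  words <- as.matrix(expand.grid(rep(list(1:4), L)))
  scores <- integer(nrow(words))
  probs <- numeric(nrow(words))
  for (w in seq_len(nrow(words))) {
    s <- 0L
    pr <- 1
    for (j in 1:L) {
      s <- s + im[words[w, j], j]
      pr <- pr * pwm$background[words[w, j]]
    }
    scores[w] <- s
    probs[w] <- pr
  }
  support <- sort(unique(scores))
  tail <- vapply(support, function(s) sum(probs[scores >= s]), 0.0)
  ok <- which(tail <= pvalue)
  idx <- if (length(ok) == 0) length(support) else min(ok)
  list(threshold_int = support[idx], tail_mass = tail[idx],
       support = support, tail = tail)
}

# layered reachability with the same gate and first-encounter rule, built on
# an adjacency list instead of data-frame scans
oracle_cascade <- function(root, act, cutoff, max_layers) {
  adj <- split(seq_len(nrow(act)), act$regulator)
  passes <- function(i) {
    if (act$edge_type[i] == "lncrna_gene") return(isTRUE(act$active[i]))
    !is.na(act$r[i]) && abs(act$r[i]) > cutoff
  }
  nodes <- root
  parent_of <- character(0)
  frontier <- root
  depth <- 0
  while (depth < max_layers && length(frontier) > 0) {
    newly <- character(0)
    for (p in sort(frontier)) {
      idx <- adj[[p]]
      if (is.null(idx)) next
      idx <- idx[order(act$target[idx])]
      for (i in idx) {
        tgt <- act$target[i]
        if (!passes(i) || tgt %in% nodes) next
        nodes <- c(nodes, tgt)
        parent_of[tgt] <- p
        newly <- c(newly, tgt)
      }
    }
    frontier <- newly
    depth <- depth + 1
  }
  list(nodes = sort(nodes),
       edges = sort(paste(parent_of, names(parent_of), sep = "->")))
}

# interval overlap by explicit base enumeration (intervals kept small)
oracle_overlap <- function(a, b) {
  if (a$chrom != b$chrom) return(FALSE)
  length(intersect(seq(a$start, a$end - 1), seq(b$start, b$end - 1))) > 0
}

# exact hypergeometric upper tail by a combinatorial sum
oracle_hyper_tail <- function(k, K, N, n) {
  if (K == 0) return(1)
  total <- 0
  for (i in k:min(K, n)) {
    total <- total + choose(K, i) * choose(N - K, n - i)
  }
  total / choose(N, n)
}

# Kahn topological sort; returns TRUE iff the directed graph is acyclic
oracle_is_acyclic <- function(edges) {
  nodes <- unique(c(edges$regulator, edges$target))
  indeg <- setNames(rep(0L, length(nodes)), nodes)
  for (t in edges$target) indeg[t] <- indeg[t] + 1L
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  el <- edges
  while (length(queue) > 0) {
    v <- queue[1]
    queue <- queue[-1]
    seen <- seen + 1L
    out <- which(el$regulator == v)
    for (i in out) {
      t <- el$target[i]
      indeg[t] <- indeg[t] - 1L
      if (indeg[t] == 0L) queue <- c(queue, t)
    }
    el <- el[el$regulator != v, , drop = FALSE]
  }
  seen == length(nodes)
}
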