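# Fixtures are built in code at test time; the default study and pipeline run
# are cached per session since several files assert against the same run.

options(regcascade.quiet = TRUE)

.rc_cache <- new.env(parent = emptyenv())

small_design <- function(...) {
  base <- list(n_tfs = 2, branching = 2, depth = 2, n_lncrnas = 2,
               n_antisense = 1, n_distractor_regulators = 2,
               distractor_edges_per_regulator = 3, n_de_genes = 10,
               n_unexpressed = 4,
               samples = list(iPSC = c(normal = 6, ASD = 6),
                              NPC = c(normal = 6, ASD = 6),
                              neuron = c(normal = 6, ASD = 6)),
               n_pathways = 3, pathway_size = 8)
  do.call(sim_design, utils::modifyList(base, list(...)))
}

# full default-conditions pipeline run, seed 1, computed once per session
default_run <- function() {
  if (!is.null(.rc_cache$run)) return(.rc_cache$run)
  dir <- file.path(tempdir(), "regcascade-default-run")
  summary <- run_pipeline(dir, default_config(), sim_design())
  .rc_cache$run <- list(dir = dir, summary = summary,
                        truth = read_truth(file.path(dir, "truth.json")),
                        cascades = read_cascade_json(
                          file.path(dir, "cascades.json")))
  .rc_cache$run
}

default_study <- function() {
  if (is.null(.rc_cache$study)) {
    .rc_cache$study <- simulate_study(sim_design(), seed = 1)
  }
  .rc_cache$study
}

# random activation table for property tests: a directed graph over `n` nodes
random_activation_table <- function(n_nodes, n_edges, lnc_frac = 0.15) {
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  reg <- sample(nodes, n_edges, replace = TRUE)
  tgt <- sample(nodes, n_edges, replace = TRUE)
  keep <- reg != tgt
  reg <- reg[keep]; tgt <- tgt[keep]
  ne <- length(reg)
  type <- ifelse(stats::runif(ne) < lnc_frac, "lncrna_gene", "tf_gene")
  r <- stats::runif(ne, -1, 1)
  r[sample(ne, max(0, round(ne * 0.1)))] <- NA  # undefined correlations
  data.frame(regulator = reg, target = tgt, edge_type = type,
             cell_type = "NPC", condition = "normal", r = r,
             active = stats::runif(ne) < 0.5, stringsAsFactors = FALSE)
}

# random valid cascade for serialization round trips
random_cascade <- function(max_layers = 3) {
  root <- "ROOT"
  nodes <- data.frame(id = root, layer = 0L, type = "PCG",
                      stringsAsFactors = FALSE)
  edges <- data.frame(parent = character(), child = character(),
                      edge_type = character(), r = numeric(),
                      stringsAsFactors = FALSE)
  frontier <- root
  counter <- 0L
  for (l in seq_len(max_layers)) {
    nxt <- character(0)
    for (p in frontier) {
      for (b in seq_len(sample(0:2, 1))) {
        counter <- counter + 1L
        id <- sprintf("N%03d", counter)
        type <- sample(c("PCG", "lncRNA"), 1)
        et <- if (type == "lncRNA") "tf_lncrna"
          else sample(c("tf_gene", "lncrna_gene"), 1)
        nodes <- rbind(nodes, data.frame(id = id, layer = l, type = type,
                                         stringsAsFactors = FALSE))
        edges <- rbind(edges, data.frame(
          parent = p, child = id, edge_type = et,
          r = if (et == "lncrna_gene") NA_real_ else
            sample(c(-1, 1), 1) * stats::runif(1, 0.81, 1),
          stringsAsFactors = FALSE))
        nxt <- c(nxt, id)
      }
    }
    frontier <- nxt
  }
  new_cascade(root, "NPC", "normal", nodes, edges)
}

expect_cascade_equal <- function(a, b) {
  expect_equal(a$root, b$root)
  expect_equal(a$cell_type, b$cell_type)
  expect_equal(a$condition, b$condition)
  expect_equal(a$nodes[order(a$nodes$id), ],
               b$nodes[order(b$nodes$id), ], ignore_attr = TRUE)
  expect_equal(a$edges[order(a$edges$child), ],
               b$edges[order(b$edges$child), ], ignore_attr = TRUE)
}
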