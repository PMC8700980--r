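# Pipeline orchestration: file-based stage handoff so each stage is
# independently runnable, testable and resumable. Every stage reads its
# predecessors' files from `dir`, writes its own outputs there, and logs a
# one-line summary. run_pipeline() executes the full order:
# simulate -> expression -> pathways -> motifs -> network -> correlate ->
# cascades -> enrich, then writes summary.json.

require_stage_file <- function(dir, file, produced_by) {
  path <- file.path(dir, file)
  if (!file.exists(path)) {
    rc_stop("missing '%s' under %s; run stage '%s' first", file, dir,
            produced_by)
  }
  path
}

read_matrix_tsv <- function(path) {
  df <- rc_read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

write_matrix_tsv <- function(m, path, first_col = "gene") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- first_col
  rc_write_tsv(df, path)
}

read_gene_classes <- function(dir) {
  df <- rc_read_tsv(require_stage_file(dir, "gene_classes.tsv", "simulate"))
  stats::setNames(df$class, df$gene)
}

#' Pipeline stages
#'
#' Each stage reads its inputs from `dir` (error naming the stage to run
#' first when they are missing), writes its outputs there, and returns its
#' key results invisibly. See [run_pipeline()] for the full order.
#'
#' @param dir working directory for stage handoff files.
#' @param config an `rc_config`.
#' @param design an `rc_sim_design` for the simulate stage.
#' @name pipeline-stages
NULL

#' @rdname pipeline-stages
#' @export
stage_simulate <- function(dir, config = default_config(),
                           design = sim_design()) {
  study <- simulate_study(design, seed = config$seed, config = config)
  write_study(study, dir)
  rc_log("stage simulate: study written to %s", dir)
  invisible(study)
}

#' @rdname pipeline-stages
#' @export
stage_expression <- function(dir, config = default_config()) {
  sheet <- read_sample_sheet(require_stage_file(dir, "samples.tsv", "simulate"))
  gene_class <- read_gene_classes(dir)
  cm <- read_counts(require_stage_file(dir, "counts.tsv", "simulate"), sheet,
                    gene_class = gene_class)
  filtered <- filter_unexpressed(cm, config$min_median_count)
  writeLines(rownames(filtered$counts), file.path(dir, "expressed_genes.txt"))
  logcpm <- normalize_cpm_log(filtered)
  write_matrix_tsv(logcpm, file.path(dir, "logcpm.tsv"))
  de <- list()
  for (ct in unique(sheet$cell_type)) {
    asd <- sheet_group(sheet, ct, "ASD")
    normal <- sheet_group(sheet, ct, "normal")
    res <- nb_differential_test(filtered, asd, normal,
                                lfc_threshold = config$lfc_threshold,
                                fdr_threshold = config$fdr_threshold)
    rc_write_tsv(res, file.path(dir, sprintf("de_%s.tsv", ct)))
    de[[ct]] <- call_degs(res, filtered$gene_class)
  }
  summary <- data.frame(cell_type = names(de),
                        degs = vapply(de, function(x) length(x$all), 0L),
                        pcg = vapply(de, function(x) length(x$pcg), 0L),
                        noncoding = vapply(de, function(x) length(x$noncoding),
                                           0L),
                        stringsAsFactors = FALSE)
  rc_write_tsv(summary, file.path(dir, "deg_summary.tsv"))
  rc_log("stage expression: DEGs per stage: %s",
         paste(sprintf("%s=%d", summary$cell_type, summary$degs),
               collapse = ", "))
  invisible(list(degs = de, summary = summary))
}

#' @rdname pipeline-stages
#' @export
stage_pathways <- function(dir, config = default_config()) {
  sheet <- read_sample_sheet(require_stage_file(dir, "samples.tsv", "simulate"))
  logcpm <- read_matrix_tsv(require_stage_file(dir, "logcpm.tsv", "expression"))
  sets <- read_gmt(require_stage_file(dir, "pathways.gmt", "simulate"))
  am <- gsva_scores(logcpm, sets)
  write_matrix_tsv(am, file.path(dir, "activity.tsv"), first_col = "set")
  med <- median_activity(am, sheet)
  rc_write_tsv(med, file.path(dir, "activity_medians.tsv"))
  tests <- list()
  for (cond in c("normal", "ASD")) {
    base <- med$median_score[med$cell_type == "iPSC" & med$condition == cond]
    for (ct in c("NPC", "neuron")) {
      other <- med$median_score[med$cell_type == ct & med$condition == cond]
      cmp <- compare_stage_activity(base, other)
      tests[[length(tests) + 1L]] <- data.frame(
        condition = cond, stage_a = "iPSC", stage_b = ct,
        t = cmp$t, pvalue = cmp$pvalue, stringsAsFactors = FALSE)
    }
  }
  tests <- do.call(rbind, tests)
  rc_write_tsv(tests, file.path(dir, "stage_tests.tsv"))
  rc_log("stage pathways: %d sets scored over %d samples", nrow(am), ncol(am))
  invisible(list(activity = am, medians = med, tests = tests))
}

#' @rdname pipeline-stages
#' @export
stage_motifs <- function(dir, config = default_config()) {
  genome <- read_fasta(require_stage_file(dir, "genome.fa", "simulate"))
  genes <- read_bed(require_stage_file(dir, "genes.bed", "simulate"))
  pwms <- parse_jaspar(require_stage_file(dir, "motifs.jaspar", "simulate"),
                       background = config$background,
                       pseudocount = config$pwm_pseudocount)
  lnc <- genes[genes$class %in% c("lncRNA", "antisense"), , drop = FALSE]
  promoters <- extract_promoters(lnc, genome,
                                 upstream = config$promoter_upstream,
                                 downstream = config$promoter_downstream)
  hits <- scan_promoters(pwms, promoters, pvalue = config$motif_pvalue,
                         granularity = config$score_granularity)
  rc_write_tsv(hits, file.path(dir, "motif_hits.tsv"))
  edges <- motif_hits_to_edges(hits)
  rc_write_tsv(edges, file.path(dir, "motif_edges.tsv"))
  rc_log("stage motifs: %d hits -> %d TF-lncRNA edge(s) over %d promoters",
         nrow(hits), nrow(edges), length(promoters))
  invisible(list(hits = hits, edges = edges))
}

#' @rdname pipeline-stages
#' @export
stage_network <- function(dir, config = default_config()) {
  expressed <- readLines(require_stage_file(dir, "expressed_genes.txt",
                                            "expression"))
  ref <- load_reference_network(require_stage_file(dir, "network.tsv",
                                                   "simulate"))
  ref <- filter_by_expression(ref, expressed)
  motif_edges <- rc_read_tsv(require_stage_file(dir, "motif_edges.tsv",
                                                "motifs"))
  genes <- read_bed(require_stage_file(dir, "genes.bed", "simulate"))
  enhancers <- read_bed(require_stage_file(dir, "enhancers.bed", "simulate"))
  lnc <- genes[genes$class %in% c("lncRNA", "antisense"), , drop = FALSE]
  enh_edges <- lncrna_enhancer_targets(lnc, enhancers)
  network <- assemble_network(ref, motif_edges, enh_edges)
  rc_write_tsv(network, file.path(dir, "network_assembled.tsv"))
  rc_log("stage network: %d edges (%d reference, %d motif, %d enhancer)",
         nrow(network), nrow(ref), nrow(motif_edges), nrow(enh_edges))
  invisible(network)
}

#' @rdname pipeline-stages
#' @export
stage_correlate <- function(dir, config = default_config()) {
  network <- rc_read_tsv(require_stage_file(dir, "network_assembled.tsv",
                                            "network"))
  logcpm <- read_matrix_tsv(require_stage_file(dir, "logcpm.tsv", "expression"))
  sheet <- read_sample_sheet(require_stage_file(dir, "samples.tsv", "simulate"))
  act <- annotate_correlations(network, logcpm, sheet,
                               cutoff = config$pair_corr_cutoff)
  rc_write_tsv(act, file.path(dir, "activations.tsv"))
  uniq <- list()
  for (ct in unique(sheet$cell_type)) {
    a <- act[act$cell_type == ct & act$condition == "ASD", , drop = FALSE]
    b <- act[act$cell_type == ct & act$condition == "normal", , drop = FALSE]
    for (dirn in c("ASD_only", "normal_only")) {
      genes <- if (dirn == "ASD_only") condition_unique_targets(a, b)
        else condition_unique_targets(b, a)
      if (length(genes) > 0) {
        uniq[[paste(ct, dirn)]] <- data.frame(cell_type = ct,
                                              direction = dirn, gene = genes,
                                              stringsAsFactors = FALSE)
      }
    }
  }
  uniq <- if (length(uniq) > 0) do.call(rbind, c(uniq, make.row.names = FALSE))
    else data.frame(cell_type = character(), direction = character(),
                    gene = character(), stringsAsFactors = FALSE)
  rc_write_tsv(uniq, file.path(dir, "unique_targets.tsv"))
  invisible(list(activations = act, unique_targets = uniq))
}

#' @rdname pipeline-stages
#' @param size_threshold "lost over threshold" size for the comparison report.
#' @export
stage_cascades <- function(dir, config = default_config(),
                           size_threshold = 20) {
  act <- rc_read_tsv(require_stage_file(dir, "activations.tsv", "correlate"))
  network <- rc_read_tsv(require_stage_file(dir, "network_assembled.tsv",
                                            "network"))
  gene_class <- read_gene_classes(dir)
  ref <- rc_read_tsv(require_stage_file(dir, "network.tsv", "simulate"))
  roots <- sort(unique(ref$regulator))
  built <- build_all_cascades(roots, act,
                              cascade_corr_cutoff = config$cascade_corr_cutoff,
                              max_layers = config$max_layers,
                              gene_class = gene_class)
  all_counted <- list()
  reports <- list()
  lost_rows <- list()
  for (ct in names(built)) {
    for (cond in names(built[[ct]])) {
      grp <- built[[ct]][[cond]]
      all_counted <- c(all_counted, unname(grp$cascades[grp$counted]))
    }
    if (all(c("normal", "ASD") %in% names(built[[ct]]))) {
      cmp <- compare_cascades(built[[ct]][["normal"]], built[[ct]][["ASD"]],
                              size_threshold = size_threshold)
      rep <- cmp$report
      if (nrow(rep) > 0) rep$cell_type <- ct
      reports[[ct]] <- rep
      for (rt in names(cmp$lost_edges)) {
        le <- cmp$lost_edges[[rt]]
        lost_rows[[paste(ct, rt)]] <- data.frame(
          cell_type = ct, root = rt, parent = le$parent, child = le$child,
          edge_type = le$edge_type, stringsAsFactors = FALSE)
      }
    }
  }
  write_cascade_json(all_counted, file.path(dir, "cascades.json"))
  report <- do.call(rbind, c(reports, make.row.names = FALSE))
  rc_write_tsv(report, file.path(dir, "cascade_comparison.tsv"))
  lost <- if (length(lost_rows) > 0)
    do.call(rbind, c(lost_rows, make.row.names = FALSE))
  else data.frame(cell_type = character(), root = character(),
                  parent = character(), child = character(),
                  edge_type = character(), stringsAsFactors = FALSE)
  rc_write_tsv(lost, file.path(dir, "lost_edges.tsv"))
  invisible(list(built = built, report = report, lost_edges = lost))
}

#' @rdname pipeline-stages
#' @export
stage_enrich <- function(dir, config = default_config()) {
  de_path <- require_stage_file(dir, "de_NPC.tsv", "expression")
  de <- rc_read_tsv(de_path)
  expressed <- readLines(require_stage_file(dir, "expressed_genes.txt",
                                            "expression"))
  sets <- read_gmt(require_stage_file(dir, "pathways.gmt", "simulate"))
  query <- de$gene[de$significant == "TRUE" | de$significant == TRUE]
  if (length(query) == 0) {
    rc_log("stage enrich: no significant NPC DEGs; writing empty table")
    res <- data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), pvalue = numeric(),
                      fdr = numeric(), stringsAsFactors = FALSE)
  } else {
    res <- hypergeom_enrich(query, expressed, sets)
  }
  rc_write_tsv(res, file.path(dir, "enrichment_npc.tsv"))
  invisible(res)
}

#' Run the full pipeline
#'
#' Executes simulate -> expression -> pathways -> motifs -> network ->
#' correlate -> cascades -> enrich under a single seed, then writes
#' `summary.json` with the headline numbers of the run (DEG counts per stage,
#' cascade counts and total sizes per group, condition-unique target counts,
#' stage-activity test p-values, motif counts, and truth-based recovery
#' metrics). Stage outputs are pure functions of (inputs, config, seed): two
#' runs with the same configuration produce byte-identical output trees.
#'
#' @param dir output directory.
#' @param config an `rc_config`.
#' @param design an `rc_sim_design`.
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(dir, config = default_config(),
                         design = sim_design()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stage_simulate(dir, config, design)
  expr <- stage_expression(dir, config)
  paths <- stage_pathways(dir, config)
  motifs <- stage_motifs(dir, config)
  stage_network(dir, config)
  corr <- stage_correlate(dir, config)
  casc <- stage_cascades(dir, config)
  enrich <- stage_enrich(dir, config)

  truth <- read_truth(file.path(dir, "truth.json"))
  recovery <- evaluate_motif_recovery(motifs$hits, truth$motif_sites)

  deg_counts <- stats::setNames(expr$summary$degs, expr$summary$cell_type)
  de_npc <- rc_read_tsv(file.path(dir, "de_NPC.tsv"))
  de_neu <- rc_read_tsv(file.path(dir, "de_neuron.tsv"))
  shared <- length(intersect(de_npc$gene[de_npc$significant %in% c(TRUE, "TRUE")],
                             de_neu$gene[de_neu$significant %in% c(TRUE, "TRUE")]))

  cascades <- list()
  for (ct in names(casc$built)) {
    for (cond in names(casc$built[[ct]])) {
      grp <- casc$built[[ct]][[cond]]
      cascades[[paste(ct, cond, sep = "_")]] <- list(
        count = length(grp$counted),
        total_size = sum(vapply(grp$cascades[grp$counted], cascade_size, 0L)))
    }
  }
  uniq <- corr$unique_targets
  tests <- paths$tests
  summary <- list(
    degs = as.list(deg_counts),
    degs_shared_npc_neuron = shared,
    stage_tests = lapply(seq_len(nrow(tests)), function(i) as.list(tests[i, ])),
    motif_hits = nrow(motifs$hits),
    motif_edges = length(unique(paste(motifs$hits$tf,
                                      motifs$hits$sequence_id))),
    motif_site_recovery = recovery,
    unique_targets = list(
      ASD_only = as.list(table(factor(
        uniq$cell_type[uniq$direction == "ASD_only"],
        levels = c("iPSC", "NPC", "neuron")))),
      normal_only = as.list(table(factor(
        uniq$cell_type[uniq$direction == "normal_only"],
        levels = c("iPSC", "NPC", "neuron"))))),
    cascades = cascades,
    lost_cascades = lapply(split(casc$report$status == "lost",
                                 casc$report$cell_type), sum),
    top_enrichment = if (nrow(enrich) > 0) {
      list(term = enrich$term[1], pvalue = enrich$pvalue[1])
    } else NULL
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  rc_log("run_pipeline: complete; summary.json written under %s", dir)
  invisible(summary)
}
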