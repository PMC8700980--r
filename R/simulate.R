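# Synthetic-data module: a complete miniature study — genome, annotations,
# motifs, reference network, enhancers, NB expression counts with planted
# regulatory structure — plus a machine-readable truth object, so every
# downstream stage is testable with no external download.
#
# Generative model (latent-activity linear-Gaussian with NB emission): per
# sample, every root regulator gets latent activity a ~ N(0,1); each planted
# target's latent value is beta * (parent latent) + eps with
# eps ~ N(0, latent_noise_sd^2), propagated in topological (layer) order.
# Mean count mu = baseline * 2^(latent + planted_lfc * I[DE gene, ASD,
# NPC/neuron stage]); counts ~ NB(mu, dispersion). In ASD samples, broken
# edges contribute beta = 0, so their whole downstream subtree decouples.

#' Synthetic study design
#'
#' Defaults define the reference study conditions: three cell types x two
#' conditions with sample counts 11/17 (iPSC), 9/21 (NPC) and 8/17 (neuron);
#' six TF-rooted cascades of branching 2 and depth 3 plus one motif-regulated
#' lncRNA per TF, each lncRNA with one enhancer-linked target gene; distractor
#' (beta = 0) edges under dedicated distractor regulators; 30% of gated edges
#' broken in ASD; DE genes (planted log2FC = 2) appearing only at the NPC and
#' neuron stages. Noise defaults (`latent_noise_sd = 0.03`,
#' `nb_dispersion = 0.003`, baseline mean counts floored at 500) are
#' calibrated so planted-edge population correlations sit near 0.99 — enough
#' margin above the 0.8 cascade gate that exact recovery holds family-wise
#' over all planted edges even in the smallest (n = 8) group — while
#' distractor edges stay near zero; see the methods vignette.
#'
#' @param n_tfs number of cascade root TFs.
#' @param branching children per protein-coding internal node.
#' @param depth planted cascade depth (layers below the root).
#' @param n_lncrnas motif-regulated lncRNAs (assigned to TFs round-robin).
#' @param n_antisense how many of the lncRNAs carry the antisense class.
#' @param n_distractor_regulators,distractor_edges_per_regulator zero-coupling
#'   edge block for specificity testing.
#' @param n_de_genes standalone genes with a planted ASD shift at NPC/neuron.
#' @param n_unexpressed genes below the median-count filter.
#' @param samples named list: cell type -> c(normal = n, ASD = n).
#' @param nb_dispersion NB dispersion phi.
#' @param latent_noise_sd sd of the per-edge latent noise eps.
#' @param standalone_latent_sd latent sd of genes outside the cascades.
#' @param coupling_strength beta for planted edges.
#' @param frac_edges_broken_in_asd fraction of gated planted edges broken.
#' @param planted_lfc log2 shift of DE genes in ASD NPC/neuron samples.
#' @param baseline_log_mean,baseline_log_sd,baseline_min lognormal baseline
#'   mean counts, clamped from below.
#' @param unexpressed_baseline mean count of the unexpressed block.
#' @param enhancer_overlap_fraction fraction of lncRNA loci overlapping an
#'   enhancer.
#' @param motif_length,motif_sharpness PFM length and consensus-base count out
#'   of 100.
#' @param sites_per_lncrna planted motif sites per lncRNA promoter.
#' @param slot_width,gene_length genomic layout, bp.
#' @param n_pathways,pathway_size synthetic gene-set collection.
#' @return validated list of class `rc_sim_design`.
#' @export
sim_design <- function(n_tfs = 6, branching = 2, depth = 3,
                       n_lncrnas = 6, n_antisense = 2,
                       n_distractor_regulators = 10,
                       distractor_edges_per_regulator = 10,
                       n_de_genes = 60, n_unexpressed = 20,
                       samples = list(iPSC = c(normal = 11, ASD = 17),
                                      NPC = c(normal = 9, ASD = 21),
                                      neuron = c(normal = 8, ASD = 17)),
                       nb_dispersion = 0.003,
                       latent_noise_sd = 0.03,
                       standalone_latent_sd = 0.3,
                       coupling_strength = 1,
                       frac_edges_broken_in_asd = 0.3,
                       planted_lfc = 2,
                       baseline_log_mean = log(800), baseline_log_sd = 0.4,
                       baseline_min = 500, unexpressed_baseline = 2,
                       enhancer_overlap_fraction = 1,
                       motif_length = 10, motif_sharpness = 85,
                       sites_per_lncrna = 1,
                       slot_width = 3000, gene_length = 600,
                       n_pathways = 6, pathway_size = 25) {
  d <- as.list(environment())
  for (k in c("n_tfs", "branching", "depth", "n_lncrnas")) {
    if (d[[k]] < 1) rc_stop("sim_design: %s must be >= 1", k)
  }
  if (d$nb_dispersion <= 0) rc_stop("sim_design: nb_dispersion must be > 0")
  for (k in c("frac_edges_broken_in_asd", "enhancer_overlap_fraction")) {
    if (d[[k]] < 0 || d[[k]] > 1) rc_stop("sim_design: %s must lie in [0,1]", k)
  }
  if (d$n_antisense > d$n_lncrnas) {
    rc_stop("sim_design: n_antisense cannot exceed n_lncrnas")
  }
  if (d$slot_width < 2 * 1300) {
    rc_stop("sim_design: slot_width too small for non-overlapping promoters")
  }
  structure(d, class = "rc_sim_design")
}

# deterministic node/edge structure (no RNG): gene table + planted edge table
sim_structure <- function(design) {
  genes <- list()
  edges <- list()
  pcg_n <- 0L
  new_pcg <- function() {
    pcg_n <<- pcg_n + 1L
    sprintf("P%03d", pcg_n)
  }
  add_gene <- function(id, class, role) {
    genes[[length(genes) + 1L]] <<- data.frame(
      id = id, class = class, role = role, stringsAsFactors = FALSE)
  }
  add_edge <- function(reg, tgt, type, layer, beta, distractor, in_reference) {
    edges[[length(edges) + 1L]] <<- data.frame(
      regulator = reg, target = tgt, edge_type = type, layer = layer,
      beta = beta, distractor = distractor, in_reference = in_reference,
      stringsAsFactors = FALSE)
  }
  tfs <- sprintf("TF%02d", seq_len(design$n_tfs))
  for (t in tfs) add_gene(t, "PCG", "tf")
  # protein-coding cascade forest: branching^l nodes at layer l under each TF
  for (t in tfs) {
    parents <- t
    for (l in seq_len(design$depth)) {
      children <- character(0)
      for (p in parents) {
        for (b in seq_len(design$branching)) {
          id <- new_pcg()
          add_gene(id, "PCG", "cascade")
          add_edge(p, id, "tf_gene", l, design$coupling_strength,
                   FALSE, TRUE)
          children <- c(children, id)
        }
      }
      parents <- children
    }
  }
  # motif-regulated lncRNAs (layer 1) and their enhancer-linked targets
  lnc_ids <- sprintf("LNC%02d", seq_len(design$n_lncrnas))
  n_overlap <- ceiling(design$enhancer_overlap_fraction * design$n_lncrnas)
  lnc_tf <- tfs[(seq_len(design$n_lncrnas) - 1L) %% design$n_tfs + 1L]
  for (j in seq_len(design$n_lncrnas)) {
    cls <- if (j > design$n_lncrnas - design$n_antisense) "antisense" else "lncRNA"
    add_gene(lnc_ids[j], cls, "lncrna")
    add_edge(lnc_tf[j], lnc_ids[j], "tf_lncrna", 1L,
             design$coupling_strength, FALSE, FALSE)
    id <- new_pcg()
    if (j <= n_overlap) {
      add_gene(id, "PCG", "enhancer_target")
      add_edge(lnc_ids[j], id, "lncrna_gene", 2L,
               design$coupling_strength, FALSE, FALSE)
    } else {
      # enhancer placed away from the locus: link not discoverable, gene is a
      # standalone bystander
      add_gene(id, "PCG", "standalone")
    }
  }
  # distractor block: beta = 0 edges under dedicated regulators
  for (dr in sprintf("DR%02d", seq_len(design$n_distractor_regulators))) {
    add_gene(dr, "PCG", "distractor_reg")
    for (b in seq_len(design$distractor_edges_per_regulator)) {
      id <- sprintf("D%03d",
                    (match(dr, sprintf("DR%02d",
                       seq_len(design$n_distractor_regulators))) - 1L) *
                      design$distractor_edges_per_regulator + b)
      add_gene(id, "PCG", "distractor_target")
      add_edge(dr, id, "tf_gene", 1L, 0, TRUE, TRUE)
    }
  }
  for (i in seq_len(design$n_de_genes)) {
    add_gene(sprintf("DEG%03d", i), "PCG", "de")
  }
  for (i in seq_len(design$n_unexpressed)) {
    add_gene(sprintf("U%03d", i), "PCG", "unexpressed")
  }
  list(genes = do.call(rbind, genes), edges = do.call(rbind, edges),
       tfs = tfs, lnc_ids = lnc_ids, lnc_tf = lnc_tf, n_overlap = n_overlap)
}

#' Generate the synthetic genome and annotations
#'
#' One chromosome of i.i.d. bases at the configured background. Every gene
#' occupies its own slot with an alternating strand and a TSS placed so the
#' promoter window fits inside the slot: promoter windows never overlap, so
#' planted motif truth is unambiguous. A configured fraction of lncRNA loci
#' overlap an enhancer interval carrying its target gene id in the BED name
#' field; the rest get a distal (non-overlapping) enhancer.
#'
#' @param design an `rc_sim_design`.
#' @param seed integer seed for the genome bases.
#' @param background base probabilities.
#' @return list: `genome` (named character), `genes` and `enhancers` (BED
#'   data.frames with class column), plus the internal structure tables.
#' @export
generate_genome_and_annotation <- function(design, seed,
                                           background = rep(0.25, 4)) {
  st <- sim_structure(design)
  genes <- st$genes
  n <- nrow(genes)
  chrom_len <- n * design$slot_width + 1000L
  need <- 2L * 1300L
  if (design$slot_width < need) {
    rc_stop("slot width %d too small; need >= %d bp per gene",
            design$slot_width, need)
  }
  set.seed(seed)
  genome <- c(chr1 = paste(sample(DNA_BASES, chrom_len, replace = TRUE,
                                  prob = background), collapse = ""))
  bed <- data.frame(chrom = "chr1", start = 0L, end = 0L, name = genes$id,
                    score = 0L, strand = "+", class = genes$class,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    base <- (i - 1L) * design$slot_width
    tss <- base + 1500L
    if (i %% 2L == 1L) {
      bed$strand[i] <- "+"
      bed$start[i] <- tss
      bed$end[i] <- tss + design$gene_length
    } else {
      bed$strand[i] <- "-"
      bed$end[i] <- tss + 1L
      bed$start[i] <- tss + 1L - design$gene_length
    }
  }
  # enhancers: overlapping for the first n_overlap lncRNAs, distal otherwise
  enh <- list()
  pcg_after <- function(lnc_idx) {
    # the enhancer-target PCG created right after lncRNA j in sim_structure
    eids <- st$edges
    hit <- eids$target[eids$regulator == st$lnc_ids[lnc_idx] &
                         eids$edge_type == "lncrna_gene"]
    if (length(hit) == 1) hit else NA_character_
  }
  standalone_after <- genes$id[genes$role == "standalone"]
  sa_i <- 0L
  for (j in seq_along(st$lnc_ids)) {
    row <- bed[bed$name == st$lnc_ids[j], ]
    base <- (which(genes$id == st$lnc_ids[j]) - 1L) * design$slot_width
    if (j <= st$n_overlap) {
      target <- pcg_after(j)
      enh[[length(enh) + 1L]] <- data.frame(
        chrom = "chr1", start = row$start + 100L, end = row$start + 400L,
        name = target, score = 0L, strand = ".", class = "enhancer",
        stringsAsFactors = FALSE)
    } else {
      sa_i <- sa_i + 1L
      enh[[length(enh) + 1L]] <- data.frame(
        chrom = "chr1", start = base + 50L, end = base + 350L,
        name = standalone_after[sa_i], score = 0L, strand = ".",
        class = "enhancer", stringsAsFactors = FALSE)
    }
  }
  enhancers <- if (length(enh) > 0) do.call(rbind, enh) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               name = character(), score = integer(), strand = character(),
               class = character(), stringsAsFactors = FALSE)
  rc_log("generate_genome_and_annotation: %d genes on 1 chromosome of %d bp, %d enhancer(s)",
         n, chrom_len, nrow(enhancers))
  list(genome = genome, genes = bed, enhancers = enhancers, structure = st)
}

#' Generate sharp position frequency matrices for the synthetic TFs
#'
#' One motif per TF: per column, the consensus base gets `motif_sharpness`
#' counts out of 100 and the others split the rest.
#' @param design an `rc_sim_design`.
#' @param background,pseudocount PWM construction parameters.
#' @return named list of `rc_pwm` objects (one per TF) with a `consensus`
#'   attribute each.
#' @export
generate_motifs <- function(design, background = rep(0.25, 4),
                            pseudocount = 0.8) {
  tfs <- sprintf("TF%02d", seq_len(design$n_tfs))
  out <- list()
  rest <- (100 - design$motif_sharpness) / 3
  hamming <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  chosen <- character(0)
  for (t in tfs) {
    # consensi kept mutually dissimilar (and to reverse complements), so no
    # planted site can double as a match for another TF's motif
    repeat {
      consensus <- sample(DNA_BASES, design$motif_length, replace = TRUE)
      word <- paste(consensus, collapse = "")
      min_d <- design$motif_length %/% 2
      ok <- all(vapply(chosen, function(w) {
        hamming(word, w) >= min_d && hamming(word, rc_revcomp(w)) >= min_d
      }, TRUE))
      if (ok) break
    }
    chosen <- c(chosen, word)
    counts <- matrix(rest, 4, design$motif_length,
                     dimnames = list(DNA_BASES, NULL))
    for (j in seq_len(design$motif_length)) {
      counts[consensus[j], j] <- design$motif_sharpness
    }
    pwm <- pwm_record(t, counts, background = background,
                      pseudocount = pseudocount)
    attr(pwm, "consensus") <- paste(consensus, collapse = "")
    out[[t]] <- pwm
  }
  out
}

# genomic promoter window of one BED row (same arithmetic as
# extract_promoters, shared so planting and extraction cannot drift)
promoter_window <- function(bed_row, upstream, downstream) {
  if (bed_row$strand == "+") {
    tss <- bed_row$start
    c(start = tss - upstream, end = tss + downstream)
  } else {
    tss <- bed_row$end - 1L
    c(start = tss - downstream + 1L, end = tss + upstream + 1L)
  }
}

#' Plant motif consensus sites into lncRNA promoters
#'
#' Writes each assigned TF's consensus (argmax base per PWM column) into the
#' promoter window of its lncRNA at recorded offsets and strands, without
#' overlapping previously planted sites. Offsets are in the promoter's own
#' coordinates (0-based from the window's 5' end, matching
#' [scan_promoters()] output); a minus-strand site means the reverse
#' complement of the consensus appears on the promoter's forward sequence.
#' With `sites_per_lncrna = 0` the genome is returned unchanged.
#'
#' @param genome named character vector.
#' @param genes BED data.frame.
#' @param assignments data.frame (lncrna, tf) pairing promoters with motifs.
#' @param pwms named list of `rc_pwm` with consensus attributes.
#' @param sites_per_lncrna sites planted per promoter.
#' @param upstream,downstream promoter window.
#' @return list: `genome` (updated) and `motif_sites` data.frame (lncrna, tf,
#'   offset, strand, genomic_start).
#' @export
plant_motif_sites <- function(genome, genes, assignments, pwms,
                              sites_per_lncrna = 1, upstream = 1000,
                              downstream = 200) {
  sites <- list()
  if (sites_per_lncrna == 0 || nrow(assignments) == 0) {
    return(list(genome = genome, motif_sites = data.frame(
      lncrna = character(), tf = character(), offset = integer(),
      strand = character(), genomic_start = integer(),
      stringsAsFactors = FALSE)))
  }
  win_len <- upstream + downstream
  for (j in seq_len(nrow(assignments))) {
    lnc <- assignments$lncrna[j]
    tf <- assignments$tf[j]
    pwm <- pwms[[tf]]
    L <- pwm$length
    if (L > win_len) rc_stop("motif '%s' longer than the promoter window", tf)
    consensus <- attr(pwm, "consensus")
    row <- genes[genes$name == lnc, ]
    if (nrow(row) != 1) rc_stop("unknown lncRNA '%s' in assignments", lnc)
    win <- promoter_window(row, upstream, downstream)
    chrom <- row$chrom
    seq <- genome[[chrom]]
    for (s in seq_len(sites_per_lncrna)) {
      offset <- 300L + (s - 1L) * (L + 20L)
      if (offset + L > win_len) {
        rc_stop("promoter of '%s' too crowded for %d site(s) of length %d",
                lnc, sites_per_lncrna, L)
      }
      site_strand <- if ((j + s) %% 2L == 0L) "-" else "+"
      word <- if (site_strand == "+") consensus else rc_revcomp(consensus)
      if (row$strand == "+") {
        gstart <- win[["start"]] + offset
        ins <- word
      } else {
        gstart <- win[["end"]] - offset - L
        ins <- rc_revcomp(word)
      }
      substr(seq, gstart + 1L, gstart + L) <- ins
      sites[[length(sites) + 1L]] <- data.frame(
        lncrna = lnc, tf = tf, offset = offset, strand = site_strand,
        genomic_start = gstart, stringsAsFactors = FALSE)
    }
    genome[[chrom]] <- seq
  }
  list(genome = genome,
       motif_sites = do.call(rbind, sites))
}

# Resample background bases wherever an lncRNA promoter scores a motif hit
# for a (TF, lncRNA) pair that was not planted. Keeps the emitted truth
# complete — every significant match in the study maps to a recorded site or
# pair — which planted-signal benchmarks require; false-positive behaviour is
# exercised on independent random sequences instead. Planted site bases are
# never touched (consensi are mutually dissimilar, so an unplanned hit can
# never lie wholly inside a planted site).
scrub_unplanned_hits <- function(genome, genes, pwms, motif_sites,
                                 planted_pairs, upstream, downstream,
                                 pvalue, granularity, max_iter = 25) {
  lnc <- genes[genes$class %in% c("lncRNA", "antisense"), , drop = FALSE]
  if (nrow(lnc) == 0 || length(pwms) == 0) return(genome)
  for (iter in seq_len(max_iter)) {
    promoters <- extract_promoters(lnc, genome, upstream, downstream)
    hits <- scan_promoters(pwms, promoters, pvalue = pvalue,
                           granularity = granularity)
    bad <- hits[!(paste(hits$tf, hits$sequence_id) %in% planted_pairs), ,
                drop = FALSE]
    if (nrow(bad) == 0) return(genome)
    for (i in seq_len(nrow(bad))) {
      lrow <- lnc[lnc$name == bad$sequence_id[i], ]
      win <- promoter_window(lrow, upstream, downstream)
      L <- pwms[[bad$tf[i]]]$length
      gpos <- if (lrow$strand == "+") {
        win[["start"]] + bad$offset[i] + 0:(L - 1L)
      } else {
        win[["end"]] - bad$offset[i] - L + 0:(L - 1L)
      }
      ms <- motif_sites[motif_sites$lncrna == bad$sequence_id[i], ,
                        drop = FALSE]
      protected <- unlist(lapply(seq_len(nrow(ms)), function(j) {
        ms$genomic_start[j] + 0:(pwms[[ms$tf[j]]]$length - 1L)
      }))
      gpos <- setdiff(gpos, protected)
      if (length(gpos) == 0) next
      seq <- genome[[lrow$chrom]]
      for (gp in gpos) {
        substr(seq, gp + 1L, gp + 1L) <- sample(DNA_BASES, 1)
      }
      genome[[lrow$chrom]] <- seq
    }
  }
  rc_stop("could not scrub unplanned motif hits after %d iterations", max_iter)
}

#' Planted edges active in a condition
#'
#' Non-distractor planted edges with positive coupling; in ASD, broken edges
#' are excluded (their beta is zeroed).
#' @param truth an `rc_sim_truth`.
#' @param condition "normal" or "ASD".
#' @return edge data.frame slice.
#' @export
truth_active_edges <- function(truth, condition) {
  e <- truth$edges
  keep <- !e$distractor & e$beta > 0
  if (condition == "ASD") keep <- keep & !e$broken
  out <- e[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate expression counts for every (cell type, condition) group
#'
#' Implements the latent-activity model described at the top of this file.
#' Root regulators draw fresh activities per cell type (the three stages are
#' distinct transcriptome states); planted DE genes receive their log2FC
#' offset only in ASD NPC/neuron samples, reproducing the stage signature of
#' few early DEGs and many later ones.
#'
#' @param design an `rc_sim_design`.
#' @param structure tables from [sim_structure()] (genes + edges).
#' @param baselines named vector of per-gene baseline mean counts.
#' @param broken character key set of broken edges ("regulator->target").
#' @return list: `counts` (matrix genes x all samples), `sheet` (sample
#'   sheet data.frame).
#' @export
simulate_expression <- function(design, structure, baselines, broken) {
  genes <- structure$genes
  edges <- structure$edges
  gid <- genes$id
  counts_blocks <- list()
  sheet_rows <- list()
  for (ct in names(design$samples)) {
    for (cond in c("normal", "ASD")) {
      nsmp <- design$samples[[ct]][[cond]]
      ids <- sprintf("%s_%s_%02d", ct, cond, seq_len(nsmp))
      latent <- matrix(0, nrow(genes), nsmp, dimnames = list(gid, ids))
      roots <- genes$role %in% c("tf", "distractor_reg")
      latent[roots, ] <- stats::rnorm(sum(roots) * nsmp)
      # distractor targets get independent variation of their own: with a
      # beta of zero their expression must not be dominated by the shared
      # library-size factor, or null correlations would inherit it
      standalone <- genes$role %in% c("de", "standalone", "distractor_target")
      latent[standalone, ] <- stats::rnorm(sum(standalone) * nsmp,
                                           sd = design$standalone_latent_sd)
      for (l in sort(unique(edges$layer))) {
        el <- edges[edges$layer == l & !edges$distractor, , drop = FALSE]
        for (i in seq_len(nrow(el))) {
          beta <- el$beta[i]
          key <- paste0(el$regulator[i], "->", el$target[i])
          if (cond == "ASD" && key %in% broken) beta <- 0
          latent[el$target[i], ] <- beta * latent[el$regulator[i], ] +
            stats::rnorm(nsmp, sd = design$latent_noise_sd)
        }
      }
      if (cond == "ASD" && ct %in% c("NPC", "neuron")) {
        de <- genes$role == "de"
        latent[de, ] <- latent[de, ] + design$planted_lfc
      }
      mu <- baselines[gid] * 2^latent
      if (any(!is.finite(mu))) {
        bad <- gid[which(rowSums(!is.finite(mu)) > 0)[1]]
        rc_stop("simulate_expression: non-finite mean for gene '%s'", bad)
      }
      cnt <- matrix(stats::rnbinom(length(mu), mu = mu,
                                   size = 1 / design$nb_dispersion),
                    nrow(genes), nsmp, dimnames = list(gid, ids))
      counts_blocks[[paste(ct, cond, sep = "_")]] <- cnt
      sheet_rows[[paste(ct, cond, sep = "_")]] <- data.frame(
        sample_id = ids, cell_type = ct, condition = cond,
        stringsAsFactors = FALSE)
    }
  }
  list(counts = do.call(cbind, counts_blocks),
       sheet = do.call(rbind, c(sheet_rows, make.row.names = FALSE)))
}

#' Generate the complete synthetic study
#'
#' Runs the full generator under a single seed: structure, genome +
#' annotations, motifs, planted motif sites, reference network with broken
#' edges selected, baselines, expression counts and the pathway collection.
#' Identical (design, seed) pairs produce identical studies.
#'
#' @param design an `rc_sim_design` (defaults: [sim_design()]).
#' @param seed integer seed.
#' @param config pipeline configuration (promoter window, background,
#'   pseudocount are taken from here).
#' @return list of class `rc_sim_study` with components genome, genes,
#'   enhancers, motifs, network (reference TSV table), counts, sheet,
#'   gene_class, pathways and `truth` (class `rc_sim_truth`).
#' @export
simulate_study <- function(design = sim_design(), seed = 1,
                           config = default_config()) {
  ann <- generate_genome_and_annotation(design, seed = seed,
                                        background = config$background)
  st <- ann$structure
  motifs <- generate_motifs(design, background = config$background,
                            pseudocount = config$pwm_pseudocount)
  assignments <- data.frame(lncrna = st$lnc_ids, tf = st$lnc_tf,
                            stringsAsFactors = FALSE)
  planted <- plant_motif_sites(ann$genome, ann$genes, assignments, motifs,
                               sites_per_lncrna = design$sites_per_lncrna,
                               upstream = config$promoter_upstream,
                               downstream = config$promoter_downstream)
  planted$genome <- scrub_unplanned_hits(
    planted$genome, ann$genes, motifs, planted$motif_sites,
    paste(assignments$tf, assignments$lncrna),
    upstream = config$promoter_upstream,
    downstream = config$promoter_downstream,
    pvalue = config$motif_pvalue, granularity = config$score_granularity)
  # broken edges: a fixed fraction of the correlation-gated planted edges
  gated <- st$edges[!st$edges$distractor &
                      st$edges$edge_type != "lncrna_gene", , drop = FALSE]
  n_break <- round(design$frac_edges_broken_in_asd * nrow(gated))
  bidx <- sample(nrow(gated), n_break)
  broken_keys <- paste0(gated$regulator[bidx], "->", gated$target[bidx])
  st$edges$broken <- paste0(st$edges$regulator, "->", st$edges$target) %in%
    broken_keys

  expressed_roles <- st$genes$role != "unexpressed"
  baselines <- stats::setNames(rep(design$unexpressed_baseline,
                                   nrow(st$genes)), st$genes$id)
  baselines[expressed_roles] <- pmax(
    exp(stats::rnorm(sum(expressed_roles), design$baseline_log_mean,
                     design$baseline_log_sd)),
    design$baseline_min)

  expr <- simulate_expression(design, st, baselines, broken_keys)

  de_ids <- st$genes$id[st$genes$role == "de"]
  de_df <- data.frame(gene = de_ids, log2FC = design$planted_lfc,
                      stringsAsFactors = FALSE)
  empty_de <- de_df[0, , drop = FALSE]
  enh_links <- st$edges[st$edges$edge_type == "lncrna_gene",
                        c("regulator", "target"), drop = FALSE]
  names(enh_links) <- c("lncrna", "target")
  rownames(enh_links) <- NULL

  # pathway collection: one set of planted DE genes, the rest random draws
  pathways <- list(planted_perturbed =
                     de_ids[seq_len(min(30, length(de_ids)))])
  pool <- st$genes$id[st$genes$role %in% c("cascade", "de", "standalone",
                                           "distractor_target")]
  for (k in seq_len(max(design$n_pathways - 1, 0))) {
    pathways[[sprintf("background_set_%02d", k)]] <-
      sort(sample(pool, min(design$pathway_size, length(pool))))
  }

  truth <- structure(list(
    de_genes = list(iPSC = empty_de, NPC = de_df, neuron = de_df),
    motif_sites = planted$motif_sites,
    edges = st$edges,
    broken_edges = st$edges[st$edges$broken,
                            c("regulator", "target", "edge_type"),
                            drop = FALSE],
    enhancer_links = enh_links
  ), class = "rc_sim_truth")
  rownames(truth$broken_edges) <- NULL

  network <- st$edges[st$edges$in_reference,
                      c("regulator", "target"), drop = FALSE]
  network$weight <- 1
  rownames(network) <- NULL

  gene_class <- stats::setNames(st$genes$class, st$genes$id)
  rc_log("simulate_study: %d genes, %d samples, %d reference edges (%d broken in ASD)",
         nrow(st$genes), ncol(expr$counts), nrow(network), n_break)
  structure(list(design = design, genome = planted$genome, genes = ann$genes,
                 enhancers = ann$enhancers, motifs = motifs,
                 network = network, counts = expr$counts, sheet = expr$sheet,
                 gene_class = gene_class, pathways = pathways, truth = truth),
            class = "rc_sim_study")
}

#' Write a synthetic study to disk
#'
#' Emits genome.fa, genes.bed, enhancers.bed, network.tsv, motifs.jaspar,
#' counts.tsv, samples.tsv, pathways.gmt and truth.json under `dir`.
#' @param study an `rc_sim_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(study$genome, file.path(dir, "genome.fa"))
  write_bed(study$genes, file.path(dir, "genes.bed"))
  write_bed(study$enhancers, file.path(dir, "enhancers.bed"))
  rc_write_tsv(study$network, file.path(dir, "network.tsv"))
  write_jaspar(study$motifs, file.path(dir, "motifs.jaspar"))
  write_counts(study$counts, file.path(dir, "counts.tsv"))
  rc_write_tsv(study$sheet, file.path(dir, "samples.tsv"))
  rc_write_tsv(data.frame(gene = names(study$gene_class),
                          class = unname(study$gene_class),
                          stringsAsFactors = FALSE),
               file.path(dir, "gene_classes.tsv"))
  write_gmt(study$pathways, file.path(dir, "pathways.gmt"))
  write_truth(study$truth, file.path(dir, "truth.json"))
  invisible(dir)
}

#' Truth JSON round trip
#' @param truth an `rc_sim_truth`.
#' @param path JSON path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = FALSE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

fix_df <- function(x, template) {
  # empty data.frames serialize as {} / []; restore typed columns
  if (is.null(x) || length(x) == 0 ||
      (is.list(x) && all(lengths(x) == 0))) return(template)
  df <- as.data.frame(x, stringsAsFactors = FALSE)
  for (k in names(template)) {
    storage.mode(df[[k]]) <- storage.mode(template[[k]])
  }
  df[, names(template), drop = FALSE]
}

#' @rdname write_truth
#' @return `read_truth` returns the `rc_sim_truth` object.
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) rc_stop("truth file not found: %s", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  de_t <- data.frame(gene = character(), log2FC = numeric(),
                     stringsAsFactors = FALSE)
  edges_t <- data.frame(regulator = character(), target = character(),
                        edge_type = character(), layer = integer(),
                        beta = numeric(), distractor = logical(),
                        in_reference = logical(), broken = logical(),
                        stringsAsFactors = FALSE)
  sites_t <- data.frame(lncrna = character(), tf = character(),
                        offset = integer(), strand = character(),
                        genomic_start = integer(), stringsAsFactors = FALSE)
  broken_t <- edges_t[, c("regulator", "target", "edge_type")]
  links_t <- data.frame(lncrna = character(), target = character(),
                        stringsAsFactors = FALSE)
  structure(list(
    de_genes = lapply(raw$de_genes, fix_df, template = de_t),
    motif_sites = fix_df(raw$motif_sites, sites_t),
    edges = fix_df(raw$edges, edges_t),
    broken_edges = fix_df(raw$broken_edges, broken_t),
    enhancer_links = fix_df(raw$enhancer_links, links_t)
  ), class = "rc_sim_truth")
}
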