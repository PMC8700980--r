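# Motif module: JASPAR PFM parsing, log-odds PWM construction, exact
# p-value -> score-threshold computation by dynamic programming over a
# discretized score distribution, strand-aware promoter extraction, and
# promoter scanning.

#' Build a PWM record from a count matrix
#'
#' The position frequency matrix (rows A,C,G,T) is converted to a log-odds
#' matrix with a total pseudocount split in proportion to the background:
#' `log_odds[b,j] = log2((counts[b,j] + pc_b) / (colsum_j + pc_total)) -
#' log2(background_b)`.
#'
#' @param tf_name motif / transcription factor name.
#' @param counts 4 x L non-negative matrix, rows A,C,G,T.
#' @param background base probabilities (A,C,G,T), summing to 1.
#' @param pseudocount total pseudocount per column (default 0.8).
#' @return an `rc_pwm` object with elements `tf_name`, `counts`, `log_odds`,
#'   `length`, `background`, `pseudocount`.
#' @export
pwm_record <- function(tf_name, counts, background = rep(0.25, 4),
                       pseudocount = 0.8) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) rc_stop("PWM '%s': counts must have 4 rows", tf_name)
  if (ncol(counts) < 1) rc_stop("PWM '%s': zero-length motif", tf_name)
  if (any(counts < 0)) rc_stop("PWM '%s': negative count", tf_name)
  cs <- colSums(counts)
  if (any(cs <= 0)) rc_stop("PWM '%s': column with zero total count", tf_name)
  rownames(counts) <- DNA_BASES
  pc <- pseudocount * background
  lo <- log2(sweep(counts + pc, 2, cs + pseudocount, "/")) -
    log2(background)
  structure(list(tf_name = tf_name, counts = counts, log_odds = lo,
                 length = ncol(counts), background = background,
                 pseudocount = pseudocount),
            class = "rc_pwm")
}

#' @export
print.rc_pwm <- function(x, ...) {
  cat(sprintf("<rc_pwm> %s, length %d\n", x$tf_name, x$length))
  invisible(x)
}

#' Parse motifs in JASPAR PFM text format
#'
#' Format: a `>ID NAME` header followed by four bracketed count rows labelled
#' A/C/G/T (any order; rows are normalized to A,C,G,T).
#'
#' @param path JASPAR text file.
#' @param background,pseudocount passed to [pwm_record()].
#' @return list of `rc_pwm` objects.
#' @export
parse_jaspar <- function(path, background = rep(0.25, 4), pseudocount = 0.8) {
  if (!file.exists(path)) rc_stop("JASPAR file not found: %s", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (length(heads) == 0) rc_stop("no motif header ('>') in %s", path)
  bounds <- c(heads, length(lines) + 1L)
  out <- list()
  for (i in seq_along(heads)) {
    header <- sub("^>\\s*", "", lines[heads[i]])
    parts <- strsplit(header, "\\s+")[[1]]
    name <- if (length(parts) >= 2) parts[2] else parts[1]
    body <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    if (length(body) != 4) {
      rc_stop("motif '%s': expected 4 count rows, found %d", name, length(body))
    }
    rows <- list()
    for (ln in body) {
      mt <- regmatches(ln, regexec("^([ACGTacgt])\\s*\\[?([^]]*)]?", ln))[[1]]
      if (length(mt) < 3) rc_stop("motif '%s': unparseable row '%s'", name, ln)
      base <- toupper(mt[2])
      vals <- suppressWarnings(as.numeric(strsplit(trimws(mt[3]), "\\s+")[[1]]))
      if (any(is.na(vals))) rc_stop("motif '%s': non-numeric count in row %s",
                                    name, base)
      if (any(vals < 0)) rc_stop("motif '%s': negative count in row %s",
                                 name, base)
      rows[[base]] <- vals
    }
    if (!setequal(names(rows), DNA_BASES)) {
      rc_stop("motif '%s': rows must cover A,C,G,T (got %s)", name,
              paste(sort(names(rows)), collapse = ","))
    }
    lens <- vapply(rows, length, 0L)
    if (length(unique(lens)) != 1) {
      rc_stop("motif '%s': row length mismatch (%s)", name,
              paste(lens, collapse = ","))
    }
    counts <- do.call(rbind, rows[DNA_BASES])
    out[[name]] <- pwm_record(name, counts, background = background,
                              pseudocount = pseudocount)
  }
  rc_log("parse_jaspar: %d motif(s) from %s", length(out), path)
  out
}

#' Write motifs in JASPAR PFM text format
#' @param pwms list of `rc_pwm` objects.
#' @param path output path.
#' @export
write_jaspar <- function(pwms, path) {
  lines <- unlist(lapply(pwms, function(p) {
    c(sprintf(">%s %s", p$tf_name, p$tf_name),
      vapply(DNA_BASES, function(b) {
        sprintf("%s  [ %s ]", b,
                paste(format(p$counts[b, ], trim = TRUE), collapse = " "))
      }, character(1)))
  }))
  writeLines(lines, path)
  invisible(path)
}

# integerized log-odds matrix: floor(score / granularity); summing these per
# window gives the discretized score used by both the DP and the scanner, so
# the p-value guarantee is exact for the scores actually gated on
pwm_int_matrix <- function(pwm, granularity = 1e-3) {
  m <- floor(pwm$log_odds / granularity)
  storage.mode(m) <- "integer"
  m
}

# reverse-complement PWM: reversed columns, complemented rows
pwm_revcomp <- function(pwm) {
  counts_rc <- pwm$counts[4:1, rev(seq_len(pwm$length)), drop = FALSE]
  pwm_record(pwm$tf_name, counts_rc, background = pwm$background,
             pseudocount = pwm$pseudocount)
}

# exact distribution of the discretized PWM score over i.i.d. background
# sequences of length L: returns integer support (ascending) and probabilities
pwm_score_distribution <- function(int_matrix, background) {
  L <- ncol(int_matrix)
  mins <- apply(int_matrix, 2, min)
  maxs <- apply(int_matrix, 2, max)
  width <- sum(maxs - mins) + 1L
  dist <- numeric(width)   # index 1 == score sum(mins)
  dist[1] <- 1
  filled <- 1L
  for (j in seq_len(L)) {
    shifted <- int_matrix[, j] - mins[j]
    newlen <- filled + (maxs[j] - mins[j])
    nd <- numeric(newlen)
    for (b in 1:4) {
      k <- shifted[b]
      idx <- (1L + k):(filled + k)
      nd[idx] <- nd[idx] + dist[seq_len(filled)] * background[b]
    }
    dist <- nd
    filled <- newlen
  }
  # restrict to achievable scores: zero-probability grid points would
  # otherwise be eligible thresholds below the attainable spectrum
  support <- sum(mins) + 0:(filled - 1L)
  keep <- dist > 0
  list(support = support[keep], prob = dist[keep])
}

#' Score threshold for a target match p-value
#'
#' Computes the exact distribution of discretized PWM scores over i.i.d.
#' background sequences of motif length (dynamic programming: per-column score
#' distributions convolved at the stated granularity) and returns the smallest
#' discretized score `s` with `P(score >= s) <= pvalue`. Discretization uses
#' conservative (floor) rounding, so the realized false-positive probability
#' never exceeds the requested p-value. If the requested p-value is smaller
#' than the probability of the single best word, the threshold is the maximum
#' score and a warning is logged.
#'
#' @param pwm an `rc_pwm` object.
#' @param pvalue target tail probability in (0, 1].
#' @param granularity score bin width in log-odds units (default 1e-3).
#' @return list with `threshold` (score units), `threshold_int` (discretized),
#'   `tail_mass` (realized `P(score >= threshold)`), `max_score_int`, and the
#'   full discretized distribution (`support`, `prob`, `tail`).
#' @export
score_threshold_from_pvalue <- function(pwm, pvalue, granularity = 1e-3) {
  if (!is.numeric(pvalue) || pvalue <= 0 || pvalue > 1) {
    rc_stop("pvalue must lie in (0, 1], got %g", pvalue)
  }
  im <- pwm_int_matrix(pwm, granularity)
  d <- pwm_score_distribution(im, pwm$background)
  tail <- rev(cumsum(rev(d$prob)))
  ok <- which(tail <= pvalue)
  if (length(ok) == 0) {
    rc_warn("PWM '%s': pvalue %g below the best word's probability %g; using max score",
            pwm$tf_name, pvalue, tail[length(tail)])
    idx <- length(d$support)
  } else {
    idx <- min(ok)
  }
  list(threshold = d$support[idx] * granularity,
       threshold_int = d$support[idx],
       tail_mass = tail[idx],
       max_score_int = d$support[length(d$support)],
       support = d$support, prob = d$prob, tail = tail)
}

#' Extract strand-aware promoter sequences
#'
#' The promoter window covers `upstream` bp 5' and `downstream` bp 3' of the
#' TSS (the strand-aware 5' end of the gene interval; BED coordinates,
#' 0-based half-open). Plus strand: `[TSS - upstream, TSS + downstream)` of
#' the forward sequence. Minus strand: the reverse complement of the
#' strand-reflected window `[TSS - downstream + 1, TSS + upstream + 1)`.
#' Windows running off the chromosome are clipped with a warning.
#'
#' @param genes BED data.frame (see [read_bed()]).
#' @param genome named character vector of chromosome sequences.
#' @param upstream,downstream window extents in bp.
#' @return named character vector of promoter sequences (names = gene names),
#'   with a `coords` attribute data.frame (chrom, start, end, strand).
#' @export
extract_promoters <- function(genes, genome, upstream = 1000,
                              downstream = 200) {
  seqs <- character(nrow(genes))
  coords <- data.frame(chrom = genes$chrom, start = NA_integer_,
                       end = NA_integer_, strand = genes$strand,
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(genes))) {
    chrom <- genes$chrom[i]
    if (!chrom %in% names(genome)) {
      rc_stop("unknown chromosome '%s' for gene '%s'", chrom, genes$name[i])
    }
    clen <- nchar(genome[[chrom]])
    strand <- genes$strand[i]
    if (strand == "+") {
      tss <- genes$start[i]
      s <- tss - upstream
      e <- tss + downstream
    } else {
      tss <- genes$end[i] - 1L
      s <- tss - downstream + 1L
      e <- tss + upstream + 1L
    }
    cs <- max(0L, s)
    ce <- min(clen, e)
    if (cs != s || ce != e) {
      rc_warn("promoter of '%s' clipped to [%d, %d)", genes$name[i], cs, ce)
    }
    if (cs >= ce) rc_stop("empty promoter window for gene '%s'", genes$name[i])
    sub <- substring(genome[[chrom]], cs + 1L, ce)
    if (strand == "-") sub <- rc_revcomp(sub)
    seqs[i] <- sub
    coords$start[i] <- cs
    coords$end[i] <- ce
  }
  names(seqs) <- genes$name
  attr(seqs, "coords") <- coords
  seqs
}

# score every window of `codes` (integer 1..4) with an integerized PWM;
# returns integer vector of window scores (length nchar - L + 1)
score_windows_int <- function(codes, int_matrix) {
  L <- ncol(int_matrix)
  npos <- length(codes) - L + 1L
  if (npos < 1L) return(integer(0))
  s <- integer(npos)
  for (j in seq_len(L)) {
    s <- s + int_matrix[codes[j:(j + npos - 1L)], j]
  }
  s
}

seq_to_codes <- function(seq) {
  match(strsplit(toupper(seq), "")[[1]], DNA_BASES)
}

#' Scan promoters for significant motif matches
#'
#' Every PWM is slid over every promoter position on both strands (set
#' `both_strands = FALSE` to restrict to the forward strand); windows whose
#' discretized score reaches the p-value threshold of
#' [score_threshold_from_pvalue()] are emitted. The distinct (TF, sequence)
#' pairs with at least one hit define the TF -> lncRNA edge set.
#'
#' @param pwms list of `rc_pwm` objects.
#' @param promoters named character vector of sequences.
#' @param pvalue per-position match p-value (default 5e-5).
#' @param granularity score bin width (default 1e-3).
#' @param both_strands scan the reverse complement as well (default TRUE).
#' @return data.frame with columns tf, sequence_id, offset (0-based on the
#'   promoter's forward coordinates), strand, score (log-odds units),
#'   pvalue_bound (realized `P(score >= observed)` under the background).
#' @export
scan_promoters <- function(pwms, promoters, pvalue = 5e-5,
                           granularity = 1e-3, both_strands = TRUE) {
  empty <- data.frame(tf = character(), sequence_id = character(),
                      offset = integer(), strand = character(),
                      score = numeric(), pvalue_bound = numeric(),
                      stringsAsFactors = FALSE)
  if (length(pwms) == 0 || length(promoters) == 0) return(empty)
  hits <- list()
  code_cache <- lapply(promoters, seq_to_codes)
  for (pwm in pwms) {
    orientations <- list(list(strand = "+", pwm = pwm))
    if (both_strands) {
      orientations <- c(orientations, list(list(strand = "-",
                                                pwm = pwm_revcomp(pwm))))
    }
    for (ori in orientations) {
      thr <- score_threshold_from_pvalue(ori$pwm, pvalue, granularity)
      im <- pwm_int_matrix(ori$pwm, granularity)
      lo <- ori$pwm$log_odds
      for (sid in names(promoters)) {
        codes <- code_cache[[sid]]
        if (length(codes) < ori$pwm$length) {
          rc_log("scan_promoters: '%s' shorter than motif '%s'; skipped",
                 sid, pwm$tf_name)
          next
        }
        sc <- score_windows_int(codes, im)
        pass <- which(sc >= thr$threshold_int)
        if (length(pass) == 0) next
        raw <- vapply(pass, function(off) {
          sum(lo[cbind(codes[off:(off + ori$pwm$length - 1L)],
                       seq_len(ori$pwm$length))])
        }, 0.0)
        pb <- vapply(sc[pass], function(s) {
          thr$tail[match(s, thr$support)]
        }, 0.0)
        hits[[length(hits) + 1L]] <- data.frame(
          tf = pwm$tf_name, sequence_id = sid, offset = pass - 1L,
          strand = ori$strand, score = raw, pvalue_bound = pb,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(hits) == 0) empty else do.call(rbind, hits)
  out <- out[order(out$tf, out$sequence_id, out$offset, out$strand), ,
             drop = FALSE]
  rownames(out) <- NULL
  rc_log("scan_promoters: %d hit(s), %d motif(s) x %d promoter(s) at p = %g",
         nrow(out), length(pwms), length(promoters), pvalue)
  out
}

#' Collapse motif hits to TF -> lncRNA regulatory edges
#' @param hits data.frame from [scan_promoters()].
#' @return edge data.frame (regulator, target, edge_type, evidence).
#' @export
motif_hits_to_edges <- function(hits) {
  if (nrow(hits) == 0) {
    return(data.frame(regulator = character(), target = character(),
                      edge_type = character(), evidence = character(),
                      stringsAsFactors = FALSE))
  }
  pairs <- unique(hits[, c("tf", "sequence_id")])
  out <- data.frame(regulator = pairs$tf, target = pairs$sequence_id,
                    edge_type = "tf_lncrna", evidence = "motif",
                    stringsAsFactors = FALSE)
  out <- out[order(out$regulator, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}
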