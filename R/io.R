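# Readers/writers for the standard formats the pipeline touches. All genomic
# coordinates are 0-based half-open (BED convention), declared once here and
# enforced everywhere.

#' Count matrix container
#'
#' Light container for gene-level read counts: an integer matrix (genes x
#' samples) plus an optional gene-class map (`PCG`, `lncRNA`, `antisense`).
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids).
#' @param gene_class optional named character vector mapping gene id to class.
#' @return an object of class `rc_counts`.
#' @export
count_matrix <- function(counts, gene_class = NULL) {
  if (!is.matrix(counts)) rc_stop("counts must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    rc_stop("counts must carry gene ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(rownames(counts))) {
    rc_stop("duplicate gene ids: %s",
            paste(unique(rownames(counts)[duplicated(rownames(counts))]),
                  collapse = ", "))
  }
  if (any(counts < 0)) rc_stop("counts must be non-negative")
  if (!is.null(gene_class)) {
    gene_class <- gene_class[rownames(counts)]
    names(gene_class) <- rownames(counts)
  }
  structure(list(counts = counts, gene_class = gene_class),
            class = "rc_counts")
}

#' @export
print.rc_counts <- function(x, ...) {
  cat(sprintf("<rc_counts> %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Read a gene-level count matrix
#'
#' TSV with a `gene` first column and one column per sample. Columns are
#' normalized to the sample-sheet order; non-integer cells and duplicate gene
#' ids are rejected.
#'
#' @param path TSV path.
#' @param sheet sample sheet (see [read_sample_sheet()]); column order of the
#'   result follows `sheet$sample_id`.
#' @param gene_class optional named character vector of gene classes.
#' @return an `rc_counts` object.
#' @export
read_counts <- function(path, sheet, gene_class = NULL) {
  raw <- rc_read_tsv(path, colClasses = "character")
  if (ncol(raw) < 2) rc_stop("count file '%s' has no sample columns", path)
  genes <- raw[[1]]
  if (anyDuplicated(genes)) {
    rc_stop("count file '%s': duplicate gene id(s): %s", path,
            paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  have <- names(raw)[-1]
  missing <- setdiff(sheet$sample_id, have)
  extra <- setdiff(have, sheet$sample_id)
  if (length(missing) > 0 || length(extra) > 0) {
    rc_stop(paste0("count file '%s' columns do not match the sample sheet",
                   "; missing: {%s}; unexpected: {%s}"),
            path, paste(missing, collapse = ","), paste(extra, collapse = ","))
  }
  mat <- matrix(NA_integer_, nrow = length(genes), ncol = nrow(sheet),
                dimnames = list(genes, sheet$sample_id))
  for (s in sheet$sample_id) {
    col <- raw[[s]]
    ok <- grepl("^[0-9]+$", col)
    if (!all(ok)) {
      i <- which(!ok)[1]
      rc_stop("count file '%s': non-integer value '%s' at gene '%s', sample '%s'",
              path, col[i], genes[i], s)
    }
    mat[, s] <- as.integer(col)
  }
  count_matrix(mat, gene_class = gene_class)
}

#' Write a count matrix as TSV (gene column first)
#' @param cm an `rc_counts` object or plain matrix.
#' @param path output path.
#' @export
write_counts <- function(cm, path) {
  m <- if (inherits(cm, "rc_counts")) cm$counts else cm
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  rc_write_tsv(df, path)
}

# ---- BED6(+class) ----------------------------------------------------------

#' Read a BED6 annotation, optionally with a 7th gene-class column
#'
#' Columns: chrom, start, end, name, score, strand (+ class). Coordinates are
#' 0-based half-open.
#' @param path BED path.
#' @return data.frame with columns chrom, start, end, name, score, strand and,
#'   when present, class.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) rc_stop("BED file not found: %s", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  cols <- c("chrom", "start", "end", "name", "score", "strand", "class")
  if (ncol(df) < 6) rc_stop("BED file '%s' must have >= 6 columns", path)
  names(df) <- cols[seq_len(min(ncol(df), 7))]
  if (any(df$start < 0) || any(df$start >= df$end)) {
    rc_stop("BED file '%s': intervals must satisfy 0 <= start < end", path)
  }
  df
}

#' @rdname read_bed
#' @param bed a BED data.frame as returned by [read_bed()].
#' @export
write_bed <- function(bed, path) {
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}

# ---- GMT -------------------------------------------------------------------

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated member genes.
#' Duplicate members within a set are dropped.
#' @param path GMT path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) rc_stop("GMT file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) rc_stop("GMT line with fewer than 3 fields: '%s'", ln)
    sets[[parts[1]]] <- unique(parts[-(1:2)])
  }
  sets
}

#' @rdname read_gmt
#' @param sets named list of gene id vectors.
#' @param descriptions optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# ---- FASTA -----------------------------------------------------------------

#' Read/write genomes as FASTA
#'
#' Thin wrappers over Biostrings returning plain named character vectors, the
#' representation the simulator and promoter extraction work with.
#' @param path FASTA path.
#' @return named character vector of chromosome sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) rc_stop("FASTA file not found: %s", path)
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(ss), names(ss))
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 80L)
  invisible(path)
}

# ---- Cascade JSON ----------------------------------------------------------

cascade_to_jsonable <- function(cs) {
  list(root = cs$root,
       cell_type = cs$cell_type,
       condition = cs$condition,
       nodes = lapply(seq_len(nrow(cs$nodes)), function(i) {
         list(id = cs$nodes$id[i], layer = cs$nodes$layer[i],
              type = cs$nodes$type[i])
       }),
       edges = lapply(seq_len(nrow(cs$edges)), function(i) {
         list(from = cs$edges$parent[i], to = cs$edges$child[i],
              edge_type = cs$edges$edge_type[i], r = cs$edges$r[i])
       }))
}

jsonable_to_cascade <- function(x) {
  nodes <- if (length(x$nodes) == 0) {
    data.frame(id = character(), layer = integer(), type = character(),
               stringsAsFactors = FALSE)
  } else {
    data.frame(id = vapply(x$nodes, `[[`, "", "id"),
               layer = vapply(x$nodes, function(n) as.integer(n$layer), 0L),
               type = vapply(x$nodes, function(n) n$type %||% "PCG", ""),
               stringsAsFactors = FALSE)
  }
  edges <- if (length(x$edges) == 0) {
    data.frame(parent = character(), child = character(),
               edge_type = character(), r = numeric(), stringsAsFactors = FALSE)
  } else {
    data.frame(parent = vapply(x$edges, `[[`, "", "from"),
               child = vapply(x$edges, `[[`, "", "to"),
               edge_type = vapply(x$edges, `[[`, "", "edge_type"),
               r = vapply(x$edges, function(e) {
                 if (is.null(e$r)) NA_real_ else as.numeric(e$r)
               }, 0.0),
               stringsAsFactors = FALSE)
  }
  new_cascade(root = x$root, cell_type = x$cell_type, condition = x$condition,
              nodes = nodes, edges = edges)
}

#' Cascade JSON round trip
#'
#' Cascades are serialized as
#' `{root, cell_type, condition, nodes:[{id, layer, type}], edges:[{from, to,
#' edge_type, r}]}`. Reading validates every cascade's tree invariants against
#' `max_layers`; the round trip is lossless.
#'
#' @param cascades a list of `rc_cascade` objects.
#' @param path JSON path.
#' @export
write_cascade_json <- function(cascades, path) {
  payload <- lapply(cascades, cascade_to_jsonable)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_cascade_json
#' @param max_layers maximum allowed cascade depth for validation.
#' @return `read_cascade_json` returns a list of `rc_cascade` objects.
#' @export
read_cascade_json <- function(path, max_layers = 3L) {
  if (!file.exists(path)) rc_stop("cascade file not found: %s", path)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(raw, jsonable_to_cascade)
  for (cs in out) validate_cascade(cs, max_layers = max_layers)
  out
}
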