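# Pipeline configuration: every numeric threshold used by the analysis lives
# here, so a run is fully described by (config, inputs, seed).

#' Default pipeline configuration
#'
#' Returns the full set of analysis parameters with their default values:
#' \describe{
#'   \item{min_median_count}{reads; genes with median count below this across
#'     all samples are treated as unexpressed (default 20).}
#'   \item{lfc_threshold}{log2 units; differential expression requires
#'     `|log2FC|` strictly above this (default 1).}
#'   \item{fdr_threshold}{BH-adjusted p-value cutoff (default 0.05).}
#'   \item{pair_corr_cutoff}{Pearson `|r|` for calling a regulator--target pair
#'     coordinately expressed (default 0.75).}
#'   \item{cascade_corr_cutoff}{stricter Pearson gate, exceeded strictly, for
#'     attaching an edge during cascade growth (default 0.8).}
#'   \item{max_layers}{maximum cascade depth below the root TF (default 3).}
#'   \item{motif_pvalue}{per-position match p-value for motif scanning
#'     (default 5e-5).}
#'   \item{promoter_upstream, promoter_downstream}{promoter window relative to
#'     the TSS, strand-aware (defaults 1000 and 200 bp).}
#'   \item{pwm_pseudocount}{total pseudocount added per PWM column, split in
#'     proportion to the background (default 0.8).}
#'   \item{background}{base probabilities A,C,G,T (default uniform).}
#'   \item{score_granularity}{discretization bin width, in log-odds units, for
#'     the exact PWM score distribution (default 1e-3).}
#'   \item{seed}{integer seed; the single source of randomness.}
#' }
#' @return a named list of class `rc_config`.
#' @export
default_config <- function() {
  structure(list(
    min_median_count    = 20,
    lfc_threshold       = 1,
    fdr_threshold       = 0.05,
    pair_corr_cutoff    = 0.75,
    cascade_corr_cutoff = 0.8,
    max_layers          = 3L,
    motif_pvalue        = 5e-5,
    promoter_upstream   = 1000L,
    promoter_downstream = 200L,
    pwm_pseudocount     = 0.8,
    background          = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
    score_granularity   = 1e-3,
    seed                = 1L
  ), class = "rc_config")
}

rc_validate_config <- function(cfg) {
  num_pos <- c("min_median_count", "lfc_threshold", "fdr_threshold",
               "pair_corr_cutoff", "cascade_corr_cutoff", "motif_pvalue",
               "promoter_upstream", "promoter_downstream", "pwm_pseudocount",
               "score_granularity")
  for (k in num_pos) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      rc_stop("config key '%s' must be a single positive number, got: %s",
              k, paste(format(v), collapse = ","))
    }
  }
  for (k in c("fdr_threshold", "motif_pvalue")) {
    if (cfg[[k]] >= 1) {
      rc_stop("config key '%s' must lie in (0,1), got %g", k, cfg[[k]])
    }
  }
  if (!is.numeric(cfg$max_layers) || length(cfg$max_layers) != 1 ||
      cfg$max_layers < 1 || cfg$max_layers != round(cfg$max_layers)) {
    rc_stop("config key 'max_layers' must be an integer >= 1")
  }
  bg <- cfg$background
  if (!is.numeric(bg) || length(bg) != 4 || any(bg <= 0)) {
    rc_stop("config key 'background' must be 4 positive base probabilities")
  }
  if (abs(sum(bg) - 1) > 1e-12) {
    rc_stop("config key 'background' must sum to 1 (got %.15f)", sum(bg))
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 ||
      cfg$seed != round(cfg$seed)) {
    rc_stop("config key 'seed' must be an integer")
  }
  invisible(cfg)
}

#' Load a pipeline configuration file
#'
#' The file is a flat YAML document of `key: value` pairs; any omitted key
#' takes its default from [default_config()]. Unknown keys produce a warning
#' (forward compatibility), out-of-range values an error. Every effective
#' value is logged.
#'
#' @param path path to the configuration file; an empty file yields the
#'   defaults.
#' @return an `rc_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) rc_stop("config file not found: %s", path)
  user <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) rc_stop("malformed config file '%s': %s", path,
                                conditionMessage(e))
  )
  cfg <- default_config()
  if (!is.null(user)) {
    if (!is.list(user)) rc_stop("config file '%s' is not a key: value document", path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown) > 0) {
      rc_warn("config file '%s': ignoring unknown key(s): %s",
              path, paste(unknown, collapse = ", "))
    }
    for (k in intersect(names(user), names(cfg))) {
      v <- user[[k]]
      if (k == "background") {
        v <- stats::setNames(as.numeric(unlist(v)), DNA_BASES)
      } else if (is.character(v)) {
        # YAML leaves scientific notation like 5e-5 as text; coerce here
        num <- suppressWarnings(as.numeric(v))
        if (is.na(num)) {
          rc_stop("config key '%s': cannot parse value '%s' as a number", k, v)
        }
        v <- num
      }
      if (k %in% c("max_layers", "promoter_upstream", "promoter_downstream",
                   "seed")) {
        v <- as.integer(v)
      }
      cfg[[k]] <- v
    }
  }
  rc_validate_config(cfg)
  for (k in names(cfg)) {
    rc_log("config %s = %s", k, paste(format(cfg[[k]]), collapse = " "))
  }
  cfg
}

#' Read a sample sheet
#'
#' TSV with columns `sample_id`, `cell_type` (iPSC/NPC/neuron) and `condition`
#' (normal/ASD). Sample ids must be unique.
#' @param path TSV path.
#' @return a data.frame with the three validated columns.
#' @export
read_sample_sheet <- function(path) {
  df <- rc_read_tsv(path)
  req <- c("sample_id", "cell_type", "condition")
  if (!all(req %in% names(df))) {
    rc_stop("sample sheet '%s' must have columns %s", path,
            paste(req, collapse = ", "))
  }
  df <- df[, req]
  validate_sample_sheet(df)
}

#' @rdname read_sample_sheet
#' @param sheet a sample-sheet data.frame to validate.
#' @export
validate_sample_sheet <- function(sheet) {
  if (anyDuplicated(sheet$sample_id)) {
    rc_stop("duplicate sample ids: %s",
            paste(unique(sheet$sample_id[duplicated(sheet$sample_id)]),
                  collapse = ", "))
  }
  bad_ct <- setdiff(unique(sheet$cell_type), c("iPSC", "NPC", "neuron"))
  if (length(bad_ct) > 0) {
    rc_stop("unknown cell_type value(s): %s", paste(bad_ct, collapse = ", "))
  }
  bad_cond <- setdiff(unique(sheet$condition), c("normal", "ASD"))
  if (length(bad_cond) > 0) {
    rc_stop("unknown condition value(s): %s", paste(bad_cond, collapse = ", "))
  }
  sheet
}

# sample ids belonging to one (cell type, condition) group
sheet_group <- function(sheet, cell_type, condition) {
  ids <- sheet$sample_id[sheet$cell_type == cell_type &
                           sheet$condition == condition]
  if (length(ids) == 0) {
    rc_stop("no samples in group (%s, %s)", cell_type, condition)
  }
  ids
}
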