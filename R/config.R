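#' Configuration for the sequencing-based stability ranking
#'
#' Thresholds of the ranking pipeline. Defaults follow common plasma-exosome
#' small-RNA practice: samples under two million sequenced reads are
#' unreliable and discarded; a miRNA is considered consistently expressed
#' when its read sum across samples is at least 10 and it is detected
#' (count > 0) in at least 80% of samples.
#'
#' @param min_reads_per_sample sample depth threshold, reads (default 2e6;
#'   samples with *fewer* reads are dropped, the boundary is kept).
#' @param min_read_sum minimum read sum across samples per miRNA (default 10).
#' @param min_detect_frac minimum fraction of samples with count > 0
#'   (default 0.8).
#' @param pseudocount added before the log2 transform (default 1, which maps
#'   zero counts to 0 and keeps all values nonnegative).
#' @param top_n number of top-ranked miRNAs to report (default 20).
#' @param scoring `"mz_diff"` (default; modified-Z of mean abundance minus
#'   modified-Z of CV) or `"inv_cv"` (modified-Z of negative CV only).
#' @param n_candidates number of ranked miRNAs collected by
#'   [select_candidates()] after exclusions (default 3).
#' @return a `ranking_config` list.
#' @export
ranking_config <- function(min_reads_per_sample = 2e6,
                           min_read_sum = 10,
                           min_detect_frac = 0.8,
                           pseudocount = 1,
                           top_n = 20,
                           scoring = c("mz_diff", "inv_cv"),
                           n_candidates = 3) {
  scoring <- match.arg(scoring)
  stopifnot(min_reads_per_sample > 0, min_read_sum > 0,
            min_detect_frac > 0, min_detect_frac <= 1,
            pseudocount > 0, top_n >= 1, n_candidates >= 1)
  structure(list(min_reads_per_sample = min_reads_per_sample,
                 min_read_sum = min_read_sum,
                 min_detect_frac = min_detect_frac,
                 pseudocount = pseudocount,
                 top_n = as.integer(top_n),
                 scoring = scoring,
                 n_candidates = as.integer(n_candidates)),
            class = "ranking_config")
}

#' Configuration for qRT-PCR validation
#'
#' @param alpha significance level for all tests (default 0.05; significance
#'   is `p <= alpha`).
#' @param spikein_target assay name of the exogenous spike-in control
#'   (default `"cel-miR-39"`).
#' @param spikein_window acceptable spike-in Ct window in cycles, inclusive
#'   (default `c(14, 19)`).
#' @param min_replicates minimum number of determined replicates needed to
#'   report a (sample, target) mean Ct (default 2 of 3).
#' @param strict_spikein if TRUE, spike-in QC failures and missing spike-in
#'   measurements are errors; by default they only warn.
#' @return a `validation_config` list.
#' @export
validation_config <- function(alpha = 0.05,
                              spikein_target = "cel-miR-39",
                              spikein_window = c(14, 19),
                              min_replicates = 2,
                              strict_spikein = FALSE) {
  stopifnot(alpha > 0, alpha < 1, length(spikein_window) == 2,
            spikein_window[1] < spikein_window[2], min_replicates >= 1)
  structure(list(alpha = alpha,
                 spikein_target = spikein_target,
                 spikein_window = as.numeric(spikein_window),
                 min_replicates = as.integer(min_replicates),
                 strict_spikein = isTRUE(strict_spikein)),
            class = "validation_config")
}

#' Read pipeline thresholds from a YAML config file
#'
#' The file may contain a `ranking:` and a `validation:` section whose keys
#' match the arguments of [ranking_config()] and [validation_config()];
#' missing keys keep their defaults.
#'
#' @param path YAML file path.
#' @return list with elements `ranking` and `validation`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  rk <- raw$ranking
  vl <- raw$validation
  check_keys <- function(given, fn, section) {
    ok <- names(formals(fn))
    bad <- setdiff(names(given), ok)
    if (length(bad) > 0)
      stop("unknown key(s) in '", section, "' section: ",
           paste(bad, collapse = ", "))
  }
  if (!is.null(rk)) check_keys(rk, ranking_config, "ranking")
  if (!is.null(vl)) check_keys(vl, validation_config, "validation")
  list(ranking = do.call(ranking_config, as.list(rk)),
       validation = do.call(validation_config, as.list(vl)))
}
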