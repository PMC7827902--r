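#' Validate a miRNA count matrix
#'
#' A count matrix is a numeric matrix of raw read counts with miRNAs in rows
#' and samples in columns; row and column names carry the gene and sample
#' identifiers. Entries must be integer-valued and nonnegative, identifiers
#' unique.
#'
#' @param counts matrix of raw read counts (genes x samples).
#' @return the validated matrix, invisibly unchanged.
#' @export
validate_count_matrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix (genes in rows, samples in columns)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene ids as rownames and sample ids as colnames")
  dup_g <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup_g) > 0)
    stop("duplicated gene ids: ", paste(dup_g, collapse = ", "))
  dup_s <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup_s) > 0)
    stop("duplicated sample ids: ", paste(dup_s, collapse = ", "))
  bad <- which(is.na(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("negative, missing or non-integer count at [",
         rownames(counts)[bad[1, 1]], ", ", colnames(counts)[bad[1, 2]], "]")
  invisible(counts)
}

#' Read a miRNA count matrix from a delimited file
#'
#' The first column holds the miRNA identifier and the header row the sample
#' identifiers; the body must be integer-valued read counts. Row and column
#' order are preserved.
#'
#' @param path file path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return a validated count matrix (genes x samples).
#' @export
read_count_matrix <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  gene_ids <- as.character(df[[1]])
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup) > 0)
    stop("duplicated gene ids: ", paste(dup, collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("count matrix body must be numeric")
  rownames(m) <- gene_ids
  validate_count_matrix(m)
  m
}

#' Write a count matrix to a delimited file
#'
#' @param counts validated count matrix.
#' @param path output file path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @export
write_count_matrix <- function(counts, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  validate_count_matrix(counts)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- data.frame(mirna = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a replicate-level Ct table
#'
#' Long-format records of qRT-PCR cycle-threshold measurements, one row per
#' (sample, target, replicate). Undetermined reactions (no amplification
#' within `max_cycles` cycles) are stored as flagged-missing, never coerced
#' to a numeric Ct.
#'
#' @param sample_id,target,replicate,ct parallel vectors; `ct` may contain
#'   `NA` for undetermined reactions.
#' @param max_cycles PCR cycle bound (default 40).
#' @return a `ct_table` data frame with columns `sample_id`, `target`,
#'   `replicate`, `ct`, `undetermined` and attribute `max_cycles`.
#' @export
ct_table <- function(sample_id, target, replicate, ct, max_cycles = 40L) {
  out <- data.frame(sample_id = as.character(sample_id),
                    target = as.character(target),
                    replicate = as.integer(replicate),
                    ct = as.numeric(ct),
                    stringsAsFactors = FALSE)
  out$undetermined <- is.na(out$ct)
  attr(out, "max_cycles") <- as.integer(max_cycles)
  class(out) <- c("ct_table", "data.frame")
  validate_ct_table(out)
  out
}

#' Validate a Ct table
#'
#' @param ct a `ct_table`.
#' @return the table, invisibly.
#' @export
validate_ct_table <- function(ct) {
  need <- c("sample_id", "target", "replicate", "ct", "undetermined")
  if (!all(need %in% names(ct)))
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  max_cycles <- attr(ct, "max_cycles")
  if (is.null(max_cycles)) max_cycles <- 40L
  det <- !ct$undetermined
  if (any(det & (is.na(ct$ct) | ct$ct <= 0)))
    stop("determined Ct values must be positive")
  over <- det & ct$ct > max_cycles
  if (any(over))
    stop("Ct above max_cycles (", max_cycles, ") at row(s): ",
         paste(which(over), collapse = ", "))
  key <- paste(ct$sample_id, ct$target, ct$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    d <- ct[duplicated(key), , drop = FALSE]
    stop("duplicate (sample, target, replicate): ",
         paste(unique(paste(d$sample_id, d$target, d$replicate, sep = "/")),
               collapse = ", "))
  }
  if (any(ct$replicate < 1)) stop("replicate indices must be >= 1")
  invisible(ct)
}

#' Read a long-format Ct table
#'
#' Expects columns `sample`/`sample_id`, `target`, `replicate`, `ct`. Ct
#' entries equal to `"Undetermined"` (case-insensitive), `"NA"` or empty are
#' stored as flagged-missing.
#'
#' @inheritParams read_count_matrix
#' @param max_cycles PCR cycle bound (default 40).
#' @return a validated `ct_table`.
#' @export
read_ct_table <- function(path, dialect = c("tsv", "csv"), max_cycles = 40L) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          colClasses = "character")
  names(df)[names(df) == "sample"] <- "sample_id"
  need <- c("sample_id", "target", "replicate", "ct")
  if (!all(need %in% names(df)))
    stop("Ct file must have columns: sample, target, replicate, ct")
  raw <- trimws(df$ct)
  undet <- tolower(raw) %in% c("undetermined", "na", "")
  ctv <- suppressWarnings(as.numeric(raw))
  if (any(!undet & is.na(ctv)))
    stop("unparseable Ct value(s): ",
         paste(unique(raw[!undet & is.na(ctv)]), collapse = ", "))
  ctv[undet] <- NA_real_
  ct_table(df$sample_id, df$target, as.integer(df$replicate), ctv,
           max_cycles = max_cycles)
}

#' Construct a miRNA stability table
#'
#' Per-miRNA summary of the sequencing-based ranking: mean log2 abundance,
#' coefficient of variation (percent of the log2 abundance) and the robust
#' stability score, with an optional dense rank (assigned by
#' [rank_select()]).
#'
#' @param gene_id character vector of miRNA names.
#' @param mean_abundance mean log2 normalized abundance (NA allowed when the
#'   table is built from published scores only).
#' @param cv_percent coefficient of variation, percent.
#' @param z_score robust (modified Z) stability score.
#' @param rank dense ranks 1..n, or NULL before ranking.
#' @return a `stability_table` data frame.
#' @export
stability_table <- function(gene_id, mean_abundance = NA_real_, cv_percent,
                            z_score, rank = NULL) {
  out <- data.frame(gene_id = as.character(gene_id),
                    mean_abundance = as.numeric(mean_abundance),
                    cv_percent = as.numeric(cv_percent),
                    z_score = as.numeric(z_score),
                    stringsAsFactors = FALSE)
  if (!is.null(rank)) out$rank <- as.integer(rank)
  if (anyDuplicated(out$gene_id))
    stop("duplicated gene ids in stability table")
  if (any(!is.finite(out$cv_percent)))
    stop("cv_percent must be finite for every row")
  if (!is.null(rank) && !identical(sort(out$rank), seq_len(nrow(out))))
    stop("ranks must be a dense permutation 1..n")
  class(out) <- c("stability_table", "data.frame")
  out
}

#' Assemble a single test report row
#'
#' @param contrast label of the comparison (e.g. "HD vs patients").
#' @param test_name statistical test used.
#' @param statistic test statistic.
#' @param p_value p-value in [0, 1]; `adjusted` says whether it is
#'   multiplicity-adjusted.
#' @param adjusted logical.
#' @param alpha significance level; `significant` is `p_value <= alpha`.
#' @return a one-row `test_report` data frame.
#' @export
test_report <- function(contrast, test_name, statistic, p_value,
                        adjusted = FALSE, alpha = 0.05) {
  if (any(p_value < 0 | p_value > 1, na.rm = TRUE))
    stop("p_value must lie in [0, 1]")
  n <- length(p_value)
  out <- data.frame(contrast = as.character(contrast),
                    test_name = as.character(test_name),
                    statistic = as.numeric(statistic),
                    p_value = as.numeric(p_value),
                    adjusted = rep_len(adjusted, n),
                    significant = as.numeric(p_value) <= alpha,
                    stringsAsFactors = FALSE)
  class(out) <- c("test_report", "data.frame")
  out
}

#' Write a result table to TSV
#'
#' Stability tables are written sorted by rank (rank 1 first); test reports
#' sorted by target (when present) then contrast. Column order is fixed so
#' output is deterministic and round-trips through the matching readers.
#'
#' @param x a `stability_table` or `test_report` data frame.
#' @param path output file path.
#' @export
write_table <- function(x, path) UseMethod("write_table")

#' @export
write_table.stability_table <- function(x, path) {
  if (is.null(x$rank)) stop("stability table must be ranked before writing")
  x <- x[order(x$rank), , drop = FALSE]
  cols <- c("gene_id", "mean_abundance", "cv_percent", "z_score", "rank")
  utils::write.table(x[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
write_table.test_report <- function(x, path) {
  ord <- if ("target" %in% names(x)) order(x$target, x$contrast)
         else order(x$contrast)
  x <- x[ord, , drop = FALSE]
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
write_table.data.frame <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a stability table written by [write_table()]
#'
#' @param path file path.
#' @return a `stability_table`.
#' @export
read_stability_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  ma <- if (is.null(df$mean_abundance)) NA_real_ else df$mean_abundance
  stability_table(df$gene_id, ma, df$cv_percent, df$z_score, rank = df$rank)
}

#' Validate a sample sheet against a set of sample ids
#'
#' A sample sheet maps sample ids to batch (study of origin), disease group
#' and optional timepoint. The join with expression or Ct data is strict:
#' samples present in the data but absent from the sheet are an error, never
#' silently dropped.
#'
#' @param sheet data frame with columns `sample_id`, `batch`, `group` and
#'   optionally `timepoint`.
#' @param sample_ids sample ids that must all be covered by the sheet
#'   (optional).
#' @return the sheet with a `timepoint` column filled in, invisibly.
#' @export
validate_sample_sheet <- function(sheet, sample_ids = NULL) {
  need <- c("sample_id", "batch", "group")
  if (!all(need %in% names(sheet)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    stop("duplicated sample ids in sheet: ",
         paste(unique(sheet$sample_id[duplicated(sheet$sample_id)]),
               collapse = ", "))
  if (any(is.na(sheet$batch) | sheet$batch == ""))
    stop("batch labels must be non-empty")
  if (any(is.na(sheet$group) | sheet$group == ""))
    stop("group labels must be non-empty")
  if (is.null(sheet$timepoint)) sheet$timepoint <- "none"
  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, sheet$sample_id)
    if (length(missing) > 0)
      stop("samples absent from the sample sheet: ",
           paste(missing, collapse = ", "))
  }
  invisible(sheet)
}
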