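#' Drop samples below the sequencing-depth threshold
#'
#' Samples whose total read count is below `min_reads` are removed; a sample
#' whose total equals the threshold exactly is kept. Every dropped sample is
#' reported by a message.
#'
#' @param counts validated count matrix (genes x samples).
#' @param min_reads depth threshold in reads (default 2e6).
#' @return the count matrix restricted to retained samples.
#' @export
drop_low_depth_samples <- function(counts, min_reads = 2e6) {
  validate_count_matrix(counts)
  totals <- colSums(counts)
  keep <- totals >= min_reads
  if (!any(keep)) stop("no samples pass depth filter (min_reads = ",
                       format(min_reads, scientific = FALSE), ")")
  for (s in colnames(counts)[!keep])
    message("depth filter: dropped sample '", s, "' (",
            format(totals[s], scientific = FALSE), " reads < ",
            format(min_reads, scientific = FALSE), ")")
  counts[, keep, drop = FALSE]
}

#' Keep consistently expressed miRNAs
#'
#' A miRNA is retained when its read sum across samples is at least
#' `min_sum` AND it is detected (count > 0) in at least a fraction
#' `min_frac` of the samples. Both predicates are evaluated on the matrix
#' given (i.e. after any depth filtering).
#'
#' @param counts count matrix with at least one sample.
#' @param min_sum minimum row sum (default 10).
#' @param min_frac minimum detection fraction in (0, 1] (default 0.8).
#' @return the filtered count matrix (possibly with zero rows).
#' @export
filter_consistent_mirnas <- function(counts, min_sum = 10, min_frac = 0.8) {
  if (ncol(counts) < 1) stop("count matrix has no samples")
  keep <- rowSums(counts) >= min_sum & rowMeans(counts > 0) >= min_frac
  dropped <- rownames(counts)[!keep]
  if (length(dropped) > 0)
    message("consistency filter: dropped ", length(dropped), " miRNA(s): ",
            paste(utils::head(dropped, 10), collapse = ", "),
            if (length(dropped) > 10) ", ..." else "")
  if (!any(keep)) message("consistency filter: no miRNAs retained")
  counts[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' For each sample j the size factor is the median, over genes g whose
#' counts are positive in every sample, of the ratio of the gene's count in
#' j to the gene's geometric mean across samples. Factors are returned as
#' raw medians of ratios, with no rescaling afterwards, so results are
#' bit-for-bit reproducible.
#'
#' @param counts count matrix; at least one gene must have all-positive
#'   counts.
#' @return named numeric vector of positive size factors, one per sample.
#' @export
estimate_size_factors <- function(counts) {
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no gene has all-positive counts; cannot form a geometric-mean ",
         "reference (pseudo-reference fallback is disabled)")
  sub <- counts[pos, , drop = FALSE]
  geomean <- exp(rowMeans(log(sub)))
  sf <- apply(sub / geomean, 2, stats::median)
  stats::setNames(as.numeric(sf), colnames(counts))
}

#' Log2 normalized abundances
#'
#' Each count is divided by its sample's size factor and log2-transformed
#' after adding a pseudocount: `value = log2(count / sf + pseudocount)`.
#'
#' @param counts count matrix.
#' @param size_factors named vector covering every sample of `counts`.
#' @param pseudocount positive real added before the log (default 1).
#' @return abundance matrix in log2 units with attributes `pseudocount`,
#'   `normalized = TRUE`, `batch_corrected = FALSE`.
#' @export
normalize_log2 <- function(counts, size_factors, pseudocount = 1) {
  missing <- setdiff(colnames(counts), names(size_factors))
  if (length(missing) > 0)
    stop("missing size factor for sample(s): ", paste(missing, collapse = ", "))
  sf <- size_factors[colnames(counts)]
  if (any(sf <= 0)) stop("size factors must be positive")
  am <- log2(sweep(counts, 2, sf, "/") + pseudocount)
  attr(am, "pseudocount") <- pseudocount
  attr(am, "normalized") <- TRUE
  attr(am, "batch_corrected") <- FALSE
  am
}

#' Remove batch effects from a normalized abundance matrix
#'
#' Per gene, an ordinary least-squares fit of abundance on batch indicators
#' (with intercept) is used to estimate batch deviations, which are then
#' subtracted so that every batch's mean equals the gene's grand mean. With
#' a batch-only design this is exactly per-batch mean-centering followed by
#' restoring the overall mean; within-batch deviations from the batch mean
#' are untouched. With a single batch the values are returned unchanged.
#'
#' @param am normalized abundance matrix from [normalize_log2()].
#' @param sheet sample sheet covering every column of `am`; its `batch`
#'   column defines the design. Every batch must contain at least two
#'   samples (a single-sample batch is confounded with the sample itself).
#' @return abundance matrix with `batch_corrected = TRUE`.
#' @export
correct_batch <- function(am, sheet) {
  if (!isTRUE(attr(am, "normalized")))
    stop("abundance matrix must be normalized before batch correction")
  sheet <- validate_sample_sheet(sheet, colnames(am))
  batch <- sheet$batch[match(colnames(am), sheet$sample_id)]
  out <- am
  if (length(unique(batch)) > 1) {
    sizes <- table(batch)
    if (any(sizes < 2))
      stop("batch(es) with a single sample: ",
           paste(names(sizes)[sizes < 2], collapse = ", "))
    grand <- rowMeans(am)
    for (b in unique(batch)) {
      idx <- batch == b
      out[, idx] <- am[, idx, drop = FALSE] -
        rowMeans(am[, idx, drop = FALSE]) + grand
    }
  }
  attr(out, "pseudocount") <- attr(am, "pseudocount")
  attr(out, "normalized") <- TRUE
  attr(out, "batch_corrected") <- TRUE
  out
}

# Robust (modified) Z transform: 0.6745 * (x - median) / MAD, with
# MAD = median(|x - median|) unscaled. Errors on MAD = 0 (constant input).
modified_z <- function(x, what = "values") {
  med <- stats::median(x)
  madv <- stats::median(abs(x - med))
  if (madv == 0)
    stop("MAD of ", what, " is zero - degenerate (constant) input")
  0.6745 * (x - med) / madv
}

#' Per-miRNA stability scores
#'
#' For each miRNA the mean log2 abundance m and the coefficient of
#' variation CV = 100 * sd / m (sample sd, n-1 denominator) are computed
#' across samples on the (batch-corrected) log2 scale. miRNAs with
#' nonpositive mean abundance are dropped with a message, as their CV is
#' undefined. Both summaries are then robust-standardized with the modified
#' Z transform `0.6745 * (x - median) / MAD` over the retained miRNAs and
#' combined into the stability score. The default `mz_diff` score,
#' `z = mz(mean) - mz(CV)`, rewards high abundance and low variability; the
#' alternative `inv_cv` score, `z = mz(-CV)`, ranks by variability alone.
#'
#' @param am batch-corrected (or single-batch) abundance matrix with at
#'   least 3 samples.
#' @param cfg a [ranking_config()].
#' @return an unranked `stability_table` (columns `gene_id`,
#'   `mean_abundance`, `cv_percent`, `z_score`).
#' @export
compute_stability <- function(am, cfg = ranking_config()) {
  if (ncol(am) < 3) stop("at least 3 samples are required")
  m <- rowMeans(am)
  s <- apply(am, 1, stats::sd)
  keep <- m > 0
  if (any(!keep))
    message("stability: dropped ", sum(!keep),
            " miRNA(s) with nonpositive mean abundance: ",
            paste(utils::head(rownames(am)[!keep], 10), collapse = ", "))
  m <- m[keep]; s <- s[keep]
  if (length(m) == 0) stop("no miRNAs with positive mean abundance")
  cv <- 100 * s / m
  z <- switch(cfg$scoring,
              mz_diff = modified_z(m, "mean abundances") -
                        modified_z(cv, "CVs"),
              inv_cv  = modified_z(-cv, "CVs"))
  stability_table(rownames(am)[keep], m, cv, z)
}

#' Rank miRNAs by stability score
#'
#' Rows are sorted by score descending; ties are broken by higher mean
#' abundance, then lexicographic gene id, so output is deterministic. Dense
#' ranks 1..n are assigned and the `top_n` best rows returned.
#'
#' @param stab a `stability_table` (ranked or not).
#' @param top_n number of rows to return; `top_n >= nrow` returns all.
#' @return a ranked `stability_table` with `top_n` rows at most.
#' @export
rank_select <- function(stab, top_n = 20) {
  if (nrow(stab) == 0) stop("stability table is empty")
  if (top_n < 1) stop("top_n must be >= 1")
  ord <- order(-stab$z_score, -stab$mean_abundance, stab$gene_id,
               na.last = TRUE)
  out <- stab[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out <- out[seq_len(min(top_n, nrow(out))), , drop = FALSE]
  class(out) <- c("stability_table", "data.frame")
  out
}

#' Select candidate reference miRNAs from a ranking
#'
#' Walks the ranked table in rank order, skipping names on the exclusion
#' list (e.g. known oncomiRs, which would be study targets rather than
#' normalizers), and collects miRNAs until `n_candidates` are found.
#' External additions (e.g. literature-recommended normalizers) are appended
#' afterwards, deduplicated. Every skip is reported by a message.
#'
#' @param ranked a ranked `stability_table`.
#' @param n_candidates number of ranked miRNAs to collect (default 3).
#' @param exclude miRNA names to skip.
#' @param add_external miRNA names appended to the panel.
#' @return character vector of candidate reference miRNAs.
#' @export
select_candidates <- function(ranked, n_candidates = 3,
                              exclude = character(),
                              add_external = character()) {
  if (is.null(ranked$rank)) stop("table must be ranked (see rank_select)")
  ord <- ranked$gene_id[order(ranked$rank)]
  picked <- character()
  for (g in ord) {
    if (g %in% exclude) {
      message("candidate selection: skipped '", g, "' (on exclusion list)")
      next
    }
    picked <- c(picked, g)
    if (length(picked) >= n_candidates) break
  }
  if (length(picked) == 0)
    stop("exclusion list removes every ranked miRNA")
  unique(c(picked, add_external))
}

#' Run the full sequencing-based stability ranking
#'
#' Convenience wrapper chaining depth filter, consistency filter,
#' median-of-ratios normalization, batch correction, stability scoring and
#' ranking.
#'
#' @param counts raw count matrix (genes x samples).
#' @param sheet sample sheet covering all samples.
#' @param cfg a [ranking_config()].
#' @return list with `ranking` (ranked stability table of `top_n` rows),
#'   `stability` (full unranked table), `abundance` (batch-corrected log2
#'   matrix) and `size_factors`.
#' @export
rank_reference_mirnas <- function(counts, sheet, cfg = ranking_config()) {
  validate_count_matrix(counts)
  sheet <- validate_sample_sheet(sheet, colnames(counts))
  cm <- drop_low_depth_samples(counts, cfg$min_reads_per_sample)
  cm <- filter_consistent_mirnas(cm, cfg$min_read_sum, cfg$min_detect_frac)
  if (nrow(cm) == 0) stop("no miRNAs pass the consistency filter")
  sf <- estimate_size_factors(cm)
  am <- normalize_log2(cm, sf, cfg$pseudocount)
  am <- correct_batch(am, sheet)
  stab <- compute_stability(am, cfg)
  list(ranking = rank_select(stab, cfg$top_n),
       stability = stab,
       abundance = am,
       size_factors = sf)
}

#' Abundance-versus-variation scatter of a stability table
#'
#' Plots mean log2 abundance against CV, the two ingredients of the
#' stability score; stable normalizer candidates sit to the bottom right
#' (high abundance, low variation).
#'
#' @param stab a `stability_table`.
#' @param label logical; label points with miRNA names (default TRUE when
#'   20 rows or fewer).
#' @param ... passed to [graphics::plot()].
#' @export
plot_stability <- function(stab, label = nrow(stab) <= 20, ...) {
  graphics::plot(stab$mean_abundance, stab$cv_percent,
                 xlab = "mean abundance (log2 normalized counts)",
                 ylab = "CV (%)", pch = 19, ...)
  if (label)
    graphics::text(stab$mean_abundance, stab$cv_percent, stab$gene_id,
                   pos = 3, cex = 0.7)
  invisible(stab)
}
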