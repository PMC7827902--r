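#' Collapse qRT-PCR replicates to per-(sample, target) mean Ct
#'
#' The mean is taken over determined replicates only. A (sample, target)
#' pair is flagged missing when fewer than `min_replicates` replicates are
#' determined; undetermined reactions never contribute a numeric value (in
#' particular they are never coerced to the cycle bound, which would bias
#' the mean).
#'
#' @param ct a validated `ct_table`.
#' @param cfg a [validation_config()].
#' @return a `collapsed_ct` data frame with columns `sample_id`, `target`,
#'   `mean_ct`, `n_replicates_used`, `missing`.
#' @export
collapse_replicates <- function(ct, cfg = validation_config()) {
  validate_ct_table(ct)
  key <- paste(ct$sample_id, ct$target, sep = "\r")
  idx <- split(seq_len(nrow(ct)), key)
  rows <- lapply(idx, function(i) {
    v <- ct$ct[i][!ct$undetermined[i]]
    n <- length(v)
    data.frame(sample_id = ct$sample_id[i[1]], target = ct$target[i[1]],
               mean_ct = if (n >= cfg$min_replicates) mean(v) else NA_real_,
               n_replicates_used = n,
               missing = n < cfg$min_replicates,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  n_miss <- sum(out$missing)
  if (n_miss > 0)
    message("collapse: ", n_miss, " (sample, target) pair(s) with fewer ",
            "than ", cfg$min_replicates, " determined replicates")
  class(out) <- c("collapsed_ct", "data.frame")
  out
}

#' Spike-in retrotranscription QC
#'
#' Each sample passes when its exogenous spike-in (default cel-miR-39) mean
#' Ct lies inside the configured window, boundaries included. Failures are
#' reported with a warning and analysis proceeds, unless `strict_spikein` is
#' set in the config, in which case a missing spike-in is an error.
#'
#' @param collapsed output of [collapse_replicates()].
#' @param cfg a [validation_config()].
#' @return data frame with columns `sample_id`, `spikein_ct`, `pass`.
#' @export
spike_in_qc <- function(collapsed, cfg = validation_config()) {
  samples <- unique(collapsed$sample_id)
  sp <- collapsed[collapsed$target == cfg$spikein_target, , drop = FALSE]
  absent <- setdiff(samples, sp$sample_id[!sp$missing])
  if (length(absent) > 0) {
    msg <- paste0("spike-in '", cfg$spikein_target, "' missing for sample(s): ",
                  paste(absent, collapse = ", "))
    if (cfg$strict_spikein) stop(msg) else warning(msg)
  }
  ctv <- sp$mean_ct[match(samples, sp$sample_id)]
  pass <- !is.na(ctv) & ctv >= cfg$spikein_window[1] &
    ctv <= cfg$spikein_window[2]
  fails <- samples[!is.na(ctv) & !pass]
  if (length(fails) > 0)
    warning("spike-in Ct outside [", cfg$spikein_window[1], ", ",
            cfg$spikein_window[2], "] for sample(s): ",
            paste(fails, collapse = ", "))
  data.frame(sample_id = samples, spikein_ct = ctv, pass = pass,
             stringsAsFactors = FALSE)
}

#' Choose parametric or nonparametric testing by Shapiro-Wilk
#'
#' A Shapiro-Wilk normality test is run in each group; the gate returns
#' `"nonparametric"` as soon as any group rejects normality at `alpha`, and
#' `"parametric"` otherwise. Groups with fewer than 3 values cannot be
#' tested and are skipped with a warning.
#'
#' @param values_by_group named list of numeric vectors (Ct means by group).
#' @param alpha significance level of the gate (default 0.05).
#' @return list with `mode` (`"parametric"` or `"nonparametric"`) and
#'   `p_values` (named, per tested group).
#' @export
normality_gate <- function(values_by_group, alpha = 0.05) {
  sizes <- vapply(values_by_group, length, integer(1))
  small <- names(values_by_group)[sizes < 3]
  if (length(small) > 0)
    warning("normality gate: group(s) with fewer than 3 values skipped: ",
            paste(small, collapse = ", "))
  tested <- values_by_group[sizes >= 3]
  if (length(tested) == 0)
    stop("no group has enough values for a normality test")
  p <- vapply(tested, function(v) stats::shapiro.test(v)$p.value, numeric(1))
  mode <- if (any(p <= alpha)) "nonparametric" else "parametric"
  list(mode = mode, p_values = p)
}

#' Two-group comparison of Ct means
#'
#' Parametric mode runs a two-sided unpaired t-test with pooled variance;
#' nonparametric mode a two-sided Mann-Whitney test, exact when both groups
#' have at most 8 values and there are no ties, otherwise the tie-corrected
#' normal approximation without continuity correction (for bit-for-bit
#' reproducibility).
#'
#' @param a,b numeric vectors of Ct means.
#' @param mode `"parametric"` or `"nonparametric"` (from [normality_gate()]).
#' @param alpha significance level.
#' @param contrast label used in the report.
#' @return a one-row `test_report`.
#' @export
two_group_test <- function(a, b, mode = c("parametric", "nonparametric"),
                           alpha = 0.05, contrast = "A vs B") {
  mode <- match.arg(mode)
  if (length(a) == 0 || length(b) == 0) stop("empty group in two-group test")
  if (mode == "parametric") {
    if (length(a) < 2 || length(b) < 2)
      stop("parametric two-group test needs >= 2 values per group")
    ht <- stats::t.test(a, b, var.equal = TRUE)
    test_report(contrast, "unpaired t-test (pooled variance)",
                unname(ht$statistic), ht$p.value, adjusted = FALSE,
                alpha = alpha)
  } else {
    if (length(a) + length(b) < 3)
      stop("Mann-Whitney test needs a combined n of at least 3")
    exact <- length(a) <= 8 && length(b) <= 8 && !anyDuplicated(c(a, b))
    ht <- suppressWarnings(
      stats::wilcox.test(a, b, exact = exact, correct = FALSE))
    nm <- if (exact) "Mann-Whitney (exact)"
          else "Mann-Whitney (normal approximation, tie-corrected)"
    test_report(contrast, nm, unname(ht$statistic), ht$p.value,
                adjusted = FALSE, alpha = alpha)
  }
}

# Dunn's post-hoc z tests on the joint ranks of all groups, with the
# standard tie correction and Bonferroni adjustment over all pairs.
dunn_all_pairs <- function(values, g, alpha = 0.05) {
  r <- rank(values)
  N <- length(values)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  tie_counts <- table(values)
  tie_term <- sum(tie_counts^3 - tie_counts) / (12 * (N - 1))
  lev <- names(rbar)
  pairs <- utils::combn(lev, 2)
  npairs <- ncol(pairs)
  rows <- lapply(seq_len(npairs), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[[i]] + 1 / n[[j]]))
    z <- (rbar[[i]] - rbar[[j]]) / se
    p <- 2 * stats::pnorm(-abs(z))
    test_report(paste(i, "vs", j), "Dunn (Bonferroni-adjusted)", z,
                min(1, p * npairs), adjusted = TRUE, alpha = alpha)
  })
  do.call(rbind, rows)
}

#' Multi-group comparison with post-hoc pairwise tests
#'
#' Parametric mode runs ordinary one-way ANOVA followed by Tukey HSD on all
#' pairs (studentized-range adjusted p-values); nonparametric mode a
#' tie-corrected Kruskal-Wallis test followed by Dunn's z tests on the joint
#' ranks, two-sided p-values Bonferroni-adjusted over the number of pairs.
#'
#' @param groups named list (>= 3 entries) of numeric vectors, each with at
#'   least 2 values.
#' @param mode `"parametric"` or `"nonparametric"`.
#' @param alpha significance level.
#' @param omnibus_contrast label for the omnibus report row (default
#'   `"between groups"`).
#' @return list with `omnibus` (one-row `test_report`) and `pairwise`
#'   (`test_report` with one row per pair, adjusted p-values).
#' @export
multi_group_test <- function(groups, mode = c("parametric", "nonparametric"),
                             alpha = 0.05,
                             omnibus_contrast = "between groups") {
  mode <- match.arg(mode)
  if (length(groups) < 3)
    stop("multi-group test needs >= 3 groups; use two_group_test for two")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("every group needs at least 2 values")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, integer(1))))
  if (mode == "parametric") {
    fit <- stats::aov(values ~ g)
    tab <- summary(fit)[[1]]
    omni <- test_report(omnibus_contrast, "one-way ANOVA",
                        tab[["F value"]][1], tab[["Pr(>F)"]][1],
                        adjusted = FALSE, alpha = alpha)
    tk <- stats::TukeyHSD(fit)$g
    pw <- do.call(rbind, lapply(rownames(tk), function(pr) {
      ab <- strsplit(pr, "-", fixed = TRUE)[[1]]
      test_report(paste(ab[1], "vs", ab[2]), "Tukey HSD",
                  tk[pr, "diff"], tk[pr, "p adj"], adjusted = TRUE,
                  alpha = alpha)
    }))
  } else {
    ht <- stats::kruskal.test(values, g)
    omni <- test_report(omnibus_contrast, "Kruskal-Wallis",
                        unname(ht$statistic), ht$p.value, adjusted = FALSE,
                        alpha = alpha)
    pw <- dunn_all_pairs(values, g, alpha = alpha)
  }
  rownames(pw) <- NULL
  list(omnibus = omni, pairwise = pw)
}

#' Per-target stability verdict
#'
#' A target is called *stable* when none of its contrasts - the
#' control-vs-patients two-group comparison, the multi-group omnibus test,
#' or any adjusted pairwise comparison - is significant at `alpha`, and
#' *unstable* otherwise. The full evidence (every contrast with its
#' p-value) is kept alongside the verdict.
#'
#' @param reports_by_target named list; each element is a `test_report` data
#'   frame holding all contrasts computed for that target.
#' @param alpha significance level.
#' @param required_contrasts contrast labels that must be present for every
#'   target (an absent one is an error, not a silent pass).
#' @return data frame with columns `target`, `verdict`, `n_significant` and
#'   attribute `evidence` (the input reports).
#' @export
stability_verdict <- function(reports_by_target, alpha = 0.05,
                              required_contrasts = c("HD vs patients",
                                                     "between groups")) {
  rows <- lapply(names(reports_by_target), function(tg) {
    rep <- reports_by_target[[tg]]
    missing <- setdiff(required_contrasts, rep$contrast)
    if (length(missing) > 0)
      stop("target '", tg, "' lacks required contrast(s): ",
           paste(missing, collapse = ", "))
    sig <- rep$p_value <= alpha
    data.frame(target = tg,
               verdict = if (any(sig)) "unstable" else "stable",
               n_significant = sum(sig),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "evidence") <- reports_by_target
  out
}

#' Full qRT-PCR stability assessment of a candidate panel
#'
#' Runs the complete validation workflow on a replicate-level Ct table:
#' replicate collapsing, spike-in QC, then for every target (spike-in
#' excluded) a control-vs-pooled-patients two-group comparison and a
#' multi-group comparison across all groups, each preceded by a
#' Shapiro-Wilk normality gate, and finally the per-target stability
#' verdict.
#'
#' @param ct a validated `ct_table`.
#' @param sheet sample sheet with `group` labels covering every sample.
#' @param cfg a [validation_config()].
#' @param control_group label of the healthy-control group (default "HD").
#' @return list with `verdicts`, `reports` (named list of `test_report`
#'   frames per target), `qc` (spike-in table) and `collapsed`.
#' @export
assess_panel_stability <- function(ct, sheet, cfg = validation_config(),
                                   control_group = "HD") {
  sheet <- validate_sample_sheet(sheet, unique(ct$sample_id))
  collapsed <- collapse_replicates(ct, cfg)
  qc <- if (cfg$spikein_target %in% collapsed$target)
    spike_in_qc(collapsed, cfg) else NULL
  targets <- setdiff(unique(collapsed$target), cfg$spikein_target)
  if (length(targets) == 0) stop("no targets beyond the spike-in control")
  two_label <- paste(control_group, "vs patients")
  reports <- lapply(targets, function(tg) {
    sub <- collapsed[collapsed$target == tg & !collapsed$missing, ,
                     drop = FALSE]
    grp <- sheet$group[match(sub$sample_id, sheet$sample_id)]
    a <- sub$mean_ct[grp == control_group]
    b <- sub$mean_ct[grp != control_group]
    gate2 <- normality_gate(list(control = a, patients = b), cfg$alpha)
    r2 <- two_group_test(a, b, gate2$mode, cfg$alpha, contrast = two_label)
    by_group <- split(sub$mean_ct, grp)
    gateM <- normality_gate(by_group, cfg$alpha)
    mg <- multi_group_test(by_group, gateM$mode, cfg$alpha)
    # post-hoc pairwise comparisons are interpreted only after a
    # significant omnibus test, the convention the verdict relies on
    rep <- if (mg$omnibus$significant)
      rbind(r2, mg$omnibus, mg$pairwise) else rbind(r2, mg$omnibus)
    rep$target <- tg
    class(rep) <- c("test_report", "data.frame")
    rep
  })
  names(reports) <- targets
  verdicts <- stability_verdict(reports, cfg$alpha,
                                required_contrasts = c(two_label,
                                                       "between groups"))
  list(verdicts = verdicts, reports = reports, qc = qc, collapsed = collapsed)
}
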