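#' Configuration for the count-matrix simulator
#'
#' The generator emulates a multi-study compendium of healthy-donor plasma
#' exosome small-RNA-seq samples: per-gene abundances are log-normal,
#' library sizes log-normal, counts negative-binomial, and a fraction of
#' genes carries a multiplicative between-study batch effect. A planted set
#' of "stable" miRNAs receives top-decile abundance, the minimum dispersion
#' and no batch effect - the ground truth a stability ranking should
#' recover. The default design mirrors a compendium of 69 samples from 3
#' study batches with 300 miRNAs and 10 planted stable ones.
#'
#' @param n_genes,n_samples,n_batches design dimensions.
#' @param base_mean_logdist `c(meanlog, sdlog)` of the per-gene abundance
#'   distribution (expected reads at unit library size). The default gives
#'   an expected library of ~5 million miRNA reads over 300 genes with a
#'   dynamic range typical of a detection-filtered consistent miRNA set.
#' @param dispersion_range `c(lo, hi)` of per-gene negative-binomial
#'   dispersion (variance = mu + disp * mu^2). Background genes draw
#'   `lo + (hi - lo) * Beta(2, 2)`, a bell over the range: most miRNAs have
#'   intermediate donor-to-donor variability and extreme stability or
#'   instability is rare. Planted genes sit at `lo` exactly.
#' @param libsize_sdlog sdlog of the log-normal per-sample library factor.
#' @param batch_effect_sdlog sdlog of the log-normal multiplicative batch
#'   effect applied to affected genes.
#' @param batch_affected_frac fraction of (non-planted) genes carrying a
#'   batch effect.
#' @param n_planted_stable number of planted stable miRNAs.
#' @param seed integer seed; the generator is fully reproducible given it.
#' @return a `count_sim_config` list.
#' @export
count_sim_config <- function(n_genes = 300, n_samples = 69, n_batches = 3,
                             base_mean_logdist = c(log(5e6 / 300) - 0.125, 0.5),
                             dispersion_range = c(0.005, 1.5),
                             libsize_sdlog = 0.3,
                             batch_effect_sdlog = 0.3,
                             batch_affected_frac = 0.5,
                             n_planted_stable = 10,
                             seed = 1) {
  stopifnot(n_genes >= 1, n_samples >= 1, n_batches >= 1,
            length(base_mean_logdist) == 2, base_mean_logdist[2] >= 0,
            length(dispersion_range) == 2, dispersion_range[1] >= 0,
            dispersion_range[1] <= dispersion_range[2],
            libsize_sdlog >= 0, batch_effect_sdlog >= 0,
            batch_affected_frac >= 0, batch_affected_frac <= 1,
            n_planted_stable >= 0, n_planted_stable <= n_genes)
  structure(list(n_genes = as.integer(n_genes),
                 n_samples = as.integer(n_samples),
                 n_batches = as.integer(n_batches),
                 base_mean_logdist = as.numeric(base_mean_logdist),
                 dispersion_range = as.numeric(dispersion_range),
                 libsize_sdlog = libsize_sdlog,
                 batch_effect_sdlog = batch_effect_sdlog,
                 batch_affected_frac = batch_affected_frac,
                 n_planted_stable = as.integer(n_planted_stable),
                 seed = as.integer(seed)),
            class = "count_sim_config")
}

#' Simulate a miRNA count matrix with planted stable genes
#'
#' Counts are drawn negative-binomially with mean
#' `lambda_g * f_j * b_{g, batch(j)}`: `lambda_g` log-normal gene
#' abundance, `f_j` log-normal library factor, `b` a multiplicative batch
#' effect for the affected gene fraction (1 otherwise), and per-gene
#' per-gene dispersion drawn over `dispersion_range` as described in
#' [count_sim_config()] (dispersions below 1e-8 fall back to Poisson
#' sampling). Planted stable genes draw their abundance from the top decile
#' of the base distribution, get the minimum dispersion and carry no batch
#' effect.
#'
#' @param cfg a [count_sim_config()].
#' @return list with `counts` (validated count matrix), `sheet` (sample
#'   sheet; all samples labelled group `"HD"`) and `truth` (list with
#'   per-gene, per-sample and batch-effect latent parameters, sufficient to
#'   score any recovery experiment).
#' @export
simulate_counts <- function(cfg = count_sim_config()) {
  if (!inherits(cfg, "count_sim_config")) stop("cfg must be a count_sim_config")
  set.seed(cfg$seed)
  meanlog <- cfg$base_mean_logdist[1]
  sdlog <- cfg$base_mean_logdist[2]
  gene_ids <- sprintf("miR-sim-%03d", seq_len(cfg$n_genes))
  planted <- rep(FALSE, cfg$n_genes)
  if (cfg$n_planted_stable > 0)
    planted[sample.int(cfg$n_genes, cfg$n_planted_stable)] <- TRUE

  lambda <- stats::rlnorm(cfg$n_genes, meanlog, sdlog)
  lambda[planted] <- stats::qlnorm(
    stats::runif(sum(planted), 0.9, 1 - 1e-12), meanlog, sdlog)
  dispersion <- cfg$dispersion_range[1] +
    diff(cfg$dispersion_range) * stats::rbeta(cfg$n_genes, 2, 2)
  dispersion[planted] <- cfg$dispersion_range[1]

  batch <- sprintf("batch%d", rep(seq_len(cfg$n_batches),
                                  length.out = cfg$n_samples))
  batch <- sort(batch)
  sample_ids <- sprintf("S%03d", seq_len(cfg$n_samples))
  libfac <- stats::rlnorm(cfg$n_samples, 0, cfg$libsize_sdlog)

  beff <- matrix(1, cfg$n_genes, cfg$n_batches,
                 dimnames = list(gene_ids, unique(batch)))
  affected <- !planted &
    stats::runif(cfg$n_genes) < cfg$batch_affected_frac
  if (any(affected) && cfg$n_batches > 1)
    beff[affected, ] <- matrix(
      stats::rlnorm(sum(affected) * cfg$n_batches, 0,
                    cfg$batch_effect_sdlog),
      sum(affected), cfg$n_batches)

  counts <- matrix(0, cfg$n_genes, cfg$n_samples,
                   dimnames = list(gene_ids, sample_ids))
  batch_idx <- match(batch, colnames(beff))
  for (g in seq_len(cfg$n_genes)) {
    mu <- lambda[g] * libfac * beff[g, batch_idx]
    counts[g, ] <- if (dispersion[g] < 1e-8) stats::rpois(cfg$n_samples, mu)
      else stats::rnbinom(cfg$n_samples, mu = mu, size = 1 / dispersion[g])
  }
  validate_count_matrix(counts)
  sheet <- data.frame(sample_id = sample_ids, batch = batch, group = "HD",
                      timepoint = "none", stringsAsFactors = FALSE)
  truth <- list(
    genes = data.frame(gene_id = gene_ids, lambda = lambda,
                       dispersion = dispersion, planted = planted,
                       batch_affected = affected, stringsAsFactors = FALSE),
    samples = data.frame(sample_id = sample_ids, batch = batch,
                         libsize_factor = libfac, stringsAsFactors = FALSE),
    batch_effects = beff)
  list(counts = counts, sheet = sheet, truth = truth)
}

#' Configuration for the qRT-PCR Ct-table simulator
#'
#' Emulates a candidate-normalizer validation experiment: a healthy-donor
#' control group and several disease groups, a small panel of target miRNAs
#' with baseline Ct in the low-to-mid 20s, an exogenous spike-in control,
#' and triplicate reactions. Default group sizes (HD 13, ALCL 14, BL 15,
#' HL 15, mALL 15) and target baselines (22.26 to 24.84 cycles) match a
#' typical pediatric hematological-malignancy cohort.
#'
#' @param group_sizes named integer vector, group label -> number of samples.
#' @param target_baselines named numeric vector, target -> baseline mean Ct.
#' @param group_shifts `NULL` (no shifts) or a data frame with columns
#'   `target`, `group`, `shift` (cycles) of planted between-group shifts.
#' @param replicate_sd replicate (technical) noise sd, cycles (default 0.3).
#' @param sample_sd biological sample-to-sample noise sd, cycles
#'   (default 0.2).
#' @param n_replicates replicates per reaction (default 3).
#' @param spikein_target spike-in assay name (default `"cel-miR-39"`).
#' @param spikein_range spike-in Ct range, drawn uniformly per sample
#'   (default `c(14, 19)`).
#' @param max_cycles PCR cycle bound; replicate Ct beyond it becomes
#'   undetermined (default 40).
#' @param seed integer seed.
#' @return a `ct_sim_config` list.
#' @export
ct_sim_config <- function(group_sizes = c(HD = 13, ALCL = 14, BL = 15,
                                          HL = 15, mALL = 15),
                          target_baselines = c("miR-486-5p" = 23.3,
                                               "miR-26a-5p" = 22.26,
                                               "miR-423-5p" = 24.84,
                                               "miR-191-5p" = 23.5),
                          group_shifts = NULL,
                          replicate_sd = 0.3,
                          sample_sd = 0.2,
                          n_replicates = 3,
                          spikein_target = "cel-miR-39",
                          spikein_range = c(14, 19),
                          max_cycles = 40,
                          seed = 1) {
  stopifnot(all(group_sizes >= 2), length(target_baselines) >= 1,
            replicate_sd >= 0, sample_sd >= 0, n_replicates >= 1,
            length(spikein_range) == 2,
            spikein_range[1] < spikein_range[2],
            all(target_baselines > 0), all(target_baselines < max_cycles))
  if (!is.null(group_shifts))
    stopifnot(is.data.frame(group_shifts),
              all(c("target", "group", "shift") %in% names(group_shifts)))
  structure(list(group_sizes = group_sizes,
                 target_baselines = target_baselines,
                 group_shifts = group_shifts,
                 replicate_sd = replicate_sd,
                 sample_sd = sample_sd,
                 n_replicates = as.integer(n_replicates),
                 spikein_target = spikein_target,
                 spikein_range = as.numeric(spikein_range),
                 max_cycles = as.integer(max_cycles),
                 seed = as.integer(seed)),
            class = "ct_sim_config")
}

#' Simulate a replicate-level qRT-PCR Ct table
#'
#' Each replicate Ct is `baseline + group shift + sample effect + replicate
#' noise`, with the sample effect drawn per (sample, target) from
#' `N(0, sample_sd^2)` and replicate noise from `N(0, replicate_sd^2)`.
#' Values beyond `max_cycles` become undetermined. The spike-in Ct is drawn
#' uniformly within `spikein_range` once per sample (it is a technical
#' control, so its replicates are identical and always inside the window).
#'
#' @param cfg a [ct_sim_config()].
#' @return list with `ct` (validated `ct_table`), `sheet` (sample sheet;
#'   batch `"run1"`, timepoint `"diagnosis"` for non-HD groups) and `truth`
#'   (per (sample, target) true mean Ct).
#' @export
simulate_ct <- function(cfg = ct_sim_config()) {
  if (!inherits(cfg, "ct_sim_config")) stop("cfg must be a ct_sim_config")
  set.seed(cfg$seed)
  groups <- rep(names(cfg$group_sizes), cfg$group_sizes)
  sample_ids <- unlist(lapply(names(cfg$group_sizes), function(g)
    sprintf("%s_%02d", g, seq_len(cfg$group_sizes[[g]]))))
  targets <- names(cfg$target_baselines)
  shift_of <- function(tg, gr) {
    if (is.null(cfg$group_shifts)) return(0)
    hit <- cfg$group_shifts$target == tg & cfg$group_shifts$group == gr
    if (any(hit)) sum(cfg$group_shifts$shift[hit]) else 0
  }
  recs <- list(); truth <- list(); k <- 0
  for (si in seq_along(sample_ids)) {
    for (tg in targets) {
      mu <- cfg$target_baselines[[tg]] + shift_of(tg, groups[si]) +
        stats::rnorm(1, 0, cfg$sample_sd)
      ctv <- mu + stats::rnorm(cfg$n_replicates, 0, cfg$replicate_sd)
      ctv[ctv > cfg$max_cycles] <- NA_real_
      k <- k + 1
      recs[[k]] <- data.frame(sample_id = sample_ids[si], target = tg,
                              replicate = seq_len(cfg$n_replicates),
                              ct = ctv, stringsAsFactors = FALSE)
      truth[[k]] <- data.frame(sample_id = sample_ids[si], target = tg,
                               group = groups[si], true_mean_ct = mu,
                               stringsAsFactors = FALSE)
    }
    sp <- stats::runif(1, cfg$spikein_range[1], cfg$spikein_range[2])
    k <- k + 1
    recs[[k]] <- data.frame(sample_id = sample_ids[si],
                            target = cfg$spikein_target,
                            replicate = seq_len(cfg$n_replicates),
                            ct = rep(sp, cfg$n_replicates),
                            stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, recs)
  ct <- ct_table(df$sample_id, df$target, df$replicate, df$ct,
                 max_cycles = cfg$max_cycles)
  sheet <- data.frame(sample_id = sample_ids, batch = "run1", group = groups,
                      timepoint = ifelse(groups == "HD", "none", "diagnosis"),
                      stringsAsFactors = FALSE)
  list(ct = ct, sheet = sheet, truth = do.call(rbind, truth))
}

#' Null Ct panel (no group shifts)
#'
#' [simulate_ct()] with all group shifts forced to zero - the reference
#' distribution for type-I-error calibration of the stability verdict.
#'
#' @param cfg a [ct_sim_config()]; its `group_shifts` are ignored.
#' @return as [simulate_ct()].
#' @export
null_panel <- function(cfg = ct_sim_config()) {
  cfg$group_shifts <- NULL
  simulate_ct(cfg)
}
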