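# Brute-force oracles, written deliberately as plain loops so they share no
# code path with the package implementation.

# median-of-ratios size factors, one explicit loop per sample
oracle_size_factors <- function(counts) {
  keep <- apply(counts, 1, function(r) all(r > 0))
  sub <- counts[keep, , drop = FALSE]
  sf <- numeric(ncol(sub))
  for (j in seq_len(ncol(sub))) {
    ratios <- numeric(nrow(sub))
    for (g in seq_len(nrow(sub))) {
      gm <- prod(sub[g, ])^(1 / ncol(sub))
      ratios[g] <- sub[g, j] / gm
    }
    sf[j] <- median(ratios)
  }
  names(sf) <- colnames(counts)
  sf
}

# spreadsheet-style stability recomputation: every intermediate explicit
oracle_stability <- function(am) {
  n <- ncol(am)
  m <- cv <- numeric(nrow(am))
  for (g in seq_len(nrow(am))) {
    x <- am[g, ]
    m[g] <- sum(x) / n
    sdev <- sqrt(sum((x - m[g])^2) / (n - 1))
    cv[g] <- 100 * sdev / m[g]
  }
  mz <- function(v) {
    med <- sort(v)[ceiling(length(v) / 2)]
    if (length(v) %% 2 == 0)
      med <- mean(sort(v)[length(v) / 2 + c(0, 1)])
    madv <- abs(v - med)
    madv <- if (length(v) %% 2 == 0)
      mean(sort(madv)[length(v) / 2 + c(0, 1)]) else
      sort(madv)[ceiling(length(v) / 2)]
    0.6745 * (v - med) / madv
  }
  data.frame(gene_id = rownames(am), mean_abundance = m, cv_percent = cv,
             z_score = mz(m) - mz(cv), stringsAsFactors = FALSE)
}

# Dunn z statistics recomputed from first principles (ranks via order/match,
# tie counts via run lengths on the sorted vector)
oracle_dunn_z <- function(values, groups) {
  N <- length(values)
  srt <- sort(values)
  rnk <- numeric(N)
  for (i in seq_len(N)) rnk[i] <- mean(which(srt == values[i]))
  runs <- rle(srt)$lengths
  tie_term <- sum(runs^3 - runs) / (12 * (N - 1))
  lev <- sort(unique(groups))
  out <- list()
  k <- 0
  for (i in seq_along(lev)) for (j in seq_along(lev)) {
    if (j <= i) next
    ri <- rnk[groups == lev[i]]; rj <- rnk[groups == lev[j]]
    se <- sqrt((N * (N + 1) / 12 - tie_term) *
                 (1 / length(ri) + 1 / length(rj)))
    k <- k + 1
    out[[k]] <- data.frame(a = lev[i], b = lev[j],
                           z = (mean(ri) - mean(rj)) / se,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# random small count fixture
random_count_matrix <- function(n_genes = 5, n_samples = 4, lambda = 50) {
  m <- matrix(rpois(n_genes * n_samples, lambda) + 1, n_genes, n_samples,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  m
}

# the published top-20 plasma-exosome stability ranking used as a frozen
# printed-value fixture
published_top20 <- function() {
  read_stability_table(system.file("extdata",
    "hd_plasma_exosome_top20_stability.tsv", package = "exoref"))
}
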