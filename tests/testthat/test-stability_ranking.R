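make_cm <- function(totals, n_genes = 4) {
  n <- length(totals)
  m <- matrix(0, n_genes, n,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("s", seq_len(n))))
  for (j in seq_len(n)) {
    base <- rep(floor(totals[j] / n_genes), n_genes)
    base[1] <- base[1] + totals[j] - sum(base)
    m[, j] <- base
  }
  m
}

test_that("depth filter keeps the inclusive boundary and drops the rest", {
  cm <- make_cm(c(1e6, 3e6, 2e6, 5e5, 4e6))
  out <- suppressMessages(drop_low_depth_samples(cm, 2e6))
  expect_equal(colnames(out), c("s2", "s3", "s5"))
  # a sample one read short of the threshold is dropped
  cm2 <- make_cm(c(1999999, 2e6))
  out2 <- suppressMessages(drop_low_depth_samples(cm2, 2e6))
  expect_equal(colnames(out2), "s2")
  # nothing below threshold: identity
  cm3 <- make_cm(c(2e6, 3e6))
  expect_equal(drop_low_depth_samples(cm3, 2e6), cm3)
  expect_error(suppressMessages(drop_low_depth_samples(cm3, 1e9)),
               "no samples pass")
})

test_that("consistency filter applies both predicates on boundaries", {
  # sum 9 < 10 removed even if detected everywhere it is present
  m <- matrix(0, 2, 10, dimnames = list(c("low", "hi"), paste0("s", 1:10)))
  m["low", 1] <- 9
  m["hi", ] <- 5
  out <- suppressMessages(filter_consistent_mirnas(m, 10, 0.8))
  expect_equal(rownames(out), "hi")

  # detected in 79/100 removed, 80/100 kept
  m2 <- matrix(0, 2, 100, dimnames = list(c("g79", "g80"), paste0("s", 1:100)))
  m2["g79", 1:79] <- 10
  m2["g80", 1:80] <- 10
  out2 <- suppressMessages(filter_consistent_mirnas(m2, 10, 0.8))
  expect_equal(rownames(out2), "g80")

  # 4x5 toy vs exhaustive evaluation of the two predicates
  m3 <- rbind(a = c(3, 3, 3, 0, 1),  # sum 10, detected 4/5
              b = c(9, 0, 0, 0, 0),  # sum 9
              c = c(2, 2, 2, 2, 2),  # sum 10, detected 5/5
              d = c(20, 30, 0, 0, 0))  # sum 50, detected 3/5
  colnames(m3) <- paste0("s", 1:5)
  expected <- rownames(m3)[sapply(rownames(m3), function(g)
    sum(m3[g, ]) >= 10 && mean(m3[g, ] > 0) >= 0.8)]
  out3 <- suppressMessages(filter_consistent_mirnas(m3, 10, 0.8))
  expect_equal(rownames(out3), expected)
  expect_equal(expected, c("a", "c"))
})

test_that("size factors match hand computation and the brute-force oracle", {
  # identical columns -> unit factors, exactly
  m <- matrix(c(5, 10, 5, 10), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_equal(estimate_size_factors(m), c(s1 = 1, s2 = 1))

  # [[10,20],[30,60]]: geomeans sqrt(200), sqrt(1800); both ratios equal
  m2 <- matrix(c(10, 30, 20, 60), 2, 2,
               dimnames = list(c("g1", "g2"), c("s1", "s2")))
  sf <- estimate_size_factors(m2)
  expect_equal(round(unname(sf), 4), c(0.7071, 1.4142))

  set.seed(42)
  for (i in 1:30) {
    m3 <- random_count_matrix(5, 4)
    expect_equal(estimate_size_factors(m3), oracle_size_factors(m3),
                 tolerance = 1e-13)
  }
  # no all-positive gene -> error
  m4 <- matrix(c(0, 1, 1, 0), 2, 2,
               dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(estimate_size_factors(m4), "all-positive")
})

test_that("size factors are column-scale equivariant", {
  # scaling one column by k multiplies its factor relative to every other
  # column by exactly k (the geometric-mean reference absorbs k^(1/n), so
  # only factor ratios are identifiable)
  set.seed(7)
  for (i in 1:50) {
    m <- random_count_matrix(6, 5)
    k <- sample(2:5, 1)
    m2 <- m
    m2[, 3] <- m[, 3] * k
    sf <- estimate_size_factors(m)
    sf2 <- estimate_size_factors(m2)
    expect_equal(sf2[[3]] / sf2[-3], k * sf[[3]] / sf[-3],
                 tolerance = 1e-12)
    # the other columns keep their relative scaling among themselves
    expect_equal(sf2[-3] / sf2[[4]], sf[-3] / sf[[4]], tolerance = 1e-12)
  }
})

test_that("size factors agree with the DESeq2 median-of-log-ratios on odd gene counts", {
  skip_if_not_installed("DESeq2")
  set.seed(8)
  m <- random_count_matrix(9, 6)
  expect_equal(unname(estimate_size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-12)
})

test_that("log2 normalization applies the closed form", {
  m <- matrix(c(30, 0, 10, 20), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  am <- normalize_log2(m, c(s1 = 1.5, s2 = 1), pseudocount = 1)
  expect_equal(am["g1", "s1"], log2(21))
  expect_equal(am["g2", "s1"], 0)  # zero count at pseudocount 1
  # unit factors: elementwise log2(counts + 1)
  am2 <- normalize_log2(m, c(s1 = 1, s2 = 1))
  expect_equal(unclass(am2), log2(unclass(m) + 1), ignore_attr = TRUE)
  expect_true(attr(am2, "normalized"))
  expect_false(attr(am2, "batch_corrected"))
  expect_error(normalize_log2(m, c(s1 = 1)), "s2")
})

test_that("batch correction equalizes batch means, is idempotent, preserves within-batch structure", {
  set.seed(11)
  n <- 20
  base <- matrix(rnorm(n * 8, 10), n, 8,
                 dimnames = list(paste0("g", 1:n), paste0("s", 1:8)))
  delta <- rnorm(n, 2, 0.5)
  am <- base
  am[, 5:8] <- am[, 5:8] + delta  # planted per-gene shift
  attr(am, "normalized") <- TRUE
  sheet <- data.frame(sample_id = colnames(am),
                      batch = rep(c("b1", "b2"), each = 4), group = "HD")
  corr <- correct_batch(am, sheet)
  expect_true(attr(corr, "batch_corrected"))
  diffs <- rowMeans(corr[, 1:4]) - rowMeans(corr[, 5:8])
  expect_lt(max(abs(diffs)), 1e-9)
  # within-batch deviations unchanged
  expect_equal(corr[, 1:4] - rowMeans(corr[, 1:4]),
               am[, 1:4] - rowMeans(am[, 1:4]), ignore_attr = TRUE)
  # idempotence
  corr2 <- correct_batch(corr, sheet)
  expect_equal(unclass(corr2), unclass(corr), tolerance = 1e-12,
               ignore_attr = TRUE)
  # single batch: values unchanged
  sheet1 <- data.frame(sample_id = colnames(am), batch = "b1", group = "HD")
  same <- correct_batch(am, sheet1)
  expect_equal(unclass(same), unclass(am), ignore_attr = TRUE)
  # singleton batch: error
  sheetbad <- data.frame(sample_id = colnames(am),
                         batch = c(rep("b1", 7), "b2"), group = "HD")
  expect_error(correct_batch(am, sheetbad), "single sample")
})

test_that("batch correction matches limma on a balanced design", {
  skip_if_not_installed("limma")
  set.seed(12)
  am <- matrix(rnorm(60, 8), 10, 6,
               dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  attr(am, "normalized") <- TRUE
  batch <- rep(c("b1", "b2"), each = 3)
  sheet <- data.frame(sample_id = colnames(am), batch = batch, group = "HD")
  mine <- correct_batch(am, sheet)
  ref <- limma::removeBatchEffect(am, batch = batch)
  expect_equal(unclass(mine), unclass(ref), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("stability scores match a spreadsheet-style oracle", {
  set.seed(13)
  am <- matrix(rnorm(5 * 4, mean = 10, sd = 1), 5, 4,
               dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  attr(am, "normalized") <- TRUE
  attr(am, "batch_corrected") <- TRUE
  stab <- compute_stability(am)
  orc <- oracle_stability(am)
  expect_equal(stab$mean_abundance, orc$mean_abundance, tolerance = 1e-12)
  expect_equal(stab$cv_percent, orc$cv_percent, tolerance = 1e-12)
  expect_equal(stab$z_score, orc$z_score, tolerance = 1e-12)
})

test_that("equal-CV miRNAs rank by abundance; lower sd never lowers the score", {
  # two genes engineered to identical CV, one more abundant
  x <- c(-1, 0, 1)
  am <- rbind(lo = 10 + x, hi = 2 * (10 + x),  # CV identical by scaling
              f1 = 8 + 3 * x, f2 = 12 + 0.5 * x, f3 = 9 + 2 * x)
  colnames(am) <- paste0("s", 1:3)
  attr(am, "normalized") <- TRUE; attr(am, "batch_corrected") <- TRUE
  stab <- compute_stability(am)
  z <- setNames(stab$z_score, stab$gene_id)
  cv <- setNames(stab$cv_percent, stab$gene_id)
  expect_equal(cv[["lo"]], cv[["hi"]], tolerance = 1e-12)
  expect_gt(z[["hi"]], z[["lo"]])

  # shrinking one gene's sd (mean fixed) never decreases its z
  am2 <- am
  am2["f1", ] <- 8 + 1.5 * x
  stab2 <- compute_stability(am2)
  expect_gte(stab2$z_score[stab2$gene_id == "f1"], z[["f1"]])
})

test_that("a constant gene trips the degenerate-MAD guard only via CV MAD", {
  am <- rbind(a = c(10, 10, 10), b = c(10, 10, 10), c = c(10, 10, 10))
  colnames(am) <- paste0("s", 1:3)
  attr(am, "normalized") <- TRUE; attr(am, "batch_corrected") <- TRUE
  expect_error(compute_stability(am), "MAD")
  # one constant gene among variable ones gets CV 0, the lowest
  am2 <- rbind(const = c(10, 10, 10), v1 = c(8, 9, 10), v2 = c(5, 10, 15),
               v3 = c(7, 9, 11))
  colnames(am2) <- paste0("s", 1:3)
  attr(am2, "normalized") <- TRUE; attr(am2, "batch_corrected") <- TRUE
  stab <- compute_stability(am2)
  expect_equal(stab$cv_percent[stab$gene_id == "const"], 0)
  expect_equal(min(stab$cv_percent), 0)
})

test_that("ranking reproduces the published top-20 order and tie rules", {
  top20 <- published_top20()
  # re-rank from the printed scores alone
  reranked <- rank_select(stability_table(top20$gene_id,
                                          cv_percent = top20$cv_percent,
                                          z_score = top20$z_score),
                          top_n = 20)
  expect_equal(reranked$gene_id[4], "miR-26a-5p")
  expect_equal(reranked$rank, top20$rank)
  expect_equal(reranked$gene_id, top20$gene_id)
  # higher-CV miR-423-5p still outranks miR-22-3p on score
  expect_lt(match("miR-423-5p", reranked$gene_id),
            match("miR-22-3p", reranked$gene_id))
  # top_n beyond n returns everything
  expect_equal(nrow(rank_select(top20, top_n = 100)), 20)
  expect_error(rank_select(top20, top_n = 0), "top_n")
  # deterministic tie-break: equal z -> higher mean abundance first, then id
  tied <- stability_table(c("b", "a", "c"), mean_abundance = c(5, 9, 5),
                          cv_percent = c(1, 1, 1), z_score = c(2, 2, 2))
  expect_equal(rank_select(tied, 3)$gene_id, c("a", "b", "c"))
})

test_that("candidate selection skips oncomiRs and appends external picks", {
  top20 <- published_top20()
  cands <- suppressMessages(select_candidates(
    top20, n_candidates = 3, exclude = c("miR-21-5p", "miR-92a-3p")))
  expect_equal(cands, c("miR-486-5p", "miR-26a-5p", "miR-423-5p"))
  panel <- suppressMessages(select_candidates(
    top20, n_candidates = 3, exclude = c("miR-21-5p", "miR-92a-3p"),
    add_external = "miR-191-5p"))
  expect_equal(panel, c("miR-486-5p", "miR-26a-5p", "miR-423-5p",
                        "miR-191-5p"))
  # empty exclusion list: plain top-k prefix
  expect_equal(select_candidates(top20, 3), top20$gene_id[1:3])
  expect_error(suppressMessages(
    select_candidates(top20, 3, exclude = top20$gene_id)), "exclusion")
})

test_that("filters and scores are permutation-equivariant", {
  set.seed(21)
  sim <- simulate_counts(count_sim_config(n_genes = 40, n_samples = 12,
                                          n_batches = 2, seed = 3))
  cm <- sim$counts
  pg <- sample(nrow(cm)); ps <- sample(ncol(cm))
  perm <- cm[pg, ps]
  f1 <- suppressMessages(filter_consistent_mirnas(cm, 10, 0.8))
  f2 <- suppressMessages(filter_consistent_mirnas(perm, 10, 0.8))
  expect_setequal(rownames(f1), rownames(f2))
  sf1 <- estimate_size_factors(cm)
  sf2 <- estimate_size_factors(perm)
  expect_equal(sf2, sf1[colnames(perm)], tolerance = 1e-12)
  am <- normalize_log2(cm, sf1)
  stab1 <- compute_stability(am)
  amp <- normalize_log2(perm, sf2)
  stab2 <- compute_stability(amp)
  z1 <- setNames(stab1$z_score, stab1$gene_id)
  z2 <- setNames(stab2$z_score, stab2$gene_id)
  expect_equal(z2[names(z1)], z1, tolerance = 1e-12)
})
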