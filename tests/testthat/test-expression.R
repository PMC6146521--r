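mat <- function(x, genes = NULL, samples = NULL) {
  m <- as.matrix(x)
  rownames(m) <- genes %||% paste0("g", seq_len(nrow(m)))
  colnames(m) <- samples %||% paste0("s", seq_len(ncol(m)))
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("size factors reproduce the hand example and symmetry", {
  m <- mat(cbind(c(10, 30), c(20, 60)))
  expect_equal(unname(compute_size_factors(m)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)
  same <- mat(cbind(c(5, 8, 100), c(5, 8, 100)))
  expect_equal(unname(compute_size_factors(same)), c(1, 1))
})

test_that("size factors are scale-equivariant and agree with the DESeq2 reference", {
  set.seed(5)
  m <- mat(matrix(rnbinom(600, mu = 80, size = 5), nrow = 100))
  f <- compute_size_factors(m)
  m2 <- m; m2[, 3] <- m2[, 3] * 4
  f2 <- compute_size_factors(m2)
  # factors are defined up to the common geometric-mean scale, so scaling
  # one column by k multiplies its factor by k relative to the others
  expect_equal(unname(f2[3] / f2[1]), unname(4 * f[3] / f[1]),
               tolerance = 1e-12)
  expect_equal(unname(f2[2] / f2[1]), unname(f[2] / f[1]), tolerance = 1e-12)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(f), unname(ref), tolerance = 1e-8)
  all_zero_somewhere <- mat(cbind(c(0, 5), c(3, 0)))
  expect_error(compute_size_factors(all_zero_somewhere),
               class = "metlink_normalization_error")
})

test_that("size factors recover true library factors on null synthetic data", {
  cfg <- cohort_config(n_patients = 2L, pt_regions_per_patient = 1L,
                       n_genes = 2000L, burden_regime = "low",
                       coupling_delta = 0, nb_dispersion = 0.02,
                       patient_effect_sd = 0, library_size_sd = 0.4, seed = 99)
  co <- simulate_cohort(cfg)
  est <- compute_size_factors(co$counts)
  truth <- co$truth$size_factors[names(est)]
  # factors are identified up to a common scale; compare normalized versions
  est <- est / exp(mean(log(est)))
  truth <- truth / exp(mean(log(truth)))
  expect_gt(stats::cor(est, truth), 0.99)
  expect_lt(max(abs(est / truth - 1)), 0.05)
})

test_that("fold-change ranking drops double zeros and ranks deterministically", {
  m <- mat(cbind(c(10, 0, 4, 4, 0), c(5, 0, 4, 4, 8)),
           genes = c("gB", "gZ", "gC", "gA", "gD"),
           samples = c("tum", "nor"))
  rk <- pair_fold_change(m, "tum", "nor", pseudocount = 0.5)
  expect_false("gZ" %in% rk$gene)
  expect_equal(attr(rk, "dropped"), "gZ")
  expect_equal(rk$rank, seq_len(nrow(rk)))
  # hand-computed FCs: gB = 10.5/5.5, gC = gA = 1, gD = 0.5/8.5
  expect_equal(rk$gene, c("gB", "gA", "gC", "gD"))
  expect_equal(rk$fc, c(10.5 / 5.5, 1, 1, 0.5 / 8.5), tolerance = 1e-12)
  # identical columns give all-FC 1
  m2 <- mat(cbind(c(3, 7), c(3, 7)), samples = c("t", "n"))
  expect_true(all(pair_fold_change(m2, "t", "n")$fc == 1))
})

test_that("pairing is checked against the sample sheet", {
  m <- mat(cbind(c(3, 7), c(3, 8)), samples = c("t", "n"))
  ss <- data.frame(sample_id = c("t", "n"), patient_id = c("A", "B"))
  expect_error(pair_fold_change(m, "t", "n", sample_sheet = ss),
               class = "metlink_pairing_error")
})

test_that("FC ranking ignores a common scaling of the raw counts", {
  # distinct, well-separated fold changes and no zero counts: the ranking is
  # invariant to a common scaling of the raw counts (with ties or zeros only
  # the pseudocount and float rounding can perturb the tie-break order)
  set.seed(8)
  raw <- mat(cbind(sample(101:200), rep(100L, 100),
                   rep(50L, 100), rep(50L, 100)),
             samples = c("t1", "n1", "t2", "n2"))
  rk1 <- pair_fold_change(normalize_counts(raw), "t1", "n1")
  rk2 <- pair_fold_change(normalize_counts(raw * 3L), "t1", "n1")
  expect_equal(rk2$gene, rk1$gene)
  expect_equal(rk2$rank, rk1$rank)
})

test_that("bh_adjust reproduces the step-up formula", {
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "metlink_data_error")
  set.seed(13)
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"), tolerance = 1e-12)
  }
})

test_that("PCA QC flags a compositional outlier and respects the threshold", {
  set.seed(17)
  base <- matrix(rnbinom(100 * 8, mu = 100, size = 20), nrow = 100)
  m <- mat(base)
  # no outliers in a homogeneous matrix of identical columns
  same <- mat(matrix(rep(c(5, 50, 500), 4), nrow = 3))
  expect_length(pca_outlier_flags(same, n_components = 2), 0L)
  # a compositional outlier (half the genes up, half down) survives
  # normalization and is flagged
  out <- m
  out[1:50, 8] <- out[1:50, 8] * 20L
  out[51:100, 8] <- out[51:100, 8] %/% 20L
  flagged <- pca_outlier_flags(out, z_threshold = 3.5)
  expect_equal(flagged, "s8", ignore_attr = TRUE)
  expect_length(pca_outlier_flags(out, z_threshold = Inf), 0L)
  expect_error(pca_outlier_flags(out, n_components = 8),
               class = "metlink_usage_error")
  expect_error(pca_outlier_flags(mat(cbind(1:3, 2:4))),
               class = "metlink_usage_error")
})

test_that("term overrepresentation matches the hypergeometric tail", {
  universe <- paste0("g", 1:100)
  selected <- paste0("g", 1:10)
  term_map <- list(hit = paste0("g", 6:10),      # term inside the selection
                   cold = paste0("g", 90:94),    # disjoint from selection
                   tiny = paste0("g", 1:2))      # below the size bound
  res <- term_overrepresentation(selected, universe, term_map,
                                 min_term = 3, max_term_frac = 0.2)
  expect_false("tiny" %in% res$term)
  # enumeration oracle: P(overlap >= 5) drawing 10 of 100 with 5 marked
  p_exact <- sum(vapply(5:5, function(k) {
    choose(5, k) * choose(95, 10 - k) / choose(100, 10)
  }, numeric(1)))
  expect_equal(res$p[res$term == "hit"], p_exact, tolerance = 1e-12)
  expect_equal(res$count[res$term == "hit"], 5L)
  expect_equal(res$expected_count[res$term == "hit"], 5 * 10 / 100)
  expect_gt(res$p[res$term == "cold"], 0.5)
  expect_error(term_overrepresentation("gX", universe, term_map),
               class = "metlink_usage_error")
  expect_error(term_overrepresentation("g1", character(0), term_map),
               class = "metlink_usage_error")
})

test_that("term test agrees with fisher.test on random 2x2 setups", {
  set.seed(23)
  universe <- paste0("g", 1:200)
  for (i in 1:20) {
    selected <- sample(universe, 30)
    term <- sample(universe, sample(5:30, 1))
    res <- term_overrepresentation(selected, universe, list(t = term),
                                   max_term_frac = 0.5)
    k <- length(intersect(term, selected))
    tab <- matrix(c(k, length(term) - k,
                    30 - k, 200 - length(term) - 30 + k), 2)
    ref <- stats::fisher.test(tab, alternative = "greater")$p.value
    expect_equal(res$p, ref, tolerance = 1e-9)
  }
})
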