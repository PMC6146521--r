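ranking_of <- function(genes, fc = rev(seq_along(genes)), tumour = "S1",
                       normal = "S0") {
  m <- matrix(c(fc * 10, rep(10, length(genes))), ncol = 2,
              dimnames = list(genes, c(tumour, normal)))
  rk <- data.table::data.table(gene = genes, fc = fc)
  data.table::setorderv(rk, c("fc", "gene"), order = c(-1L, 1L))
  rk[, rank := seq_len(.N)]
  data.table::setattr(rk, "tumour_sample", tumour)
  data.table::setattr(rk, "normal_sample", normal)
  data.table::setattr(rk, "class", c("fc_ranking", class(rk)))
  rk[]
}

test_that("associate collapses to genes, excludes intergenic, applies min_altered", {
  genes <- paste0("g", 1:20)
  rk <- ranking_of(genes)
  v <- rbind(
    toy_variants(3, pos = 1:3, gene = "g1", sample_id = "S1"),   # one gene, 3 records
    toy_variants(1, pos = 4L, gene = NA_character_, sample_id = "S1",
                 func_region = "intergenic", exonic_func = "none"),
    toy_variants(1, pos = 5L, gene = "g2", sample_id = "S1"),
    toy_variants(1, pos = 6L, gene = "g9", sample_id = "OTHER"))  # wrong sample
  r <- associate(rk, v, "non_silent", min_altered = 3L)
  expect_false(r$tested)           # only 2 altered genes: g1, g2
  expect_equal(r$n_altered, 2L)
  r2 <- associate(rk, v, "non_silent", min_altered = 2L)
  expect_true(r2$tested)
  expect_equal(r2$n_unaltered, 18L)

  # no altered genes at all -> not tested
  r0 <- associate(rk, v[0], "stopgain")
  expect_false(r0$tested)

  # every gene altered -> no comparison group
  v_all <- toy_variants(20, pos = 1:20, gene = genes, sample_id = "S1")
  expect_error(associate(rk, v_all, "non_silent"),
               class = "metlink_usage_error")
})

test_that("associate reproduces the KS test on the rank partition", {
  genes <- paste0("g", sprintf("%02d", 1:8))
  rk <- ranking_of(genes)
  # altered genes occupy ranks 1..3 (highest FC)
  v <- toy_variants(3, pos = 1:3, gene = rk$gene[rk$rank <= 3], sample_id = "S1")
  r <- associate(rk, v, "non_silent")
  oracle <- oracle_ks(1:3, 4:8)
  expect_equal(r$D, oracle$D, tolerance = 1e-12)
  expect_equal(r$p, oracle$p, tolerance = 1e-12)
})

test_that("the -log10 sentinel and significance flag behave", {
  set.seed(2)
  genes <- paste0("g", sprintf("%03d", 1:400))
  rk <- ranking_of(genes)
  v <- toy_variants(30, pos = 1:30, gene = rk$gene[rk$rank <= 30],
                    sample_id = "S1")
  r <- associate(rk, v, "non_silent")
  expect_true(r$significant)
  expect_gt(r$neglog10p, 10)
  expect_equal(r$display, "Inf")
  expect_equal(r$significant, r$neglog10p > -log10(0.05))
})

test_that("association is invariant to monotone transforms of FC", {
  set.seed(4)
  genes <- paste0("g", sprintf("%03d", 1:50))
  fc <- sort(runif(50, 0.1, 10), decreasing = TRUE)
  rk1 <- ranking_of(genes, fc)
  rk2 <- ranking_of(genes, fc^2)        # strictly increasing transform
  v <- toy_variants(8, pos = 1:8, gene = sample(genes, 8), sample_id = "S1")
  r1 <- associate(rk1, v, "non_silent")
  r2 <- associate(rk2, v, "non_silent")
  expect_equal(r1$D, r2$D)
  expect_equal(r1$p, r2$p)
})

test_that("matrix assembly honours exclusions and missing rankings", {
  genes <- paste0("g", 1:30)
  rks <- list(S1 = ranking_of(genes, tumour = "S1"),
              S2 = ranking_of(genes, tumour = "S2"))
  v <- rbind(toy_variants(5, pos = 1:5, gene = genes[1:5], sample_id = "S1"),
             toy_variants(4, pos = 6:9, gene = genes[6:9], sample_id = "S2"))
  am <- build_association_matrix(rks, v, classes = c("non_silent", "stopgain"))
  expect_equal(dim(am$wide), c(2L, 2L))
  expect_equal(colnames(am$wide), c("S1", "S2"))
  expect_equal(am$results$tested,
               c(TRUE, FALSE, TRUE, FALSE))  # stopgain cells lack members
  am2 <- build_association_matrix(rks, v, classes = "non_silent",
                                  exclude_samples = "S2")
  expect_equal(colnames(am2$wide), "S1")
  rks$S3 <- NULL
  rks_with_null <- c(rks, list(S3 = NULL))
  expect_warning(build_association_matrix(rks_with_null, v,
                                          classes = "non_silent"),
                 "no fold-change ranking")
  expect_error(build_association_matrix(rks, v, classes = "bogus"),
               class = "metlink_usage_error")
})
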