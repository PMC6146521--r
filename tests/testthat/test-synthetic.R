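test_that("configuration is validated", {
  expect_error(cohort_config(n_patients = 2), class = "metlink_config_error")  # no seed
  expect_error(cohort_config(seed = 1, n_genes = 5), class = "metlink_config_error")
  expect_error(cohort_config(seed = 1, pt_regions_per_patient = 7),
               class = "metlink_config_error")
  bad_spec <- default_weights <- metlink:::default_spectrum_weights()
  bad_spec[1] <- bad_spec[1] + 0.01
  expect_error(cohort_config(seed = 1, spectrum_weights = bad_spec),
               class = "metlink_config_error")
  cfg <- cohort_config(seed = 1)
  expect_equal(sum(cfg$spectrum_weights), 1, tolerance = 1e-12)
  expect_equal(sum(cfg$functional_class_mix), 1, tolerance = 1e-12)
})

test_that("default spectrum weights encode the stated pair and change ratios", {
  w <- metlink:::default_spectrum_weights()
  cg <- sum(w[c("C>A", "C>G", "C>T", "G>A", "G>C", "G>T")])
  ts <- sum(w[c("C>T", "G>A", "A>G", "T>C")])
  expect_equal(cg / (1 - cg), 9, tolerance = 1e-12)
  expect_equal((1 - ts) / ts, 3, tolerance = 1e-12)
})

test_that("simulation is deterministic and structured per patient", {
  cfg <- small_cohort_config(seed = 321)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$variants, b$variants)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth$coupling, b$truth$coupling)

  ss <- a$samples
  for (p in unique(ss$patient_id)) {
    roles <- ss$role[ss$patient_id == p]
    expect_equal(sum(roles == "N"), 1L)
    expect_equal(sum(roles == "MT"), 1L)
    expect_gte(sum(roles == "PT"), 1L)
  }
  expect_equal(sum(ss$role == "PT"), sum(cfg$pt_regions_per_patient))
  expect_equal(dim(a$counts), c(cfg$n_genes, nrow(ss)))
})

test_that("true EMVs are absent from every PT region of their patient", {
  co <- simulate_cohort(small_cohort_config(seed = 11))
  tv <- co$truth$variants
  for (p in unique(tv$patient_id)) {
    pt_samples <- co$samples$sample_id[co$samples$patient_id == p &
                                         co$samples$role == "PT"]
    emv_keys <- unique(variant_key(tv[tv$patient_id == p & tv$is_emv]))
    pt_keys <- variant_key(tv[tv$sample_id %in% pt_samples])
    expect_length(intersect(emv_keys, pt_keys), 0L)
    expect_gt(length(emv_keys), 0L)
  }
})

test_that("common_variant_rate = 0 yields no population frequency above 1%", {
  co <- simulate_cohort(small_cohort_config(seed = 12, common_variant_rate = 0))
  v <- co$variants
  for (cl in c("exac_all", "esp6500_all", "kg_all", "kg_eur")) {
    expect_true(all(is.na(v[[cl]]) | v[[cl]] <= 0.01))
  }
})

test_that("empirical spectrum recovers the configured weights", {
  cfg <- cohort_config(n_patients = 1L, pt_regions_per_patient = 1L,
                       n_genes = 2000L, burden_regime = "high",
                       fail_evidence_rate = 0, common_variant_rate = 0,
                       seed = 77)
  # pool several simulated samples to pass 10,000 SNVs
  snvs <- list()
  for (s in c(77, 78, 79)) {
    cfg$seed <- s
    co <- simulate_variant_tables(cfg)
    v <- co$variants
    snvs[[as.character(s)]] <- v[v$variant_type == "SNV"]
  }
  v <- data.table::rbindlist(snvs)
  expect_gt(nrow(v), 10000)
  sp <- summarize_spectrum(v)
  tv_ts <- sp$transversions / sp$transitions
  expect_lt(abs(tv_ts - 3) / 3, 0.1)
  cg_at <- sp$cg_pair_mutations / sp$at_pair_mutations
  expect_lt(abs(cg_at - 9) / 9, 0.25)
  observed <- sp$substitutions
  gof <- stats::chisq.test(observed, p = cfg$spectrum_weights)
  expect_gt(gof$p.value, 0.01)
})

test_that("burden targets respect the regime intervals", {
  co <- simulate_cohort(cohort_config(n_patients = 2L,
                                      pt_regions_per_patient = 1L,
                                      n_genes = 500L,
                                      burden_regime = c("low", "high"),
                                      fail_evidence_rate = 0,
                                      common_variant_rate = 0, seed = 31))
  v <- co$variants
  counts <- table(v$sample_id)
  low_samples <- co$samples$sample_id[co$samples$patient_id == "P01" &
                                        co$samples$role != "N"]
  high_samples <- co$samples$sample_id[co$samples$patient_id == "P02" &
                                         co$samples$role != "N"]
  expect_true(all(counts[low_samples] >= 54 & counts[low_samples] <= 306))
  expect_true(all(counts[high_samples] >= 1490 & counts[high_samples] <= 3029))
})

test_that("counts carry the configured coupling", {
  # null coupling: every recorded shift is zero
  co0 <- simulate_cohort(small_cohort_config(seed = 41, coupling_delta = 0))
  expect_true(nrow(co0$truth$coupling) == 0L ||
                all(co0$truth$coupling$log2fc_shift == 0))
  # strong coupling, no noise: empirical mean log2 FC of coupled genes
  cfg <- cohort_config(n_patients = 1L, pt_regions_per_patient = 1L,
                       n_genes = 2000L, burden_regime = "low",
                       coupling_delta = 2, coupling_fraction = 1,
                       nb_dispersion = 0, patient_effect_sd = 0,
                       library_size_sd = 0, seed = 7)
  co <- simulate_cohort(cfg)
  norm <- normalize_counts(co$counts)
  rk <- pair_fold_change(norm, "P01.MT", "P01.N", sample_sheet = co$samples)
  coupled <- co$truth$coupling$gene[co$truth$coupling$sample_id == "P01.MT"]
  lfc <- log2(rk$fc[rk$gene %in% coupled])
  expect_equal(mean(lfc), 2, tolerance = 0.1 / 2)  # within +-0.1 of 2.0
})

test_that("fixtures round-trip losslessly and tolerate an empty cohort", {
  co <- simulate_cohort(small_cohort_config(seed = 55))
  d <- withr::local_tempdir()
  write_fixtures(co, d)
  back <- read_fixtures(d)
  expect_identical(back$counts, structure(co$counts, size_factors = NULL,
                                          coupling = NULL))
  va <- data.table::copy(co$variants)
  data.table::setorderv(va, c("sample_id", "chrom", "pos"))
  expect_equal(as.data.frame(back$variants), as.data.frame(va))
  expect_equal(as.data.frame(back$samples), as.data.frame(co$samples))
  expect_equal(back$config, co$config)
  expect_equal(back$truth$size_factors, co$truth$size_factors)

  empty <- simulate_cohort(cohort_config(n_patients = 0L, n_genes = 50L,
                                         seed = 9))
  d2 <- withr::local_tempdir()
  expect_no_error(write_fixtures(empty, d2))
  back2 <- read_fixtures(d2)
  expect_equal(nrow(back2$variants), 0L)
  expect_equal(ncol(back2$counts), 0L)
})
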