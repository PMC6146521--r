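make_pss <- function(mt_keys, pt_keys_list, patient = "P1") {
  to_set <- function(keys) {
    if (length(keys) == 0L) return(toy_variants(0))
    toy_variants(length(keys), pos = keys, gene = paste0("G", keys %% 5))
  }
  pts <- paste0(patient, ".PT", seq_along(pt_keys_list))
  sets <- c(lapply(pt_keys_list, to_set), list(to_set(mt_keys)))
  names(sets) <- c(pts, paste0(patient, ".MT"))
  patient_sample_set(patient, paste0(patient, ".N"), pts,
                     paste0(patient, ".MT"), sets)
}

test_that("EMV is the MT set minus the union of all PT regions", {
  p <- make_pss(mt_keys = c(1L, 2L, 3L, 4L),
                pt_keys_list = list(c(2L, 9L), c(8L), c(3L, 7L)))
  emv <- derive_emv(p)
  expect_setequal(emv$pos, c(1L, 4L))
  # empty MT set
  expect_equal(nrow(derive_emv(make_pss(integer(0), list(1:3)))), 0L)
  # MT-only variant is exclusive even when PT sets are empty
  expect_equal(derive_emv(make_pss(5L, list(integer(0))))$pos, 5L)
})

test_that("EMV invariants hold and match brute force on random cohorts", {
  for (seed in 1:60) {
    cohort <- random_identity_cohort(seed)
    for (p in cohort) {
      emv <- derive_emv(p)
      mt_keys <- variant_key(p$variant_sets[[p$mt_sample]])
      pt_keys <- unlist(lapply(p$pt_samples, function(s) {
        variant_key(p$variant_sets[[s]])
      }))
      # brute force: test each MT variant against every PT region
      brute <- mt_keys[vapply(mt_keys, function(k) !k %in% pt_keys, logical(1))]
      expect_setequal(variant_key(emv), brute)
      expect_true(all(variant_key(emv) %in% mt_keys))
      expect_length(intersect(variant_key(emv), pt_keys), 0L)
    }
  }
})

test_that("recurrence collapses per patient and matches hand enumeration", {
  # one variant in 3 samples of one patient counts once
  p1 <- make_pss(mt_keys = 10L, pt_keys_list = list(10L, 10L), patient = "P1")
  # the same identity in two other patients
  p2 <- make_pss(mt_keys = c(10L, 11L), pt_keys_list = list(12L), patient = "P2")
  p3 <- make_pss(mt_keys = integer(0), pt_keys_list = list(c(10L, 12L)),
                 patient = "P3")
  rec <- cross_patient_recurrence(list(p1, p2, p3))
  vr <- rec$variant_recurrence
  expect_equal(vr$n_patients[vr$pos == 10L], 3L)
  expect_equal(vr$n_patients[vr$pos == 11L], 1L)
  expect_equal(vr$n_patients[vr$pos == 12L], 2L)
  expect_error(cross_patient_recurrence(list(p1, p1)),
               class = "metlink_data_error")
})

test_that("recurrence matches brute force and ignores sample order/duplication", {
  for (seed in 1:40) {
    cohort <- random_identity_cohort(seed + 1000)
    rec <- cross_patient_recurrence(cohort)$variant_recurrence
    counts <- new.env(parent = emptyenv())
    for (p in cohort) {
      keys <- unique(unlist(lapply(c(p$pt_samples, p$mt_sample), function(s) {
        variant_key(p$variant_sets[[s]])
      })))
      for (k in keys) assign(k, (mget(k, counts, ifnotfound = 0)[[1]]) + 1, counts)
    }
    got <- stats::setNames(rec$n_patients, variant_key(rec))
    for (k in ls(counts)) expect_equal(unname(got[k]), get(k, counts))
    expect_equal(length(got), length(ls(counts)))

    # duplicating records within a sample must not change counts
    dup <- lapply(cohort, function(p) {
      p$variant_sets[[p$mt_sample]] <-
        rbind(p$variant_sets[[p$mt_sample]], p$variant_sets[[p$mt_sample]])
      p
    })
    expect_equal(cross_patient_recurrence(dup)$variant_recurrence, rec)
  }
})

test_that("gene rates normalize by length and rank deterministically", {
  v <- rbind(
    toy_variants(2, pos = c(1L, 2L), gene = "GA"),
    toy_variants(3, pos = c(3L, 4L, 5L), gene = "GB"),
    toy_variants(1, pos = 6L, gene = "GC"))
  gl <- data.frame(gene = c("GA", "GB", "GC", "GD"),
                   length_bp = c(1000, 3000, 500, 800))
  r <- gene_mutation_rates(v, gl)
  expect_equal(r$rate_per_kb[r$gene == "GA"], 2.0)
  expect_equal(r$rate_per_kb[r$gene == "GB"], 1.0)
  expect_equal(r$rate_per_kb[r$gene == "GC"], 2.0)
  expect_equal(r$rate_per_kb[r$gene == "GD"], 0.0)
  # duplicate identities count once; ties break lexicographically
  r2 <- gene_mutation_rates(rbind(v, v), gl)
  expect_equal(r2$rate_per_kb, r$rate_per_kb)
  expect_equal(r$gene[1:2], c("GA", "GC"))
  expect_warning(gene_mutation_rates(toy_variants(1, gene = "GX"), gl),
                 "absent from the length table")
  expect_error(gene_mutation_rates(v, data.frame(gene = "GA", length_bp = 0)),
               class = "metlink_data_error")
})
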