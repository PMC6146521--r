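# Builders for small in-code fixtures and independent brute-force oracles.

toy_variants <- function(n = 1L, ...) {
  base <- data.table::data.table(
    patient_id = "P1", sample_id = "S1", chrom = "chrS",
    pos = seq_len(n) * 100L, ref = "C", alt = "T", variant_type = "SNV",
    depth = 100L, alt_forward = 25L, alt_reverse = 25L,
    allele_fraction = 0.5, zygosity = "het", gene = "GENE1",
    func_region = "exonic", exonic_func = "nonsynonymous",
    exac_all = NA_real_, esp6500_all = NA_real_, kg_all = NA_real_,
    kg_eur = NA_real_)
  overrides <- list(...)
  for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
  base
}

# The 10-variant cascade fixture: 3 fail depth, 2 fail one strand, 1 common
# (ExAC 5%), 1 homozygote at ExAC 60%, 3 clean.
cascade_fixture <- function() {
  v <- toy_variants(10L, gene = paste0("G", 1:10))
  v$depth[1:3] <- c(19L, 10L, 5L)
  v$alt_forward[1:3] <- c(5L, 3L, 2L)
  v$alt_reverse[1:3] <- c(5L, 3L, 2L)
  v$alt_forward[4] <- 3L          # strand failure, forward
  v$alt_reverse[5] <- 0L          # strand failure, reverse
  v$exac_all[6] <- 0.05           # common in population
  v$exac_all[7] <- 0.6            # common homozygote
  v$zygosity[7] <- "hom_alt"
  v
}

random_variant_table <- function(n, seed) {
  set.seed(seed)
  data.table::data.table(
    patient_id = "P1", sample_id = "S1", chrom = "chrS",
    pos = sample.int(1e6, n), ref = "C",
    alt = sample(c("T", "A", "G"), n, replace = TRUE),
    variant_type = sample(c("SNV", "insertion", "deletion"), n,
                          replace = TRUE, prob = c(0.8, 0.1, 0.1)),
    depth = sample(5:60, n, replace = TRUE),
    alt_forward = sample(0:15, n, replace = TRUE),
    alt_reverse = sample(0:15, n, replace = TRUE),
    allele_fraction = stats::runif(n),
    zygosity = sample(c("het", "hom_alt"), n, replace = TRUE, prob = c(0.8, 0.2)),
    gene = sample(paste0("G", 1:20), n, replace = TRUE),
    func_region = sample(FUNC_REGIONS_T, n, replace = TRUE),
    exonic_func = sample(c("nonsynonymous", "synonymous", "stopgain", "none"),
                         n, replace = TRUE),
    exac_all = ifelse(stats::runif(n) < 0.4, NA, stats::runif(n, 0, 0.8)),
    esp6500_all = ifelse(stats::runif(n) < 0.6, NA, stats::runif(n, 0, 0.05)),
    kg_all = NA_real_, kg_eur = NA_real_)
}

FUNC_REGIONS_T <- c("exonic", "intronic", "splicing", "UTR3", "UTR5",
                    "intergenic")

# Independent record-by-record reapplication of the four filter rules.
brute_force_filter <- function(v, min_af = 0.1, min_depth = 20,
                               min_strand = 4, max_af = 0.01, hom_af = 0.5) {
  keep <- logical(nrow(v))
  for (i in seq_len(nrow(v))) {
    r <- as.list(v[i])
    af_ok <- if (r$variant_type == "SNV") r$allele_fraction >= min_af else TRUE
    ev_ok <- r$depth >= min_depth && r$alt_forward >= min_strand &&
      r$alt_reverse >= min_strand
    pops <- c(r$exac_all, r$esp6500_all, r$kg_all, r$kg_eur)
    pops[is.na(pops)] <- 0
    common <- any(pops > max_af) ||
      (r$zygosity == "hom_alt" && pops[1] > hom_af)
    keep[i] <- af_ok && ev_ok && !common
  }
  keep
}

# Exhaustive KS oracle: D from the two ECDFs on the pooled grid, exact
# two-sided p by enumerating every label assignment of the pooled values.
oracle_ks <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  ecdf_at <- function(x, g) vapply(g, function(t) mean(x <= t), numeric(1))
  d_of <- function(x, y) max(abs(ecdf_at(x, grid) - ecdf_at(y, grid)))
  d_obs <- d_of(a, b)
  pooled <- c(a, b)
  n <- length(a)
  picks <- utils::combn(length(pooled), n)
  ds <- apply(picks, 2L, function(idx) d_of(pooled[idx], pooled[-idx]))
  list(D = d_obs, p = mean(ds >= d_obs - 1e-12))
}

# Small random multi-patient cohorts of bare variant identities, for the
# set-algebra brute-force checks.
random_identity_cohort <- function(seed, n_patients = 3L) {
  set.seed(seed)
  universe <- sprintf("chrS:%d:C:T", sample.int(500, 40))
  make_set <- function() {
    ids <- sample(universe, sample(0:12, 1))
    if (length(ids) == 0L) {
      return(toy_variants(0L))
    }
    parts <- data.table::tstrsplit(ids, ":", fixed = TRUE)
    toy_variants(length(ids), pos = as.integer(parts[[2]]),
                 gene = paste0("G", as.integer(parts[[2]]) %% 7))
  }
  lapply(seq_len(n_patients), function(i) {
    k <- sample(1:3, 1)
    pts <- paste0("P", i, ".PT", seq_len(k))
    sets <- c(lapply(seq_len(k), function(j) make_set()),
              list(make_set()))
    names(sets) <- c(pts, paste0("P", i, ".MT"))
    patient_sample_set(paste0("P", i), paste0("P", i, ".N"), pts,
                       paste0("P", i, ".MT"), sets)
  })
}

small_cohort_config <- function(seed, ...) {
  cohort_config(n_patients = 2L, pt_regions_per_patient = c(2L, 1L),
                n_genes = 200L, burden_regime = "low", seed = seed, ...)
}
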