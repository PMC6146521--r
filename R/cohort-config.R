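# Configuration of the synthetic matched-cohort generator.

FUNCTIONAL_CLASSES <- c("nonsynonymous", "synonymous", "stopgain", "stoploss",
                        "frameshift_indel", "nonframeshift_indel", "intronic",
                        "UTR3", "UTR5", "intergenic", "splicing")

BURDEN_INTERVALS <- list(low = c(54L, 306L), high = c(1490L, 3029L))

# Default substitution-type weights: C:G-pair mutations 9x A:T-pair and
# transversions 3x transitions, split evenly within each (pair, change)
# stratum.
default_spectrum_weights <- function(cg_over_at = 9, tv_over_ts = 3) {
  cg <- cg_over_at / (1 + cg_over_at)
  tv <- tv_over_ts / (1 + tv_over_ts)
  w <- c("C>T" = cg * (1 - tv) / 2, "G>A" = cg * (1 - tv) / 2,
         "C>A" = cg * tv / 4, "C>G" = cg * tv / 4,
         "G>C" = cg * tv / 4, "G>T" = cg * tv / 4,
         "A>G" = (1 - cg) * (1 - tv) / 2, "T>C" = (1 - cg) * (1 - tv) / 2,
         "A>C" = (1 - cg) * tv / 4, "A>T" = (1 - cg) * tv / 4,
         "T>A" = (1 - cg) * tv / 4, "T>G" = (1 - cg) * tv / 4)
  w[SUBSTITUTION_TYPES]
}

# Default functional-class mix echoing the observed filtered-variant
# composition (~46% exonic, 14.5% intronic, 11.6% 3'UTR); categories this
# generator does not model (upstream/downstream/ncRNA) are folded into
# "intergenic".
default_functional_mix <- function() {
  c(nonsynonymous = 0.290, synonymous = 0.114, stopgain = 0.026,
    stoploss = 0.003, frameshift_indel = 0.025, nonframeshift_indel = 0.022,
    intronic = 0.145, UTR3 = 0.116, UTR5 = 0.035, intergenic = 0.214,
    splicing = 0.010)
}

#' Synthetic cohort configuration
#'
#' Describes a matched cohort: `n_patients` patients, each with one normal,
#' one metastasis and `pt_regions_per_patient` primary-tumour regions
#' (1-6); per-patient mutation-burden regimes with target filtered-variant
#' counts drawn from the low (54-306) or high (1490-3029) interval; a
#' substitution spectrum; a functional-class mix; per-site sequencing
#' evidence models; and a mutation-to-expression coupling with mean log2
#' fold-change shift `coupling_delta` applied to a fraction
#' `coupling_fraction` of the genes carrying a non-silent mutation in a
#' tumour sample.
#'
#' @param n_patients Number of patients.
#' @param pt_regions_per_patient Integer (recycled) or vector per patient,
#'   each in 1..6.
#' @param n_genes Number of genes (>= 10).
#' @param burden_regime `"low"` / `"high"` per patient (recycled).
#' @param spectrum_weights Probabilities over the 12 ref>alt SNV types.
#' @param functional_class_mix Probabilities over the 11 functional classes.
#' @param depth_mean,depth_dispersion Negative-binomial per-site depth model
#'   (mean 100 by default, matching typical exome coverage).
#' @param strand_split Probability a non-reference read maps forward.
#' @param allele_fraction_model List with `p_hom`, `p_clonal`,
#'   `hom_shape`, `clonal_shape`, `subclonal_shape` (beta parameters).
#' @param common_variant_rate Fraction of injected variants given a
#'   population allele frequency above 1%.
#' @param fail_evidence_rate Extra variants injected per sample, as a
#'   fraction of the burden target, whose evidence fails the cascade.
#' @param emv_fraction Fraction of a metastasis' variants absent from every
#'   PT region of the same patient (true exclusive metastatic variants).
#' @param coupling_delta Mean log2 fold-change shift for coupled genes.
#' @param coupling_fraction Fraction of non-silently mutated genes coupled.
#' @param nb_dispersion Negative-binomial expression dispersion (0 =
#'   Poisson).
#' @param patient_effect_sd Log-scale SD of the multiplicative patient
#'   effect on expression means.
#' @param library_size_sd Log-scale SD of per-sample library-size factors.
#' @param seed Integer seed (mandatory; below 2^31).
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 7L,
                          pt_regions_per_patient = c(6L, 4L, 1L, 1L, 2L, 3L, 5L),
                          n_genes = 2000L,
                          burden_regime = c("low", "high", "low", "high",
                                            "low", "low", "high"),
                          spectrum_weights = default_spectrum_weights(),
                          functional_class_mix = default_functional_mix(),
                          depth_mean = 100,
                          depth_dispersion = 8,
                          strand_split = 0.5,
                          allele_fraction_model = list(
                            p_hom = 0.08, p_clonal = 0.7,
                            hom_shape = c(45, 5), clonal_shape = c(18, 18),
                            subclonal_shape = c(6, 18)),
                          common_variant_rate = 0.05,
                          fail_evidence_rate = 0.3,
                          emv_fraction = 0.3,
                          coupling_delta = 1,
                          coupling_fraction = 0.25,
                          nb_dispersion = 0.1,
                          patient_effect_sd = 0.25,
                          library_size_sd = 0.3,
                          seed) {
  if (missing(seed) || !is_count(seed) || abs(seed) >= 2^31 - 10) {
    ml_config_error("an integer seed below 2^31 is mandatory")
  }
  if (!is_count(n_patients) || n_patients < 0) {
    ml_config_error("n_patients must be a non-negative integer")
  }
  if (!is_count(n_genes) || n_genes < 10) {
    ml_config_error("n_genes must be an integer >= 10")
  }
  pt <- as.integer(rep_len(pt_regions_per_patient, max(n_patients, 1L)))
  if (n_patients > 0 && (any(pt < 1L) || any(pt > 6L))) {
    ml_config_error("pt_regions_per_patient must lie in 1..6")
  }
  regime <- rep_len(as.character(burden_regime), max(n_patients, 1L))
  if (n_patients > 0 && !all(regime %in% names(BURDEN_INTERVALS))) {
    ml_config_error("burden_regime entries must be 'low' or 'high'")
  }
  if (!setequal(names(spectrum_weights), SUBSTITUTION_TYPES)) {
    ml_config_error("spectrum_weights must be named by the 12 substitution types")
  }
  spectrum_weights <- spectrum_weights[SUBSTITUTION_TYPES]
  check_prob_vector(spectrum_weights, "spectrum_weights")
  if (!setequal(names(functional_class_mix), FUNCTIONAL_CLASSES)) {
    ml_config_error("functional_class_mix must be named by the 11 functional classes")
  }
  functional_class_mix <- functional_class_mix[FUNCTIONAL_CLASSES]
  check_prob_vector(functional_class_mix, "functional_class_mix")
  for (fr in c(strand_split, common_variant_rate, emv_fraction,
               coupling_fraction)) {
    if (!is_fraction(fr)) ml_config_error("rates and fractions must lie in [0, 1]")
  }
  if (depth_mean <= 0 || depth_dispersion <= 0 || nb_dispersion < 0 ||
      fail_evidence_rate < 0 || patient_effect_sd < 0 || library_size_sd < 0) {
    ml_config_error("scale parameters must be non-negative (depth model positive)")
  }
  afm <- allele_fraction_model
  if (!all(c("p_hom", "p_clonal", "hom_shape", "clonal_shape",
             "subclonal_shape") %in% names(afm))) {
    ml_config_error("allele_fraction_model is missing components")
  }
  structure(
    list(n_patients = as.integer(n_patients),
         pt_regions_per_patient = if (n_patients > 0) pt[seq_len(n_patients)] else integer(0),
         n_genes = as.integer(n_genes),
         burden_regime = if (n_patients > 0) regime[seq_len(n_patients)] else character(0),
         spectrum_weights = spectrum_weights,
         functional_class_mix = functional_class_mix,
         depth_mean = depth_mean,
         depth_dispersion = depth_dispersion,
         strand_split = strand_split,
         allele_fraction_model = afm,
         common_variant_rate = common_variant_rate,
         fail_evidence_rate = fail_evidence_rate,
         emv_fraction = emv_fraction,
         coupling_delta = coupling_delta,
         coupling_fraction = coupling_fraction,
         nb_dispersion = nb_dispersion,
         patient_effect_sd = patient_effect_sd,
         library_size_sd = library_size_sd,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}
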