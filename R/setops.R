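# Multi-sample set algebra: patient sample sets, metastasis-exclusive
# variants, cross-patient recurrence, length-normalized gene rates.

#' Patient sample set
#'
#' Groups one patient's samples (one normal, 1-6 primary-tumour regions, one
#' metastasis) together with the per-sample post-cascade variant sets.
#'
#' @param patient_id Patient identifier.
#' @param normal_sample,mt_sample Sample ids of the matched normal and the
#'   metastasis.
#' @param pt_samples Character vector of primary-tumour region sample ids
#'   (non-empty, at most 6).
#' @param variant_sets Named list (by sample id) of filtered variant tables;
#'   tumour samples must be present, the normal may be absent or empty.
#' @return Object of class `patient_sample_set`.
#' @export
patient_sample_set <- function(patient_id, normal_sample, pt_samples,
                               mt_sample, variant_sets) {
  if (length(mt_sample) != 1L || is.na(mt_sample)) {
    ml_data_error(paste0("patient ", patient_id, " needs exactly one metastasis sample"))
  }
  if (length(normal_sample) != 1L) {
    ml_data_error(paste0("patient ", patient_id, " needs exactly one normal sample"))
  }
  if (length(pt_samples) < 1L) {
    ml_data_error(paste0("patient ", patient_id, " needs at least one PT region"))
  }
  missing_sets <- setdiff(c(pt_samples, mt_sample), names(variant_sets))
  if (length(missing_sets)) {
    ml_data_error(paste0("patient ", patient_id, " lacks variant sets for: ",
                         paste(missing_sets, collapse = ", ")))
  }
  structure(
    list(patient_id = patient_id,
         normal_sample = normal_sample,
         pt_samples = pt_samples,
         mt_sample = mt_sample,
         variant_sets = variant_sets),
    class = "patient_sample_set"
  )
}

#' Build patient sample sets from a filtered-variant table and sample sheet
#'
#' @param variants Filtered variant table (all tumour samples).
#' @param sample_sheet data.frame with `sample_id`, `patient_id`, `role`
#'   (`N`, `PT`, `MT`) and `region_index`.
#' @return Named list of [patient_sample_set()] objects.
#' @export
make_patient_sets <- function(variants, sample_sheet) {
  v <- data.table::as.data.table(variants)
  ss <- data.table::as.data.table(sample_sheet)
  out <- lapply(split(ss, ss$patient_id), function(p) {
    sets <- split(v[v$sample_id %in% p$sample_id], by = "sample_id")
    for (s in setdiff(p$sample_id, names(sets))) {
      sets[[s]] <- v[0L]
    }
    patient_sample_set(
      patient_id = p$patient_id[1L],
      normal_sample = p$sample_id[p$role == "N"],
      pt_samples = p$sample_id[p$role == "PT"][order(p$region_index[p$role == "PT"])],
      mt_sample = p$sample_id[p$role == "MT"],
      variant_sets = sets
    )
  })
  out[order(names(out))]
}

#' Exclusive metastatic variants (EMV)
#'
#' Variants of the metastasis set absent, by identity (chrom, pos, ref,
#' alt), from every primary-tumour region of the same patient.  A site that
#' is heterozygous in a PT region and homozygous in the metastasis is still
#' "detected in primary tumours" and therefore not exclusive.  Matched-
#' normal variants are assumed subtracted upstream by the caller; when
#' `check_normal = TRUE`, any identity present in the patient's normal set
#' (if available) is removed as well.
#'
#' @param p A [patient_sample_set()] with post-cascade variant sets.
#' @param check_normal Also subtract the normal sample's set if present.
#' @return The metastasis records that are exclusive (same columns as the
#'   input sets).
#' @export
derive_emv <- function(p, check_normal = FALSE) {
  if (!inherits(p, "patient_sample_set")) {
    ml_usage_error("derive_emv expects a patient_sample_set")
  }
  mt <- data.table::as.data.table(p$variant_sets[[p$mt_sample]])
  if (is.null(mt)) ml_data_error(paste0("patient ", p$patient_id, " has no MT variant set"))
  if (nrow(mt) == 0L) return(mt)
  others <- p$pt_samples
  if (check_normal && p$normal_sample %in% names(p$variant_sets)) {
    others <- c(others, p$normal_sample)
  }
  seen <- unlist(lapply(others, function(s) {
    vs <- p$variant_sets[[s]]
    if (is.null(vs) || nrow(vs) == 0L) character(0) else variant_key(vs)
  }), use.names = FALSE)
  emv <- mt[!variant_key(mt) %in% seen]
  stopifnot(all(variant_key(emv) %in% variant_key(mt)))
  emv
}

#' Cross-patient recurrence of filtered variants
#'
#' Counts, for each variant identity and each gene, the number of distinct
#' patients carrying it; a variant counts once per patient no matter how
#' many of that patient's samples contain it.
#'
#' @param cohort List of [patient_sample_set()] objects.
#' @return List with `variant_recurrence` (`chrom`, `pos`, `ref`, `alt`,
#'   `n_patients`) and `gene_recurrence` (`gene`, `n_patients`), both sorted
#'   by decreasing count.
#' @export
cross_patient_recurrence <- function(cohort) {
  if (length(cohort) < 1L) ml_usage_error("recurrence needs at least one patient")
  ids <- vapply(cohort, function(p) p$patient_id, character(1))
  if (anyDuplicated(ids)) ml_data_error("duplicate patient_id in cohort")
  per_patient <- data.table::rbindlist(lapply(cohort, function(p) {
    v <- data.table::rbindlist(
      lapply(c(p$pt_samples, p$mt_sample), function(s) {
        vs <- data.table::as.data.table(p$variant_sets[[s]])
        vs[, c("chrom", "pos", "ref", "alt", "gene"), with = FALSE]
      }),
      use.names = TRUE)
    unique(v)[, patient_id := p$patient_id]
  }))
  if (nrow(per_patient) == 0L) {
    return(list(
      variant_recurrence = data.table::data.table(
        chrom = character(0), pos = integer(0), ref = character(0),
        alt = character(0), n_patients = integer(0)),
      gene_recurrence = data.table::data.table(
        gene = character(0), n_patients = integer(0))))
  }
  vr <- per_patient[, .(n_patients = data.table::uniqueN(patient_id)),
                    by = .(chrom, pos, ref, alt)]
  data.table::setorderv(vr, c("n_patients", "chrom", "pos"), order = c(-1L, 1L, 1L))
  gr <- unique(per_patient[!is.na(gene), .(gene, patient_id)])[
    , .(n_patients = data.table::uniqueN(patient_id)), by = gene]
  data.table::setorderv(gr, c("n_patients", "gene"), order = c(-1L, 1L))
  list(variant_recurrence = vr[], gene_recurrence = gr[])
}

#' Length-normalized gene mutation rates
#'
#' Rate per gene = number of distinct variant identities in the gene per
#' kilobase of gene length.  Genes present in the length table but without
#' variants get rate 0; variants in genes missing from the length table are
#' skipped with a warning.
#'
#' @param variants Filtered variant table (any number of samples).
#' @param gene_lengths data.frame with columns `gene` and `length_bp`
#'   (positive).
#' @return `data.table` with `gene`, `n_variants`, `length_bp`,
#'   `rate_per_kb`, sorted by decreasing rate, ties broken by gene symbol.
#' @export
gene_mutation_rates <- function(variants, gene_lengths) {
  gl <- data.table::as.data.table(gene_lengths)
  if (!all(c("gene", "length_bp") %in% names(gl))) {
    ml_usage_error("gene_lengths needs columns 'gene' and 'length_bp'")
  }
  if (any(is.na(gl$length_bp)) || any(gl$length_bp <= 0)) {
    ml_data_error("gene lengths must be positive")
  }
  v <- data.table::as.data.table(variants)
  v <- v[!is.na(gene)]
  unknown <- setdiff(unique(v$gene), gl$gene)
  if (length(unknown)) {
    warning(sprintf("skipping %d gene(s) absent from the length table: %s",
                    length(unknown),
                    paste(utils::head(unknown, 5), collapse = ", ")))
    v <- v[!gene %in% unknown]
  }
  counts <- if (nrow(v)) {
    unique(v[, .(chrom, pos, ref, alt, gene)])[, .(n_variants = .N), by = gene]
  } else {
    data.table::data.table(gene = character(0), n_variants = integer(0))
  }
  out <- merge(gl, counts, by = "gene", all.x = TRUE)
  out[is.na(n_variants), n_variants := 0L]
  out[, rate_per_kb := n_variants / (length_bp / 1000)]
  data.table::setorderv(out, c("rate_per_kb", "gene"), order = c(-1L, 1L))
  out[, .(gene, n_variants, length_bp, rate_per_kb)]
}
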