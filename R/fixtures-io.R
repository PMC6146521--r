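# Plain-text fixture round-trip: VCF v4.2 per tumour sample, annotation /
# counts / sample-sheet / gene-length TSVs, and a versioned truth record.

TRUTH_FORMAT_VERSION <- 1L

vcf_header_lines <- function(sample_id) {
  c("##fileformat=VCFv4.2",
    "##source=metlink-synthetic-cohort",
    "##contig=<ID=chrS>",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"High-quality read depth\">",
    "##INFO=<ID=ADF,Number=1,Type=Integer,Description=\"Non-reference reads, forward strand\">",
    "##INFO=<ID=ADR,Number=1,Type=Integer,Description=\"Non-reference reads, reverse strand\">",
    "##INFO=<ID=AF_TUM,Number=1,Type=Float,Description=\"Tumour allele fraction\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample_id))
}

write_sample_vcf <- function(v, sample_id, path) {
  v <- v[order(v$chrom, v$pos), ]
  gt <- ifelse(v$zygosity == "hom_alt", "1/1", "0/1")
  info <- sprintf("DP=%d;ADF=%d;ADR=%d;AF_TUM=%.17g",
                  v$depth, v$alt_forward, v$alt_reverse, v$allele_fraction)
  body <- sprintf("chrS\t%d\t.\t%s\t%s\t.\t.\t%s\tGT\t%s",
                  v$pos, v$ref, v$alt, info, gt)
  writeLines(c(vcf_header_lines(sample_id), body), path)
  path
}

# VCF v4.2 reading is delegated to VariantAnnotation; the files carry
# single-sample, single-allele records with INFO DP/ADF/ADR/AF_TUM and
# FORMAT GT.
read_sample_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path, genome = "chrS")
  n <- nrow(vcf)
  if (n == 0L) {
    return(data.table::data.table(
      chrom = character(0), pos = integer(0), ref = character(0),
      alt = character(0), depth = integer(0), alt_forward = integer(0),
      alt_reverse = integer(0), allele_fraction = numeric(0),
      zygosity = character(0)))
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  inf <- VariantAnnotation::info(vcf)
  gt <- VariantAnnotation::geno(vcf)$GT[, 1L]
  data.table::data.table(
    chrom = as.character(GenomeInfoDb::seqnames(rr)),
    pos = as.integer(BiocGenerics::start(rr)),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = as.character(unlist(VariantAnnotation::alt(vcf))),
    depth = as.integer(inf$DP),
    alt_forward = as.integer(inf$ADF),
    alt_reverse = as.integer(inf$ADR),
    allele_fraction = as.numeric(inf$AF_TUM),
    zygosity = ifelse(gt == "1/1", "hom_alt", "het"))
}

#' Write a simulated cohort to plain-text fixtures
#'
#' Emits one VCF v4.2 per tumour sample (INFO `DP`, `ADF`, `ADR`, `AF_TUM`;
#' FORMAT `GT`), a cohort-wide annotation TSV keyed by variant identity, a
#' raw counts TSV, a sample sheet, a gene-length table, and a versioned
#' JSON truth record.  The files round-trip losslessly through
#' [read_fixtures()].
#'
#' @param cohort A `metlink_cohort` from [simulate_cohort()].
#' @param out_dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_fixtures <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "metlink_cohort"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) ml_io_error(paste0("cannot create directory ", out_dir))
  vcf_dir <- file.path(out_dir, "vcf")
  dir.create(vcf_dir, showWarnings = FALSE)
  v <- data.table::as.data.table(cohort$variants)
  tumour_samples <- cohort$samples$sample_id[cohort$samples$role != "N"]
  vcf_paths <- stats::setNames(
    vapply(tumour_samples, function(s) {
      write_sample_vcf(v[v$sample_id == s], s,
                       file.path(vcf_dir, paste0(s, ".vcf")))
    }, character(1)),
    tumour_samples)
  ann_cols <- c("chrom", "pos", "ref", "alt", "gene", "func_region",
                "exonic_func", POP_AF_COLUMNS)
  ann <- if (nrow(v)) unique(v[, ann_cols, with = FALSE]) else v[, ann_cols, with = FALSE]
  data.table::setorderv(ann, c("chrom", "pos", "ref", "alt"))
  paths <- list(
    vcf = vcf_paths,
    annotations = file.path(out_dir, "annotations.tsv"),
    counts = file.path(out_dir, "counts.tsv"),
    sample_sheet = file.path(out_dir, "sample_sheet.tsv"),
    gene_lengths = file.path(out_dir, "gene_lengths.tsv"),
    truth = file.path(out_dir, "truth.json"),
    config = file.path(out_dir, "cohort_config.cfg"))
  data.table::fwrite(ann, paths$annotations, sep = "\t")
  counts_dt <- data.table::data.table(gene = rownames(cohort$counts))
  if (ncol(cohort$counts) > 0) {
    counts_dt <- cbind(counts_dt, data.table::as.data.table(cohort$counts))
  }
  data.table::fwrite(counts_dt, paths$counts, sep = "\t")
  data.table::fwrite(cohort$samples, paths$sample_sheet, sep = "\t")
  data.table::fwrite(cohort$gene_lengths, paths$gene_lengths, sep = "\t")
  truth_payload <- list(
    format_version = TRUTH_FORMAT_VERSION,
    seed = cohort$truth$seed,
    variants = cohort$truth$variants,
    coupling = cohort$truth$coupling,
    size_factors = as.list(cohort$truth$size_factors))
  jsonlite::write_json(truth_payload, paths$truth, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  write_flat_config(cohort$config, paths$config)
  invisible(paths)
}

#' Read a fixture directory back into a cohort object
#'
#' @param dir Directory written by [write_fixtures()].
#' @return A `metlink_cohort` equivalent to the one written.
#' @export
read_fixtures <- function(dir) {
  if (!dir.exists(dir)) ml_io_error(paste0("no such fixture directory: ", dir))
  samples <- data.table::fread(file.path(dir, "sample_sheet.tsv"),
                               colClasses = list(character = c("sample_id", "patient_id", "role")))
  ann <- data.table::fread(file.path(dir, "annotations.tsv"))
  counts_dt <- data.table::fread(file.path(dir, "counts.tsv"))
  counts <- as.matrix(counts_dt, rownames = "gene")
  storage.mode(counts) <- "integer"
  gene_lengths <- data.table::fread(file.path(dir, "gene_lengths.tsv"))
  tumour_samples <- samples$sample_id[samples$role != "N"]
  per_sample <- lapply(tumour_samples, function(s) {
    dt <- read_sample_vcf(file.path(dir, "vcf", paste0(s, ".vcf")))
    if (nrow(dt)) dt[, sample_id := s]
    dt
  })
  v <- data.table::rbindlist(per_sample, use.names = TRUE, fill = TRUE)
  if (nrow(v)) {
    v[, patient_id := samples$patient_id[match(sample_id, samples$sample_id)]]
    v <- merge(v, ann, by = c("chrom", "pos", "ref", "alt"),
               all.x = TRUE, sort = FALSE)
    v[gene == "", gene := NA_character_]  # fwrite serializes NA as ""
    v[, variant_type := data.table::fcase(
      nchar(ref) == 1L & nchar(alt) == 1L, "SNV",
      nchar(alt) > nchar(ref), "insertion",
      nchar(ref) > nchar(alt), "deletion",
      default = "substitution_block")]
    v <- v[, VARIANT_COLUMNS, with = FALSE]
    data.table::setorderv(v, c("sample_id", "chrom", "pos"))
  } else {
    empty <- stats::setNames(rep(list(character(0)), length(VARIANT_COLUMNS)),
                             VARIANT_COLUMNS)
    v <- data.table::as.data.table(empty)
  }
  truth_raw <- jsonlite::read_json(file.path(dir, "truth.json"),
                                   simplifyVector = TRUE)
  if (!identical(as.integer(truth_raw$format_version), TRUTH_FORMAT_VERSION)) {
    ml_data_error("unsupported truth record version")
  }
  truth <- structure(
    list(variants = data.table::as.data.table(truth_raw$variants),
         samples = samples,
         coupling = data.table::as.data.table(truth_raw$coupling),
         size_factors = unlist(truth_raw$size_factors),
         seed = truth_raw$seed),
    class = "sim_truth")
  config <- read_flat_config(file.path(dir, "cohort_config.cfg"))
  structure(
    list(variants = v, counts = counts, samples = samples,
         gene_lengths = gene_lengths, truth = truth, config = config),
    class = "metlink_cohort")
}

# Flat key = value serialization of a cohort_config (INI-style, no
# sections; vectors comma-separated).
write_flat_config <- function(config, path) {
  fields <- config[setdiff(names(config), "allele_fraction_model")]
  afm <- config$allele_fraction_model
  flat <- c(fields,
            list(af_p_hom = afm$p_hom, af_p_clonal = afm$p_clonal,
                 af_hom_shape = afm$hom_shape,
                 af_clonal_shape = afm$clonal_shape,
                 af_subclonal_shape = afm$subclonal_shape))
  lines <- vapply(names(flat), function(k) {
    v <- flat[[k]]
    vals <- if (is.numeric(v)) format(v, digits = 17) else as.character(v)
    paste0(k, " = ", paste(vals, collapse = ","))
  }, character(1))
  writeLines(lines, path)
  path
}

read_flat_config <- function(path) {
  if (!file.exists(path)) ml_io_error(paste0("no such config file: ", path))
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "[")]
  kv <- regmatches(lines, regexec("^([^=]+?)\\s*=\\s*(.*)$", lines))
  keys <- vapply(kv, `[`, character(1), 2L)
  vals <- lapply(kv, function(x) {
    parts <- strsplit(x[3L], ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) num else trimws(parts)
  })
  names(vals) <- trimws(keys)
  cohort_config(
    n_patients = vals$n_patients,
    pt_regions_per_patient = vals$pt_regions_per_patient,
    n_genes = vals$n_genes,
    burden_regime = vals$burden_regime,
    spectrum_weights = stats::setNames(vals$spectrum_weights, SUBSTITUTION_TYPES),
    functional_class_mix = stats::setNames(vals$functional_class_mix,
                                           FUNCTIONAL_CLASSES),
    depth_mean = vals$depth_mean,
    depth_dispersion = vals$depth_dispersion,
    strand_split = vals$strand_split,
    allele_fraction_model = list(
      p_hom = vals$af_p_hom, p_clonal = vals$af_p_clonal,
      hom_shape = vals$af_hom_shape, clonal_shape = vals$af_clonal_shape,
      subclonal_shape = vals$af_subclonal_shape),
    common_variant_rate = vals$common_variant_rate,
    fail_evidence_rate = vals$fail_evidence_rate,
    emv_fraction = vals$emv_fraction,
    coupling_delta = vals$coupling_delta,
    coupling_fraction = vals$coupling_fraction,
    nb_dispersion = vals$nb_dispersion,
    patient_effect_sd = vals$patient_effect_sd,
    library_size_sd = vals$library_size_sd,
    seed = vals$seed)
}
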