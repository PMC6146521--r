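# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @keywords internal
ml_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "metlink_error", "error")))
}

ml_data_error   <- function(msg) ml_error(msg, "metlink_data_error")
ml_usage_error  <- function(msg) ml_error(msg, "metlink_usage_error")
ml_config_error <- function(msg) ml_error(msg, "metlink_config_error")
ml_io_error     <- function(msg) ml_error(msg, "metlink_io_error")

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == trunc(x)
}

is_fraction <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}

# probability vector check used by cohort_config
check_prob_vector <- function(p, what, tol = 1e-12) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0)) {
    ml_config_error(sprintf("%s must be a non-negative numeric vector", what))
  }
  if (abs(sum(p) - 1) > tol) {
    ml_config_error(sprintf("%s must sum to 1 (got %.15g)", what, sum(p)))
  }
  invisible(TRUE)
}

# Variant identity key used throughout the set algebra: a variant is the
# tuple (chrom, pos, ref, alt); genotype and evidence are not part of it.
variant_key <- function(x) {
  paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
}

VARIANT_COLUMNS <- c(
  "patient_id", "sample_id", "chrom", "pos", "ref", "alt", "variant_type",
  "depth", "alt_forward", "alt_reverse", "allele_fraction", "zygosity",
  "gene", "func_region", "exonic_func",
  "exac_all", "esp6500_all", "kg_all", "kg_eur"
)

POP_AF_COLUMNS <- c("exac_all", "esp6500_all", "kg_all", "kg_eur")

FUNC_REGIONS <- c("exonic", "intronic", "splicing", "UTR3", "UTR5",
                  "upstream", "downstream", "intergenic")

EXONIC_FUNCS <- c("nonsynonymous", "synonymous", "stopgain", "stoploss",
                  "frameshift_indel", "nonframeshift_indel", "none")

VARIANT_TYPES <- c("SNV", "insertion", "deletion", "substitution_block")

as_variant_table <- function(x) {
  x <- data.table::as.data.table(x)
  missing_cols <- setdiff(VARIANT_COLUMNS, names(x))
  if (length(missing_cols)) {
    ml_data_error(paste0("variant table is missing columns: ",
                         paste(missing_cols, collapse = ", ")))
  }
  x
}
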