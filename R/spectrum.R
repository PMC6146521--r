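# Mutation-spectrum classification and summaries.

SUBSTITUTION_TYPES <- c("C>A", "C>G", "C>T", "G>A", "G>C", "G>T",
                        "A>C", "A>G", "A>T", "T>A", "T>C", "T>G")

MUTATION_CLASSES <- c("stopgain", "non_silent", "hom_non_silent",
                      "silent_exonic", "indel_all")

#' Classify a single-nucleotide substitution
#'
#' Assigns each ref/alt base pair to its Watson-Crick pair class (a C:G-pair
#' mutation iff the reference base is C or G) and to transition
#' (purine<->purine or pyrimidine<->pyrimidine) versus transversion.
#'
#' @param ref,alt Single bases in `A`, `C`, `G`, `T`; vectors are recycled
#'   to common length.
#' @return A `data.frame` with columns `pair_class` (`"CG"`/`"AT"`) and
#'   `change_class` (`"transition"`/`"transversion"`).
#' @export
classify_substitution <- function(ref, alt) {
  n <- max(length(ref), length(alt))
  ref <- rep_len(toupper(as.character(ref)), n)
  alt <- rep_len(toupper(as.character(alt)), n)
  bases <- c("A", "C", "G", "T")
  bad <- !(ref %in% bases) | !(alt %in% bases) | ref == alt
  if (any(bad)) {
    ml_usage_error(paste0(
      "classify_substitution expects single-base ref != alt; offending input: ",
      paste(utils::head(paste0(ref[bad], ">", alt[bad]), 5), collapse = ", ")))
  }
  purine <- c("A", "G")
  transition <- (ref %in% purine) == (alt %in% purine)
  data.frame(
    pair_class = ifelse(ref %in% c("C", "G"), "CG", "AT"),
    change_class = ifelse(transition, "transition", "transversion"),
    stringsAsFactors = FALSE
  )
}

is_snv <- function(v) {
  v$variant_type == "SNV" & nchar(v$ref) == 1L & nchar(v$alt) == 1L
}

#' Mutation-class membership
#'
#' Tests each variant record for membership in one of the analysis classes:
#' `stopgain`; `non_silent` (nonsynonymous, stopgain, stoploss, frameshift
#' indel, or splicing-region); `hom_non_silent` (non-silent and homozygous);
#' `silent_exonic` (synonymous); `indel_all` (insertions and deletions).
#'
#' @param v Variant table.
#' @param cls One of `r paste(MUTATION_CLASSES, collapse = ", ")`.
#' @return Logical vector, one element per record.
#' @export
mutation_class_membership <- function(v, cls) {
  if (length(cls) != 1L || !cls %in% MUTATION_CLASSES) {
    ml_usage_error(paste0("unknown mutation class: ", paste(cls, collapse = ", "),
                          " (expected one of ", paste(MUTATION_CLASSES, collapse = ", "), ")"))
  }
  v <- data.table::as.data.table(v)
  non_silent <- v$exonic_func %in% c("nonsynonymous", "stopgain", "stoploss",
                                     "frameshift_indel") |
    v$func_region == "splicing"
  switch(cls,
    stopgain = v$exonic_func == "stopgain",
    non_silent = non_silent,
    hom_non_silent = non_silent & v$zygosity == "hom_alt",
    silent_exonic = v$exonic_func == "synonymous",
    indel_all = v$variant_type %in% c("insertion", "deletion")
  )
}

#' Summarize the mutation spectrum of a variant set
#'
#' Counts the 12 ref>alt substitution types among SNVs, totals transitions /
#' transversions and C:G-pair / A:T-pair mutations, and tabulates fractions
#' of variants per genomic region (over all variants) and per exonic
#' functional class (over exonic variants).
#'
#' @param variants Variant table.
#' @return An object of class `spectrum_summary`: a list with
#'   `substitutions` (named count vector over the 12 types), `transitions`,
#'   `transversions`, `cg_pair_mutations`, `at_pair_mutations`,
#'   `func_region_fractions`, `exonic_func_fractions`, `n_variants`,
#'   `n_snv`.  With no input, counts are 0 and fractions `NaN`.
#' @export
summarize_spectrum <- function(variants) {
  v <- data.table::as.data.table(variants)
  n <- nrow(v)
  subs <- stats::setNames(integer(length(SUBSTITUTION_TYPES)), SUBSTITUTION_TYPES)
  transitions <- transversions <- cg <- at <- 0L
  n_snv <- 0L
  if (n > 0L) {
    snv <- v[is_snv(v)]
    n_snv <- nrow(snv)
    if (n_snv > 0L) {
      type <- paste0(snv$ref, ">", snv$alt)
      tab <- table(factor(type, levels = SUBSTITUTION_TYPES))
      subs[names(tab)] <- as.integer(tab)
      cl <- classify_substitution(snv$ref, snv$alt)
      transitions <- sum(cl$change_class == "transition")
      transversions <- sum(cl$change_class == "transversion")
      cg <- sum(cl$pair_class == "CG")
      at <- sum(cl$pair_class == "AT")
    }
  }
  region_frac <- stats::setNames(rep(NaN, length(FUNC_REGIONS)), FUNC_REGIONS)
  exonic_frac <- stats::setNames(rep(NaN, length(EXONIC_FUNCS) - 1L),
                                 setdiff(EXONIC_FUNCS, "none"))
  if (n > 0L) {
    region_frac[] <- as.numeric(table(factor(v$func_region, levels = FUNC_REGIONS))) / n
    n_exonic <- sum(v$func_region == "exonic")
    if (n_exonic > 0L) {
      ef <- v$exonic_func[v$func_region == "exonic"]
      exonic_frac[] <- as.numeric(
        table(factor(ef, levels = names(exonic_frac)))) / n_exonic
    }
  }
  structure(
    list(substitutions = subs,
         transitions = transitions,
         transversions = transversions,
         cg_pair_mutations = cg,
         at_pair_mutations = at,
         func_region_fractions = region_frac,
         exonic_func_fractions = exonic_frac,
         n_variants = n,
         n_snv = n_snv),
    class = "spectrum_summary"
  )
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat("Mutation spectrum:", x$n_variants, "variants (", x$n_snv, "SNVs )\n")
  cat("  transitions:", x$transitions, " transversions:", x$transversions, "\n")
  cat("  C:G-pair:", x$cg_pair_mutations, " A:T-pair:", x$at_pair_mutations, "\n")
  invisible(x)
}
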