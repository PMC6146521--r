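#' Filter cascade configuration
#'
#' Thresholds for the somatic "filtered variants" cascade: minimum tumour
#' allele fraction (applied to SNVs, mirroring the false-positive filter's
#' scope), minimum read depth and per-strand non-reference read support,
#' and the population-frequency rules (any panel frequency strictly above
#' `max_pop_af` discards the variant; homozygous calls with ExAC frequency
#' strictly above `common_hom_af` are discarded as common germline).
#'
#' @param min_allele_fraction Minimum tumour allele fraction, inclusive.
#' @param min_depth Minimum high-quality read depth at the site, inclusive.
#' @param min_alt_per_strand Minimum non-reference reads on each strand,
#'   inclusive.
#' @param max_pop_af Population allele-frequency cutoff; strictly greater
#'   discards ("more than 1%").
#' @param common_hom_af ExAC frequency above which a homozygous call is
#'   treated as a common germline variant; strictly greater discards.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_allele_fraction = 0.1,
                          min_depth = 20L,
                          min_alt_per_strand = 4L,
                          max_pop_af = 0.01,
                          common_hom_af = 0.5) {
  if (!is_fraction(min_allele_fraction) || !is_fraction(max_pop_af) ||
      !is_fraction(common_hom_af)) {
    ml_config_error("allele-fraction and population-frequency thresholds must lie in [0, 1]")
  }
  if (!is_count(min_depth) || min_depth < 0 ||
      !is_count(min_alt_per_strand) || min_alt_per_strand < 0) {
    ml_config_error("min_depth and min_alt_per_strand must be non-negative integers")
  }
  structure(
    list(min_allele_fraction = min_allele_fraction,
         min_depth = as.integer(min_depth),
         min_alt_per_strand = as.integer(min_alt_per_strand),
         max_pop_af = max_pop_af,
         common_hom_af = common_hom_af),
    class = "filter_config"
  )
}

#' Allele-fraction predicate
#'
#' TRUE iff the tumour allele fraction is at or above the threshold
#' (the cutoff is inclusive).
#'
#' @param v Variant table (one or more records).
#' @param cfg A [filter_config()].
#' @return Logical vector, one element per record.
#' @export
passes_allele_fraction <- function(v, cfg = filter_config()) {
  v <- data.table::as.data.table(v)
  af <- v$allele_fraction
  if (is.null(af) || anyNA(af)) {
    bad <- if (is.null(af)) seq_len(nrow(v)) else which(is.na(af))
    ml_data_error(paste0("missing allele_fraction for record(s): ",
                         paste(utils::head(variant_key(v)[bad], 5), collapse = ", ")))
  }
  af >= cfg$min_allele_fraction
}

#' Depth and strand-support predicate
#'
#' TRUE iff read depth and the non-reference read count on *each* strand
#' meet their (inclusive) minima.
#'
#' @inheritParams passes_allele_fraction
#' @return Logical vector.
#' @export
passes_depth_strand <- function(v, cfg = filter_config()) {
  v <- data.table::as.data.table(v)
  if (anyNA(v$depth) || anyNA(v$alt_forward) || anyNA(v$alt_reverse)) {
    bad <- which(is.na(v$depth) | is.na(v$alt_forward) | is.na(v$alt_reverse))
    ml_data_error(paste0("missing depth/strand evidence for record(s): ",
                         paste(utils::head(variant_key(v)[bad], 5), collapse = ", ")))
  }
  v$depth >= cfg$min_depth &
    v$alt_forward >= cfg$min_alt_per_strand &
    v$alt_reverse >= cfg$min_alt_per_strand
}

#' Common-variant predicate
#'
#' TRUE iff the variant looks like a common germline variant: any population
#' panel frequency strictly above `max_pop_af`, or a homozygous call with
#' ExAC frequency strictly above `common_hom_af`.  Missing panel entries
#' count as frequency 0 (absence from a panel is not evidence of
#' commonness), so a variant with no annotation is kept.
#'
#' @inheritParams passes_allele_fraction
#' @return Logical vector.
#' @export
is_common_variant <- function(v, cfg = filter_config()) {
  v <- data.table::as.data.table(v)
  af <- lapply(POP_AF_COLUMNS, function(cl) {
    x <- v[[cl]]
    if (is.null(x)) x <- rep(NA_real_, nrow(v))
    data.table::fifelse(is.na(x), 0, as.numeric(x))
  })
  names(af) <- POP_AF_COLUMNS
  any_common <- Reduce(`|`, lapply(af, function(x) x > cfg$max_pop_af))
  hom_common <- v$zygosity == "hom_alt" & af$exac_all > cfg$common_hom_af
  any_common | hom_common
}

#' Run the somatic filter cascade
#'
#' Applies the four filter stages to caller output (tumour records with the
#' matched normal already subtracted upstream): the allele-fraction rule
#' (SNVs only; indels bypass it), the depth/strand evidence rule, removal of
#' common homozygotes, and the population-frequency rule.  The filters are
#' conjunctive, so the surviving set does not depend on the stage order;
#' the per-stage log does.  Record order is preserved.
#'
#' @param variants Variant table.
#' @param cfg A [filter_config()].
#' @param stage_order Permutation of `c("af", "depth_strand", "hom_common",
#'   "pop")`; exposed mainly for the order-invariance property test.
#' @return A list with `variants` (survivors, input order preserved) and
#'   `log`, a named integer vector with elements `input`, `af_pass`,
#'   `depth_strand_pass`, `hom_common_removed`, `pop_pass`.  `*_pass`
#'   entries count records still alive after that stage; `hom_common_removed`
#'   counts records dropped at its stage.
#' @export
run_filter_cascade <- function(variants, cfg = filter_config(),
                               stage_order = c("af", "depth_strand",
                                               "hom_common", "pop")) {
  if (!setequal(stage_order, c("af", "depth_strand", "hom_common", "pop")) ||
      length(stage_order) != 4L) {
    ml_usage_error("stage_order must be a permutation of af, depth_strand, hom_common, pop")
  }
  v <- as_variant_table(variants)
  log <- c(input = nrow(v), af_pass = 0L, depth_strand_pass = 0L,
           hom_common_removed = 0L, pop_pass = 0L)
  if (nrow(v) == 0L) {
    return(list(variants = v, log = log))
  }
  alive <- rep(TRUE, nrow(v))
  common <- is_common_variant(v, cfg)
  hom <- v$zygosity == "hom_alt" &
    data.table::fifelse(is.na(v$exac_all), 0, as.numeric(v$exac_all)) > cfg$common_hom_af
  for (stage in stage_order) {
    keep <- switch(
      stage,
      af = {
        # the min-var-frac rule comes from an SNV-scoped filter: indels bypass
        snv <- v$variant_type == "SNV"
        pass <- rep(TRUE, nrow(v))
        if (any(snv)) pass[snv] <- passes_allele_fraction(v[snv], cfg)
        pass
      },
      depth_strand = passes_depth_strand(v, cfg),
      hom_common = !hom,
      pop = !common
    )
    if (stage == "hom_common") {
      log["hom_common_removed"] <- sum(alive & !keep)
    }
    alive <- alive & keep
    if (stage == "af") log["af_pass"] <- sum(alive)
    if (stage == "depth_strand") log["depth_strand_pass"] <- sum(alive)
    if (stage == "pop") log["pop_pass"] <- sum(alive)
  }
  list(variants = v[alive], log = log)
}
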