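# Synthetic matched-cohort generator: variant tables with evidence and
# annotations, and negative-binomial expression counts with a known
# mutation-to-expression coupling.

GENE_BLOCK <- 10000L   # bp of synthetic coordinate space reserved per gene
GENE_SPAN  <- 5000L    # positions 1..GENE_SPAN of a block are "the gene"

gene_ids <- function(n_genes) sprintf("G%05d", seq_len(n_genes))

draw_bases <- function(n, k = 1L) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")
  }, character(1))
}

# Attribute draw for a batch of variants: functional class, gene, unique
# position, ref/alt, and (rare) population allele frequencies.
make_variant_attrs <- function(n, config, used_pos, common = FALSE) {
  if (n == 0L) {
    return(data.table::data.table(
      chrom = character(0), pos = integer(0), ref = character(0),
      alt = character(0), variant_type = character(0), gene = character(0),
      func_region = character(0), exonic_func = character(0),
      exac_all = numeric(0), esp6500_all = numeric(0), kg_all = numeric(0),
      kg_eur = numeric(0)))
  }
  cls <- sample(FUNCTIONAL_CLASSES, n, replace = TRUE,
                prob = config$functional_class_mix)
  genic <- cls != "intergenic"
  gene_idx <- sample.int(config$n_genes, n, replace = TRUE)
  gene <- ifelse(genic, gene_ids(config$n_genes)[gene_idx], NA_character_)
  # unique synthetic positions: genic within the gene block, intergenic in a
  # reserved tail region
  pos <- integer(n)
  for (i in seq_len(n)) {
    repeat {
      p <- if (genic[i]) {
        (gene_idx[i] - 1L) * GENE_BLOCK + sample.int(GENE_SPAN, 1L)
      } else {
        config$n_genes * GENE_BLOCK + sample.int(5000000L, 1L)
      }
      key <- as.character(p)
      if (is.null(used_pos[[key]])) {
        used_pos[[key]] <- TRUE
        pos[i] <- p
        break
      }
    }
  }
  func_region <- data.table::fcase(
    cls %in% c("nonsynonymous", "synonymous", "stopgain", "stoploss",
               "frameshift_indel", "nonframeshift_indel"), "exonic",
    cls == "intronic", "intronic",
    cls == "UTR3", "UTR3",
    cls == "UTR5", "UTR5",
    cls == "splicing", "splicing",
    cls == "intergenic", "intergenic")
  exonic_func <- ifelse(func_region == "exonic", cls, "none")
  is_indel <- cls %in% c("frameshift_indel", "nonframeshift_indel")
  ref <- character(n); alt <- character(n); vtype <- character(n)
  n_snv <- sum(!is_indel)
  if (n_snv > 0L) {
    sub <- sample(SUBSTITUTION_TYPES, n_snv, replace = TRUE,
                  prob = config$spectrum_weights)
    ref[!is_indel] <- substr(sub, 1L, 1L)
    alt[!is_indel] <- substr(sub, 3L, 3L)
    vtype[!is_indel] <- "SNV"
  }
  if (any(is_indel)) {
    idx <- which(is_indel)
    ins <- stats::runif(length(idx)) < 0.5
    len <- ifelse(cls[idx] == "frameshift_indel",
                  sample(c(1L, 2L), length(idx), replace = TRUE), 3L)
    anchor <- draw_bases(length(idx))
    for (k in seq_along(idx)) {
      i <- idx[k]
      if (ins[k]) {
        ref[i] <- anchor[k]
        alt[i] <- paste0(anchor[k], draw_bases(1L, len[k]))
        vtype[i] <- "insertion"
      } else {
        ref[i] <- paste0(anchor[k], draw_bases(1L, len[k]))
        alt[i] <- anchor[k]
        vtype[i] <- "deletion"
      }
    }
  }
  draw_af <- function() {
    if (common) {
      stats::runif(n, 0.011, 0.9)
    } else {
      ifelse(stats::runif(n) < 0.5, NA_real_, stats::runif(n, 0, 0.008))
    }
  }
  exac <- draw_af()
  jitter_af <- function(base) {
    cap <- if (common) 1 else 0.0099  # rare variants must stay below the 1% rule
    x <- pmin(cap, base * stats::runif(n, 0.7, 1.3))
    ifelse(stats::runif(n) < (if (common) 0.2 else 0.5), NA_real_, x)
  }
  base_af <- data.table::fifelse(is.na(exac), 0, exac)
  data.table::data.table(
    chrom = "chrS", pos = pos, ref = ref, alt = alt, variant_type = vtype,
    gene = gene, func_region = func_region, exonic_func = exonic_func,
    exac_all = exac, esp6500_all = jitter_af(base_af),
    kg_all = jitter_af(base_af), kg_eur = jitter_af(base_af))
}

# allele-fraction mixture for somatic (tumour) or germline-like (common)
# variants
draw_allele_fraction <- function(n, afm, germline = FALSE) {
  if (germline) {
    hom <- stats::runif(n) < 0.3
    af <- ifelse(hom, stats::rbeta(n, 60, 3), stats::rbeta(n, 30, 30))
    return(af)
  }
  u <- stats::runif(n)
  af <- numeric(n)
  hom <- u < afm$p_hom
  clo <- !hom & (stats::runif(n) < afm$p_clonal)
  sub <- !hom & !clo
  af[hom] <- stats::rbeta(sum(hom), afm$hom_shape[1], afm$hom_shape[2])
  af[clo] <- stats::rbeta(sum(clo), afm$clonal_shape[1], afm$clonal_shape[2])
  af[sub] <- stats::rbeta(sum(sub), afm$subclonal_shape[1], afm$subclonal_shape[2])
  af
}

# evidence designed to pass the default cascade thresholds
sim_evidence_pass <- function(n, config, germline = FALSE) {
  if (n == 0L) {
    return(data.table::data.table(depth = integer(0), alt_forward = integer(0),
                                  alt_reverse = integer(0),
                                  allele_fraction = numeric(0)))
  }
  afm <- config$allele_fraction_model
  depth <- stats::rnbinom(n, mu = config$depth_mean, size = config$depth_dispersion)
  af <- draw_allele_fraction(n, afm, germline)
  alt <- stats::rbinom(n, depth, af)
  fwd <- stats::rbinom(n, alt, config$strand_split)
  ok <- depth >= 20L & fwd >= 4L & (alt - fwd) >= 4L & af >= 0.1
  tries <- 0L
  while (any(!ok) && tries < 30L) {
    i <- which(!ok)
    depth[i] <- stats::rnbinom(length(i), mu = config$depth_mean,
                               size = config$depth_dispersion)
    af[i] <- draw_allele_fraction(length(i), afm, germline)
    alt[i] <- stats::rbinom(length(i), depth[i], af[i])
    fwd[i] <- stats::rbinom(length(i), alt[i], config$strand_split)
    ok <- depth >= 20L & fwd >= 4L & (alt - fwd) >= 4L & af >= 0.1
    tries <- tries + 1L
  }
  if (any(!ok)) {  # force the stragglers
    i <- which(!ok)
    depth[i] <- pmax(depth[i], 40L)
    af[i] <- pmax(af[i], 0.25)
    alt[i] <- pmax(8L, round(depth[i] * af[i]))
    fwd[i] <- alt[i] %/% 2L
  }
  data.table::data.table(depth = as.integer(depth),
                         alt_forward = as.integer(fwd),
                         alt_reverse = as.integer(alt - fwd),
                         allele_fraction = pmin(1, alt / pmax(depth, 1L)))
}

# evidence designed to fail exactly one cascade rule (depth, strand, or --
# for SNVs -- allele fraction)
sim_evidence_fail <- function(n, config, is_snv) {
  if (n == 0L) {
    return(data.table::data.table(depth = integer(0), alt_forward = integer(0),
                                  alt_reverse = integer(0),
                                  allele_fraction = numeric(0)))
  }
  mode <- ifelse(is_snv,
                 sample(c("depth", "strand", "af"), n, replace = TRUE),
                 sample(c("depth", "strand"), n, replace = TRUE))
  depth <- integer(n); fwd <- integer(n); rev <- integer(n); af <- numeric(n)
  for (i in seq_len(n)) {
    if (mode[i] == "depth") {
      depth[i] <- sample(5:19, 1L)
      af[i] <- stats::runif(1, 0.15, 0.6)
      a <- stats::rbinom(1L, depth[i], af[i])
      fwd[i] <- stats::rbinom(1L, a, 0.5); rev[i] <- a - fwd[i]
    } else if (mode[i] == "strand") {
      depth[i] <- 20L + stats::rpois(1L, config$depth_mean)
      fwd[i] <- sample(0:3, 1L)
      rev[i] <- sample(4:20, 1L)
      af[i] <- max(0.1, (fwd[i] + rev[i]) / depth[i])
    } else {
      depth[i] <- max(100L, 20L + stats::rpois(1L, config$depth_mean))
      af[i] <- stats::runif(1, 0.04, 0.095)
      a <- max(8L, round(depth[i] * af[i]))
      fwd[i] <- a %/% 2L; rev[i] <- a - fwd[i]
    }
  }
  data.table::data.table(depth = depth, alt_forward = fwd, alt_reverse = rev,
                         allele_fraction = af)
}

sample_sheet_for <- function(config) {
  if (config$n_patients == 0L) {
    return(data.table::data.table(sample_id = character(0),
                                  patient_id = character(0),
                                  role = character(0),
                                  region_index = integer(0)))
  }
  data.table::rbindlist(lapply(seq_len(config$n_patients), function(i) {
    pid <- sprintf("P%02d", i)
    k <- config$pt_regions_per_patient[i]
    data.table::data.table(
      sample_id = c(paste0(pid, ".N"), paste0(pid, ".PT", seq_len(k)),
                    paste0(pid, ".MT")),
      patient_id = pid,
      role = c("N", rep("PT", k), "MT"),
      region_index = c(NA_integer_, seq_len(k), NA_integer_))
  }))
}

#' Simulate per-sample somatic variant tables
#'
#' Builds, per patient, a truncal variant pool shared by all tumour samples,
#' region-private variants, and metastasis-private variants (the true
#' exclusive metastatic variants, a fraction `emv_fraction` of the
#' metastasis burden).  Per-sample burden targets are drawn from the
#' patient's regime interval (54-306 or 1490-3029 filtered variants).  On
#' top of the filter-passing variants, each sample receives
#' `fail_evidence_rate` extra variants whose evidence fails the cascade and
#' common population variants at `common_variant_rate`.
#'
#' @param config A [cohort_config()].
#' @return List with `variants` (tumour-sample variant table), `samples`
#'   (sample sheet), and `truth` (`sim_truth`: per-sample injected variants
#'   with origin labels and EMV flags; expression coupling and library
#'   factors are filled in by [simulate_counts()]).
#' @export
simulate_variant_tables <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  sheet <- sample_sheet_for(config)
  all_rows <- list()
  for (i in seq_len(config$n_patients)) {
    pid <- sprintf("P%02d", i)
    used_pos <- new.env(parent = emptyenv())
    k <- config$pt_regions_per_patient[i]
    interval <- BURDEN_INTERVALS[[config$burden_regime[i]]]
    pt_ids <- paste0(pid, ".PT", seq_len(k))
    mt_id <- paste0(pid, ".MT")
    targets <- round(stats::runif(k + 1L, interval[1], interval[2]))
    t_mt <- targets[k + 1L]
    n_emv <- round(config$emv_fraction * t_mt)
    n_trunk <- t_mt - n_emv
    trunk <- make_variant_attrs(n_trunk, config, used_pos)
    emv <- make_variant_attrs(n_emv, config, used_pos)
    privates <- lapply(seq_len(k), function(j) {
      make_variant_attrs(max(0L, targets[j] - n_trunk), config, used_pos)
    })
    membership <- list()
    for (j in seq_len(k)) {
      membership[[pt_ids[j]]] <- rbind(
        if (nrow(trunk)) cbind(trunk, origin = "trunk") else NULL,
        if (nrow(privates[[j]])) cbind(privates[[j]], origin = "pt_private") else NULL)
    }
    membership[[mt_id]] <- rbind(
      if (nrow(trunk)) cbind(trunk, origin = "trunk") else NULL,
      if (nrow(emv)) cbind(emv, origin = "mt_private") else NULL)
    for (s in c(pt_ids, mt_id)) {
      core <- data.table::as.data.table(membership[[s]])
      n_pass <- nrow(core)
      n_fail <- round(config$fail_evidence_rate * n_pass)
      fail <- make_variant_attrs(n_fail, config, used_pos)
      r <- config$common_variant_rate
      n_common <- if (r >= 1) 0L else round(r / (1 - r) * (n_pass + n_fail))
      common <- make_variant_attrs(n_common, config, used_pos, common = TRUE)
      ev_pass <- sim_evidence_pass(n_pass, config)
      ev_fail <- sim_evidence_fail(n_fail, config, fail$variant_type == "SNV")
      ev_common <- sim_evidence_pass(n_common, config, germline = TRUE)
      block <- rbind(
        cbind(core, ev_pass),
        if (n_fail) cbind(fail, origin = "fail", ev_fail) else NULL,
        if (n_common) cbind(common, origin = "common", ev_common) else NULL)
      block[, `:=`(sample_id = s, patient_id = pid,
                   zygosity = data.table::fifelse(allele_fraction > 0.8,
                                                  "hom_alt", "het"))]
      all_rows[[length(all_rows) + 1L]] <- block
    }
  }
  truth_variants <- if (length(all_rows)) {
    data.table::rbindlist(all_rows, use.names = TRUE)
  } else {
    data.table::data.table()
  }
  if (nrow(truth_variants)) {
    truth_variants[, is_emv := origin == "mt_private"]
    truth_variants[, designed_pass := origin %in% c("trunk", "pt_private", "mt_private")]
    data.table::setorderv(truth_variants, c("sample_id", "chrom", "pos"))
    variants <- truth_variants[, VARIANT_COLUMNS, with = FALSE]
  } else {
    empty <- stats::setNames(
      rep(list(character(0)), length(VARIANT_COLUMNS)), VARIANT_COLUMNS)
    variants <- data.table::as.data.table(empty)
    variants[, pos := integer(0)]
    truth_variants <- data.table::copy(variants)[
      , `:=`(origin = character(0), is_emv = logical(0),
             designed_pass = logical(0))]
  }
  truth <- structure(
    list(variants = truth_variants, samples = sheet,
         coupling = NULL, size_factors = NULL, seed = config$seed),
    class = "sim_truth")
  list(variants = variants, samples = sheet, truth = truth)
}

#' Simulate an expression count matrix coupled to the mutation truth
#'
#' Negative-binomial counts for every sample (normals included), with
#' log-normal gene base means, a multiplicative per-patient effect, a
#' per-sample library-size factor, and -- for tumour samples -- a mean log2
#' fold-change shift of `coupling_delta` applied to a fraction
#' `coupling_fraction` of genes carrying a non-silent filter-passing
#' mutation in that sample.  With `nb_dispersion = 0` counts are Poisson.
#'
#' @param truth A `sim_truth` from [simulate_variant_tables()].
#' @param config The same [cohort_config()].
#' @return Integer count matrix (genes x samples) with attributes
#'   `size_factors` (named, the true library factors) and `coupling`
#'   (data.table `sample_id`, `gene`, `log2fc_shift`).
#' @export
simulate_counts <- function(truth, config) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "cohort_config"))
  set.seed(config$seed + 1L)
  genes <- gene_ids(config$n_genes)
  samples <- truth$samples$sample_id
  n_s <- length(samples)
  base_mean <- stats::rlnorm(config$n_genes, meanlog = log(100), sdlog = 1.3)
  patients <- unique(truth$samples$patient_id)
  pe <- stats::setNames(stats::rlnorm(length(patients), 0, config$patient_effect_sd),
                        patients)
  sf <- stats::setNames(stats::rlnorm(n_s, 0, config$library_size_sd), samples)
  shift <- matrix(0, nrow = config$n_genes, ncol = n_s,
                  dimnames = list(genes, samples))
  coupling <- data.table::data.table(sample_id = character(0),
                                     gene = character(0),
                                     log2fc_shift = numeric(0))
  tv <- truth$variants
  if (nrow(tv)) {
    ns <- tv[tv$designed_pass & !is.na(tv$gene) &
               mutation_class_membership(tv, "non_silent"),
             .(sample_id, gene)]
    ns <- unique(ns)
    if (nrow(ns)) {
      picked <- stats::runif(nrow(ns)) < config$coupling_fraction
      ns <- ns[picked]
      if (nrow(ns)) {
        ns[, log2fc_shift := config$coupling_delta]
        for (r in seq_len(nrow(ns))) {
          shift[ns$gene[r], ns$sample_id[r]] <- ns$log2fc_shift[r]
        }
        coupling <- ns
      }
    }
  }
  mu <- base_mean %o% rep(1, n_s)
  pe_by_sample <- pe[truth$samples$patient_id]
  mu <- sweep(mu, 2L, pe_by_sample * sf, `*`) * 2^shift
  counts <- if (config$nb_dispersion > 0) {
    stats::rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
  } else {
    stats::rpois(length(mu), mu)
  }
  m <- matrix(as.integer(counts), nrow = config$n_genes, ncol = n_s,
              dimnames = list(genes, samples))
  attr(m, "size_factors") <- sf
  attr(m, "coupling") <- coupling
  m
}

#' Simulate a complete cohort
#'
#' Convenience wrapper: variant tables plus coupled counts, with the truth
#' record completed (coupling table and true library-size factors).
#'
#' @param config A [cohort_config()].
#' @return Object of class `metlink_cohort`: `variants`, `counts`,
#'   `samples`, `gene_lengths`, `truth`, `config`.
#' @export
simulate_cohort <- function(config) {
  sim <- simulate_variant_tables(config)
  counts <- simulate_counts(sim$truth, config)
  sim$truth$coupling <- attr(counts, "coupling")
  sim$truth$size_factors <- attr(counts, "size_factors")
  structure(
    list(variants = sim$variants,
         counts = counts,
         samples = sim$samples,
         gene_lengths = data.table::data.table(gene = gene_ids(config$n_genes),
                                               length_bp = GENE_SPAN),
         truth = sim$truth,
         config = config),
    class = "metlink_cohort")
}
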