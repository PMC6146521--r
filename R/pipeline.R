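# End-to-end orchestration: simulate or load -> filter -> set algebra ->
# expression -> association -> report bundle.

#' Pipeline run configuration
#'
#' Exactly one of `input_dir` (a fixture directory as written by
#' [write_fixtures()]) or `cohort` (a [cohort_config()] for simulation mode)
#' must be given.
#'
#' @param out_dir Output directory.
#' @param input_dir Fixture directory to analyse, or `NULL`.
#' @param cohort A [cohort_config()] for simulation mode, or `NULL`.
#' @param filter A [filter_config()].
#' @param pseudocount Fold-change pseudocount.
#' @param z_threshold,n_components PCA outlier QC parameters.
#' @param min_altered Minimum altered genes per association cell.
#' @param classes Mutation classes for the association matrix.
#' @param emv_only Restrict each metastasis' variants to its exclusive
#'   metastatic set before association.
#' @param seed Seed recorded in the manifest (simulation mode takes its seed
#'   from `cohort`).
#' @return Object of class `run_config`.
#' @export
run_config <- function(out_dir,
                       input_dir = NULL,
                       cohort = NULL,
                       filter = filter_config(),
                       pseudocount = 0.5,
                       z_threshold = 3.5,
                       n_components = 4L,
                       min_altered = 3L,
                       classes = MUTATION_CLASSES,
                       emv_only = FALSE,
                       seed = NULL) {
  if (is.null(input_dir) == is.null(cohort)) {
    ml_config_error("exactly one of input_dir or a simulation cohort config must be given")
  }
  if (!is.null(cohort) && !inherits(cohort, "cohort_config")) {
    ml_config_error("cohort must be a cohort_config")
  }
  structure(
    list(out_dir = out_dir, input_dir = input_dir, cohort = cohort,
         filter = filter, pseudocount = pseudocount,
         z_threshold = z_threshold, n_components = as.integer(n_components),
         min_altered = as.integer(min_altered), classes = classes,
         emv_only = isTRUE(emv_only),
         seed = if (is.null(seed)) cohort$seed else as.integer(seed)),
    class = "run_config")
}

#' Run the full pipeline
#'
#' Sequences the stages: obtain a cohort (simulation or fixtures), run the
#' filter cascade per tumour sample, derive exclusive metastatic variants
#' and cross-patient recurrence, summarize the mutation spectrum and
#' length-normalized gene rates, normalize expression and compute per-pair
#' fold-change rankings (excluding PCA-flagged samples), and build the
#' mutation-expression association matrix.  All outputs are written as TSV
#' or JSON under `out_dir`; rerunning with the same configuration and seed
#' reproduces them byte-identically (the manifest records the seed and a
#' hash of the configuration, not timestamps).
#'
#' @param cfg A [run_config()].
#' @return The report bundle (class `metlink_run`), invisibly: cohort,
#'   per-sample filter logs, filtered variants, EMV sets, recurrence tables,
#'   spectrum summary, gene rates, QC flags, rankings, association matrix,
#'   and output paths.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "load"
  bundle <- tryCatch({
    cohort <- if (!is.null(cfg$cohort)) {
      simulate_cohort(cfg$cohort)
    } else {
      read_fixtures(cfg$input_dir)
    }

    stage <- "filter"
    tumour_samples <- cohort$samples$sample_id[cohort$samples$role != "N"]
    v <- data.table::as.data.table(cohort$variants)
    filtered_list <- list()
    filter_logs <- list()
    for (s in tumour_samples) {
      res <- run_filter_cascade(v[v$sample_id == s], cfg$filter)
      filtered_list[[s]] <- res$variants
      filter_logs[[s]] <- as.list(res$log)
    }
    filtered <- data.table::rbindlist(filtered_list, use.names = TRUE)

    stage <- "setops"
    patient_sets <- make_patient_sets(filtered, cohort$samples)
    emv <- lapply(patient_sets, derive_emv)
    recurrence <- cross_patient_recurrence(patient_sets)
    spectrum <- summarize_spectrum(filtered)
    mt_samples <- cohort$samples$sample_id[cohort$samples$role == "MT"]
    gene_rates <- gene_mutation_rates(filtered[filtered$sample_id %in% mt_samples],
                                      cohort$gene_lengths)

    stage <- "expression"
    size_factors <- compute_size_factors(cohort$counts)
    norm <- normalize_counts(cohort$counts, size_factors)
    qc_flags <- pca_outlier_flags(cohort$counts,
                                  n_components = min(cfg$n_components,
                                                     ncol(cohort$counts) - 1L),
                                  z_threshold = cfg$z_threshold,
                                  size_factors = size_factors)
    ss <- data.table::as.data.table(cohort$samples)
    normal_of <- function(s) {
      pid <- ss$patient_id[ss$sample_id == s]
      ss$sample_id[ss$patient_id == pid & ss$role == "N"]
    }
    usable <- setdiff(tumour_samples, qc_flags)
    usable <- usable[!vapply(usable, function(s) normal_of(s) %in% qc_flags,
                             logical(1))]
    rankings <- stats::setNames(lapply(usable, function(s) {
      pair_fold_change(norm, s, normal_of(s), pseudocount = cfg$pseudocount,
                       sample_sheet = ss)
    }), usable)

    stage <- "associate"
    assoc_input <- filtered
    if (cfg$emv_only) {
      emv_all <- data.table::rbindlist(emv, use.names = TRUE)
      assoc_input <- rbind(filtered[!filtered$sample_id %in% mt_samples],
                           emv_all)
    }
    assoc <- build_association_matrix(rankings, assoc_input,
                                      classes = cfg$classes,
                                      min_altered = cfg$min_altered)

    list(cohort = cohort, filtered = filtered, filter_logs = filter_logs,
         patient_sets = patient_sets, emv = emv, recurrence = recurrence,
         spectrum = spectrum, gene_rates = gene_rates,
         size_factors = size_factors, qc_flags = qc_flags,
         rankings = rankings, association = assoc, config = cfg)
  }, metlink_error = function(e) {
    ml_error(paste0("pipeline stage '", stage, "' failed: ",
                    conditionMessage(e)), class(e)[1])
  })

  bundle$paths <- write_bundle(bundle, cfg$out_dir)
  class(bundle) <- "metlink_run"
  invisible(bundle)
}

write_bundle <- function(bundle, out_dir) {
  paths <- list(
    filtered = file.path(out_dir, "filtered_variants.tsv"),
    filter_logs = file.path(out_dir, "filter_stage_logs.json"),
    emv = file.path(out_dir, "emv.tsv"),
    variant_recurrence = file.path(out_dir, "variant_recurrence.tsv"),
    gene_recurrence = file.path(out_dir, "gene_recurrence.tsv"),
    spectrum = file.path(out_dir, "spectrum.json"),
    gene_rates = file.path(out_dir, "gene_mutation_rates.tsv"),
    size_factors = file.path(out_dir, "size_factors.tsv"),
    qc_flags = file.path(out_dir, "qc_flags.txt"),
    association_wide = file.path(out_dir, "association_matrix.tsv"),
    association_long = file.path(out_dir, "association_long.tsv"),
    manifest = file.path(out_dir, "manifest.json"))
  data.table::fwrite(bundle$filtered, paths$filtered, sep = "\t")
  jsonlite::write_json(bundle$filter_logs, paths$filter_logs, auto_unbox = TRUE)
  emv_all <- data.table::rbindlist(bundle$emv, use.names = TRUE)
  data.table::fwrite(emv_all, paths$emv, sep = "\t")
  data.table::fwrite(bundle$recurrence$variant_recurrence,
                     paths$variant_recurrence, sep = "\t")
  data.table::fwrite(bundle$recurrence$gene_recurrence,
                     paths$gene_recurrence, sep = "\t")
  sp <- bundle$spectrum
  jsonlite::write_json(
    list(substitutions = as.list(sp$substitutions),
         transitions = sp$transitions, transversions = sp$transversions,
         cg_pair_mutations = sp$cg_pair_mutations,
         at_pair_mutations = sp$at_pair_mutations,
         func_region_fractions = as.list(sp$func_region_fractions),
         exonic_func_fractions = as.list(sp$exonic_func_fractions),
         n_variants = sp$n_variants, n_snv = sp$n_snv),
    paths$spectrum, auto_unbox = TRUE, digits = NA, na = "string")
  data.table::fwrite(bundle$gene_rates, paths$gene_rates, sep = "\t")
  data.table::fwrite(
    data.table::data.table(sample_id = names(bundle$size_factors),
                           size_factor = as.numeric(bundle$size_factors)),
    paths$size_factors, sep = "\t")
  writeLines(as.character(bundle$qc_flags), paths$qc_flags)
  wide_dt <- data.table::as.data.table(bundle$association$wide,
                                       keep.rownames = "mutation_class")
  data.table::fwrite(wide_dt, paths$association_wide, sep = "\t")
  data.table::fwrite(bundle$association$results, paths$association_long,
                     sep = "\t")
  cfg_file <- tempfile()
  on.exit(unlink(cfg_file))
  saveRDS(bundle$config[setdiff(names(bundle$config), "out_dir")], cfg_file,
          version = 2)
  manifest <- list(
    package = "metlink",
    package_version = as.character(utils::packageVersion("metlink")),
    seed = bundle$config$seed,
    config_hash = unname(tools::md5sum(cfg_file)),
    emv_counts = lapply(bundle$emv, nrow),
    n_filtered = nrow(bundle$filtered),
    outputs = lapply(paths[names(paths) != "manifest"], basename))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA)
  paths
}

#' Render a human-readable run report
#'
#' @param bundle A `metlink_run` from [run_pipeline()].
#' @param path Optional file to write the markdown report to.
#' @return The report as a character vector of markdown lines, invisibly if
#'   written to a file.
#' @export
render_report <- function(bundle, path = NULL) {
  required <- c("spectrum", "recurrence", "emv", "association", "filter_logs")
  missing_parts <- required[!required %in% names(bundle)]
  if (length(missing_parts)) {
    ml_usage_error(paste0("incomplete bundle, missing: ",
                          paste(missing_parts, collapse = ", ")))
  }
  sp <- bundle$spectrum
  lines <- c(
    "# metlink run report", "",
    "## Mutation spectrum (filtered variants)", "",
    sprintf("- variants: %d (SNVs: %d)", sp$n_variants, sp$n_snv),
    sprintf("- transitions: %d, transversions: %d", sp$transitions, sp$transversions),
    sprintf("- C:G-pair: %d, A:T-pair: %d", sp$cg_pair_mutations, sp$at_pair_mutations),
    "", "## Exclusive metastatic variants", "")
  emv_counts <- vapply(bundle$emv, nrow, integer(1))
  if (length(emv_counts) == 0L || sum(emv_counts) == 0L) {
    lines <- c(lines, "none")
  } else {
    lines <- c(lines, sprintf("- %s: %d EMV", names(emv_counts), emv_counts))
  }
  vr <- bundle$recurrence$variant_recurrence
  lines <- c(lines, "", "## Cross-patient recurrence", "",
             sprintf("- variants in >1 patient: %d", sum(vr$n_patients > 1)))
  wide <- bundle$association$wide
  sig <- bundle$association$significant
  shown <- wide
  shown[sig] <- paste0("**", shown[sig], "**")
  header <- paste(c("class", colnames(shown)), collapse = " | ")
  sep <- paste(rep("---", ncol(shown) + 1L), collapse = " | ")
  rows <- vapply(rownames(shown), function(r) {
    paste(c(r, shown[r, ]), collapse = " | ")
  }, character(1))
  lines <- c(lines, "", "## Mutation-expression association (-log10 p)", "",
             paste0("| ", header, " |"), paste0("| ", sep, " |"),
             paste0("| ", rows, " |"), "",
             "Bold marks significant cells (p < 0.05); 'Inf' marks -log10 p > 10.")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
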