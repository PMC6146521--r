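# Mutation-expression association: ranks of mutated genes on the FC-sorted
# list, two-sample KS against the unmutated genes, assembled per sample and
# mutation class into an association matrix.

NEGLOG10_SENTINEL <- 10

#' Associate one mutation class with one fold-change ranking
#'
#' Splits the genes of a tumour-versus-normal fold-change ranking into
#' "altered" (carrying at least one variant of the requested class in that
#' tumour sample; gene-level collapse, intergenic variants excluded) and
#' "unaltered", and compares the two groups' list positions with the
#' two-sample KS test.  Cells with fewer than `min_altered` altered genes
#' are reported as not tested.  `-log10(p)` values above 10 are flagged
#' with the display sentinel `"Inf"`; the numeric value is preserved.
#'
#' @param rank An `fc_ranking` from [pair_fold_change()].
#' @param variants Variant table; only records of `rank`'s tumour sample are
#'   used (it is an error if none could, i.e. the table has no `sample_id`).
#' @param cls Mutation class, see [mutation_class_membership()].
#' @param min_altered Minimum altered-gene count for testing, default 3.
#' @param one_sample Use the one-sample KS of altered positions against a
#'   uniform distribution over the list instead of the two-sample test.
#' @return One-row `data.table` of class `association_result`: `sample_id`,
#'   `mutation_class`, `n_altered`, `n_unaltered`, `D`, `p`, `neglog10p`,
#'   `display` (`"Inf"` sentinel applied), `significant`, `tested`.
#' @export
associate <- function(rank, variants, cls, min_altered = 3L,
                      one_sample = FALSE) {
  if (!inherits(rank, "fc_ranking") || nrow(rank) == 0L) {
    ml_usage_error("associate needs a non-empty fc_ranking")
  }
  tumour <- attr(rank, "tumour_sample")
  v <- data.table::as.data.table(variants)
  v <- v[v$sample_id == tumour]
  member <- mutation_class_membership(v, cls)
  altered_genes <- unique(v$gene[member & !is.na(v$gene) &
                                   v$func_region != "intergenic"])
  altered <- rank$rank[rank$gene %in% altered_genes]
  unaltered <- rank$rank[!rank$gene %in% altered_genes]
  n_a <- length(altered)
  n_u <- length(unaltered)
  if (n_a > 0L && n_u == 0L) {
    ml_usage_error("every ranked gene is altered; no comparison group")
  }
  base <- data.table::data.table(
    sample_id = tumour, mutation_class = cls,
    n_altered = n_a, n_unaltered = n_u,
    D = NA_real_, p = NA_real_, neglog10p = NA_real_,
    display = "", significant = FALSE, tested = FALSE)
  if (n_a < min_altered) {
    data.table::setattr(base, "class", c("association_result", class(base)))
    return(base[])
  }
  if (one_sample) {
    g <- nrow(rank)
    ks <- suppressWarnings(stats::ks.test(altered, stats::punif, min = 0, max = g))
    d <- unname(ks$statistic); p <- ks$p.value
  } else {
    ks <- ks_two_sample(altered, unaltered)
    d <- ks$statistic; p <- ks$p.value
  }
  nl <- -log10(max(p, .Machine$double.xmin))
  data.table::set(base, j = c("D", "p", "neglog10p", "display",
                              "significant", "tested"),
                  value = list(d, p, nl,
                               if (nl > NEGLOG10_SENTINEL) "Inf"
                               else formatC(nl, format = "fg", digits = 3),
                               p < 0.05, TRUE))
  data.table::setattr(base, "class", c("association_result", class(base)))
  base[]
}

#' Build the sample-by-class association matrix
#'
#' One cell per (tumour sample, mutation class): the KS comparison of
#' altered versus unaltered genes' positions on that sample's fold-change
#' ranking.  Samples without a ranking (for example flagged by QC) are
#' reported as not tested with a warning, or omitted entirely when they were
#' explicitly excluded.
#'
#' @param rankings Named list of `fc_ranking` objects, one per tumour
#'   sample.
#' @param variants Filtered variant table for all tumour samples.
#' @param classes Mutation classes to test (rows of the matrix).
#' @param min_altered Minimum altered-gene count per cell.
#' @param exclude_samples Sample ids to drop (QC outliers); their columns
#'   are absent from the result.
#' @return Object of class `association_matrix`: list with `results` (long
#'   `data.table`), `wide` (character matrix classes x samples of formatted
#'   `-log10 p`, `"Inf"` sentinel, `""` for untested), `significant`
#'   (logical matrix), `classes`, `samples`.
#' @export
build_association_matrix <- function(rankings, variants,
                                     classes = MUTATION_CLASSES,
                                     min_altered = 3L,
                                     exclude_samples = character(0)) {
  if (length(rankings) == 0L) ml_usage_error("no fold-change rankings supplied")
  if (is.null(names(rankings)) || any(names(rankings) == "")) {
    ml_usage_error("rankings must be a named list keyed by tumour sample id")
  }
  bad_cls <- setdiff(classes, MUTATION_CLASSES)
  if (length(bad_cls)) ml_usage_error(paste0("unknown class: ", paste(bad_cls, collapse = ", ")))
  samples <- setdiff(names(rankings), exclude_samples)
  rows <- list()
  for (s in samples) {
    rk <- rankings[[s]]
    for (cls in classes) {
      if (is.null(rk)) {
        warning(sprintf("no fold-change ranking for sample %s; cell not tested", s))
        r <- data.table::data.table(
          sample_id = s, mutation_class = cls, n_altered = 0L, n_unaltered = 0L,
          D = NA_real_, p = NA_real_, neglog10p = NA_real_, display = "",
          significant = FALSE, tested = FALSE)
      } else {
        # a fully-altered gene list leaves no comparison group; report the
        # cell as not tested instead of aborting the whole grid
        r <- tryCatch(
          associate(rk, variants, cls, min_altered = min_altered),
          metlink_usage_error = function(e) {
            warning(sprintf("sample %s, class %s: %s (cell not tested)",
                            s, cls, conditionMessage(e)))
            data.table::data.table(
              sample_id = s, mutation_class = cls,
              n_altered = nrow(rk), n_unaltered = 0L,
              D = NA_real_, p = NA_real_, neglog10p = NA_real_,
              display = "", significant = FALSE, tested = FALSE)
          })
      }
      rows[[length(rows) + 1L]] <- r
    }
  }
  results <- data.table::rbindlist(rows)
  wide <- matrix("", nrow = length(classes), ncol = length(samples),
                 dimnames = list(classes, samples))
  sig <- matrix(FALSE, nrow = length(classes), ncol = length(samples),
                dimnames = list(classes, samples))
  for (i in seq_len(nrow(results))) {
    wide[results$mutation_class[i], results$sample_id[i]] <- results$display[i]
    sig[results$mutation_class[i], results$sample_id[i]] <- results$significant[i]
  }
  structure(list(results = results, wide = wide, significant = sig,
                 classes = classes, samples = samples),
            class = "association_matrix")
}

#' @export
print.association_matrix <- function(x, ...) {
  cat("Mutation-expression association matrix (-log10 p; 'Inf' = p < 1e-10;",
      "* marks p < 0.05; blank = not tested)\n")
  shown <- x$wide
  shown[x$significant] <- paste0(shown[x$significant], "*")
  print(shown, quote = FALSE)
  invisible(x)
}
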