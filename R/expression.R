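# Expression normalization, per-pair fold-change rankings, BH adjustment,
# and PCA-based outlier QC.

validate_count_matrix <- function(m, allow_real = FALSE) {
  if (!is.matrix(m) || !is.numeric(m)) {
    ml_data_error("count matrix must be a numeric matrix")
  }
  if (is.null(rownames(m)) || is.null(colnames(m)) ||
      anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    ml_data_error("count matrix needs unique gene rownames and sample colnames")
  }
  if (any(m < 0) || anyNA(m)) ml_data_error("counts must be non-negative and non-missing")
  if (!allow_real && any(m != trunc(m))) {
    ml_data_error("raw counts must be integers")
  }
  invisible(m)
}

#' Median-of-ratios size factors
#'
#' Per-sample scaling factors from the median-of-ratios method: for each
#' gene with non-zero count in every sample, form the ratio of its count to
#' its geometric mean across samples; a sample's factor is the median of
#' these ratios.
#'
#' @param m Raw count matrix (genes x samples).
#' @return Named positive numeric vector of size factors.
#' @export
compute_size_factors <- function(m) {
  validate_count_matrix(m)
  if (ncol(m) < 2L) ml_usage_error("size factors need at least 2 samples")
  all_pos <- rowSums(m > 0) == ncol(m)
  if (!any(all_pos)) {
    ml_error("no gene has a non-zero count in every sample; cannot normalize",
             "metlink_normalization_error")
  }
  lm <- log(m[all_pos, , drop = FALSE])
  loggeo <- rowMeans(lm)
  factors <- apply(lm, 2L, function(col) exp(stats::median(col - loggeo)))
  stats::setNames(as.numeric(factors), colnames(m))
}

#' Normalize a count matrix by size factors
#'
#' @param m Raw count matrix.
#' @param size_factors Optional factors; computed with
#'   [compute_size_factors()] when missing.
#' @return Normalized matrix with attribute `size_factors`.
#' @export
normalize_counts <- function(m, size_factors = NULL) {
  validate_count_matrix(m)
  if (is.null(size_factors)) size_factors <- compute_size_factors(m)
  if (is.null(names(size_factors))) names(size_factors) <- colnames(m)
  if (!setequal(names(size_factors), colnames(m)) || any(size_factors <= 0)) {
    ml_usage_error("size_factors must be positive and named by sample")
  }
  out <- sweep(m, 2L, size_factors[colnames(m)], `/`)
  attr(out, "size_factors") <- size_factors[colnames(m)]
  out
}

#' Tumour-versus-normal fold-change ranking
#'
#' Gene-wise fold change `FC = (tumour + c) / (normal + c)` on normalized
#' counts, with pseudocount `c` keeping FC finite when a count is zero.
#' Genes with zero normalized count in both samples are dropped (and listed
#' in the `dropped` attribute).  Genes are ranked 1..G by descending FC;
#' ties are broken lexicographically by gene identifier, so the ranking is
#' deterministic.
#'
#' @param m_norm Normalized count matrix (see [normalize_counts()]).
#' @param tumour,normal Sample identifiers (columns of `m_norm`).
#' @param pseudocount Pseudocount `c`, default 0.5.
#' @param sample_sheet Optional data.frame with `sample_id` and `patient_id`;
#'   when given, the pair must belong to one patient.
#' @return `data.table` of class `fc_ranking` with columns `gene`, `fc`,
#'   `rank`, sorted by rank; attributes `tumour_sample`, `normal_sample`,
#'   `dropped`.
#' @export
pair_fold_change <- function(m_norm, tumour, normal, pseudocount = 0.5,
                             sample_sheet = NULL) {
  if (!all(c(tumour, normal) %in% colnames(m_norm))) {
    ml_usage_error("tumour and normal must be columns of the matrix")
  }
  if (!is.null(sample_sheet)) {
    ss <- data.table::as.data.table(sample_sheet)
    pt <- ss$patient_id[match(tumour, ss$sample_id)]
    pn <- ss$patient_id[match(normal, ss$sample_id)]
    if (is.na(pt) || is.na(pn) || pt != pn) {
      ml_error("tumour and normal samples must come from the same patient",
               "metlink_pairing_error")
    }
  }
  t_cnt <- m_norm[, tumour]
  n_cnt <- m_norm[, normal]
  keep <- !(t_cnt == 0 & n_cnt == 0)
  dropped <- rownames(m_norm)[!keep]
  fc <- (t_cnt[keep] + pseudocount) / (n_cnt[keep] + pseudocount)
  out <- data.table::data.table(gene = rownames(m_norm)[keep], fc = fc)
  data.table::setorderv(out, c("fc", "gene"), order = c(-1L, 1L))
  out[, rank := seq_len(.N)]
  data.table::setattr(out, "tumour_sample", tumour)
  data.table::setattr(out, "normal_sample", normal)
  data.table::setattr(out, "dropped", dropped)
  data.table::setattr(out, "class", c("fc_ranking", class(out)))
  out[]
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: with order statistics `p_(1) <= ... <= p_(G)`,
#' `adj_(i) = min_{j >= i} min(1, G/j * p_(j))`.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as input.
#' @export
bh_adjust <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    ml_data_error("p-values must lie in [0, 1] with no missing entries")
  }
  g <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(g / (g:1) * p[o]))[ro]
  adj
}

#' Flag expression outlier samples by PCA
#'
#' Runs PCA on log2(normalized counts + 1) with gene centering and flags
#' samples whose Euclidean distance from the sample centroid in the first
#' `n_components` components is a robust (median/MAD) z-score above
#' `z_threshold`.  Flagged samples should be excluded from downstream
#' group comparisons.
#'
#' @param m Raw count matrix.
#' @param n_components Number of leading components, default 4.
#' @param z_threshold Robust z-score cutoff; `Inf` flags nothing.
#' @param size_factors Optional precomputed size factors.
#' @return Character vector of flagged sample ids (possibly empty), with the
#'   per-sample distances and z-scores as attributes.
#' @export
pca_outlier_flags <- function(m, n_components = 4L, z_threshold = 3.5,
                              size_factors = NULL) {
  validate_count_matrix(m)
  if (ncol(m) < 3L) ml_usage_error("PCA QC needs at least 3 samples")
  if (n_components >= ncol(m)) {
    ml_usage_error("n_components must be smaller than the number of samples")
  }
  norm <- normalize_counts(m, size_factors)
  lx <- log2(norm + 1)
  lx <- lx[apply(lx, 1L, stats::var) > 0, , drop = FALSE]
  if (nrow(lx) == 0L) {
    res <- character(0)
    attr(res, "distance") <- stats::setNames(rep(0, ncol(m)), colnames(m))
    attr(res, "z") <- stats::setNames(rep(0, ncol(m)), colnames(m))
    return(res)
  }
  pc <- stats::prcomp(t(lx), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  centroid <- colMeans(scores)
  d <- sqrt(rowSums(sweep(scores, 2L, centroid)^2))
  med <- stats::median(d)
  s <- stats::mad(d, center = med)
  z <- if (s > 0) (d - med) / s else rep(0, length(d))
  flagged <- colnames(m)[z > z_threshold]
  attr(flagged, "distance") <- stats::setNames(d, colnames(m))
  attr(flagged, "z") <- stats::setNames(z, colnames(m))
  flagged
}
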