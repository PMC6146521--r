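# Term overrepresentation by one-sided Fisher / hypergeometric test.

#' Term overrepresentation test
#'
#' One-sided Fisher exact test (hypergeometric upper tail) per term on the
#' 2x2 table (selected vs not) x (in term vs not), restricted to terms whose
#' size within the universe lies in `[min_term, max_term_frac * |universe|)`
#' ("more than 2 and less than 2% of observed genes" with the defaults).
#' Reports the observed overlap and the expected count
#' `|term| * |selected| / |universe|`, with BH-adjusted p-values.
#'
#' @param selected_genes Character vector, a subset of `universe` (for
#'   example the 10% of genes with the lowest p-values).
#' @param universe Character vector of all observed genes.
#' @param term_map Either a named list of gene vectors, or a data.frame with
#'   columns `term` and `gene`.
#' @param min_term Minimum term size (within the universe), inclusive.
#' @param max_term_frac Maximum term size as a fraction of the universe,
#'   exclusive.
#' @return `data.table` with `term`, `term_size`, `count`, `expected_count`,
#'   `p`, `p_adjusted`, sorted by `p`.
#' @export
term_overrepresentation <- function(selected_genes, universe, term_map,
                                    min_term = 3L, max_term_frac = 0.02) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) ml_usage_error("empty gene universe")
  selected <- unique(as.character(selected_genes))
  if (!all(selected %in% universe)) {
    ml_usage_error("selected genes must be a subset of the universe")
  }
  if (is.data.frame(term_map)) {
    tm <- data.table::as.data.table(term_map)
    if (!all(c("term", "gene") %in% names(tm))) {
      ml_usage_error("term_map data.frame needs columns 'term' and 'gene'")
    }
    term_map <- split(as.character(tm$gene), as.character(tm$term))
  }
  term_map <- lapply(term_map, function(g) unique(intersect(g, universe)))
  sizes <- lengths(term_map)
  max_size <- max_term_frac * length(universe)
  eligible <- sizes >= min_term & sizes < max_size
  term_map <- term_map[eligible]
  if (length(term_map) == 0L) {
    return(data.table::data.table(term = character(0), term_size = integer(0),
                                  count = integer(0), expected_count = numeric(0),
                                  p = numeric(0), p_adjusted = numeric(0)))
  }
  n_u <- length(universe)
  n_s <- length(selected)
  res <- data.table::rbindlist(lapply(names(term_map), function(tn) {
    tg <- term_map[[tn]]
    k <- length(intersect(tg, selected))
    # P(X >= k), X ~ Hypergeom(|term| white, n_u - |term| black, n_s draws)
    p <- stats::phyper(k - 1L, length(tg), n_u - length(tg), n_s,
                       lower.tail = FALSE)
    data.table::data.table(term = tn, term_size = length(tg), count = k,
                           expected_count = length(tg) * n_s / n_u, p = p)
  }))
  res[, p_adjusted := bh_adjust(p)]
  data.table::setorderv(res, c("p", "term"))
  res[]
}
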