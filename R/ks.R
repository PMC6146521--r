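# Two-sample Kolmogorov-Smirnov test: D from the empirical CDFs, exact
# two-sided p by lattice-path counting when the smaller sample is small,
# asymptotic Kolmogorov distribution otherwise.

#' Two-sample Kolmogorov-Smirnov test
#'
#' Computes `D = sup |ECDF_a - ECDF_b|` and its two-sided p-value.  When the
#' smaller sample has at most `exact_limit` observations and the pooled data
#' carry no ties, the p-value is exact: it enumerates, by dynamic programming
#' over monotone lattice paths (equivalently, over all label assignments of
#' the pooled order statistics), the probability that a random assignment
#' attains `D` at least as large as observed.  Otherwise the asymptotic
#' Kolmogorov distribution is used with effective sample size
#' `n_e = n*m/(n+m)`.
#'
#' @param a,b Numeric vectors, each non-empty.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact computation;
#'   default `NULL` decides by `exact_limit` and the presence of ties.
#' @param exact_limit Largest size of the smaller sample for which the exact
#'   p-value is attempted by default.
#' @return A list of class `ks_two_sample`: `statistic` (D), `p.value`,
#'   `n`, `m`, `exact` (logical: was the exact distribution used).
#' @export
ks_two_sample <- function(a, b, exact = NULL, exact_limit = 10L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 1L || length(b) < 1L || anyNA(a) || anyNA(b)) {
    ml_usage_error("ks_two_sample requires two non-empty numeric samples without NAs")
  }
  n <- length(a); m <- length(b)
  pooled <- sort(unique(c(a, b)))
  fa <- stats::ecdf(a)(pooled)
  fb <- stats::ecdf(b)(pooled)
  d <- max(abs(fa - fb))
  has_ties <- anyDuplicated(c(a, b)) > 0L
  use_exact <- if (is.null(exact)) min(n, m) <= exact_limit && !has_ties else isTRUE(exact)
  if (use_exact && has_ties) {
    # the path-counting argument assumes exchangeable distinct pooled values
    use_exact <- FALSE
  }
  p <- if (use_exact) {
    ks_exact_pvalue(n, m, d)
  } else {
    ks_asymptotic_pvalue(n, m, d)
  }
  structure(list(statistic = d, p.value = p, n = n, m = m, exact = use_exact),
            class = "ks_two_sample")
}

# P(D >= d) under the null, by counting monotone lattice paths from (0,0) to
# (n,m) whose maximal |i*m - j*n| stays strictly below the observed integer
# statistic c = d*n*m.  All arithmetic on the band test is integer-exact;
# path counts are doubles with periodic rescaling to avoid overflow.
ks_exact_pvalue <- function(n, m, d) {
  c_int <- as.integer(round(d * n * m))
  if (c_int <= 0L) return(1)
  u <- numeric(m + 1L)
  # row i = 0: reachable prefix of cells strictly inside the band
  j <- 0:m
  u[1L] <- 1
  for (jj in seq_len(m)) {
    u[jj + 1L] <- if (jj * n < c_int) u[jj] else 0
  }
  log_scale <- 0
  for (i in 1:n) {
    inside <- abs(i * m - j * n) < c_int
    # u_new[j] = (u_new[j-1] + u_old[j]) if inside else 0
    new <- numeric(m + 1L)
    acc <- 0
    for (jj in 0:m) {
      if (inside[jj + 1L]) {
        acc <- if (jj == 0L) u[1L] else new[jj] + u[jj + 1L]
      } else {
        acc <- 0
      }
      new[jj + 1L] <- acc
    }
    u <- new
    mx <- max(u)
    if (mx > 1e250) {
      u <- u / 1e250
      log_scale <- log_scale + 250 * log(10)
    }
  }
  if (u[m + 1L] <= 0) return(1)
  log_inside <- log(u[m + 1L]) + log_scale
  p <- 1 - exp(log_inside - lchoose(n + m, n))
  min(max(p, 0), 1)
}

# Two-sided asymptotic p: Kolmogorov distribution at sqrt(n_e) * D.
ks_asymptotic_pvalue <- function(n, m, d) {
  if (d <= 0) return(1)
  n_e <- n * m / (n + m)
  lambda2 <- n_e * d^2
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda2))
  min(max(p, 0), 1)
}

#' @export
print.ks_two_sample <- function(x, ...) {
  cat(sprintf("Two-sample KS: D = %.6g, p = %.6g (%s; n = %d, m = %d)\n",
              x$statistic, x$p.value,
              if (x$exact) "exact" else "asymptotic", x$n, x$m))
  invisible(x)
}
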