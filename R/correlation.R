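# Kendall tau-b correlation with a dataset-permutation null.
#
# With only a handful of time points and many zeros, taxon index series
# are short and tie-heavy, so rank correlation with an explicit tie
# correction (tau-b) is the pairwise statistic, and its significance is
# calibrated empirically: every taxon's series is permuted independently
# across time points to build null datasets, all pairwise taus from the
# null datasets are pooled, and observed |tau| values are compared against
# that pooled null. Benjamini-Hochberg (and Bonferroni, for reference)
# control the error rate over the tens of thousands of pairs; the critical
# tau is the smallest |tau| still declared significant.

#' Kendall's tau-b between two series
#'
#' Tie-corrected rank correlation: `tau_b = (C - D) /
#' sqrt((n0 - n1)(n0 - n2))` with `n0 = n(n-1)/2` and `n1`, `n2` the
#' numbers of tied pairs within each series. Returns `NA` (undefined) if
#' either series is constant.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return tau-b in [-1, 1], or `NA` if undefined.
#' @export
kendall_tau_b <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 2L) stop("need at least 2 observations")
  pr <- combn(length(x), 2L)
  sx <- sign(x[pr[2L, ]] - x[pr[1L, ]])
  sy <- sign(y[pr[2L, ]] - y[pr[1L, ]])
  n0 <- ncol(pr)
  dx <- n0 - sum(sx == 0)
  dy <- n0 - sum(sy == 0)
  if (dx == 0 || dy == 0) return(NA_real_)
  sum(sx * sy) / sqrt(dx * dy)
}

#' All pairwise Kendall tau-b correlations between rows
#'
#' Vectorized over sample pairs: for each pair of columns (s < t) the sign
#' of the difference is recorded per taxon, so that concordant-minus-
#' discordant counts for every taxon pair are a single cross-product, and
#' tied pairs are the zero signs. Constant rows give `NA` against
#' everything (flagged in `"undefined_taxa"`); the diagonal is 1.
#'
#' @param x taxa x samples numeric matrix (>= 2 rows, >= 2 columns).
#' @return Symmetric taxa x taxa tau matrix.
#' @export
tau_matrix <- function(x) {
  stopifnot(is.matrix(x), nrow(x) >= 2L, ncol(x) >= 2L)
  pr <- combn(ncol(x), 2L)
  S <- sign(x[, pr[2L, ], drop = FALSE] - x[, pr[1L, ], drop = FALSE])
  n0 <- ncol(pr)
  untied <- n0 - rowSums(S == 0)
  num <- S %*% t(S)
  den <- sqrt(outer(untied, untied))
  tau <- ifelse(den == 0, NA_real_, num / den)
  diag(tau) <- 1
  dimnames(tau) <- list(rownames(x), rownames(x))
  attr(tau, "undefined_taxa") <- rownames(x)[untied == 0]
  tau
}

#' Pooled permutation null distribution of tau
#'
#' Generates `n_perm` null datasets by independently permuting every
#' taxon's values across time points (destroying cross-taxon association
#' while preserving each taxon's value distribution), computes all
#' pairwise tau-b within each null dataset, and pools them into one
#' vector. Undefined taus (constant rows) are dropped.
#'
#' @param index taxa x samples matrix (>= 2 taxa).
#' @param n_perm number of null datasets (default 100).
#' @param seed RNG seed.
#' @return Numeric vector of pooled null taus.
#' @export
permutation_null <- function(index, n_perm = 100, seed = 1) {
  stopifnot(nrow(index) >= 2L)
  nT <- ncol(index)
  with_seed(derive_seed(seed, 11L), {
    pooled <- vector("list", n_perm)
    for (b in seq_len(n_perm)) {
      perm <- t(apply(index, 1, function(r) r[sample.int(nT)]))
      tm <- tau_matrix(perm)
      pooled[[b]] <- tm[upper.tri(tm)]
    }
    out <- unlist(pooled)
    out[!is.na(out)]
  })
}

#' Permutation p-values for observed tau values
#'
#' Two-sided on magnitude with add-one smoothing:
#' `p = (1 + #{|null| >= |tau_obs|}) / (1 + N_null)`.
#'
#' @param tau observed tau matrix (or vector).
#' @param null_taus pooled null vector from [permutation_null()].
#' @return p-values with the same shape as `tau`; `NA` tau gives `NA` p.
#' @export
tau_pvalues <- function(tau, null_taus) {
  if (length(null_taus) == 0L) stop("empty null distribution")
  sorted <- sort(abs(null_taus))
  N <- length(sorted)
  # count of |null| >= |tau| via position in the sorted null
  cnt <- N - findInterval(abs(tau) - 1e-12, sorted)
  p <- (1 + cnt) / (1 + N)
  p[is.na(tau)] <- NA_real_
  if (is.matrix(tau)) {
    p <- matrix(p, nrow(tau), ncol(tau), dimnames = dimnames(tau))
    diag(p) <- NA_real_
  }
  p
}

#' Multiple-comparison adjustment and critical tau
#'
#' Applies Benjamini-Hochberg step-up adjustment (and Bonferroni, reported
#' alongside) over all unique pairwise p-values, and derives the critical
#' tau: the smallest |tau| among pairs significant at `alpha` after BH
#' adjustment (`Inf` if none).
#'
#' @param p symmetric p-value matrix from [tau_pvalues()].
#' @param tau observed tau matrix.
#' @param alpha significance level (default 0.05).
#' @return List with matrices `p_adjusted` (BH), `p_bonferroni`,
#'   `significant` (logical, BH <= alpha), and scalar `critical_tau`.
#' @export
adjust_and_threshold <- function(p, tau, alpha = 0.05) {
  ut <- upper.tri(p)
  pv <- p[ut]
  ok <- !is.na(pv)
  bh <- bonf <- rep(NA_real_, length(pv))
  bh[ok] <- p.adjust(pv[ok], method = "BH")
  bonf[ok] <- p.adjust(pv[ok], method = "bonferroni")
  fill <- function(v) {
    m <- matrix(NA_real_, nrow(p), ncol(p), dimnames = dimnames(p))
    m[ut] <- v
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    m
  }
  p_adj <- fill(bh)
  p_bonf <- fill(bonf)
  sig <- !is.na(p_adj) & p_adj <= alpha
  critical_tau <- if (any(sig)) min(abs(tau[sig])) else Inf
  list(p_adjusted = p_adj, p_bonferroni = p_bonf, significant = sig,
       critical_tau = critical_tau)
}

#' Full correlation-significance analysis of an index table
#'
#' Computes the pairwise tau-b matrix, the pooled permutation null, raw
#' and adjusted p-values, and the critical tau.
#'
#' @param index taxa x time points index matrix.
#' @param n_perm number of permutation null datasets (default 100).
#' @param alpha significance level (default 0.05).
#' @param seed RNG seed for the permutation null.
#' @return A `correlation_result` list: `tau`, `null_taus`, `p`,
#'   `p_adjusted`, `p_bonferroni`, `significant`, `critical_tau`, `alpha`,
#'   `n_permutations`, `seed`.
#' @export
correlation_significance <- function(index, n_perm = 100, alpha = 0.05,
                                     seed = 1) {
  tau <- tau_matrix(index)
  null_taus <- permutation_null(index, n_perm = n_perm, seed = seed)
  p <- tau_pvalues(tau, null_taus)
  adj <- adjust_and_threshold(p, tau, alpha = alpha)
  structure(c(list(tau = tau, null_taus = null_taus, p = p, alpha = alpha,
                   n_permutations = n_perm, seed = seed), adj),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  m <- sum(upper.tri(x$tau))
  nsig <- sum(x$significant[upper.tri(x$significant)], na.rm = TRUE)
  cat(sprintf(paste0("correlation_result: %d taxa, %d pairs, %d null taus; ",
                     "%d significant at alpha=%.2f, critical |tau| = %s\n"),
              nrow(x$tau), m, length(x$null_taus), nsig, x$alpha,
              format(round(x$critical_tau, 3))))
  invisible(x)
}

#' Long-format pair table from a correlation result
#'
#' @param result a `correlation_result`.
#' @return data.frame with taxon_a, taxon_b, tau, p, p_adj, p_bonferroni,
#'   significant.
#' @export
correlation_pairs <- function(result) {
  ut <- which(upper.tri(result$tau), arr.ind = TRUE)
  data.frame(taxon_a = rownames(result$tau)[ut[, 1]],
             taxon_b = colnames(result$tau)[ut[, 2]],
             tau = result$tau[ut], p = result$p[ut],
             p_adj = result$p_adjusted[ut],
             p_bonferroni = result$p_bonferroni[ut],
             significant = result$significant[ut],
             stringsAsFactors = FALSE)
}
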