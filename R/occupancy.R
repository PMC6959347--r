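# Site-occupancy filtering of OTUs from PCR replicate detection histories.
#
# Each field sample is treated as a site assayed by K independent PCR
# replicates. For one OTU, the probability of observing k positive
# replicates out of K at a site is a zero-inflated binomial:
#
#   P(k) = psi * C(K, k) p^k (1-p)^(K-k) + (1 - psi) * 1{k = 0}
#
# where psi is the probability the OTU truly occurs at the site and p the
# per-replicate detection probability. OTUs whose maximum-likelihood psi
# falls below a threshold (default 0.8) are treated as likely false
# positives and removed.

#' Build per-OTU detection histories from a count table
#'
#' A detection is any strictly positive read count. Field samples are
#' grouped by time point; each (OTU, field sample) record carries k (number
#' of replicates with a detection) and K (replicates assayed). Replicates
#' with zero total reads still count in K.
#'
#' @param counts OTU x sample count matrix.
#' @param metadata data.frame with `sample_id`, `type`, `timepoint`,
#'   `replicate`; only `type == "field"` columns are used.
#' @return data.frame with columns `otu`, `sample`, `k`, `K`.
#' @export
detection_history <- function(counts, metadata) {
  fld <- metadata[metadata$type == "field", , drop = FALSE]
  fld <- fld[fld$sample_id %in% colnames(counts), , drop = FALSE]
  if (nrow(fld) == 0L) stop("no field samples in metadata/counts")
  groups <- split(fld$sample_id, fld$timepoint)
  det <- counts[, fld$sample_id, drop = FALSE] > 0
  recs <- lapply(names(groups), function(g) {
    cols <- groups[[g]]
    data.frame(otu = rownames(counts),
               sample = g,
               k = as.integer(rowSums(det[, cols, drop = FALSE])),
               K = length(cols),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

# Log-likelihood of (psi, p) for one OTU's history.
occupancy_loglik <- function(psi, p, k, K) {
  lik <- psi * dbinom(k, K, p) + (1 - psi) * (k == 0)
  sum(log(lik))
}

#' Fit the site-occupancy model for one OTU
#'
#' Maximizes the zero-inflated binomial likelihood over (psi, p) by a
#' coarse 0.01 grid followed by bounded local optimization, breaking exact
#' ties toward smaller psi. Degenerate histories are handled at the
#' boundary: all-detected gives (1, 1); never-detected gives (0, 0) with p
#' unidentifiable and reported as 0 by convention.
#'
#' @param k integer vector, detections per sample.
#' @param K integer vector (or scalar) of replicates assayed per sample.
#' @return List with `psi_hat`, `p_hat`, `log_lik`.
#' @export
fit_occupancy <- function(k, K) {
  if (length(K) == 1L) K <- rep(K, length(k))
  stopifnot(length(k) >= 1L, all(k >= 0L), all(k <= K), all(K >= 1L))
  if (all(k == 0L)) return(list(psi_hat = 0, p_hat = 0, log_lik = 0))
  if (all(k == K)) return(list(psi_hat = 1, p_hat = 1, log_lik = 0))

  grid <- seq(0, 1, by = 0.01)
  # ll[i, j] = loglik(psi_i, p_j); built sample-by-sample, vectorized in p
  B <- vapply(grid, function(p) dbinom(k, K, p), numeric(length(k)))
  z <- as.numeric(k == 0)
  ll <- matrix(0, length(grid), length(grid))
  for (s in seq_along(k)) {
    ll <- ll + log(outer(grid, B[s, ]) + outer(1 - grid, rep(z[s],
                                                             length(grid))))
  }
  best <- which(ll >= max(ll[is.finite(ll)]) - 1e-12, arr.ind = TRUE)
  # ties broken toward smaller psi (then smaller p for determinism)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  start <- c(grid[best[1]], grid[best[2]])

  nll <- function(par) -occupancy_loglik(par[1], par[2], k, K)
  opt <- tryCatch(
    optim(pmin(pmax(start, 1e-6), 1 - 1e-6), nll, method = "L-BFGS-B",
          lower = 1e-9, upper = 1 - 1e-9),
    error = function(e) NULL)
  if (!is.null(opt) && -opt$value >= ll[best[1], best[2]]) {
    psi_hat <- opt$par[1]; p_hat <- opt$par[2]; logl <- -opt$value
  } else {
    psi_hat <- start[1]; p_hat <- start[2]
    logl <- ll[best[1], best[2]]
  }
  # snap to boundaries when the optimizer is within numerical dust of them
  if (psi_hat > 1 - 1e-6) psi_hat <- 1
  if (p_hat > 1 - 1e-6) p_hat <- 1
  list(psi_hat = psi_hat, p_hat = p_hat, log_lik = logl)
}

#' Fit occupancy for every OTU in a detection history table
#'
#' @param history output of [detection_history()].
#' @return data.frame with `otu`, `psi_hat`, `p_hat`, `log_lik`.
#' @export
fit_occupancy_all <- function(history) {
  per_otu <- split(history, history$otu)
  out <- lapply(per_otu, function(h) {
    fit <- fit_occupancy(h$k, h$K)
    data.frame(otu = h$otu[1], psi_hat = fit$psi_hat, p_hat = fit$p_hat,
               log_lik = fit$log_lik, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Filter OTUs by estimated occurrence probability
#'
#' Retains OTUs with `psi_hat >= threshold` (the boundary is kept; only
#' strictly smaller estimates are eliminated).
#'
#' @param estimates output of [fit_occupancy_all()].
#' @param threshold occupancy probability threshold (default 0.8).
#' @return List with `retained` (character vector of OTU ids) and `audit`
#'   (per-OTU data.frame with a `retained` flag).
#' @export
filter_otus <- function(estimates, threshold = 0.8) {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1)
    stop("'threshold' must be in [0, 1]")
  audit <- estimates
  audit$retained <- estimates$psi_hat >= threshold
  list(retained = estimates$otu[audit$retained], audit = audit)
}
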