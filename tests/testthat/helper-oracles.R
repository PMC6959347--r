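# Independent oracles. These deliberately use the slowest, most literal
# formulation of each statistic and share no code with the package
# implementations they check.

# Kendall tau-b by naive O(n^2) pair enumeration.
oracle_tau <- function(x, y) {
  n <- length(x)
  C <- D <- tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      dx <- x[j] - x[i]
      dy <- y[j] - y[i]
      if (dx == 0 && dy == 0) {
        tx <- tx + 1; ty <- ty + 1
      } else if (dx == 0) {
        tx <- tx + 1
      } else if (dy == 0) {
        ty <- ty + 1
      } else if (sign(dx) == sign(dy)) {
        C <- C + 1
      } else {
        D <- D + 1
      }
    }
  }
  n0 <- n * (n - 1) / 2
  den <- sqrt((n0 - tx) * (n0 - ty))
  if (den == 0) return(NA_real_)
  (C - D) / den
}

# Benjamini-Hochberg step-up, coded from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Topological overlap by an explicit triple loop.
oracle_tom <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  tom <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      shared <- 0
      for (u in seq_len(n)) shared <- shared + a[i, u] * a[u, j]
      tom[i, j] <- (shared + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  tom
}

# All permutations of a vector, recursively (40,320 rows for n = 8).
all_perms <- function(v) {
  n <- length(v)
  if (n == 1L) return(matrix(v, 1, 1))
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(v[i], all_perms(v[-i]), deparse.level = 0)))
}

# Exact null distribution of tau for untied series of length n: tau of
# each rank permutation against the identity order.
exact_tau_null <- function(n) {
  P <- all_perms(seq_len(n))
  pr <- utils::combn(n, 2)
  S <- sign(P[, pr[2, ], drop = FALSE] - P[, pr[1, ], drop = FALSE])
  rowSums(S) / ncol(pr)
}

# Occupancy likelihood maximized by brute-force fine grid (ties kept at
# the smallest psi, then smallest p, matching the fit convention).
oracle_occupancy_grid <- function(k, K, step = 0.001) {
  if (length(K) == 1L) K <- rep(K, length(k))
  grid <- seq(0, 1, by = step)
  B <- vapply(grid, function(p) dbinom(k, K, p), numeric(length(k)))
  z <- as.numeric(k == 0)
  best <- c(NA, NA)
  best_ll <- -Inf
  for (psi in grid) {
    # rows = candidate p, columns = samples
    lik <- psi * t(B) + rep((1 - psi) * z, each = length(grid))
    ll <- rowSums(log(lik))
    i <- which.max(ll)
    if (ll[i] > best_ll + 1e-12) {
      best_ll <- ll[i]
      best <- c(psi, grid[i])
    }
  }
  list(psi = best[1], p = best[2], log_lik = best_ll)
}
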