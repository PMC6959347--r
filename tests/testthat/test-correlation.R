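# Kendall tau-b, the permutation null, and multiple-comparison control.

test_that("tau-b is exact on monotone series", {
  expect_equal(kendall_tau_b(1:4, 1:4), 1)
  expect_equal(kendall_tau_b(1:4, 4:1), -1)
  expect_error(kendall_tau_b(1:4, 1:5), "length mismatch")
  expect_true(is.na(kendall_tau_b(c(1, 1, 1), c(1, 2, 3))))
})

test_that("tau-b equals the naive pair-counting oracle on tied series", {
  expect_equal(kendall_tau_b(c(1, 1, 2, 3), c(1, 2, 2, 3)),
               oracle_tau(c(1, 1, 2, 3), c(1, 2, 2, 3)))
  set.seed(17)
  for (i in 1:300) {
    n <- sample(3:10, 1)
    x <- sample(0:4, n, replace = TRUE)
    y <- sample(0:4, n, replace = TRUE)
    expect_identical(is.na(kendall_tau_b(x, y)), is.na(oracle_tau(x, y)))
    if (!is.na(oracle_tau(x, y)))
      expect_equal(kendall_tau_b(x, y), oracle_tau(x, y), tolerance = 1e-12)
  }
})

test_that("tau-b agrees with stats::cor where both are defined", {
  set.seed(18)
  for (i in 1:50) {
    x <- sample(0:5, 8, replace = TRUE)
    y <- sample(0:5, 8, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(kendall_tau_b(x, y), cor(x, y, method = "kendall"),
                 tolerance = 1e-12)
  }
})

test_that("tau_matrix matches the scalar function cell by cell", {
  set.seed(19)
  X <- matrix(sample(0:3, 10 * 8, replace = TRUE), 10, 8,
              dimnames = list(paste0("r", 1:10), NULL))
  X[4, ] <- 2  # constant row
  tm <- tau_matrix(X)
  expect_equal(unname(diag(tm)), rep(1, 10))
  expect_equal(tm, t(tm))
  expect_equal(attr(tm, "undefined_taxa"), "r4")
  for (i in 1:9) {
    for (j in (i + 1):10) {
      expect_equal(tm[i, j], kendall_tau_b(X[i, ], X[j, ]), tolerance = 1e-12)
    }
  }
})

test_that("each null dataset contributes choose(m, 2) taus", {
  set.seed(20)
  X <- matrix(rnorm(20 * 8), 20, 8)
  null <- permutation_null(X, n_perm = 7, seed = 5)
  expect_length(null, 7 * choose(20, 2))
  expect_identical(null, permutation_null(X, n_perm = 7, seed = 5))
  expect_false(identical(null, permutation_null(X, n_perm = 7, seed = 6)))
})

test_that("the pooled null is centred near zero for untied series", {
  set.seed(21)
  X <- matrix(rnorm(30 * 8), 30, 8)
  null <- permutation_null(X, n_perm = 40, seed = 2)
  se <- sd(null) / sqrt(length(null))
  # dependent draws: use a generous multiple of the naive standard error
  expect_lt(abs(mean(null)), 10 * se + 0.01)
})

test_that("permutation tail matches exhaustive n=8 enumeration", {
  exact <- exact_tau_null(8)
  p_exact <- mean(abs(exact) >= 5 / 7 - 1e-12)
  set.seed(22)
  X <- matrix(rnorm(40 * 8), 40, 8)
  n_perm <- 60
  null <- permutation_null(X, n_perm = n_perm, seed = 3)
  per_dataset <- matrix(abs(null) >= 5 / 7 - 1e-12, ncol = n_perm)
  f <- colMeans(per_dataset)  # one tail estimate per null dataset
  se <- sd(f) / sqrt(n_perm)
  expect_lt(abs(mean(f) - p_exact), qnorm(0.995) * se + 1e-3)
})

test_that("p-values follow the add-one smoothed tail count", {
  null <- seq(-0.9, 0.9, length.out = 10000)
  expect_equal(tau_pvalues(0.999, null), 1 / (10000 + 1))
  expect_gt(tau_pvalues(0, null), 0.9)
  set.seed(23)
  null <- rnorm(500, 0, 0.3)
  taus <- runif(20, -1, 1)
  for (t in taus) {
    direct <- (1 + sum(abs(null) >= abs(t) - 1e-12)) / (1 + length(null))
    expect_equal(unname(tau_pvalues(t, null)), direct)
  }
})

test_that("BH adjustment matches the worked example and the oracle", {
  p <- c(0.01, 0.02, 0.03)
  expect_equal(oracle_bh(p), c(0.03, 0.03, 0.03))
  tau <- matrix(0.9, 3, 3); diag(tau) <- 1
  pm <- matrix(NA_real_, 3, 3)
  pm[upper.tri(pm)] <- p
  pm[lower.tri(pm)] <- t(pm)[lower.tri(pm)]
  adj <- adjust_and_threshold(pm, tau, alpha = 0.05)
  expect_equal(adj$p_adjusted[upper.tri(pm)], c(0.03, 0.03, 0.03))
  set.seed(24)
  for (i in 1:20) {
    m <- sample(3:40, 1)
    pv <- runif(m)^2
    expect_equal(stats::p.adjust(pv, "BH"), oracle_bh(pv), tolerance = 1e-12)
  }
})

test_that("the smallest p-value's BH adjustment can equal Bonferroni", {
  # with m equal p-values BH adjusts each to p (rank-m step-up), NOT m*p;
  # the BH/Bonferroni equivalence holds for a dominant smallest p-value
  p <- rep(0.02, 6)
  expect_equal(oracle_bh(p), p)
  p2 <- c(0.001, 0.5, 0.6)
  expect_equal(min(oracle_bh(p2)), min(stats::p.adjust(p2, "bonferroni")))
})

test_that("BH significance contains Bonferroni significance", {
  set.seed(25)
  X <- matrix(sample(0:3, 15 * 8, replace = TRUE), 15, 8,
              dimnames = list(paste0("t", 1:15), NULL))
  res <- correlation_significance(X, n_perm = 30, seed = 4)
  ut <- upper.tri(res$p)
  ok <- !is.na(res$p_adjusted[ut])
  bh_sig <- res$p_adjusted[ut][ok] <= res$alpha
  bf_sig <- res$p_bonferroni[ut][ok] <= res$alpha
  expect_true(all(bh_sig[bf_sig]))
  # BH keeps the p-value ordering
  o <- order(res$p[ut][ok])
  expect_true(all(diff(res$p_adjusted[ut][ok][o]) >= -1e-12))
})

test_that("critical tau is the smallest significant |tau|, Inf if none", {
  tau <- matrix(c(1, 0.95, 0.1,
                  0.95, 1, 0.2,
                  0.1, 0.2, 1), 3, 3)
  pm <- matrix(c(NA, 0.001, 0.9,
                 0.001, NA, 0.8,
                 0.9, 0.8, NA), 3, 3)
  adj <- adjust_and_threshold(pm, tau, alpha = 0.05)
  expect_equal(adj$critical_tau, 0.95)
  adj2 <- adjust_and_threshold(pm, tau, alpha = 1e-6)
  expect_identical(adj2$critical_tau, Inf)
})

test_that("constant series are excluded from testing with an audit trail", {
  X <- rbind(a = c(1, 2, 3, 4), b = c(4, 3, 2, 1), c = c(2, 2, 2, 2))
  res <- correlation_significance(X, n_perm = 10, seed = 1)
  expect_true(all(is.na(res$tau["c", c("a", "b")])))
  expect_true(all(is.na(res$p_adjusted["c", c("a", "b")])))
  expect_equal(attr(res$tau, "undefined_taxa"), "c")
  expect_false(any(res$significant["c", ]))
})
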