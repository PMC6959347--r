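# Proportional decontamination and Bray-Curtis replicate QC.

test_that("proportionalize divides by column sums and flags empty columns", {
  counts <- cbind(s1 = c(2, 2, 4), s2 = c(0, 0, 0))
  rownames(counts) <- c("a", "b", "c")
  props <- proportionalize(counts)
  expect_equal(unname(props[, "s1"]), c(0.25, 0.25, 0.5))
  expect_equal(unname(props[, "s2"]), c(0, 0, 0))
  expect_equal(attr(props, "zero_columns"), "s2")
  expect_error(proportionalize(cbind(c(-1, 2))), "negative")
})

test_that("every proportion column sums to 0 or 1 on generated data", {
  sim <- simulate_community(community_scenario(n_taxa = 20, n_modules = 2,
                                               n_loci = 1, seed = 5))
  props <- proportionalize(sim$counts[[1]])
  expect_true(all(abs(colSums(props) - 1) < 1e-9 | colSums(props) == 0))
})

test_that("contamination estimate takes max (or mean) across controls", {
  props <- cbind(f1 = c(0.7, 0.3), ctl1 = c(0.1, 0.9), ctl2 = c(0.3, 0.7))
  rownames(props) <- c("a", "b")
  expect_equal(unname(estimate_contamination(props, c("ctl1", "ctl2"))["a"]),
               0.3)
  expect_equal(unname(estimate_contamination(props, c("ctl1", "ctl2"),
                                             method = "mean")["a"]), 0.2)
  none <- estimate_contamination(props, character(0))
  expect_true(all(none == 0))
})

test_that("injected contaminants are detected in the control columns", {
  sim <- simulate_community(community_scenario(seed = 4))
  props <- proportionalize(sim$counts[["16S"]])
  ctrl <- sim$metadata$sample_id[sim$metadata$type != "field"]
  prof <- estimate_contamination(props, ctrl)
  cont <- rownames(props)[sub("_OTU[0-9]+$", "", rownames(props)) %in%
                            sim$truth$contaminants]
  expect_gt(mean(prof[cont] > 0), 0.9)
})

test_that("subtraction floors at zero, renormalizes, and is idempotent", {
  props <- cbind(s1 = c(0.05, 0.95), s2 = c(0.5, 0.5))
  rownames(props) <- c("a", "b")
  prof <- c(a = 0.3, b = 0)
  out <- subtract_contamination(props, prof)
  expect_equal(unname(out[, "s1"]), c(0, 1))
  expect_equal(unname(colSums(out)), c(1, 1))
  # zero-contamination profile is the identity
  ident <- subtract_contamination(props, c(a = 0, b = 0))
  expect_equal(ident, props, ignore_attr = TRUE)
  # rows already zeroed stay zero under a second application
  again <- subtract_contamination(out, prof)
  expect_true(all(again["a", out["a", ] == 0] == 0))
})

test_that("control-only taxa vanish from all field samples", {
  sim <- simulate_community(community_scenario(seed = 4))
  meta <- sim$metadata
  ctrl <- meta$sample_id[meta$type != "field"]
  fld <- meta$sample_id[meta$type == "field"]
  props <- proportionalize(sim$counts[["18S"]])
  post <- subtract_contamination(props, estimate_contamination(props, ctrl))
  # contaminants whose field proportion never exceeds their control maximum
  prof <- estimate_contamination(props, ctrl)
  fully_covered <- rownames(props)[apply(props[, fld] <= prof, 1, all) &
                                     prof > 0]
  expect_gt(length(fully_covered), 0)
  expect_true(all(post[fully_covered, fld] == 0))
})

test_that("contaminant signal is at least 90% removed on defaults", {
  sim <- simulate_community(community_scenario(seed = 4))
  meta <- sim$metadata
  ctrl <- meta$sample_id[meta$type != "field"]
  fld <- meta$sample_id[meta$type == "field"]
  reduced <- vapply(names(sim$counts), function(l) {
    props <- proportionalize(sim$counts[[l]])
    post <- subtract_contamination(props, estimate_contamination(props, ctrl))
    cont <- rownames(props)[sub("_OTU[0-9]+$", "", rownames(props)) %in%
                              sim$truth$contaminants]
    pre_tot <- rowSums(props[cont, fld])
    post_tot <- rowSums(post[cont, fld])
    mean(post_tot < 0.1 * pmax(pre_tot, .Machine$double.xmin))
  }, numeric(1))
  expect_gte(mean(reduced), 0.9)
})

test_that("bray_curtis matches hand values and the vegan oracle", {
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(1, 0, 0), c(0, 2, 3)), 1)
  expect_equal(bray_curtis(c(0.5, 0.5, 0), c(0.25, 0.25, 0.5)), 0.5)
  expect_equal(bray_curtis(c(0, 0), c(0, 0)), 0)
  skip_if_not_installed("vegan")
  set.seed(2)
  for (i in 1:20) {
    x <- runif(12); y <- runif(12)
    expect_equal(bray_curtis(x, y),
                 as.numeric(vegan::vegdist(rbind(x, y), "bray")),
                 tolerance = 1e-12)
  }
})

test_that("bray_curtis is symmetric, bounded, and 0 iff proportional", {
  set.seed(9)
  for (i in 1:25) {
    x <- rgamma(10, 0.5); y <- rgamma(10, 0.5)
    b <- bray_curtis(x, y)
    expect_equal(b, bray_curtis(y, x))
    expect_gte(b, 0); expect_lte(b, 1)
  }
  x <- runif(6)
  expect_equal(bray_curtis(x / sum(x), 3 * x / sum(3 * x)), 0)
})

test_that("replicate_dissimilarity returns the max pair per sample", {
  props <- cbind(r1 = c(1, 0) / 1, r2 = c(1, 0) / 1, r3 = c(0, 1) / 1)
  rownames(props) <- c("a", "b")
  d <- replicate_dissimilarity(props, list(s = c("r1", "r2", "r3")))
  expect_equal(unname(d), 1)
  d1 <- replicate_dissimilarity(props, list(s = "r1"))
  expect_equal(unname(d1), 0)
})

test_that("drop threshold is strict: 0.49 retained, 0.50 dropped", {
  d <- c(t1 = 0.49, t2 = 0.50, t3 = 0.1)
  out <- drop_dissimilar_samples(d, threshold = 0.49)
  expect_setequal(out$retained, c("t1", "t3"))
  expect_error(drop_dissimilar_samples(c(a = 0.9, b = 0.95), 0.49),
               "all samples dropped")
})

test_that("the planted corrupted replicate drops exactly its time point", {
  sc <- community_scenario(seed = 11, corrupt_timepoint = 4)
  res <- run_pipeline(pipeline_config(seed = 11, scenario = sc))
  for (l in names(res$replicate_qc)) {
    rep <- res$replicate_qc[[l]]
    expect_identical(rep$sample[rep$dropped], "4")
  }
})

test_that("collapse_replicates averages and renormalizes", {
  props <- cbind(r1 = c(0.2, 0.8), r2 = c(0.4, 0.6))
  rownames(props) <- c("a", "b")
  out <- collapse_replicates(props, list(s = c("r1", "r2")))
  expect_equal(unname(out[, "s"]), c(0.3, 0.7))
})
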