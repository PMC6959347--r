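# Synthetic community generator: planted structure, bias, contamination.

small_scenario <- function(...) {
  community_scenario(n_taxa = 24, n_modules = 3, n_loci = 2,
                     library_size = 5000, otus_per_taxon = 1, ...)
}

test_that("identical scenario and seed give bit-identical output", {
  sc <- small_scenario(seed = 9)
  s1 <- simulate_community(sc)
  s2 <- simulate_community(sc)
  expect_identical(s1, s2)
  s3 <- simulate_community(small_scenario(seed = 10))
  expect_false(identical(s1$counts, s3$counts))
})

test_that("zero noise forces identical rank orders within modules", {
  sc <- community_scenario(n_taxa = 10, n_modules = 2, n_timepoints = 4,
                           sigma = 0, terrestrial_fraction = 0, seed = 3)
  lat <- generate_latent_dynamics(sc)
  tau <- tau_matrix(lat$abundance)
  for (g in 1:2) {
    idx <- names(lat$module_truth)[lat$module_truth == g]
    sub <- tau[idx, idx]
    expect_true(all(abs(sub[upper.tri(sub)] - 1) < 1e-12))
  }
})

test_that("latent abundances are nonnegative with a positive entry per taxon", {
  for (seed in c(1, 7, 23)) {
    lat <- generate_latent_dynamics(small_scenario(seed = seed))
    expect_true(all(lat$abundance >= 0))
    expect_true(all(apply(lat$abundance, 1, max) > 0))
  }
})

test_that("archetypes peak at distinct time points and are rank-distinct", {
  sc <- community_scenario(seed = 5)
  lat <- generate_latent_dynamics(sc)
  expect_equal(anyDuplicated(lat$peaks), 0L)
  G <- nrow(lat$archetype)
  for (g in seq_len(G - 1)) {
    for (h in seq(g + 1, G)) {
      expect_lte(abs(kendall_tau_b(lat$archetype[g, ], lat$archetype[h, ])),
                 sc$arch_max_tau + 1e-12)
    }
  }
})

test_that("too many modules for the time series errors", {
  sc <- community_scenario(n_taxa = 30, n_modules = 9, n_timepoints = 8,
                           terrestrial_fraction = 0)
  expect_error(generate_latent_dynamics(sc), "n_modules")
})

test_that("within-module tau exceeds between-module tau (sigma 0.3, seed 1)", {
  sc <- community_scenario(n_taxa = 60, n_modules = 3, sigma = 0.3, seed = 1,
                           terrestrial_fraction = 0)
  lat <- generate_latent_dynamics(sc)
  tau <- tau_matrix(lat$abundance)
  mt <- lat$module_truth
  ut <- which(upper.tri(tau), arr.ind = TRUE)
  same <- mt[ut[, 1]] == mt[ut[, 2]]
  within_mean <- mean(tau[ut][same], na.rm = TRUE)
  between_mean <- mean(tau[ut][!same], na.rm = TRUE)
  expect_gt(within_mean, between_mean)
  # planted-structure sanity margin
  expect_gte(within_mean - between_mean, 0.3)
})

test_that("noise-free environment variables track their archetypes exactly", {
  sc <- small_scenario(seed = 2, env_noise_frac = 0)
  lat <- generate_latent_dynamics(sc)
  env <- generate_environment(sc, lat)
  link <- attr(env, "linkage")
  expect_gte(length(link), 1L)
  for (v in names(link)) {
    expect_equal(cor(env[[v]], lat$archetype[link[[v]], ]), 1,
                 tolerance = 1e-12)
  }
})

test_that("linked variables reach Spearman 0.7; noise variables stay weak", {
  sc <- community_scenario(seed = 1)  # default env_noise_frac = 0.1
  lat <- generate_latent_dynamics(sc)
  env <- generate_environment(sc, lat)
  link <- attr(env, "linkage")
  for (v in names(link)) {
    expect_gte(abs(cor(env[[v]], lat$archetype[link[[v]], ],
                       method = "spearman")), 0.7)
  }
  for (v in attr(env, "noise_variables")) {
    rs <- apply(lat$archetype, 1, function(s)
      abs(cor(env[[v]], s, method = "spearman")))
    expect_true(all(rs < 0.99))
  }
})

test_that("read proportions follow latent abundance when unbiased", {
  sc <- community_scenario(n_taxa = 20, n_modules = 2, n_loci = 1,
                           otus_per_taxon = 1, terrestrial_fraction = 0,
                           contamination_rate = 0, detection_prob = 1,
                           efficiency_zero_fraction = 0,
                           library_size = 2e5, n_replicates = 1, seed = 6)
  lat <- generate_latent_dynamics(sc)
  sim <- generate_reads(sc, lat)
  counts <- sim$counts[[1]]
  field <- sim$metadata$sample_id[sim$metadata$type == "field"]
  E <- sim$truth$efficiency[, 1]
  for (t in c(1, 4, 8)) {
    col <- counts[, sprintf("T%02d_R1", t)]
    w <- lat$abundance[, t] * E[sub("_OTU1$", "", names(col))]
    expected <- w / sum(w)
    expect_lt(max(abs(col / sum(col) - expected)), 0.01)
  }
})

test_that("contaminant-only taxa have zero field counts without contamination", {
  sc <- community_scenario(n_taxa = 30, n_modules = 3, n_loci = 2,
                           otus_per_taxon = 1, terrestrial_fraction = 0.2,
                           contamination_rate = 0, seed = 8)
  sim <- simulate_community(sc)
  field <- sim$metadata$sample_id[sim$metadata$type == "field"]
  ctrl <- sim$metadata$sample_id[sim$metadata$type != "field"]
  terr_otus <- sim$taxonomy$otu_id[sim$taxonomy$habitat == "terrestrial"]
  for (l in names(sim$counts)) {
    expect_true(all(sim$counts[[l]][terr_otus, field] == 0))
  }
  # but the contaminant pool does land in the controls at some locus
  ctrl_reads <- sum(vapply(sim$counts, function(m)
    sum(m[terr_otus, ctrl]), numeric(1)))
  expect_gt(ctrl_reads, 0)
})

test_that("non-amplifying taxon-locus pairs yield zero counts (seed 7)", {
  sc <- community_scenario(seed = 7)
  sim <- simulate_community(sc)
  E <- sim$truth$efficiency
  otu_tax <- sub("_OTU[0-9]+$", "", rownames(sim$counts[[1]]))
  checked <- 0L
  for (tx in rownames(E)) {
    dead <- names(which(E[tx, ] == 0))
    live <- names(which(E[tx, ] > 0))
    if (!length(dead) || !length(live)) next
    rows <- which(otu_tax == tx)
    for (l in dead) expect_equal(sum(sim$counts[[l]][rows, ]), 0)
    checked <- checked + 1L
  }
  expect_gt(checked, 5L)  # the 25% zero spike must actually bite
  # and at least one such taxon is seen at a live locus
  tx <- rownames(E)[rowSums(E == 0) > 0 & rowSums(E > 0) > 0][1]
  live <- names(which(E[tx, ] > 0))[1]
  expect_gt(sum(sim$counts[[live]][otu_tax == tx, ]), 0)
})

test_that("field replicate column sums equal the configured library size", {
  sc <- small_scenario(seed = 12)
  sim <- simulate_community(sc)
  field <- sim$metadata$sample_id[sim$metadata$type == "field"]
  for (l in names(sim$counts)) {
    expect_true(all(colSums(sim$counts[[l]][, field]) == sc$library_size))
  }
})

test_that("scenario validation rejects bad parameters", {
  expect_error(community_scenario(n_taxa = 0), "positive integer")
  expect_error(community_scenario(detection_prob = 1.2), "probability")
  expect_error(community_scenario(terrestrial_fraction = 1), "terrestrial")
  expect_error(community_scenario(sigma = -1), "sigma")
})

test_that("write_simulation/read_simulation round-trips the tables", {
  sc <- small_scenario(seed = 3)
  sim <- simulate_community(sc)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  back <- read_simulation(dir)
  expect_setequal(names(back$counts), names(sim$counts))
  for (l in names(sim$counts)) {
    expect_equal(back$counts[[l]], sim$counts[[l]] * 1.0,
                 ignore_attr = TRUE)
    expect_identical(rownames(back$counts[[l]]), rownames(sim$counts[[l]]))
  }
  expect_equal(back$metadata, sim$metadata)
  expect_equal(back$environment$temperature, sim$environment$temperature)
})
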