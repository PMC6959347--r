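# Synthetic multi-locus eDNA community generator.
#
# The generator plants a known community structure -- groups of taxa whose
# latent abundances follow shared seasonal archetypes -- and pushes it
# through the observation process that makes real metabarcoding data hard:
# constant per-taxon-per-locus amplification bias (including primers that
# simply never amplify a taxon), per-replicate detection failure,
# proportional contamination shared with negative/blank controls, and
# multinomial read sampling at finite library size. Environmental
# covariates are statistically tied to specific planted modules so that
# downstream association steps have a recoverable truth.

LOCUS_NAMES <- c("16S", "18S", "COI", "12S")

#' Define a synthetic community scenario
#'
#' A scenario is the complete stated world for one simulation: community
#' size and structure, sampling design (time points, loci, PCR replicates,
#' controls), and the observation-process parameters. Defaults emulate an
#' eight-time-point, four-locus bimonthly marine survey with triplicate
#' PCRs.
#'
#' @param n_taxa total number of taxa (marine + terrestrial).
#' @param n_modules number of planted subnetworks (seasonal groups).
#' @param n_timepoints number of sampling time points.
#' @param n_loci number of amplified loci (default 4: 16S, 18S, COI, 12S).
#' @param n_replicates PCR replicates per field sample.
#' @param library_size expected reads per PCR replicate.
#' @param detection_prob probability that a truly present taxon amplifies in
#'   one PCR replicate.
#' @param contamination_rate expected proportion of a field replicate's reads
#'   drawn from the contaminant pool.
#' @param n_controls number of negative/blank control samples.
#' @param terrestrial_fraction fraction of taxa flagged terrestrial; these
#'   form the contaminant pool.
#' @param seed integer RNG seed governing the whole simulation.
#' @param sigma lognormal noise SD on latent abundances (0 = noiseless).
#' @param arch_log_range natural-log dynamic range of each module
#'   archetype (peak over trough; default 5, about 150-fold).
#' @param arch_max_tau maximum |Kendall tau| allowed between any two
#'   module archetypes (distinctness criterion; default 0.55).
#' @param abundance_floor latent values below `abundance_floor` times the
#'   taxon maximum are set to exact zero (genuine absences).
#' @param efficiency_zero_fraction fraction of taxon-locus pairs whose
#'   amplification efficiency is exactly zero (primer does not amplify).
#' @param control_depth control library depth as a fraction of
#'   `library_size` (blanks are low-biomass).
#' @param otus_per_taxon OTUs generated per taxon (agglomeration exercise).
#' @param env_noise_frac noise SD on linked environmental variables, as a
#'   fraction of the linked archetype's SD.
#' @param corrupt_timepoint optional time point whose first PCR replicate is
#'   scrambled at every locus (plants a replicate-QC failure).
#' @return A `community_scenario` object (validated list).
#' @export
community_scenario <- function(n_taxa = 120, n_modules = 6, n_timepoints = 8,
                               n_loci = 4, n_replicates = 3,
                               library_size = 20000, detection_prob = 0.9,
                               contamination_rate = 0.02, n_controls = 4,
                               terrestrial_fraction = 0.1, seed = 1,
                               sigma = 0.3, arch_log_range = 5,
                               arch_max_tau = 0.55,
                               abundance_floor = 1e-3,
                               efficiency_zero_fraction = 0.25,
                               control_depth = 0.05, otus_per_taxon = 2,
                               env_noise_frac = 0.1,
                               corrupt_timepoint = NA_integer_) {
  sc <- list(n_taxa = as.integer(n_taxa), n_modules = as.integer(n_modules),
             n_timepoints = as.integer(n_timepoints),
             n_loci = as.integer(n_loci),
             n_replicates = as.integer(n_replicates),
             library_size = as.integer(library_size),
             detection_prob = detection_prob,
             contamination_rate = contamination_rate,
             n_controls = as.integer(n_controls),
             terrestrial_fraction = terrestrial_fraction,
             seed = as.integer(seed), sigma = sigma,
             arch_log_range = arch_log_range, arch_max_tau = arch_max_tau,
             abundance_floor = abundance_floor,
             efficiency_zero_fraction = efficiency_zero_fraction,
             control_depth = control_depth,
             otus_per_taxon = as.integer(otus_per_taxon),
             env_noise_frac = env_noise_frac,
             corrupt_timepoint = as.integer(corrupt_timepoint))
  counts <- c("n_taxa", "n_modules", "n_timepoints", "n_loci",
              "n_replicates", "library_size", "otus_per_taxon")
  for (f in counts) {
    if (is.na(sc[[f]]) || sc[[f]] < 1L)
      stop(sprintf("'%s' must be a positive integer", f))
  }
  stop_if_not_prob(sc$detection_prob, "detection_prob")
  stop_if_not_prob(sc$contamination_rate, "contamination_rate")
  stop_if_not_prob(sc$control_depth, "control_depth")
  stop_if_not_prob(sc$efficiency_zero_fraction, "efficiency_zero_fraction")
  if (sc$terrestrial_fraction < 0 || sc$terrestrial_fraction >= 1)
    stop("'terrestrial_fraction' must be in [0, 1)")
  if (sc$n_controls < 0L) stop("'n_controls' must be >= 0")
  if (sc$sigma < 0) stop("'sigma' must be >= 0")
  sc$n_terrestrial <- as.integer(round(sc$terrestrial_fraction * sc$n_taxa))
  sc$n_marine <- sc$n_taxa - sc$n_terrestrial
  if (sc$n_marine < sc$n_modules)
    stop("not enough marine taxa for the requested number of modules")
  class(sc) <- "community_scenario"
  sc
}

#' @export
print.community_scenario <- function(x, ...) {
  cat(sprintf(paste0("community_scenario: %d taxa (%d marine in %d modules,",
                     " %d terrestrial), %d time points x %d replicates, ",
                     "%d loci, seed %d\n"),
              x$n_taxa, x$n_marine, x$n_modules, x$n_terrestrial,
              x$n_timepoints, x$n_replicates, x$n_loci, x$seed))
  invisible(x)
}

marine_taxon_names <- function(n) sprintf("Fam%03d", seq_len(n))
terrestrial_taxon_names <- function(n) {
  if (n == 0L) character(0) else sprintf("TerrFam%02d", seq_len(n))
}

# Draw distinct smooth seasonal archetypes. Each is a smoothed Gaussian
# random profile rescaled to a fixed log dynamic range; candidates are
# rejected until every archetype peaks at its own time point and all
# pairwise |Kendall tau| between archetypes stay below `max_tau`. The tau
# cap matters: the downstream network is unsigned (|tau|^beta), so two
# modules whose archetypes are near rank-mirrors of one another would be
# structurally unrecoverable no matter how little noise is added.
draw_archetypes <- function(G, TT, log_range, max_tau, max_try = 1000L) {
  smooth3 <- function(u)
    (u + c(u[1], u[-TT]) + c(u[-1], u[TT])) / 3
  arch <- matrix(NA_real_, G, TT)
  for (g in seq_len(G)) {
    placed <- FALSE
    for (i in seq_len(max_try)) {
      u <- smooth3(rnorm(TT))
      if (diff(range(u)) == 0) next
      u <- (u - max(u)) / diff(range(u)) * log_range
      s <- exp(u)
      ok <- TRUE
      if (g > 1L) {
        prev <- seq_len(g - 1L)
        taus <- vapply(prev, function(h) kendall_tau_b(s, arch[h, ]),
                       numeric(1))
        pk <- vapply(prev, function(h) which.max(arch[h, ]), integer(1))
        ok <- all(!is.na(taus)) && all(abs(taus) <= max_tau) &&
          !(which.max(s) %in% pk)
      }
      if (ok) {
        arch[g, ] <- s
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not draw ", G, " distinct archetypes over ", TT,
           " time points (try fewer modules or a larger arch_max_tau)")
  }
  rownames(arch) <- paste0("module", seq_len(G))
  colnames(arch) <- paste0("T", seq_len(TT))
  arch
}

#' Generate latent community dynamics with planted modules
#'
#' Taxa are assigned to modules; each module has a smooth seasonal
#' archetype with a module-specific peak time point, a fixed log dynamic
#' range, and bounded pairwise rank similarity to every other archetype
#' (so planted modules are distinguishable by construction). Taxon `i` in
#' module `g` has latent abundance
#' `A_i(t) = scale_i * s_g(t) * exp(e_it)` with `e_it ~ N(0, sigma^2)`;
#' values below `abundance_floor` times the taxon maximum are zeroed to
#' create genuine absences. The first taxon of each module is noise-free
#' and acts as the planted hub.
#'
#' @param scenario a [community_scenario()].
#' @return List with `abundance` (marine taxa x time points),
#'   `module_truth` (named integer vector), `archetype` (modules x time
#'   points), `peaks` (per-module peak time point), and `hub_taxa`.
#' @export
generate_latent_dynamics <- function(scenario) {
  stopifnot(inherits(scenario, "community_scenario"))
  if (scenario$n_modules > scenario$n_timepoints)
    stop("n_modules > n_timepoints: cannot place distinct archetype peaks")
  G <- scenario$n_modules
  TT <- scenario$n_timepoints
  n <- scenario$n_marine
  modules <- sort(rep_len(seq_len(G), n))
  taxa <- marine_taxon_names(n)
  names(modules) <- taxa
  hub_taxa <- taxa[!duplicated(modules)]
  with_seed(derive_seed(scenario$seed, 1L), {
    archetype <- draw_archetypes(G, TT, scenario$arch_log_range,
                                 scenario$arch_max_tau)
    peaks <- apply(archetype, 1, which.max)
    scale_i <- rlnorm(n, meanlog = 0, sdlog = 1)
    eps <- matrix(rnorm(n * TT, 0, scenario$sigma), n, TT)
    eps[taxa %in% hub_taxa, ] <- 0
    A <- scale_i * archetype[modules, , drop = FALSE] * exp(eps)
    dimnames(A) <- list(taxa, paste0("T", seq_len(TT)))
    floor_i <- scenario$abundance_floor * apply(A, 1, max)
    A[A < floor_i] <- 0
    list(abundance = A, module_truth = modules, archetype = archetype,
         peaks = peaks, hub_taxa = hub_taxa)
  })
}

# Environmental variable templates: intercept and slope applied to the
# linked module archetype (units are plausible for a temperate coastal
# station; only the rank/linear structure matters downstream).
ENV_TEMPLATES <- data.frame(
  variable = c("temperature", "chlorophyll_a", "dissolved_oxygen", "nitrate"),
  alpha = c(12, 0.5, 8, 1), beta = c(4, 5, 2.5, 8),
  stringsAsFactors = FALSE)

#' Generate environmental covariates linked to planted modules
#'
#' Up to four variables are linear-plus-noise functions of distinct module
#' archetypes (`v(t) = alpha + beta * s_g(t) + N(0, tau^2)` with
#' `tau = env_noise_frac * sd(s_g)`); salinity is always an unlinked
#' pure-noise variable. The linkage map is recorded in the `"linkage"`
#' attribute (variable name -> module id).
#'
#' @param scenario a [community_scenario()].
#' @param latent output of [generate_latent_dynamics()].
#' @return data.frame with column `timepoint` and one column per variable.
#' @export
generate_environment <- function(scenario, latent) {
  TT <- scenario$n_timepoints
  n_linked <- min(scenario$n_modules, nrow(ENV_TEMPLATES))
  with_seed(derive_seed(scenario$seed, 2L), {
    env <- data.frame(timepoint = seq_len(TT))
    linkage <- integer(0)
    for (j in seq_len(n_linked)) {
      s <- latent$archetype[j, ]
      tau <- scenario$env_noise_frac * sd(s)
      v <- ENV_TEMPLATES$alpha[j] + ENV_TEMPLATES$beta[j] * s +
        rnorm(TT, 0, tau)
      env[[ENV_TEMPLATES$variable[j]]] <- v
      linkage[ENV_TEMPLATES$variable[j]] <- j
    }
    env$salinity <- rnorm(TT, mean = 33.5, sd = 0.2)
    attr(env, "linkage") <- linkage
    attr(env, "noise_variables") <- "salinity"
    env
  })
}

#' Generate multi-locus read count tables, controls and taxonomy
#'
#' Implements the observation model: per-locus, per-replicate read vectors
#' are multinomial draws from latent abundance times a fixed taxon-by-locus
#' amplification efficiency (log-normal with a zero-mass spike), gated by a
#' per-replicate Bernoulli detection event, and mixed with a contaminant
#' pool (the terrestrial taxa) at `contamination_rate`. Controls draw from
#' the contaminant pool only, at reduced depth. Efficiencies are constant
#' across samples, so within-taxon read proportions track latent abundance
#' up to a taxon-specific constant -- the property the eDNA index exploits.
#'
#' @param scenario a [community_scenario()].
#' @param latent output of [generate_latent_dynamics()].
#' @return An `edna_simulation` list: `counts` (list of OTU x sample
#'   matrices, one per locus), `metadata`, `taxonomy`, and `truth`
#'   (module labels, efficiency matrix, contaminant set, hubs, latent).
#' @export
generate_reads <- function(scenario, latent) {
  stopifnot(inherits(scenario, "community_scenario"))
  TT <- scenario$n_timepoints
  R <- scenario$n_replicates
  L <- scenario$n_loci
  loci <- if (L <= length(LOCUS_NAMES)) LOCUS_NAMES[seq_len(L)] else
    c(LOCUS_NAMES, paste0("L", seq_len(L - length(LOCUS_NAMES)) + 4L))
  marine <- rownames(latent$abundance)
  terr <- terrestrial_taxon_names(scenario$n_terrestrial)
  taxa <- c(marine, terr)
  n_tax <- length(taxa)
  K <- scenario$otus_per_taxon

  with_seed(derive_seed(scenario$seed, 3L), {
    # fixed per-taxon-per-locus efficiencies with a non-amplifying spike
    E <- matrix(rlnorm(n_tax * L), n_tax, L, dimnames = list(taxa, loci))
    zero_mask <- matrix(runif(n_tax * L) < scenario$efficiency_zero_fraction,
                        n_tax, L)
    E[zero_mask] <- 0
    # every taxon must amplify at >= 1 locus, else it is unobservable noise
    dead <- rowSums(E > 0) == 0
    if (any(dead)) E[dead, 1L] <- rlnorm(sum(dead))

    # split each taxon into OTUs with fixed within-taxon weights
    otu_tax <- rep(taxa, each = K)
    otu_ids <- sprintf("%s_OTU%d", otu_tax, rep(seq_len(K), n_tax))
    otu_w <- as.vector(vapply(seq_len(n_tax), function(i) {
      w <- rgamma(K, shape = 2); w / sum(w)
    }, numeric(K)))

    # contaminant pool: terrestrial taxa with fixed pool weights
    pool_w_tax <- setNames(numeric(n_tax), taxa)
    if (length(terr)) pool_w_tax[terr] <- rlnorm(length(terr))

    # taxonomy: agglomeration rank, habitat, trophic level
    rank_tax <- sample(c("Family", "Order", "Class"), n_tax, replace = TRUE,
                       prob = c(0.8, 0.12, 0.08))
    trophic_tax <- sample(0:5, n_tax, replace = TRUE,
                          prob = c(0.2, 0.25, 0.25, 0.15, 0.1, 0.05))
    taxonomy <- data.frame(
      otu_id = otu_ids, taxon = otu_tax,
      rank = rank_tax[match(otu_tax, taxa)],
      habitat = ifelse(otu_tax %in% terr, "terrestrial", "marine"),
      trophic_level = trophic_tax[match(otu_tax, taxa)],
      stringsAsFactors = FALSE)

    field_ids <- as.vector(t(outer(seq_len(TT), seq_len(R),
                                   function(t, r) sprintf("T%02d_R%d", t, r))))
    n_neg <- ceiling(scenario$n_controls / 2)
    ctrl_ids <- c(if (n_neg) sprintf("NEG%d", seq_len(n_neg)),
                  if (scenario$n_controls - n_neg)
                    sprintf("BLK%d", seq_len(scenario$n_controls - n_neg)))
    metadata <- data.frame(
      sample_id = c(field_ids, ctrl_ids),
      type = c(rep("field", length(field_ids)),
               rep(c("negative", "blank"),
                   c(n_neg, scenario$n_controls - n_neg))),
      timepoint = c(rep(seq_len(TT), each = R),
                    rep(NA_integer_, scenario$n_controls)),
      replicate = c(rep(seq_len(R), TT),
                    rep(NA_integer_, scenario$n_controls)),
      stringsAsFactors = FALSE)

    A_full <- matrix(0, n_tax, TT, dimnames = list(taxa, NULL))
    A_full[marine, ] <- latent$abundance
    crate <- scenario$contamination_rate
    ctrl_depth <- max(1L, round(scenario$control_depth * scenario$library_size))

    counts <- lapply(seq_len(L), function(l) {
      pool_tax <- pool_w_tax * E[, l]
      pool_otu <- pool_tax[otu_tax] * otu_w
      if (sum(pool_otu) > 0) pool_otu <- pool_otu / sum(pool_otu)
      m <- matrix(0L, length(otu_ids), nrow(metadata),
                  dimnames = list(otu_ids, metadata$sample_id))
      for (t in seq_len(TT)) {
        for (r in seq_len(R)) {
          det <- rbinom(n_tax, 1L, scenario$detection_prob)
          w_tax <- A_full[, t] * E[, l] * det
          w_otu <- w_tax[otu_tax] * otu_w
          sig <- sum(w_otu)
          probs <- (if (sig > 0) (1 - crate) * w_otu / sig else 0 * w_otu) +
            crate * pool_otu
          if (!is.na(scenario$corrupt_timepoint) &&
              t == scenario$corrupt_timepoint && r == 1L) {
            probs <- rgamma(length(otu_ids), shape = 0.3)
            probs <- probs / sum(probs)
          }
          sid <- sprintf("T%02d_R%d", t, r)
          if (sum(probs) > 0)
            m[, sid] <- rmultinom(1L, scenario$library_size,
                                  probs / sum(probs))
        }
      }
      for (cid in ctrl_ids) {
        if (sum(pool_otu) > 0)
          m[, cid] <- rmultinom(1L, ctrl_depth, pool_otu)
      }
      m
    })
    names(counts) <- loci

    structure(list(
      counts = counts, metadata = metadata, taxonomy = taxonomy,
      truth = list(module_truth = latent$module_truth,
                   archetype = latent$archetype, peaks = latent$peaks,
                   hub_taxa = latent$hub_taxa, efficiency = E,
                   contaminants = terr, latent_abundance = latent$abundance,
                   otu_weights = setNames(otu_w, otu_ids)),
      scenario = scenario), class = "edna_simulation")
  })
}

#' Run the full generator: latent dynamics, environment, reads
#'
#' @param scenario a [community_scenario()].
#' @return An `edna_simulation` with an `environment` table and its
#'   module linkage recorded in `truth$env_linkage`.
#' @export
simulate_community <- function(scenario) {
  latent <- generate_latent_dynamics(scenario)
  env <- generate_environment(scenario, latent)
  sim <- generate_reads(scenario, latent)
  sim$environment <- env
  sim$truth$env_linkage <- attr(env, "linkage")
  sim$truth$noise_variables <- attr(env, "noise_variables")
  sim
}

#' @export
print.edna_simulation <- function(x, ...) {
  cat(sprintf("edna_simulation: %d OTUs x %d samples at %d loci (%s)\n",
              nrow(x$counts[[1]]), ncol(x$counts[[1]]), length(x$counts),
              paste(names(x$counts), collapse = ", ")))
  invisible(x)
}

#' Write a simulation to a directory of TSV/JSON files
#'
#' Emits one count TSV per locus, metadata/taxonomy/environment TSVs, the
#' scenario, and the ground truth as JSON.
#'
#' @param sim an `edna_simulation`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (l in names(sim$counts)) {
    write_count_table(sim$counts[[l]],
                      file.path(dir, sprintf("counts_%s.tsv", l)))
  }
  write_tsv(sim$metadata, file.path(dir, "metadata.tsv"))
  write_tsv(sim$taxonomy, file.path(dir, "taxonomy.tsv"))
  if (!is.null(sim$environment))
    write_tsv(sim$environment, file.path(dir, "environment.tsv"))
  truth <- sim$truth
  truth$efficiency <- as.data.frame(truth$efficiency)
  truth$archetype <- as.data.frame(truth$archetype)
  truth$latent_abundance <- as.data.frame(truth$latent_abundance)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(sim$scenario), file.path(dir, "scenario.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read simulation inputs back from a directory
#'
#' Restores the tables needed to run the pipeline (counts, metadata,
#' taxonomy, environment); ground truth is not reloaded.
#'
#' @param dir directory written by [write_simulation()].
#' @return List with `counts`, `metadata`, `taxonomy`, `environment`.
#' @export
read_simulation <- function(dir) {
  files <- list.files(dir, pattern = "^counts_.*\\.tsv$", full.names = TRUE)
  if (!length(files)) stop("no counts_<locus>.tsv files in ", dir)
  loci <- sub("^counts_(.*)\\.tsv$", "\\1", basename(files))
  counts <- lapply(files, read_count_table)
  names(counts) <- loci
  env_path <- file.path(dir, "environment.tsv")
  list(counts = counts,
       metadata = read_tsv(file.path(dir, "metadata.tsv")),
       taxonomy = read_tsv(file.path(dir, "taxonomy.tsv")),
       environment = if (file.exists(env_path)) read_tsv(env_path))
}
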