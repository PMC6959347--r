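# Pipeline orchestration: one configuration drives the fixed stage order
#
#   occupancy filter -> decontamination -> replicate QC -> agglomerate ->
#   per-locus index -> ensemble -> terrestrial removal ->
#   correlation + permutation null -> network modules ->
#   environment association
#
# with a manifest recording what every stage kept and dropped.

#' Build a validated pipeline configuration
#'
#' Either `scenario` (a [community_scenario()] to simulate) or `input_dir`
#' (a directory in the layout of [write_simulation()]) must be supplied.
#'
#' @param seed integer seed governing simulation and the permutation null
#'   (mandatory).
#' @param scenario optional [community_scenario()].
#' @param input_dir optional directory of input TSVs.
#' @param output_dir optional directory for stage outputs.
#' @param occupancy_threshold minimum estimated occurrence probability
#'   (default 0.8).
#' @param bray_curtis_threshold replicate dissimilarity cutoff (default
#'   0.49).
#' @param alpha significance level for the correlation test (default 0.05).
#' @param edge_threshold visualization edge-weight threshold (default 0.2).
#' @param hub_fraction top-connectivity fraction (default 0.10).
#' @param min_module_size minimum module size (default 5).
#' @param beta soft-threshold exponent (default 22, the published
#'   operating point of the unsigned tau network), or `"auto"` for
#'   scale-free selection. On 8-point tau matrices the scale-free fit is
#'   weak and its fallback can pick an exponent too soft to separate
#'   modules, so the fixed default is recommended.
#' @param n_permutations null datasets for the permutation null (default
#'   100).
#' @param contamination_method "max" (default) or "mean".
#' @param cut_quantile static-cut quantile of dendrogram merge heights.
#' @param r2_target scale-free topology R^2 target.
#' @param do_occupancy,do_decontamination,do_replicate_qc,do_terrestrial_removal
#'   stage toggles.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed, scenario = NULL, input_dir = NULL,
                            output_dir = NULL, occupancy_threshold = 0.8,
                            bray_curtis_threshold = 0.49, alpha = 0.05,
                            edge_threshold = 0.2, hub_fraction = 0.10,
                            min_module_size = 5, beta = 22,
                            n_permutations = 100,
                            contamination_method = "max",
                            cut_quantile = 0.99, r2_target = 0.8,
                            do_occupancy = TRUE, do_decontamination = TRUE,
                            do_replicate_qc = TRUE,
                            do_terrestrial_removal = TRUE) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("'seed' is mandatory")
  if (is.null(scenario) && is.null(input_dir))
    stop("either 'scenario' or 'input_dir' must be given")
  stop_if_not_prob(occupancy_threshold, "occupancy_threshold")
  stop_if_not_prob(bray_curtis_threshold, "bray_curtis_threshold")
  stop_if_not_prob(alpha, "alpha")
  stop_if_not_prob(hub_fraction, "hub_fraction")
  stop_if_not_prob(cut_quantile, "cut_quantile")
  if (!identical(beta, "auto") && (!is.numeric(beta) || beta < 1))
    stop("'beta' must be \"auto\" or a number >= 1")
  if (min_module_size < 1) stop("'min_module_size' must be >= 1")
  if (n_permutations < 1) stop("'n_permutations' must be >= 1")
  structure(list(seed = as.integer(seed), scenario = scenario,
                 input_dir = input_dir, output_dir = output_dir,
                 occupancy_threshold = occupancy_threshold,
                 bray_curtis_threshold = bray_curtis_threshold,
                 alpha = alpha, edge_threshold = edge_threshold,
                 hub_fraction = hub_fraction,
                 min_module_size = as.integer(min_module_size), beta = beta,
                 n_permutations = as.integer(n_permutations),
                 contamination_method = contamination_method,
                 cut_quantile = cut_quantile, r2_target = r2_target,
                 do_occupancy = isTRUE(do_occupancy),
                 do_decontamination = isTRUE(do_decontamination),
                 do_replicate_qc = isTRUE(do_replicate_qc),
                 do_terrestrial_removal = isTRUE(do_terrestrial_removal)),
            class = "pipeline_config")
}

run_stage <- function(manifest, name, code) {
  res <- tryCatch(code, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  res
}

#' Run the full eDNA community analysis pipeline
#'
#' Executes every stage in fixed order on simulated or file-based inputs;
#' identical config + seed gives identical outputs. When
#' `config$output_dir` is set, all stage outputs are written as TSV/JSON.
#'
#' @param config a [pipeline_config()].
#' @return A `pipeline_result` list: per-locus QC products, `ensemble`
#'   index, `correlation`, `network`, association tables, `manifest`, and
#'   (for simulated inputs) `truth`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  # config snapshot excludes filesystem paths so that identical analyses
  # written to different directories produce byte-identical outputs
  manifest <- list(config = unclass(config[!(names(config) %in%
                                               c("scenario", "output_dir",
                                                 "input_dir"))]),
                   package_version = as.character(utils::packageVersion("ednanet")),
                   stages = list())
  note <- function(name, ...) {
    manifest$stages[[name]] <<- list(...)
  }

  # --- inputs -------------------------------------------------------------
  if (!is.null(config$scenario)) {
    sim <- run_stage(manifest, "simulate", simulate_community(config$scenario))
    note("simulate", n_otus = nrow(sim$counts[[1]]),
         n_samples = ncol(sim$counts[[1]]), n_loci = length(sim$counts))
  } else {
    sim <- run_stage(manifest, "load", read_simulation(config$input_dir))
    note("load", n_otus = nrow(sim$counts[[1]]),
         n_samples = ncol(sim$counts[[1]]), n_loci = length(sim$counts))
  }
  metadata <- sim$metadata
  taxonomy <- sim$taxonomy
  field_meta <- metadata[metadata$type == "field", ]
  control_ids <- metadata$sample_id[metadata$type %in% c("negative", "blank")]
  groups <- split(field_meta$sample_id, field_meta$timepoint)

  occupancy_reports <- list()
  qc_reports <- list()
  locus_index <- list()
  locus_props <- list()

  for (l in names(sim$counts)) {
    counts <- sim$counts[[l]]

    # occupancy filter (per locus, first step of decontamination)
    if (config$do_occupancy) {
      hist <- run_stage(manifest, paste0("occupancy:", l),
                        detection_history(counts, metadata))
      est <- fit_occupancy_all(hist)
      filt <- filter_otus(est, threshold = config$occupancy_threshold)
      occupancy_reports[[l]] <- filt$audit
      note(paste0("occupancy:", l), otus_in = nrow(counts),
           otus_retained = length(filt$retained),
           otus_dropped = nrow(counts) - length(filt$retained))
      counts <- counts[filt$retained, , drop = FALSE]
    } else {
      note(paste0("occupancy:", l), skipped = TRUE)
    }

    props <- proportionalize(counts)

    # proportional decontamination against controls
    if (config$do_decontamination) {
      prof <- estimate_contamination(props, control_ids,
                                     method = config$contamination_method)
      props <- subtract_contamination(props, prof)
      note(paste0("decontamination:", l),
           n_controls = length(attr(prof, "controls")),
           otus_with_contamination = sum(prof > 0))
    } else {
      note(paste0("decontamination:", l), skipped = TRUE)
    }

    # replicate dissimilarity QC, then collapse replicates
    field_props <- props[, intersect(colnames(props), field_meta$sample_id),
                         drop = FALSE]
    if (config$do_replicate_qc) {
      dis <- replicate_dissimilarity(field_props, groups)
      qc <- drop_dissimilar_samples(dis,
                                    threshold = config$bray_curtis_threshold)
      qc_reports[[l]] <- qc$report
      keep_groups <- groups[qc$retained]
      note(paste0("replicate_qc:", l), samples_in = length(groups),
           samples_retained = length(qc$retained),
           samples_dropped = length(groups) - length(qc$retained))
    } else {
      keep_groups <- groups
      note(paste0("replicate_qc:", l), skipped = TRUE)
    }
    collapsed <- collapse_replicates(field_props, keep_groups)

    # agglomerate OTUs to Family-or-higher taxa, then the eDNA index
    taxa_props <- run_stage(manifest, paste0("agglomerate:", l),
                            agglomerate_taxa(collapsed, taxonomy))
    n_dropped_otus <- attr(taxa_props, "dropped_otus")
    cs <- colSums(taxa_props)
    taxa_props <- sweep(taxa_props, 2, ifelse(cs == 0, 1, cs), "/")
    note(paste0("agglomerate:", l), otus_in = nrow(collapsed),
         taxa_out = nrow(taxa_props),
         otus_dropped_unannotated = n_dropped_otus)
    locus_props[[l]] <- taxa_props
    locus_index[[l]] <- edna_index(taxa_props, locus = l)
  }

  # --- align loci and build the ensemble ---------------------------------
  all_taxa <- sort(unique(unlist(lapply(locus_index, rownames))))
  all_tp <- sort(unique(unlist(lapply(locus_index, colnames))))
  aligned <- lapply(names(locus_index), function(l) {
    m <- matrix(0, length(all_taxa), length(all_tp),
                dimnames = list(all_taxa, all_tp))
    src <- locus_index[[l]]
    missing_tp <- setdiff(all_tp, colnames(src))
    if (length(missing_tp)) m[, missing_tp] <- NA_real_
    m[rownames(src), colnames(src)] <- src
    m
  })
  names(aligned) <- names(locus_index)
  ensemble <- run_stage(manifest, "ensemble", ensemble_index(aligned))
  note("ensemble", taxa = nrow(ensemble), timepoints = ncol(ensemble))

  if (config$do_terrestrial_removal) {
    ensemble <- remove_terrestrial(ensemble, taxonomy)
    note("terrestrial_removal", removed = length(attr(ensemble, "removed")),
         taxa_retained = nrow(ensemble))
  } else {
    note("terrestrial_removal", skipped = TRUE)
  }

  # drop taxa never detected (all-zero rows carry no rank information)
  detected <- apply(ensemble, 1, function(r) any(!is.na(r) & r > 0))
  analysis_index <- ensemble[detected, , drop = FALSE]
  note("detected_taxa", taxa = nrow(analysis_index),
       dropped_all_zero = sum(!detected))

  # --- correlation, network, environment ---------------------------------
  cor_input <- analysis_index
  cor_input[is.na(cor_input)] <- 0
  correlation <- run_stage(manifest, "correlation",
                           correlation_significance(
                             cor_input, n_perm = config$n_permutations,
                             alpha = config$alpha, seed = config$seed))
  note("correlation", pairs = sum(upper.tri(correlation$tau)),
       significant = sum(correlation$significant[
         upper.tri(correlation$significant)], na.rm = TRUE),
       critical_tau = correlation$critical_tau)

  network <- run_stage(manifest, "network",
                       network_modules(correlation$tau, beta = config$beta,
                                       min_size = config$min_module_size,
                                       cut_quantile = config$cut_quantile,
                                       hub_fraction = config$hub_fraction,
                                       edge_threshold = config$edge_threshold,
                                       r2_target = config$r2_target))
  mod_tab <- table(network$modules)
  note("network", beta = network$beta,
       modules = sum(names(mod_tab) != "unassigned"),
       unassigned = sum(network$modules == "unassigned"))

  profiles <- module_env_assoc <- taxon_env <- conn_env <- NULL
  if (!is.null(sim$environment)) {
    profiles <- module_richness(analysis_index, network$modules)
    module_env_assoc <- rbind(
      module_env_correlation(profiles, sim$environment, "spearman",
                             "richness"),
      module_env_correlation(profiles, sim$environment, "spearman",
                             "mean_index"),
      module_env_correlation(profiles, sim$environment, "pearson",
                             "richness"))
    taxon_env <- taxon_env_correlation(analysis_index, sim$environment)
    # per module: designated variable = strongest richness association
    conn_env <- list()
    for (m in setdiff(unique(network$modules), "unassigned")) {
      if (sum(network$modules == m) < 4L) next
      sub <- module_env_assoc[module_env_assoc$module == m &
                                module_env_assoc$summary == "richness" &
                                module_env_assoc$method == "spearman" &
                                !module_env_assoc$undefined, ]
      if (!nrow(sub)) next
      v <- sub$variable[which.max(abs(sub$r))]
      ce <- connectivity_env_relationship(network$connectivity, taxon_env,
                                          network$modules, m, v)
      conn_env[[length(conn_env) + 1L]] <-
        data.frame(module = m, variable = v, r = ce$r, p = ce$p, n = ce$n,
                   stringsAsFactors = FALSE)
    }
    conn_env <- if (length(conn_env)) do.call(rbind, conn_env)
    note("environment_association",
         modules_tested = length(unique(module_env_assoc$module)),
         variables = length(setdiff(colnames(sim$environment), "timepoint")))
  } else {
    note("environment_association", skipped = TRUE)
  }

  result <- structure(list(
    config = config, manifest = manifest,
    occupancy = occupancy_reports, replicate_qc = qc_reports,
    locus_index = locus_index, ensemble = ensemble,
    analysis_index = analysis_index, correlation = correlation,
    network = network, module_profiles = profiles,
    module_env = module_env_assoc, taxon_env = taxon_env,
    connectivity_env = conn_env,
    truth = sim$truth, environment = sim$environment),
    class = "pipeline_result")

  if (!is.null(config$output_dir)) write_pipeline_outputs(result)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  for (nm in names(x$manifest$stages)) {
    st <- x$manifest$stages[[nm]]
    cat(sprintf("  %-22s %s\n", nm,
                paste(names(st), unlist(st), sep = "=", collapse = ", ")))
  }
  invisible(x)
}

# Write all stage outputs (deterministic: no wall-clock content).
write_pipeline_outputs <- function(result) {
  dir <- result$config$output_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (l in names(result$occupancy)) {
    write_tsv(result$occupancy[[l]],
              file.path(dir, sprintf("occupancy_%s.tsv", l)))
  }
  for (l in names(result$replicate_qc)) {
    write_tsv(result$replicate_qc[[l]],
              file.path(dir, sprintf("replicate_qc_%s.tsv", l)))
  }
  for (l in names(result$locus_index)) {
    write_count_table(result$locus_index[[l]],
                      file.path(dir, sprintf("index_%s.tsv", l)),
                      id_col = "taxon")
  }
  write_count_table(result$ensemble, file.path(dir, "index_ensemble.tsv"),
                    id_col = "taxon")
  write_tsv(correlation_pairs(result$correlation),
            file.path(dir, "correlation_pairs.tsv"))
  write_tsv(data.frame(tau = result$correlation$null_taus),
            file.path(dir, "null_taus.tsv"))
  write_tsv(data.frame(taxon = names(result$network$modules),
                       module = unname(result$network$modules),
                       connectivity = unname(result$network$connectivity[
                         names(result$network$modules)])),
            file.path(dir, "modules.tsv"))
  write_tsv(result$network$edges, file.path(dir, "edges.tsv"))
  if (!is.null(result$network$scale_free_fits))
    write_tsv(result$network$scale_free_fits,
              file.path(dir, "scale_free_fits.tsv"))
  writeLines(dendrogram_newick(result$network),
             file.path(dir, "dendrogram.nwk"))
  if (!is.null(result$module_profiles))
    write_tsv(result$module_profiles, file.path(dir, "module_richness.tsv"))
  if (!is.null(result$module_env))
    write_tsv(result$module_env, file.path(dir, "module_env.tsv"))
  if (!is.null(result$taxon_env))
    write_tsv(result$taxon_env, file.path(dir, "taxon_env.tsv"))
  if (!is.null(result$connectivity_env))
    write_tsv(result$connectivity_env,
              file.path(dir, "connectivity_env.tsv"))
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(dir)
}
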