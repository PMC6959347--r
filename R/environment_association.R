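# Associating subnetworks and taxa with environmental variables.
#
# Module-level summaries (taxon richness per time point, as in a
# subnetwork richness plot, and mean ensemble index as an alternative) are
# correlated with each environmental variable by Pearson and Spearman
# correlation. Taxon-level Spearman correlations and the relationship
# between a taxon's intramodular connectivity and its environmental
# correlation complete the picture: in a coherent subnetwork, the most
# connected taxa track the shared driver most closely.

# Time-point ids of an index table: numeric-convertible column names
# (possibly "T3"-style) if present, else positional.
timepoints_of <- function(index) {
  cn <- colnames(index)
  if (is.null(cn)) return(seq_len(ncol(index)))
  tp <- suppressWarnings(as.integer(sub("^T", "", cn)))
  if (anyNA(tp)) seq_len(ncol(index)) else tp
}

#' Per-module richness and mean index over time
#'
#' Richness at time t is the number of module taxa with index > 0 at t.
#'
#' @param index taxa x time points index matrix.
#' @param modules named label vector (taxon -> module).
#' @return data.frame with module, timepoint, richness, mean_index.
#' @export
module_richness <- function(index, modules) {
  modules <- modules[rownames(index)]
  mods <- setdiff(unique(modules), NA)
  tp <- timepoints_of(index)
  out <- lapply(mods, function(m) {
    sub <- index[modules == m, , drop = FALSE]
    data.frame(module = m, timepoint = tp,
               richness = colSums(sub > 0, na.rm = TRUE),
               mean_index = colMeans(sub, na.rm = TRUE),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Correlation with an undefined flag for constant/degenerate series.
safe_cor <- function(x, y, method) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L || sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, undefined = TRUE))
  ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value, undefined = FALSE)
}

#' Correlate module profiles with environmental variables
#'
#' @param profiles output of [module_richness()].
#' @param environment data.frame with `timepoint` plus variable columns.
#' @param method "spearman" (default) or "pearson".
#' @param summary module summary series: "richness" (default) or
#'   "mean_index".
#' @return data.frame with module, variable, method, summary, r, p,
#'   undefined.
#' @export
module_env_correlation <- function(profiles, environment,
                                   method = c("spearman", "pearson"),
                                   summary = c("richness", "mean_index")) {
  method <- match.arg(method)
  summary <- match.arg(summary)
  vars <- setdiff(colnames(environment), "timepoint")
  mods <- unique(profiles$module)
  if (length(unique(profiles$timepoint)) < 3L)
    stop("need >= 3 shared time points")
  out <- list()
  for (m in mods) {
    prof <- profiles[profiles$module == m, ]
    prof <- prof[order(prof$timepoint), ]
    env_m <- environment[match(prof$timepoint, environment$timepoint), ]
    series <- prof[[summary]]
    for (v in vars) {
      sc <- safe_cor(series, env_m[[v]], method)
      out[[length(out) + 1L]] <- data.frame(
        module = m, variable = v, method = method, summary = summary,
        r = sc$r, p = sc$p, undefined = sc$undefined,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Correlate each taxon's index series with environmental variables
#'
#' Taxa are ordered for presentation by hierarchical clustering of their
#' pairwise tau (order stored in the `"taxon_order"` attribute).
#'
#' @param index taxa x time points index matrix.
#' @param environment data.frame with `timepoint` plus variable columns.
#' @param method "spearman" (default) or "pearson".
#' @return data.frame with taxon, variable, method, r, p, undefined.
#' @export
taxon_env_correlation <- function(index, environment,
                                  method = c("spearman", "pearson")) {
  method <- match.arg(method)
  vars <- setdiff(colnames(environment), "timepoint")
  env_t <- environment[match(timepoints_of(index), environment$timepoint), ]
  out <- list()
  for (i in seq_len(nrow(index))) {
    for (v in vars) {
      sc <- safe_cor(index[i, ], env_t[[v]], method)
      out[[length(out) + 1L]] <- data.frame(
        taxon = rownames(index)[i], variable = v, method = method,
        r = sc$r, p = sc$p, undefined = sc$undefined,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  ord <- rownames(index)
  if (nrow(index) >= 3L) {
    tau <- tau_matrix(index)
    tau[is.na(tau)] <- 0
    hc <- hclust(as.dist(1 - tau), method = "average")
    ord <- rownames(index)[hc$order]
  }
  attr(res, "taxon_order") <- ord
  res
}

#' Connectivity versus environmental correlation within a module
#'
#' Spearman correlation, within one module, between each taxon's
#' intramodular connectivity k_i and its correlation r_i with a designated
#' environmental variable. A positive value means the better-connected
#' taxa are the ones tracking the variable.
#'
#' @param k named connectivity vector from [intramodular_connectivity()].
#' @param taxon_env output of [taxon_env_correlation()].
#' @param modules named module label vector.
#' @param module module label to analyse (needs >= 4 taxa).
#' @param variable environmental variable name.
#' @return List with `r`, `p`, `n`.
#' @export
connectivity_env_relationship <- function(k, taxon_env, modules, module,
                                          variable) {
  taxa <- names(modules)[modules == module]
  if (length(taxa) < 4L) stop("module has fewer than 4 taxa")
  sub <- taxon_env[taxon_env$variable == variable &
                     taxon_env$taxon %in% taxa & !taxon_env$undefined, ]
  ki <- k[sub$taxon]
  sc <- safe_cor(ki, sub$r, "spearman")
  list(r = sc$r, p = sc$p, n = length(ki))
}
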