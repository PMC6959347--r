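# Weighted co-occurrence network: soft-threshold adjacency, topological
# overlap, dendrogram branch cutting into subnetworks, connectivity and
# hubs.
#
# The adjacency a_ij = |tau_ij|^beta turns the correlation matrix into a
# weighted, undirected taxon network; beta is chosen by the scale-free
# topology criterion (smallest exponent whose connectivity distribution
# fits a power law with R^2 above target). The topological overlap measure
# (TOM) credits shared neighbours as well as direct links; clustering on
# 1 - TOM with average linkage and cutting the dendrogram yields modules
# ("subnetworks") of taxa with coherent dynamics.

#' Soft-threshold adjacency from a tau matrix
#'
#' `a_ij = |tau_ij|^beta` with zero diagonal; undefined (NA) taus give 0.
#'
#' @param tau symmetric correlation matrix.
#' @param beta soft-threshold exponent (>= 1).
#' @return Adjacency matrix in [0, 1].
#' @export
adjacency_matrix <- function(tau, beta) {
  stopifnot(beta >= 1)
  a <- abs(tau)^beta
  a[is.na(a)] <- 0
  diag(a) <- 0
  a
}

# Scale-free fit: regress log10 p(k) on log10 k over connectivity bins.
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 3L)
    return(list(r_squared = NA_real_, slope = NA_real_))
  brk <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, breaks = brk, include.lowest = TRUE)
  mean_k <- tapply(k, bin, mean)
  freq <- tapply(k, bin, length) / length(k)
  ok <- !is.na(mean_k) & !is.na(freq) & freq > 0 & mean_k > 0
  if (sum(ok) < 3L) return(list(r_squared = NA_real_, slope = NA_real_))
  fit <- lm(log10(freq[ok]) ~ log10(mean_k[ok]))
  list(r_squared = summary(fit)$r.squared, slope = unname(coef(fit)[2]))
}

#' Choose the soft threshold by the scale-free topology criterion
#'
#' For each candidate beta, computes node connectivities k_i under
#' `a_ij = |tau_ij|^beta` and the R^2 of the log10 p(k) vs log10 k
#' regression over connectivity bins. Selects the smallest beta with
#' `r_squared >= r2_target` and negative slope; if none qualifies, falls
#' back to the argmax R^2 with a warning.
#'
#' @param tau correlation matrix.
#' @param candidates candidate exponents (default 1:30).
#' @param r2_target scale-free fit target (default 0.8).
#' @param n_bins connectivity bins for the fit (default 10).
#' @return List with `beta` and a `fits` data.frame (beta, r_squared,
#'   slope).
#' @export
select_beta <- function(tau, candidates = 1:30, r2_target = 0.8,
                        n_bins = 10) {
  at <- abs(tau)
  at[is.na(at)] <- 0
  diag(at) <- 0
  fits <- lapply(candidates, function(b) {
    k <- rowSums(at^b)
    f <- scale_free_fit(k, n_bins)
    data.frame(beta = b, r_squared = f$r_squared, slope = f$slope)
  })
  fits <- do.call(rbind, fits)
  if (all(is.na(fits$r_squared))) stop("connectivities are degenerate")
  pass <- !is.na(fits$r_squared) & fits$r_squared >= r2_target &
    !is.na(fits$slope) & fits$slope < 0
  if (any(pass)) {
    beta <- fits$beta[which(pass)[1]]
  } else {
    beta <- fits$beta[which.max(fits$r_squared)]
    warning(sprintf(
      "no candidate reached scale-free R^2 >= %.2f; using argmax (beta=%d)",
      r2_target, beta))
  }
  list(beta = beta, fits = fits)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' i != j, with `k_i = sum_u a_iu`; the diagonal is 1.
#'
#' @param a adjacency matrix (zero diagonal).
#' @return TOM matrix in [0, 1] with unit diagonal.
#' @export
topological_overlap <- function(a) {
  k <- rowSums(a)
  shared <- a %*% a
  tom <- (shared + a) / (outer(k, k, pmin) + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Cut a TOM dendrogram into modules
#'
#' Average-linkage clustering on 1 - TOM; a static cut at `cut_quantile`
#' times the maximum merge height (the classic "tree" variant of dynamic
#' branch cutting) defines branches, branches with at least `min_size`
#' leaves become modules, and smaller branches are merged into the module
#' with highest mean TOM to their members (else labelled "unassigned").
#' Module labels are colour-style names ordered by module size.
#'
#' @param tom topological overlap matrix.
#' @param min_size minimum module size (default 5).
#' @param cut_quantile fraction of the maximum merge height at which the
#'   static cut is made (default 0.99).
#' @return List with `modules` (named character vector taxon -> label) and
#'   `dendrogram` (the `hclust` object).
#' @export
cut_modules <- function(tom, min_size = 5, cut_quantile = 0.99) {
  n <- nrow(tom)
  if (min_size > n) stop("min_size exceeds the number of taxa")
  hc <- hclust(as.dist(1 - tom), method = "average")
  # average linkage is monotone; clamp float-level inversions for cutree
  hc$height <- cummax(hc$height)
  h <- cut_quantile * max(hc$height)
  cl <- cutree(hc, h = h)
  sizes <- table(cl)
  core_ids <- as.integer(names(sizes)[sizes >= min_size])
  labs <- rep("unassigned", n)
  names(labs) <- rownames(tom)
  if (length(core_ids)) {
    # merge each small branch into the nearest core module by mean TOM
    assign_to <- cl
    for (sid in as.integer(names(sizes)[sizes < min_size])) {
      members <- which(cl == sid)
      mean_tom <- vapply(core_ids, function(cid)
        mean(tom[members, cl == cid, drop = FALSE]), numeric(1))
      if (max(mean_tom) > 0) {
        assign_to[members] <- core_ids[which.max(mean_tom)]
      } else {
        assign_to[members] <- NA_integer_
      }
    }
    final_sizes <- sort(table(assign_to), decreasing = TRUE)
    palette <- module_palette(length(final_sizes))
    for (i in seq_along(final_sizes)) {
      labs[!is.na(assign_to) &
             assign_to == as.integer(names(final_sizes)[i])] <- palette[i]
    }
  }
  list(modules = labs, dendrogram = hc)
}

#' Intramodular connectivity
#'
#' `k_i` = sum of adjacency weights from taxon i to other members of its
#' module. Unassigned taxa get 0.
#'
#' @param a adjacency matrix.
#' @param modules named label vector from [cut_modules()].
#' @return Named numeric vector of within-module connectivities.
#' @export
intramodular_connectivity <- function(a, modules) {
  modules <- modules[rownames(a)]
  k <- setNames(numeric(nrow(a)), rownames(a))
  for (m in setdiff(unique(modules), "unassigned")) {
    idx <- which(modules == m)
    k[idx] <- rowSums(a[idx, idx, drop = FALSE])
  }
  k
}

#' Hub taxa per module
#'
#' The top `ceil(fraction * module size)` taxa by intramodular
#' connectivity in each module (ties broken by taxon id); the module hub
#' is the argmax.
#'
#' @param k connectivity vector from [intramodular_connectivity()].
#' @param modules named label vector.
#' @param fraction top fraction per module (default 0.10).
#' @return data.frame with taxon, module, connectivity, `top` flag and
#'   `hub` flag.
#' @export
hub_taxa <- function(k, modules, fraction = 0.10) {
  modules <- modules[names(k)]
  out <- lapply(setdiff(unique(modules), "unassigned"), function(m) {
    idx <- names(k)[modules == m]
    ord <- idx[order(-k[idx], idx)]
    n_top <- ceiling(fraction * length(idx))
    data.frame(taxon = ord, module = m, connectivity = unname(k[ord]),
               top = seq_along(ord) <= n_top,
               hub = seq_along(ord) == 1L, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Thresholded within-module edge list
#'
#' Retains within-module pairs with adjacency above `threshold` (the
#' visualization rule: weak edges are hidden).
#'
#' @param a adjacency matrix.
#' @param modules named label vector.
#' @param threshold minimum edge weight (default 0.2, strictly `>`).
#' @return data.frame with source, target, weight, module.
#' @export
edge_list <- function(a, modules, threshold = 0.2) {
  modules <- modules[rownames(a)]
  ut <- which(upper.tri(a), arr.ind = TRUE)
  same <- modules[ut[, 1]] == modules[ut[, 2]] &
    modules[ut[, 1]] != "unassigned"
  keep <- same & a[ut] > threshold
  data.frame(source = rownames(a)[ut[keep, 1]],
             target = colnames(a)[ut[keep, 2]],
             weight = a[ut][keep],
             module = unname(modules[ut[keep, 1]]),
             stringsAsFactors = FALSE)
}

#' Build the full network model from a tau matrix
#'
#' Runs beta selection (or uses a fixed exponent), adjacency, TOM,
#' module detection, connectivity, hubs and the thresholded edge list.
#'
#' @param tau correlation matrix.
#' @param beta integer exponent, or `"auto"` for scale-free selection.
#' @param min_size minimum module size (default 5).
#' @param cut_quantile static-cut quantile of merge heights (default 0.99).
#' @param hub_fraction top-connectivity fraction per module (default 0.10).
#' @param edge_threshold visualization edge-weight threshold (default 0.2).
#' @param r2_target scale-free R^2 target when `beta = "auto"`.
#' @return A `network_model` list: `beta`, `scale_free_fits`, `adjacency`,
#'   `tom`, `dendrogram`, `modules`, `connectivity`, `hubs`, `edges`.
#' @export
network_modules <- function(tau, beta = "auto", min_size = 5,
                            cut_quantile = 0.99, hub_fraction = 0.10,
                            edge_threshold = 0.2, r2_target = 0.8) {
  fits <- NULL
  if (identical(beta, "auto")) {
    sel <- select_beta(tau, r2_target = r2_target)
    beta <- sel$beta
    fits <- sel$fits
  }
  a <- adjacency_matrix(tau, beta)
  tom <- topological_overlap(a)
  cut <- cut_modules(tom, min_size = min_size, cut_quantile = cut_quantile)
  k <- intramodular_connectivity(a, cut$modules)
  structure(list(beta = beta, scale_free_fits = fits, adjacency = a,
                 tom = tom, dendrogram = cut$dendrogram,
                 modules = cut$modules, connectivity = k,
                 hubs = hub_taxa(k, cut$modules, fraction = hub_fraction),
                 edges = edge_list(a, cut$modules,
                                   threshold = edge_threshold)),
            class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  tab <- sort(table(x$modules), decreasing = TRUE)
  cat(sprintf("network_model: %d taxa, beta = %d, %d modules\n",
              length(x$modules), x$beta,
              sum(names(tab) != "unassigned")))
  print(tab)
  invisible(x)
}

#' Export a module dendrogram as Newick text
#'
#' @param model a `network_model` (or an `hclust` object).
#' @return Newick string.
#' @export
dendrogram_newick <- function(model) {
  hc <- if (inherits(model, "hclust")) model else model$dendrogram
  ape::write.tree(ape::as.phylo(hc))
}
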