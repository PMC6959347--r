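# Proportional decontamination and replicate quality control.
#
# Contamination (tag-jumping, reagent or cross-sample carry-over) shows up
# in negative controls and blanks. The most-likely per-OTU proportional
# contribution of contamination is estimated from the control columns and
# subtracted from every sample's read proportions; samples whose PCR
# replicates disagree strongly (Bray-Curtis dissimilarity above 0.49) are
# dropped outright.

#' Convert counts to within-sample read proportions
#'
#' Divides each column by its sum. All-zero columns stay all-zero and are
#' flagged in the `"zero_columns"` attribute.
#'
#' @param counts nonnegative taxa x samples matrix.
#' @return Proportion matrix of the same shape.
#' @export
proportionalize <- function(counts) {
  if (any(counts < 0)) stop("negative counts")
  cs <- colSums(counts)
  props <- sweep(counts, 2, ifelse(cs == 0, 1, cs), "/")
  attr(props, "zero_columns") <- colnames(counts)[cs == 0]
  props
}

#' Estimate per-OTU contamination proportions from controls
#'
#' The contamination proportion of OTU i is its maximum (default) or mean
#' read proportion across control columns; OTUs absent from all controls
#' get 0. With no controls, all proportions are 0.
#'
#' @param props proportion matrix from [proportionalize()].
#' @param control_ids control column names (may be empty).
#' @param method `"max"` (conservative, default) or `"mean"`.
#' @return Named numeric vector `c_i` with a `"controls"` attribute.
#' @export
estimate_contamination <- function(props, control_ids,
                                   method = c("max", "mean")) {
  method <- match.arg(method)
  control_ids <- intersect(control_ids, colnames(props))
  if (length(control_ids) == 0L) {
    ci <- setNames(rep(0, nrow(props)), rownames(props))
  } else {
    ctrl <- props[, control_ids, drop = FALSE]
    ci <- if (method == "max") apply(ctrl, 1, max) else rowMeans(ctrl)
  }
  attr(ci, "controls") <- control_ids
  ci
}

#' Subtract contamination proportions and renormalize
#'
#' `p'_ij = max(0, p_ij - c_i)`, then each nonzero column is renormalized
#' to sum to 1 (all-zero columns stay zero).
#'
#' @param props proportion matrix.
#' @param profile contamination vector from [estimate_contamination()].
#' @return Decontaminated proportion matrix.
#' @export
subtract_contamination <- function(props, profile) {
  if (!all(rownames(props) %in% names(profile)))
    stop("contamination profile does not cover all taxa")
  out <- pmax(props - profile[rownames(props)], 0)
  cs <- colSums(out)
  out <- sweep(out, 2, ifelse(cs == 0, 1, cs), "/")
  attr(out, "zero_columns") <- colnames(out)[cs == 0]
  out
}

#' Bray-Curtis dissimilarity between two composition vectors
#'
#' `BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i)`; two all-zero vectors
#' give 0 by convention.
#'
#' @param x,y nonnegative numeric vectors of equal length.
#' @return A number in [0, 1].
#' @export
bray_curtis <- function(x, y) {
  stopifnot(length(x) == length(y))
  tot <- sum(x + y)
  if (tot == 0) return(0)
  sum(abs(x - y)) / tot
}

#' Maximum pairwise Bray-Curtis dissimilarity among PCR replicates
#'
#' @param props proportion matrix (columns are replicates).
#' @param groups named list mapping each field sample (time point) to its
#'   replicate column names. Groups with a single replicate pass trivially
#'   with value 0.
#' @return Named numeric vector: per sample, max pairwise Bray-Curtis.
#' @export
replicate_dissimilarity <- function(props, groups) {
  vapply(groups, function(cols) {
    cols <- intersect(cols, colnames(props))
    if (length(cols) < 2L) return(0)
    m <- props[, cols, drop = FALSE]
    worst <- 0
    for (i in seq_len(ncol(m) - 1L)) {
      for (j in seq(i + 1L, ncol(m))) {
        worst <- max(worst, bray_curtis(m[, i], m[, j]))
      }
    }
    worst
  }, numeric(1))
}

#' Drop samples with overly dissimilar replicates
#'
#' Samples whose max pairwise Bray-Curtis exceeds the threshold (strictly
#' `>`; the boundary value is retained) are removed.
#'
#' @param dissim output of [replicate_dissimilarity()].
#' @param threshold Bray-Curtis cutoff (default 0.49).
#' @return List with `retained` sample names and a QC `report` data.frame.
#' @export
drop_dissimilar_samples <- function(dissim, threshold = 0.49) {
  dropped <- dissim > threshold
  if (all(dropped)) {
    stop("all samples dropped by replicate QC; max Bray-Curtis values: ",
         paste(sprintf("%s=%.3f", names(dissim), dissim), collapse = ", "))
  }
  list(retained = names(dissim)[!dropped],
       report = data.frame(sample = names(dissim), max_bray_curtis = dissim,
                           dropped = dropped, row.names = NULL,
                           stringsAsFactors = FALSE))
}

#' Collapse PCR replicates to one proportion column per sample
#'
#' Surviving replicates are averaged (arithmetic mean of proportions) and
#' renormalized.
#'
#' @param props proportion matrix.
#' @param groups named list mapping sample -> replicate columns (only
#'   retained samples should be passed).
#' @return Proportion matrix with one column per group.
#' @export
collapse_replicates <- function(props, groups) {
  cols <- lapply(groups, intersect, x = colnames(props))
  keep <- lengths(cols) > 0L
  out <- vapply(cols[keep], function(cc)
    rowMeans(props[, cc, drop = FALSE]), numeric(nrow(props)))
  out <- matrix(out, nrow = nrow(props),
                dimnames = list(rownames(props), names(cols)[keep]))
  cs <- colSums(out)
  sweep(out, 2, ifelse(cs == 0, 1, cs), "/")
}
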