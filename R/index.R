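# The eDNA abundance index.
#
# Raw read counts confound organismal abundance with primer-template
# amplification bias. Assuming that bias is constant within a taxon-locus
# pair across samples, the within-sample read proportion of a taxon,
# rescaled by that taxon's maximum proportion across samples,
#
#   index_ij = p_ij / max_j(p_ij)  in [0, 1],
#
# tracks relative change in abundance over time for each taxon
# independently of its (unknown) amplification efficiency. Indices from
# loci that amplify a taxon are averaged into an ensemble index; loci that
# never amplify it carry no information and are excluded.

#' Agglomerate OTU counts to Family-or-higher taxa
#'
#' Sums counts over OTUs sharing a taxon label (the most specific rank
#' available at or above Family: Family, else Order, else Class). OTUs with
#' a missing/empty taxon label are dropped and counted in the
#' `"dropped_otus"` attribute.
#'
#' @param counts OTU x sample matrix (counts or proportions).
#' @param taxonomy data.frame with `otu_id`, `taxon`, `habitat`.
#' @return Taxon x sample matrix.
#' @export
agglomerate_taxa <- function(counts, taxonomy) {
  idx <- match(rownames(counts), taxonomy$otu_id)
  if (anyNA(idx)) stop("OTUs missing from taxonomy: ",
                       paste(head(rownames(counts)[is.na(idx)]), collapse = ", "))
  taxon <- taxonomy$taxon[idx]
  habitat <- taxonomy$habitat[idx]
  annotated <- !is.na(taxon) & taxon != ""
  conflicts <- tapply(habitat[annotated], taxon[annotated],
                      function(h) length(unique(h)) > 1L)
  if (any(conflicts))
    stop("conflicting habitat flags within taxa: ",
         paste(names(conflicts)[conflicts], collapse = ", "))
  kept <- counts[annotated, , drop = FALSE]
  out <- rowsum(kept, group = taxon[annotated])
  attr(out, "dropped_otus") <- sum(!annotated)
  out
}

#' Compute the per-locus eDNA index
#'
#' Each taxon row of the proportion table is divided by its maximum across
#' samples. Rows with max 0 stay all-zero (0/0 := 0) and are flagged.
#'
#' @param props taxon x sample proportion matrix for one locus.
#' @param locus label stored in the `"locus"` attribute.
#' @return Index matrix in [0, 1]; detected rows attain exactly 1 at their
#'   maximum.
#' @export
edna_index <- function(props, locus = "locus") {
  rm_ <- apply(props, 1, max)
  out <- props / ifelse(rm_ == 0, 1, rm_)
  attr(out, "locus") <- locus
  attr(out, "undetected_taxa") <- rownames(props)[rm_ == 0]
  out
}

#' Combine per-locus eDNA indices into an ensemble index
#'
#' A locus contributes to a taxon's ensemble iff it detected that taxon at
#' one or more time points (an all-zero row means the locus does not
#' amplify the taxon and carries no information). Each cell is the mean of
#' the contributing loci's values at that cell; `NA` cells (e.g. time
#' points a locus lost to QC) are excluded cell-wise. Taxa detected by no
#' locus are all-zero.
#'
#' @param index_list named list of per-locus index matrices with identical
#'   row and column names.
#' @return Ensemble index matrix with a per-taxon `"provenance"` attribute
#'   listing contributing loci.
#' @export
ensemble_index <- function(index_list) {
  stopifnot(length(index_list) >= 1L)
  ref <- index_list[[1]]
  for (m in index_list[-1]) {
    if (!identical(dimnames(m), dimnames(ref)))
      stop("per-locus index tables are misaligned")
  }
  taxa <- rownames(ref)
  detects <- vapply(index_list, function(m)
    apply(m, 1, function(r) any(!is.na(r) & r > 0)), logical(length(taxa)))
  detects <- matrix(detects, nrow = length(taxa),
                    dimnames = list(taxa, names(index_list)))
  num <- matrix(0, nrow(ref), ncol(ref), dimnames = dimnames(ref))
  den <- matrix(0, nrow(ref), ncol(ref), dimnames = dimnames(ref))
  for (l in names(index_list)) {
    m <- index_list[[l]]
    use <- detects[, l] & !is.na(m)
    num[use] <- num[use] + m[use]
    den <- den + use
  }
  out <- num / ifelse(den == 0, 1, den)
  attr(out, "locus") <- "ensemble"
  attr(out, "provenance") <- apply(detects, 1, function(d)
    paste(colnames(detects)[d], collapse = ","))
  out
}

#' Remove terrestrial taxa from an index table
#'
#' @param index taxon x sample matrix.
#' @param taxonomy data.frame with `taxon` and `habitat` columns.
#' @return Matrix restricted to marine taxa, with removed taxa listed in
#'   the `"removed"` attribute.
#' @export
remove_terrestrial <- function(index, taxonomy) {
  hab <- taxonomy$habitat[match(rownames(index), taxonomy$taxon)]
  terrestrial <- !is.na(hab) & hab == "terrestrial"
  out <- index[!terrestrial, , drop = FALSE]
  attr(out, "locus") <- attr(index, "locus")
  attr(out, "removed") <- rownames(index)[terrestrial]
  out
}
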