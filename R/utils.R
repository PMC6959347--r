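# Internal helpers shared across the pipeline.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' All randomness in the package flows through this wrapper so that no
#' function leaves global RNG state behind and identical seeds give
#' bit-identical results.
#' @noRd
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Derive a sub-stream seed from a master seed; stays below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647L)
}

stop_if_not_prob <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("'%s' must be a probability in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

# Module label palette, ordered by module size at assignment time.
# "unassigned" is reserved and never used for a real module.
module_palette <- function(n) {
  base <- c("blue", "grey", "green", "yellow", "orange", "black",
            "brown", "red", "pink", "purple", "turquoise", "magenta",
            "cyan", "salmon", "tan", "gold")
  if (n <= length(base)) base[seq_len(n)] else
    c(base, paste0("module", seq_len(n - length(base))))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items,
#' used to score recovery of planted subnetworks. 1 means identical
#' partitions (up to label renaming), 0 is the expected value for
#' independent random partitions.
#'
#' @param a,b vectors of cluster labels of equal length.
#' @return A single number, at most 1.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

write_tsv <- function(x, path, rownames_col = NULL) {
  if (!is.null(rownames_col)) {
    x <- data.frame(setNames(list(rownames(x)), rownames_col),
                    as.data.frame(x), check.names = FALSE)
  }
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read a taxa-by-samples count table from TSV
#'
#' The first column holds OTU/taxon identifiers; remaining columns are
#' samples. Used for interchange with external tools.
#' @param path TSV file path.
#' @return Integer matrix with taxa as rownames.
#' @export
read_count_table <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Write a taxa-by-samples matrix to TSV
#' @param x matrix with taxa rownames.
#' @param path output path.
#' @param id_col name for the identifier column.
#' @export
write_count_table <- function(x, path, id_col = "otu_id") {
  write_tsv(x, path, rownames_col = id_col)
}
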