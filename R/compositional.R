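# Genus aggregation, prevalence/abundance filtering, CLR transform.

#' Aggregate a feature (ASV) count table to genus relative abundances
#'
#' Features without a genus label are discarded; counts are summed per genus
#' and each sample row is renormalised to relative abundance. Samples whose
#' retained counts are all zero are excluded with a warning.
#'
#' @param counts Numeric matrix, samples x features (rownames = sample ids).
#' @param genus Character vector of genus labels per feature column; `NA` or
#'   `""` marks unlabeled features.
#' @return Numeric matrix samples x genera of relative abundances (rows sum
#'   to 1). Total retained counts per sample are attached as attribute
#'   `"retained_counts"`.
#' @export
genus_aggregate <- function(counts, genus) {
  .assert(is.matrix(counts) && ncol(counts) == length(genus),
          "counts must be a samples x features matrix matching genus labels")
  .assert(all(counts >= 0), "counts must be non-negative")
  labeled <- !is.na(genus) & nzchar(genus)
  counts <- counts[, labeled, drop = FALSE]
  genus <- genus[labeled]
  genera <- sort(unique(genus))
  agg <- vapply(genera, function(g) {
    rowSums(counts[, genus == g, drop = FALSE])
  }, numeric(nrow(counts)))
  if (nrow(counts) == 1L) agg <- matrix(agg, nrow = 1L,
                                        dimnames = list(rownames(counts),
                                                        genera))
  tot <- rowSums(agg)
  zero <- tot == 0
  if (any(zero)) {
    warning(sprintf("excluding %d sample(s) with all-zero retained counts",
                    sum(zero)))
    agg <- agg[!zero, , drop = FALSE]
    tot <- tot[!zero]
  }
  rel <- agg / tot
  attr(rel, "retained_counts") <- tot
  rel
}

#' Prevalence/abundance genus filter
#'
#' A genus is retained iff it is present in at least `min_prevalence` of
#' samples at relative abundance `detection` or more, OR it reaches
#' `dominance` relative abundance in any single sample. Defaults: detected at
#' 0.01% in at least 10% of samples, or 10% abundance anywhere.
#'
#' @param matrix Relative-abundance matrix, samples x genera.
#' @param min_prevalence Prevalence threshold (proportion of samples,
#'   default 0.10; the comparison is `>=` on the raw fraction).
#' @param detection Detection abundance for the prevalence clause
#'   (default 1e-4).
#' @param dominance Single-sample abundance sufficient on its own
#'   (default 0.10).
#' @return Character vector of retained genus names.
#' @export
genus_filter <- function(matrix, min_prevalence = 0.10, detection = 1e-4,
                         dominance = 0.10) {
  .assert(is.matrix(matrix) && nrow(matrix) >= 1L,
          "need a matrix with at least one sample")
  prev <- colMeans(matrix >= detection)
  peak <- apply(matrix, 2L, max)
  colnames(matrix)[prev >= min_prevalence | peak >= dominance]
}

#' Centered log-ratio transform of a relative-abundance matrix
#'
#' Zeros are replaced according to the pseudocount policy, rows are
#' renormalised, and each row is mapped to
#' `clr(x)_g = ln(x_g) - mean_g ln(x_g)`, so every output row sums to zero.
#' The default policy (`pseudocount = "auto"`) adds half the smallest nonzero
#' relative abundance in the matrix to every entry (multiplicative-
#' replacement practice); a fixed numeric pseudocount may be supplied
#' instead. The pseudocount is only applied when the matrix contains zeros.
#'
#' @param matrix Relative-abundance matrix, samples x genera, values >= 0;
#'   no row may be all zero.
#' @param pseudocount `"auto"` or a positive number.
#' @return CLR coordinate matrix with the same dimnames; rows sum to 0.
#' @examples
#' m <- matrix(c(0.8, 0.2, 0.5, 0.5), 2, byrow = TRUE)
#' rowSums(clr_transform(m))  # ~0
#' @export
clr_transform <- function(matrix, pseudocount = "auto") {
  .assert(is.matrix(matrix) && all(matrix >= 0),
          "matrix must be numeric with non-negative entries")
  .assert(all(rowSums(matrix) > 0), "a row of all zeros cannot be transformed")
  x <- matrix / rowSums(matrix)
  if (any(x == 0)) {
    pc <- if (identical(pseudocount, "auto")) {
      min(x[x > 0]) / 2
    } else {
      .assert(is.numeric(pseudocount) && pseudocount > 0,
              "pseudocount must be 'auto' or a positive number")
      pseudocount
    }
    x <- x + pc
    x <- x / rowSums(x)
  }
  lx <- log(x)
  out <- lx - rowMeans(lx)
  dimnames(out) <- dimnames(matrix)
  out
}

#' Standardize a vector to z-scores
#'
#' `(x - mean(x)) / sd(x)` with the sample standard deviation (n - 1
#' denominator).
#'
#' @param values Numeric vector, length >= 2, nonzero spread.
#' @return Standardized vector with mean 0 and sd 1.
#' @export
standardize <- function(values) {
  .assert(is.numeric(values) && length(values) >= 2L,
          "need at least 2 values")
  s <- stats::sd(values)
  .assert(is.finite(s) && s > 0, "cannot standardize a zero-spread vector")
  (values - mean(values)) / s
}
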