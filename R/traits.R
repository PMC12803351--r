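# Binary trait-presence matrices, pairwise mutual information, repertoires.

#' Build a binary genome-by-trait presence matrix
#'
#' Transporter traits (ABC, PTS, MFS) are 1 iff the corresponding count is
#' positive; pathway traits take the completeness calls as given.
#'
#' @param censuses Data frame from [census_table()] (`genome_id`, `abc`,
#'   `pts`, `mfs`).
#' @param pathways Optional data frame from [pathway_table()] (`genome_id`
#'   plus 0/1 pathway columns); must cover exactly the same genomes.
#' @return Binary integer matrix (genomes x traits) with dimnames.
#' @export
build_presence_matrix <- function(censuses, pathways = NULL) {
  .assert(is.data.frame(censuses) &&
            all(c("genome_id", "abc", "pts", "mfs") %in% names(censuses)),
          "censuses must have columns genome_id, abc, pts, mfs")
  .assert(!anyDuplicated(censuses$genome_id),
          "duplicate genome ids in censuses")
  mat <- cbind(ABC = as.integer(censuses$abc > 0),
               PTS = as.integer(censuses$pts > 0),
               MFS = as.integer(censuses$mfs > 0))
  rownames(mat) <- censuses$genome_id
  if (!is.null(pathways)) {
    .assert(is.data.frame(pathways) && "genome_id" %in% names(pathways),
            "pathways must have a genome_id column")
    .assert(setequal(pathways$genome_id, censuses$genome_id),
            "censuses and pathways cover different genome sets")
    pw <- pathways[match(censuses$genome_id, pathways$genome_id), ,
                   drop = FALSE]
    pcols <- setdiff(names(pw), "genome_id")
    pmat <- as.matrix(pw[, pcols, drop = FALSE])
    storage.mode(pmat) <- "integer"
    .assert(all(pmat %in% c(0L, 1L)), "pathway values must be binary")
    mat <- cbind(mat, pmat)
  }
  mat
}

# Plug-in mutual information (bits) between two binary vectors; shared with
# the diagonal entropy. 0 log 0 terms are treated as 0.
.mi_binary <- function(x, y, base = 2) {
  n <- length(x)
  mi <- 0
  for (a in unique(x)) {
    px <- mean(x == a)
    for (b in unique(y)) {
      pxy <- mean(x == a & y == b)
      if (pxy > 0) {
        py <- mean(y == b)
        mi <- mi + pxy * log(pxy / (px * py), base = base)
      }
    }
  }
  mi
}

.entropy_binary <- function(x, base = 2) {
  p <- table(x) / length(x)
  -sum(ifelse(p > 0, p * log(p, base = base), 0))
}

#' Pairwise mutual information between binary traits
#'
#' Plug-in (maximum-likelihood) estimator of mutual information, in bits by
#' default, over the empirical joint frequencies of every trait pair. The
#' diagonal holds each trait's plug-in entropy. Constant traits have zero
#' mutual information with everything by convention.
#'
#' @param matrix Binary genome-by-trait matrix as from
#'   [build_presence_matrix()]; at least two genomes.
#' @param base Logarithm base (default 2, i.e. bits).
#' @return Symmetric trait-by-trait numeric matrix.
#' @examples
#' m <- cbind(A = c(0, 0, 1, 1), B = c(0, 1, 0, 1))
#' pairwise_mi(m)
#' @export
pairwise_mi <- function(matrix, base = 2) {
  .assert(is.matrix(matrix) && nrow(matrix) >= 2L,
          "need a matrix with at least 2 genomes")
  .assert(all(matrix %in% c(0, 1)), "presence values must be binary")
  k <- ncol(matrix)
  out <- diag(vapply(seq_len(k), function(j) {
    .entropy_binary(matrix[, j], base)
  }, numeric(1)), nrow = k)
  if (k >= 2L) {
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        v <- .mi_binary(matrix[, i], matrix[, j], base)
        out[i, j] <- out[j, i] <- v
      }
    }
  }
  dimnames(out) <- list(colnames(matrix), colnames(matrix))
  out
}

#' Group genomes by exact transporter repertoire
#'
#' Each genome is assigned to exactly one combination — its exact presence
#' pattern over the requested traits (as in an UpSet plot). Set sizes are the
#' per-trait column sums; intersection sizes are the group cardinalities.
#'
#' @param matrix Binary presence matrix.
#' @param traits Traits defining the repertoire (default ABC, PTS, MFS).
#' @return List with `groups` (named list of genome id vectors, names like
#'   `"ABC+PTS"` or `"none"`), `intersection_sizes` (named integer vector) and
#'   `set_sizes` (per-trait totals).
#' @export
repertoire_groups <- function(matrix, traits = c("ABC", "PTS", "MFS")) {
  miss <- setdiff(traits, colnames(matrix))
  .assert(length(miss) == 0L, "trait(s) not in matrix: %s",
          paste(miss, collapse = ", "))
  sub <- matrix[, traits, drop = FALSE]
  label <- apply(sub, 1L, function(r) {
    on <- traits[r == 1]
    if (length(on) == 0L) "none" else paste(on, collapse = "+")
  })
  groups <- split(rownames(sub), label)
  sizes <- vapply(groups, length, integer(1))
  ord <- order(-sizes, names(groups))
  groups <- groups[ord]
  sizes <- sizes[ord]
  list(groups = groups,
       intersection_sizes = sizes,
       set_sizes = colSums(sub))
}
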