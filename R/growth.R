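# Growth-curve AUC, Spearman associations, prevalence filtering.

#' Area under a growth curve
#'
#' Trapezoidal integral of OD600 over time, in OD x hours. No baseline
#' subtraction by default; with `baseline = TRUE` the first OD value is
#' subtracted from the whole curve before integration.
#'
#' @param times Strictly increasing time points (hours), length >= 2.
#' @param od600 Non-negative optical densities, same length as `times`.
#' @param baseline Subtract the initial OD before integrating?
#' @return The AUC (numeric scalar).
#' @examples
#' curve_auc(c(0, 72), c(0.5, 0.5))  # 36
#' @export
curve_auc <- function(times, od600, baseline = FALSE) {
  .assert(is.numeric(times) && is.numeric(od600) &&
            length(times) == length(od600) && length(times) >= 2L,
          "times and od600 must be numeric vectors of equal length >= 2")
  .assert(all(diff(times) > 0), "times must be strictly increasing")
  .assert(all(od600 >= 0), "od600 must be non-negative")
  y <- if (baseline) od600 - od600[1] else od600
  n <- length(y)
  sum(diff(times) * (y[-1] + y[-n]) / 2)
}

# All permutations of 1..n as an (n! x n) integer matrix.
.all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  p <- .all_perms(n - 1L)
  m <- nrow(p)
  out <- matrix(0L, m * n, n)
  for (i in seq_len(n)) {
    rest <- (seq_len(n))[-i]
    out[((i - 1L) * m + 1L):(i * m), ] <-
      cbind(rep.int(i, m), matrix(rest[p], m, n - 1L))
  }
  out
}

#' Spearman rank correlation with tie-aware p-value
#'
#' Spearman's rho computed as the Pearson correlation of midranks (average
#' ranks for ties). The two-sided p-value is exact (full permutation
#' enumeration over rank orderings) for n <= 9, and uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` with n - 2 degrees of freedom
#' otherwise.
#'
#' @param x,y Paired numeric vectors, n >= 3.
#' @return List with `rho`, `p`, `n`, `method`, and `undefined` (TRUE with
#'   `rho = NA` when either input is constant).
#' @export
spearman_assoc <- function(x, y) {
  .assert(is.numeric(x) && is.numeric(y) && length(x) == length(y),
          "x and y must be numeric vectors of equal length")
  n <- length(x)
  .assert(n >= 3L, "need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "undefined",
                undefined = TRUE))
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 9L) {
    perms <- .all_perms(n)
    rho_perm <- apply(perms, 1L, function(idx) stats::cor(rx[idx], ry))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    method <- "t approximation"
  }
  list(rho = rho, p = p, n = n, method = method, undefined = FALSE)
}

#' Filter genes by intermediate prevalence
#'
#' Retains a gene iff its prevalence across species lies strictly between 25%
#' and 75%. Genes fixed (or nearly fixed) for presence or absence carry little
#' contrast for regression and are dropped.
#'
#' @param matrix Binary species-by-gene presence matrix.
#' @param lower,upper Strict prevalence bounds (defaults 0.25 and 0.75).
#' @return Character vector of retained gene (column) names.
#' @export
prevalence_gene_filter <- function(matrix, lower = 0.25, upper = 0.75) {
  .assert(is.matrix(matrix) && nrow(matrix) >= 1L,
          "need a matrix with at least one species")
  prev <- colMeans(matrix)
  colnames(matrix)[prev > lower & prev < upper]
}
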