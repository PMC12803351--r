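# Random-intercept linear mixed model fit by profiled maximum likelihood.

#' Fit a random-intercept linear mixed model by maximum likelihood
#'
#' Fits `y = X beta + u_group + e` with `u ~ N(0, sigma_u^2)` and
#' `e ~ N(0, sigma_e^2)` by maximum likelihood, profiling the likelihood over
#' the single variance ratio `theta = sigma_u^2 / sigma_e^2`. For fixed
#' `theta` the marginal covariance is block diagonal
#' (`I + theta J` per group), so GLS quantities have closed per-group forms;
#' the 1-D profile is then maximised numerically and compared against the
#' `theta = 0` (ordinary least squares) boundary. Wald z statistics and
#' two-sided p-values are reported per fixed effect.
#'
#' Constant predictors are dropped with a warning; any remaining rank
#' deficiency is an error naming the aliased columns.
#'
#' @param outcome Numeric response vector (e.g. log10 CFU).
#' @param predictors Data frame or matrix of fixed-effect predictors
#'   (typically binary gene-presence indicators).
#' @param group Grouping factor (biological repeat index); at least 2 groups.
#' @return An object of class `mixed_model_fit`: `coefficients` (data frame
#'   with estimate, se, z, p), `sigma_u2`, `sigma_e2`, `theta`, `loglik`,
#'   `n`, `n_groups`, `dropped` (names of constant predictors removed).
#' @export
fit_random_intercept_lmm <- function(outcome, predictors, group) {
  y <- as.numeric(outcome)
  X0 <- as.matrix(as.data.frame(predictors))
  .assert(nrow(X0) == length(y) && length(group) == length(y),
          "outcome, predictors and group must have matching lengths")
  g <- factor(group)
  .assert(nlevels(g) >= 2L, "need at least 2 groups")
  keep <- apply(X0, 2L, function(col) stats::sd(col) > 0)
  dropped <- colnames(X0)[!keep]
  if (length(dropped) > 0L) {
    warning(sprintf("dropping constant predictor(s): %s",
                    paste(dropped, collapse = ", ")))
  }
  X <- cbind(`(Intercept)` = 1, X0[, keep, drop = FALSE])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop(sprintf("design is rank deficient; aliased predictor(s): %s",
                 paste(aliased, collapse = ", ")), call. = FALSE)
  }
  n <- length(y)
  gi <- split(seq_len(n), g)
  msize <- vapply(gi, length, integer(1))

  # Profile log-likelihood pieces at a given theta >= 0.
  gls <- function(theta) {
    A <- matrix(0, ncol(X), ncol(X))
    b <- numeric(ncol(X))
    for (k in seq_along(gi)) {
      idx <- gi[[k]]
      Xg <- X[idx, , drop = FALSE]
      yg <- y[idx]
      cg <- theta / (1 + msize[k] * theta)
      sx <- colSums(Xg)
      sy <- sum(yg)
      A <- A + crossprod(Xg) - cg * tcrossprod(sx)
      b <- b + crossprod(Xg, yg) - cg * sx * sy
    }
    beta <- solve(A, b)
    r <- y - drop(X %*% beta)
    quad <- 0
    for (k in seq_along(gi)) {
      idx <- gi[[k]]
      cg <- theta / (1 + unname(msize[k]) * theta)
      quad <- quad + sum(r[idx]^2) - cg * sum(r[idx])^2
    }
    sigma_e2 <- unname(quad) / n
    ll <- -n / 2 * (log(2 * pi * sigma_e2) + 1) -
      0.5 * sum(log1p(msize * theta))
    ll <- unname(ll)
    list(beta = beta, A = A, sigma_e2 = sigma_e2, loglik = ll)
  }

  prof <- function(ltheta) gls(exp(ltheta))$loglik
  opt <- stats::optimize(prof, interval = c(-25, 15), maximum = TRUE,
                         tol = 1e-10)
  cand_theta <- c(0, exp(opt$maximum))
  lls <- vapply(cand_theta, function(th) gls(th)$loglik, numeric(1))
  theta <- cand_theta[which.max(lls)]
  fit <- gls(theta)

  se <- sqrt(diag(fit$sigma_e2 * solve(fit$A)))
  z <- fit$beta / se
  coef <- data.frame(term = colnames(X), estimate = as.numeric(fit$beta),
                     se = se, z = z, p = 2 * stats::pnorm(-abs(z)),
                     stringsAsFactors = FALSE)
  rownames(coef) <- NULL
  structure(list(coefficients = coef,
                 sigma_u2 = theta * fit$sigma_e2,
                 sigma_e2 = fit$sigma_e2,
                 theta = theta,
                 loglik = fit$loglik,
                 n = n, n_groups = nlevels(g),
                 dropped = dropped),
            class = "mixed_model_fit")
}

#' @export
print.mixed_model_fit <- function(x, ...) {
  cat(sprintf(
    "Random-intercept LMM (ML): n = %d, groups = %d\n", x$n, x$n_groups))
  cat(sprintf("sigma_u^2 = %.4g, sigma_e^2 = %.4g, logLik = %.4f\n",
              x$sigma_u2, x$sigma_e2, x$loglik))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Mixed model for CFU outcomes with gene-presence predictors
#'
#' Convenience wrapper around [fit_random_intercept_lmm()] for colony-count
#' outcomes: by default the outcome is `log10(CFU + 1)`; `scale = "raw"` fits
#' the untransformed counts.
#'
#' @param cfu Non-negative CFU counts.
#' @param predictors Binary gene-presence predictors (e.g. ABC, PTS, MFS,
#'   RPI, PGM, KDGP indicators).
#' @param group Biological-repeat index.
#' @param scale `"log10"` (default, fits log10(CFU + 1)) or `"raw"`.
#' @return A `mixed_model_fit`.
#' @export
cfu_mixed_model <- function(cfu, predictors, group,
                            scale = c("log10", "raw")) {
  scale <- match.arg(scale)
  .assert(all(cfu >= 0), "CFU counts must be non-negative")
  y <- if (scale == "log10") log10(cfu + 1) else cfu
  fit_random_intercept_lmm(y, predictors, group)
}
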