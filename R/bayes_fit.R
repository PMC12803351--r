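# Posterior summaries, per-genus fitting, and the second-stage
# transporter-count regression.

#' Highest posterior density interval
#'
#' Shortest contiguous interval containing at least `mass` of the sorted
#' draws.
#'
#' @param x Numeric vector of posterior draws.
#' @param mass Posterior mass (default 0.95).
#' @return Length-2 numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(x, mass = 0.95) {
  .assert(is.numeric(x) && length(x) >= 2L, "need at least 2 draws")
  .assert(mass > 0 && mass <= 1, "mass must lie in (0, 1]")
  s <- sort(x)
  n <- length(s)
  k <- ceiling(mass * n)
  if (k >= n) return(c(s[1], s[n]))
  starts <- seq_len(n - k + 1L)
  widths <- s[starts + k - 1L] - s[starts]
  i <- which.min(widths)
  c(s[i], s[i + k - 1L])
}

#' Summarize the beta posterior of a genus model
#'
#' Reports the posterior mean of beta, 66% and 95% equal-tail (quantile)
#' intervals, the 95% highest posterior density interval, and whether that
#' HPD interval excludes zero, along with the beta R-hat and effective sample
#' size.
#'
#' @param draws A [sample_posterior()] result (>= 100 total draws).
#' @param genus Optional genus label overriding the model's.
#' @return One-row data frame: `genus`, `beta_mean`, `ci66_lo`, `ci66_hi`,
#'   `ci95_lo`, `ci95_hi`, `hpd95_lo`, `hpd95_hi`, `excludes_zero`,
#'   `rhat_beta`, `ess_beta`.
#' @export
summarize_posterior <- function(draws, genus = NULL) {
  .assert(inherits(draws, "posterior_draws"),
          "draws must be a posterior_draws object")
  b <- posterior_vector(draws, "beta")
  .assert(length(b) >= 100L, "need at least 100 total draws")
  et66 <- stats::quantile(b, c(0.17, 0.83), names = FALSE)
  et95 <- stats::quantile(b, c(0.025, 0.975), names = FALSE)
  hpd <- hpd_interval(b, 0.95)
  data.frame(
    genus = if (is.null(genus)) draws$genus else genus,
    beta_mean = mean(b),
    ci66_lo = et66[1], ci66_hi = et66[2],
    ci95_lo = et95[1], ci95_hi = et95[2],
    hpd95_lo = hpd[1], hpd95_hi = hpd[2],
    excludes_zero = hpd[1] > 0 || hpd[2] < 0,
    rhat_beta = unname(draws$rhat["beta"]),
    ess_beta = unname(draws$ess["beta"]),
    stringsAsFactors = FALSE
  )
}

#' Fit the sugar-association model for every genus
#'
#' For each genus column of a CLR matrix, fits the univariate Bayesian model
#' of standardized CLR abundance on standardized sugar exposure and
#' summarizes the beta posterior. Samples without a defined exposure are
#' dropped first; the exposure is standardized once over the retained
#' samples, and each genus column is standardized independently. Genus
#' columns with zero variance are skipped (recorded in the `"skipped"`
#' attribute). Per-genus seeds are derived deterministically from the master
#' seed, so results do not depend on which genera are fitted together.
#'
#' @param clr CLR coordinate matrix, samples x genera (rownames = sample
#'   ids).
#' @param exposure Either a numeric vector of sugar exposures aligned with
#'   `rownames(clr)` (NA = undefined), or a data frame from
#'   [lagged_exposure()] with columns `sample_id`, `sugar_exposure`.
#' @param seed Master seed.
#' @param chains,iter,warmup Passed to [sample_posterior()].
#' @return Data frame of [summarize_posterior()] rows in column order of
#'   `clr`, with attribute `"skipped"` (character vector) and `"n_samples"`.
#' @export
fit_all_genera <- function(clr, exposure, seed = 1L, chains = 4L,
                           iter = 1000L, warmup = 1000L) {
  .assert(is.matrix(clr), "clr must be a matrix (samples x genera)")
  if (is.data.frame(exposure)) {
    .assert(all(c("sample_id", "sugar_exposure") %in% names(exposure)),
            "exposure data frame needs columns sample_id, sugar_exposure")
    expo <- exposure$sugar_exposure[
      match(rownames(clr), exposure$sample_id)]
  } else {
    .assert(length(exposure) == nrow(clr),
            "exposure length must match the number of samples")
    expo <- as.numeric(exposure)
  }
  ok <- !is.na(expo)
  .assert(sum(ok) >= 3L, "need at least 3 samples with defined exposure")
  clr <- clr[ok, , drop = FALSE]
  x <- standardize(expo[ok])
  genera <- colnames(clr)
  if (is.null(genera)) genera <- sprintf("genus_%03d", seq_len(ncol(clr)))
  skipped <- character()
  rows <- list()
  for (g in seq_along(genera)) {
    yg <- clr[, g]
    if (stats::sd(yg) == 0) {
      skipped <- c(skipped, genera[g])
      next
    }
    model <- sugar_genus_model(standardize(yg), x, genus = genera[g])
    dr <- sample_posterior(model, chains = chains, iter = iter,
                           warmup = warmup, seed = derive_seed(seed, g))
    rows[[length(rows) + 1L]] <- summarize_posterior(dr)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(genus = character(), beta_mean = numeric(),
                      ci66_lo = numeric(), ci66_hi = numeric(),
                      ci95_lo = numeric(), ci95_hi = numeric(),
                      hpd95_lo = numeric(), hpd95_hi = numeric(),
                      excludes_zero = logical(), rhat_beta = numeric(),
                      ess_beta = numeric())
  }
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "n_samples") <- sum(ok)
  out
}

#' Second-stage regression of genus sugar coefficients on transporter counts
#'
#' Regresses the per-genus posterior mean sugar coefficients (already on the
#' z-score scale) on the genus mean count of one transporter type, normalized
#' by its maximum, using the same Normal(0,1)/Exponential(1) priors and MCMC
#' machinery as the per-genus models. The fitted mean curve is simulated over
#' the covariate range from the posterior draws with a 95% band, and the
#' Spearman rank correlation between counts and coefficients is attached.
#'
#' @param beta_means Numeric vector of per-genus sugar coefficients.
#' @param counts Genus mean transporter counts, same length and order
#'   (max > 0).
#' @param transporter_type Label, e.g. `"ABC"`.
#' @param seed,chains,iter,warmup Passed to [sample_posterior()].
#' @param n_grid Grid size for the fitted-mean curve.
#' @return An object of class `trait_regression`: `summary` (one-row data
#'   frame as [summarize_posterior()]), `draws`, `curve` (data frame
#'   `count_norm`, `mu_mean`, `mu_lo`, `mu_hi`), `spearman`
#'   ([spearman_assoc()] result), `transporter_type`, `counts_norm`.
#' @export
trait_regression <- function(beta_means, counts, transporter_type = "ABC",
                             seed = 1L, chains = 4L, iter = 1000L,
                             warmup = 1000L, n_grid = 50L) {
  .assert(is.numeric(beta_means) && is.numeric(counts) &&
            length(beta_means) == length(counts),
          "beta_means and counts must be numeric vectors of equal length")
  ok <- !is.na(beta_means) & !is.na(counts)
  beta_means <- beta_means[ok]
  counts <- counts[ok]
  .assert(length(counts) >= 3L,
          "need at least 3 genera with both a coefficient and a count")
  .assert(max(counts) > 0, "covariate maximum must be positive")
  xn <- counts / max(counts)
  model <- sugar_genus_model(beta_means, xn,
                             genus = paste0("trait:", transporter_type))
  dr <- sample_posterior(model, chains = chains, iter = iter,
                         warmup = warmup, seed = seed)
  a <- posterior_vector(dr, "alpha")
  b <- posterior_vector(dr, "beta")
  grid <- seq(min(xn), max(xn), length.out = n_grid)
  mu <- outer(b, grid) + a      # draws x grid
  curve <- data.frame(
    count_norm = grid,
    mu_mean = colMeans(mu),
    mu_lo = apply(mu, 2L, stats::quantile, probs = 0.025),
    mu_hi = apply(mu, 2L, stats::quantile, probs = 0.975)
  )
  structure(
    list(summary = summarize_posterior(dr, genus = transporter_type),
         draws = dr, curve = curve,
         spearman = spearman_assoc(counts, beta_means),
         transporter_type = transporter_type,
         counts_norm = xn),
    class = "trait_regression"
  )
}

#' @export
print.trait_regression <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Trait regression (%s): beta mean %.3f [95%% CI %.3f, %.3f]\n",
              x$transporter_type, s$beta_mean, s$ci95_lo, s$ci95_hi))
  cat(sprintf("Spearman rho %.3f (p = %.3g, %s)\n",
              x$spearman$rho, x$spearman$p, x$spearman$method))
  invisible(x)
}

#' Spearman correlation between transporter counts and sugar coefficients
#'
#' Rank correlation between genus mean transporter counts and the per-genus
#' sugar-association coefficients (delegates to [spearman_assoc()]). A
#' constant covariate yields the undefined flag.
#'
#' @inheritParams trait_regression
#' @return A [spearman_assoc()] result list.
#' @export
trait_spearman <- function(beta_means, counts, transporter_type = "ABC") {
  ok <- !is.na(beta_means) & !is.na(counts)
  .assert(sum(ok) >= 3L, "need at least 3 paired genera")
  res <- spearman_assoc(counts[ok], beta_means[ok])
  res$transporter_type <- transporter_type
  res
}
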