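# Bayesian univariate sugar-association model and in-package MCMC sampler.
#
# Model (per genus):
#   y_i ~ Normal(alpha + beta * x_i, sigma)
#   alpha ~ Normal(0, 1), beta ~ Normal(0, 1), sigma ~ Exponential(1)
# Sampling runs on (alpha, beta, log sigma) with the Jacobian correction,
# using adaptive random-walk Metropolis (covariance and step-scale adaptation
# during warmup only, frozen afterwards). The Gaussian likelihood depends on
# the data only through sufficient statistics, so each MCMC iteration is O(1)
# in the sample size.

#' Construct a per-genus sugar-association model
#'
#' @param y Outcome vector (standardized CLR abundances of one genus).
#' @param x Predictor vector (standardized sugar exposure), same length.
#' @param genus Optional genus label.
#' @return An object of class `genus_model` carrying the data and its
#'   sufficient statistics.
#' @export
sugar_genus_model <- function(y, x, genus = NA_character_) {
  .assert(is.numeric(y) && is.numeric(x) && length(y) == length(x),
          "y and x must be numeric vectors of equal length")
  .assert(all(is.finite(y)) && all(is.finite(x)),
          "y and x must be finite")
  structure(
    list(genus = genus, y = y, x = x,
         n = length(y),
         Sx = sum(x), Sy = sum(y),
         Sxx = sum(x^2), Syy = sum(y^2), Sxy = sum(x * y)),
    class = "genus_model"
  )
}

#' Log posterior density of a genus model
#'
#' Sum of the Gaussian log likelihood and the log prior densities
#' (`alpha, beta ~ Normal(0, 1)`, `sigma ~ Exponential(1)`); no
#' state-dependent terms are dropped. States with `sigma <= 0` have density
#' `-Inf`.
#'
#' @param model A [sugar_genus_model()].
#' @param alpha,beta,sigma Parameter state.
#' @return Log density (scalar).
#' @export
log_posterior <- function(model, alpha, beta, sigma) {
  .assert(inherits(model, "genus_model"), "model must be a genus_model")
  if (!is.finite(sigma) || sigma <= 0) return(-Inf)
  sse <- model$Syy - 2 * alpha * model$Sy - 2 * beta * model$Sxy +
    2 * alpha * beta * model$Sx + model$n * alpha^2 + beta^2 * model$Sxx
  ll <- -model$n / 2 * log(2 * pi) - model$n * log(sigma) -
    sse / (2 * sigma^2)
  ll + stats::dnorm(alpha, 0, 1, log = TRUE) +
    stats::dnorm(beta, 0, 1, log = TRUE) +
    stats::dexp(sigma, 1, log = TRUE)
}

# One adaptive random-walk Metropolis chain.
# lp: log target on the sampling scale; d: dimension; init: start state.
.amh_chain <- function(lp, d, init, warmup, iter, target_accept = 0.3) {
  th <- init
  lp_cur <- lp(th)
  tries <- 0
  while (!is.finite(lp_cur) && tries < 10) {
    th <- init + stats::rnorm(d, 0, 0.1)
    lp_cur <- lp(th)
    tries <- tries + 1
  }
  if (!is.finite(lp_cur)) {
    stop("non-finite posterior at initialization after 10 jitter retries",
         call. = FALSE)
  }
  log_s <- log(2.38 / sqrt(d))
  Lt <- diag(d)                      # t(chol(Sigma_hat))
  warm <- matrix(0, warmup, d)
  out <- matrix(0, iter, d)
  n_acc <- 0L
  total <- warmup + iter
  for (i in seq_len(total)) {
    z <- stats::rnorm(d)
    prop <- th + exp(log_s) * drop(Lt %*% z)
    lp_prop <- lp(prop)
    lacc <- lp_prop - lp_cur
    if (is.finite(lacc) && log(stats::runif(1)) < lacc) {
      th <- prop
      lp_cur <- lp_prop
      if (i > warmup) n_acc <- n_acc + 1L
    }
    if (i <= warmup) {
      acc_prob <- if (is.finite(lacc)) min(1, exp(lacc)) else 0
      log_s <- log_s + (acc_prob - target_accept) / i^0.6
      warm[i, ] <- th
      if (i >= 100L && i %% 100L == 0L) {
        # second half of warmup so far: drops the initial transient
        Sig <- stats::cov(warm[max(1L, floor(i / 2)):i, , drop = FALSE]) +
          diag(1e-8, d)
        ch <- tryCatch(chol(Sig), error = function(e) NULL)
        if (!is.null(ch)) Lt <- t(ch)
      }
    } else {
      out[i - warmup, ] <- th
    }
  }
  list(draws = out, accept = n_acc / iter)
}

# Split R-hat over an iter x chains matrix of draws for one parameter.
.split_rhat <- function(mat) {
  n <- nrow(mat)
  half <- floor(n / 2)
  pieces <- cbind(mat[seq_len(half), , drop = FALSE],
                  mat[(n - half + 1L):n, , drop = FALSE])
  m <- ncol(pieces)
  nn <- nrow(pieces)
  means <- colMeans(pieces)
  vars <- apply(pieces, 2L, stats::var)
  W <- mean(vars)
  if (W == 0) return(1)
  B <- nn * stats::var(means)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# Effective sample size for one chain via Geyer's initial positive sequence.
.ess_one <- function(x) {
  n <- length(x)
  if (stats::sd(x) == 0) return(n)
  r <- stats::acf(x, lag.max = min(n - 1L, 250L), plot = FALSE,
                  demean = TRUE)$acf[, 1, 1]
  g <- r[-1]
  tau <- 1
  k <- 1L
  while (k + 1L <= length(g)) {
    pair <- g[k] + g[k + 1L]
    if (pair <= 0) break
    tau <- tau + 2 * pair
    k <- k + 2L
  }
  max(n / tau, 1)
}

#' Sample the posterior of a genus model
#'
#' Runs `chains` adaptive random-walk Metropolis chains over
#' `(alpha, beta, log sigma)` (with the log-sigma Jacobian correction);
#' proposal covariance and step scale adapt during warmup only and are frozen
#' afterwards. With `sigma_fixed` supplied, sigma is held at that value and
#' only `(alpha, beta)` are sampled (used for conjugate cross-checks).
#' Split R-hat and effective sample sizes are computed per parameter; a
#' warning is raised when any split R-hat exceeds 1.01. Identical seeds give
#' bit-identical draws.
#'
#' @param model A [sugar_genus_model()].
#' @param chains Number of chains (default 4).
#' @param iter Retained draws per chain (default 1000; the default totals
#'   4000 draws).
#' @param warmup Warmup iterations per chain, discarded (default 1000).
#' @param seed Integer master seed; chain seeds are derived from it.
#' @param sigma_fixed Optional positive value fixing sigma.
#' @param init Initial `(alpha, beta, sigma)` state (default `c(0, 0, 1)`).
#' @return An object of class `posterior_draws`: `draws` (array
#'   iter x chains x parameters, sigma on its natural scale), `rhat`, `ess`,
#'   `accept`, plus the call settings.
#' @export
sample_posterior <- function(model, chains = 4L, iter = 1000L,
                             warmup = 1000L, seed = 1L,
                             sigma_fixed = NULL, init = c(0, 0, 1)) {
  .assert(inherits(model, "genus_model"), "model must be a genus_model")
  .assert(chains >= 1L && iter >= 1L && warmup >= 0L,
          "chains, iter must be >= 1 and warmup >= 0")
  fixed <- !is.null(sigma_fixed)
  if (fixed) {
    .assert(is.numeric(sigma_fixed) && sigma_fixed > 0,
            "sigma_fixed must be positive")
    d <- 2L
    lp <- function(th) {
      log_posterior(model, th[1], th[2], sigma_fixed)
    }
    init_s <- init[1:2]
    pars <- c("alpha", "beta")
  } else {
    d <- 3L
    lp <- function(th) {
      ls <- th[3]
      log_posterior(model, th[1], th[2], exp(ls)) + ls
    }
    init_s <- c(init[1], init[2], log(init[3]))
    pars <- c("alpha", "beta", "sigma")
  }
  draws <- array(NA_real_, dim = c(iter, chains, d),
                 dimnames = list(NULL, NULL, pars))
  accept <- numeric(chains)
  for (ch in seq_len(chains)) {
    res <- with_seed(derive_seed(seed, ch),
                     .amh_chain(lp, d, init_s, warmup, iter))
    x <- res$draws
    if (!fixed) x[, 3] <- exp(x[, 3])
    draws[, ch, ] <- x
    accept[ch] <- res$accept
  }
  rhat <- vapply(pars, function(p) {
    .split_rhat(matrix(draws[, , p], nrow = iter))
  }, numeric(1))
  ess <- vapply(pars, function(p) {
    sum(vapply(seq_len(chains), function(ch) .ess_one(draws[, ch, p]),
               numeric(1)))
  }, numeric(1))
  if (any(rhat > 1.01, na.rm = TRUE)) {
    warning(sprintf("split R-hat above 1.01 for: %s",
                    paste(pars[rhat > 1.01], collapse = ", ")))
  }
  structure(list(draws = draws, rhat = rhat, ess = ess, accept = accept,
                 chains = chains, iter = iter, warmup = warmup, seed = seed,
                 sigma_fixed = if (fixed) sigma_fixed else NULL,
                 genus = model$genus),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("<posterior_draws> %d chains x %d draws (warmup %d)\n",
              x$chains, x$iter, x$warmup))
  pars <- dimnames(x$draws)[[3]]
  for (p in pars) {
    v <- as.vector(x$draws[, , p])
    cat(sprintf("  %-5s mean %8.4f sd %7.4f  rhat %.3f  ess %.0f\n",
                p, mean(v), stats::sd(v), x$rhat[p], x$ess[p]))
  }
  invisible(x)
}

#' Extract pooled draws of one parameter
#'
#' @param draws A `posterior_draws` object.
#' @param parameter `"alpha"`, `"beta"` or `"sigma"`.
#' @return Numeric vector of all post-warmup draws across chains.
#' @export
posterior_vector <- function(draws, parameter = "beta") {
  .assert(inherits(draws, "posterior_draws"),
          "draws must be a posterior_draws object")
  .assert(parameter %in% dimnames(draws$draws)[[3]],
          "unknown parameter %s", parameter)
  as.vector(draws$draws[, , parameter])
}
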