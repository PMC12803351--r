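# The per-genus Bayesian model, sampler, summaries, and the second stage.

test_that("log posterior matches closed forms and an independent oracle", {
  # prior-only value with no data
  m0 <- sugar_genus_model(numeric(0), numeric(0))
  expect_equal(log_posterior(m0, 0, 0, 1),
               2 * (-0.5 * log(2 * pi)) - 1, tolerance = 1e-12)
  # single point y = 0 at x = 0 adds one standard-normal log density
  m1 <- sugar_genus_model(0, 0)
  expect_equal(log_posterior(m1, 0, 0, 1),
               log_posterior(m0, 0, 0, 1) + dnorm(0, log = TRUE),
               tolerance = 1e-12)
  # sigma <= 0 is rejected
  expect_equal(log_posterior(m1, 0, 0, -1), -Inf)
  expect_equal(log_posterior(m1, 0, 0, 0), -Inf)

  # random states against a directly coded density sum
  set.seed(61)
  for (i in 1:20) {
    n <- sample(2:30, 1)
    x <- rnorm(n); y <- rnorm(n)
    m <- sugar_genus_model(y, x)
    a <- rnorm(1); b <- rnorm(1); s <- rexp(1) + 0.05
    oracle <- sum(dnorm(y, a + b * x, s, log = TRUE)) +
      dnorm(a, log = TRUE) + dnorm(b, log = TRUE) + dexp(s, log = TRUE)
    expect_equal(log_posterior(m, a, b, s), oracle, tolerance = 1e-10)
  }
})

test_that("sampler is deterministic under seed and recovers the prior at n = 0", {
  m0 <- sugar_genus_model(numeric(0), numeric(0))
  d1 <- suppressWarnings(sample_posterior(m0, seed = 7))
  d2 <- suppressWarnings(sample_posterior(m0, seed = 7))
  expect_identical(d1$draws, d2$draws)
  d3 <- suppressWarnings(sample_posterior(m0, seed = 8))
  expect_false(identical(d1$draws, d3$draws))

  b <- posterior_vector(d1, "beta")
  s <- posterior_vector(d1, "sigma")
  mcse <- function(v, ess) sd(v) / sqrt(ess)
  expect_lt(abs(mean(b) - 0), 3 * mcse(b, d1$ess["beta"]))
  expect_lt(abs(sd(b) - 1), 0.15)
  expect_lt(abs(mean(s) - 1), 3 * mcse(s, d1$ess["sigma"]))
  expect_true(all(s > 0))
})

test_that("with sigma fixed the posterior matches the conjugate closed form", {
  for (i in 1:5) {
    d <- gen_genus_model_data(80, alpha = 0.2, beta = 0.6, sigma = 0.7,
                              seed = 70 + i)
    m <- sugar_genus_model(d$y, d$x)
    dr <- suppressWarnings(
      sample_posterior(m, seed = 70 + i, sigma_fixed = 0.7))
    X <- cbind(1, d$x)
    P <- diag(2) + crossprod(X) / 0.49
    mu <- solve(P, crossprod(X, d$y) / 0.49)
    a <- posterior_vector(dr, "alpha")
    b <- posterior_vector(dr, "beta")
    expect_lt(abs(mean(a) - mu[1]), 3 * sd(a) / sqrt(dr$ess["alpha"]))
    expect_lt(abs(mean(b) - mu[2]), 3 * sd(b) / sqrt(dr$ess["beta"]))
  }
})

test_that("HPD interval equals the brute-force shortest window", {
  set.seed(62)
  draws <- c(rnorm(700), rnorm(300, 4))   # bimodal-ish, sorted windows differ
  got <- hpd_interval(draws, 0.95)
  s <- sort(draws)
  n <- length(s)
  k <- ceiling(0.95 * n)
  best <- c(Inf, NA, NA)
  for (i in 1:(n - k + 1)) {
    w <- s[i + k - 1] - s[i]
    if (w < best[1]) best <- c(w, s[i], s[i + k - 1])
  }
  expect_equal(got, best[2:3])
  # mass guarantee by construction
  expect_gte(mean(draws >= got[1] & draws <= got[2]), 0.95 - 1 / n)
  # degenerate draws give a point interval that excludes zero
  sm <- summarize_posterior(structure(list(
    draws = array(2, c(100, 1, 3),
                  dimnames = list(NULL, NULL, c("alpha", "beta", "sigma"))),
    rhat = c(alpha = 1, beta = 1, sigma = 1),
    ess = c(alpha = 100, beta = 100, sigma = 100),
    genus = "g"), class = "posterior_draws"))
  expect_equal(c(sm$hpd95_lo, sm$hpd95_hi), c(2, 2))
  expect_true(sm$excludes_zero)
})

test_that("posterior summaries nest intervals and call zero exclusion", {
  d <- gen_genus_model_data(120, alpha = 0, beta = 0.8, sigma = 0.5,
                            seed = 81)
  m <- sugar_genus_model(d$y, d$x)
  dr <- suppressWarnings(sample_posterior(m, seed = 81))
  sm <- summarize_posterior(dr)
  expect_gte(sm$ci66_lo, sm$ci95_lo)
  expect_lte(sm$ci66_hi, sm$ci95_hi)
  expect_lte(sm$hpd95_hi - sm$hpd95_lo, sm$ci95_hi - sm$ci95_lo + 1e-12)
  expect_true(sm$excludes_zero)           # strong planted effect

  # symmetric draws around zero do not exclude zero
  sym <- suppressWarnings(
    sample_posterior(sugar_genus_model(numeric(0), numeric(0)), seed = 5))
  expect_false(summarize_posterior(sym)$excludes_zero)
})

test_that("fit_all_genera recovers planted signs and skips flat genera", {
  set.seed(63)
  n <- 300
  x <- rnorm(n)
  betas <- c(gNeg = -0.5, gNull = 0, gPos = 0.5)
  clr <- sapply(betas, function(b) b * scale(x)[, 1] + rnorm(n))
  rownames(clr) <- sprintf("s%03d", 1:n)
  clr <- cbind(clr, gFlat = 0)
  out <- suppressWarnings(fit_all_genera(clr, x, seed = 64, chains = 2,
                                         iter = 500, warmup = 500))
  expect_equal(attr(out, "skipped"), "gFlat")
  expect_equal(out$genus, names(betas))
  expect_lt(out$beta_mean[out$genus == "gNeg"], 0)
  expect_gt(out$beta_mean[out$genus == "gPos"], 0)
  expect_true(out$excludes_zero[out$genus == "gNeg"])
  expect_true(out$excludes_zero[out$genus == "gPos"])
  expect_false(out$excludes_zero[out$genus == "gNull"])

  # NA exposures are excluded before standardization
  x2 <- x; x2[1:10] <- NA
  out2 <- suppressWarnings(fit_all_genera(clr[, 1:3], x2, seed = 64,
                                          chains = 2, iter = 250,
                                          warmup = 250))
  expect_equal(attr(out2, "n_samples"), n - 10L)

  # empty input gives an empty table
  e <- fit_all_genera(matrix(numeric(0), nrow = n, ncol = 0), x, seed = 1)
  expect_equal(nrow(e), 0L)
})

test_that("trait regression recovers a planted linear relation", {
  pair <- gen_trait_beta_pair(n_genera = 40, trait_effect = 1, sigma = 0.02,
                              seed = 65)
  reg <- suppressWarnings(
    trait_regression(pair$betas$beta_mean, pair$census$mean_abc,
                     seed = 66, chains = 2, iter = 500, warmup = 500))
  expect_gt(reg$summary$beta_mean, 0)
  expect_gt(reg$summary$ci95_lo, 0)
  expect_gt(reg$spearman$rho, 0.9)
  # covariate normalization by the maximum
  expect_equal(sort(unique(round(suppressWarnings(
    trait_regression(c(0.1, 0.2, 0.4), c(10, 20, 40), seed = 1, chains = 1,
                     iter = 100, warmup = 100))$counts_norm, 10))),
    c(0.25, 0.5, 1))
  # refuses fewer than 3 genera
  expect_error(trait_regression(c(1, 2), c(1, 2)), "at least 3")
  expect_error(trait_regression(0.5, 1), "at least 3")
})

test_that("trait spearman delegates to the rank statistic with ties", {
  beta <- c(0.1, 0.3, 0.2, 0.5)
  cnt <- c(5, 10, 10, 20)
  res <- trait_spearman(beta, cnt)
  expect_equal(res$rho, cor(rank(cnt), rank(beta)), tolerance = 1e-12)
  expect_equal(trait_spearman(sort(beta), c(1, 2, 3, 4))$rho, 1)
  expect_equal(trait_spearman(rev(sort(beta)), c(1, 2, 3, 4))$rho, -1)
  # constant covariate flags undefined
  expect_true(trait_spearman(beta, rep(3, 4))$undefined)
})
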