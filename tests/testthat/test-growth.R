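# Growth-curve AUC, Spearman association, prevalence filter, mixed model.

test_that("curve AUC is the trapezoid and is additive over intervals", {
  expect_equal(curve_auc(c(0, 72), c(0.5, 0.5)), 36)
  expect_equal(curve_auc(c(0, 10), c(0, 1)), 5)
  # logistic curve: package value equals a directly coded trapezoid
  tt <- c(0, 18, 36, 54, 72)
  od <- 1 / (1 + exp(-0.15 * (tt - 30)))
  direct <- sum(diff(tt) * (od[-1] + od[-5]) / 2)
  expect_equal(curve_auc(tt, od), direct, tolerance = 1e-9)
  # additivity over contiguous intervals
  expect_equal(curve_auc(tt[1:3], od[1:3]) + curve_auc(tt[3:5], od[3:5]),
               curve_auc(tt, od), tolerance = 1e-12)
  # baseline subtraction
  expect_equal(curve_auc(c(0, 10), c(0.2, 0.2), baseline = TRUE), 0)
  expect_error(curve_auc(c(0, 0, 1), c(1, 1, 1)), "strictly increasing")
})

test_that("spearman_assoc matches the midrank Pearson oracle and cor.test", {
  x <- c(1, 2, 2, 4)
  y <- c(10, 20, 15, 40)
  res <- spearman_assoc(x, y)
  # independent oracle: Pearson correlation of midranks
  oracle <- cor(rank(x), rank(y))
  expect_equal(res$rho, oracle, tolerance = 1e-12)
  expect_equal(res$rho, unname(cor.test(x, y, method = "spearman",
                                        exact = FALSE)$estimate),
               tolerance = 1e-12)

  # perfect monotone cases
  z <- c(3, 1, 4, 1.5, 9)
  expect_equal(spearman_assoc(z, z)$rho, 1)
  expect_equal(spearman_assoc(z, -z)$rho, -1)
  expect_equal(spearman_assoc(z, -z)$p, spearman_assoc(z, z)$p)

  # invariance under strictly monotone transforms
  set.seed(31)
  a <- rnorm(15); b <- rnorm(15)
  expect_equal(spearman_assoc(exp(a), b)$rho, spearman_assoc(a, b)$rho,
               tolerance = 1e-12)
  expect_equal(spearman_assoc(a, b^3)$rho, spearman_assoc(a, b)$rho,
               tolerance = 1e-12)

  # t approximation for n > 9 agrees with the closed-form t CDF
  big <- spearman_assoc(a, b)
  tstat <- big$rho * sqrt((15 - 2) / (1 - big$rho^2))
  expect_equal(big$p, 2 * pt(-abs(tstat), 13), tolerance = 1e-12)
  expect_equal(big$method, "t approximation")

  # exact permutation p at small n agrees with cor.test's exact method
  x5 <- c(2, 5, 1, 4, 3); y5 <- c(1, 4, 2, 5, 3)
  expect_equal(spearman_assoc(x5, y5)$p,
               cor.test(x5, y5, method = "spearman", exact = TRUE)$p.value,
               tolerance = 1e-12)

  # constant input flags undefined
  flat <- spearman_assoc(rep(1, 5), y5)
  expect_true(flat$undefined)
  expect_true(is.na(flat$rho))
})

test_that("prevalence filter keeps genes strictly between 25% and 75%", {
  m <- sapply(c(a = 4, b = 8, c = 12, d = 20, e = 6), function(k) {
    rep(c(1, 0), c(k, 24 - k))
  })
  expect_setequal(prevalence_gene_filter(m), c("b", "c"))
  # boundary: exactly 25% is excluded
  m25 <- cbind(g = rep(c(1, 0), c(6, 18)))
  expect_length(prevalence_gene_filter(m25), 0L)
  m50 <- cbind(g = rep(c(1, 0), 12))
  expect_equal(prevalence_gene_filter(m50), "g")
})

test_that("LMM with no group variance reproduces OLS", {
  set.seed(41)
  n <- 60; g <- rep(1:6, each = 10)
  X <- data.frame(ABC = rbinom(n, 1, 0.5), PTS = rbinom(n, 1, 0.4))
  eps <- rnorm(n)
  eps <- eps - ave(eps, g)          # zero group means: sigma_u^2 = 0 regime
  y <- 1 + 0.8 * X$ABC - 0.3 * X$PTS + eps
  fit <- fit_random_intercept_lmm(y, X, g)
  ols <- coef(lm(y ~ ABC + PTS, data = X))
  expect_equal(fit$coefficients$estimate, unname(ols), tolerance = 1e-6)
  expect_equal(fit$sigma_u2, 0, tolerance = 1e-8)
})

test_that("balanced intercept-only LMM matches closed-form ANOVA ML", {
  set.seed(42)
  g <- rep(1:6, each = 5)
  y <- rnorm(30) + rep(rnorm(6, sd = 2), each = 5)
  fit <- fit_random_intercept_lmm(y, matrix(numeric(0), nrow = 30, ncol = 0),
                                  g)
  # closed-form ML for the balanced one-way random-effects model
  N <- 30; k <- 6; m <- 5
  ybar_g <- tapply(y, g, mean); ybar <- mean(y)
  SSW <- sum((y - rep(ybar_g, each = m))^2)
  SSB <- m * sum((ybar_g - ybar)^2)
  sigma_e2 <- SSW / (N - k)
  lambda <- SSB / k
  sigma_u2 <- max((lambda - sigma_e2) / m, 0)
  expect_equal(fit$sigma_e2, sigma_e2, tolerance = 1e-6)
  expect_equal(fit$sigma_u2, sigma_u2, tolerance = 1e-6)
  expect_equal(fit$coefficients$estimate, ybar, tolerance = 1e-8)
})

test_that("LMM agrees with lme4 maximum likelihood on an unbalanced design", {
  skip_if_not_installed("lme4")
  set.seed(43)
  n <- 90
  g <- sample(1:8, n, replace = TRUE)
  X <- data.frame(ABC = rbinom(n, 1, 0.5), RPI = rbinom(n, 1, 0.3))
  y <- 2 + X$ABC - 0.5 * X$RPI + rep(rnorm(8, sd = 0.8), length.out = 8)[g] +
    rnorm(n, sd = 0.6)
  fit <- fit_random_intercept_lmm(y, X, g)
  ref <- lme4::lmer(y ~ ABC + RPI + (1 | g), data = cbind(X, g = g, y = y),
                    REML = FALSE)
  expect_equal(fit$coefficients$estimate, unname(lme4::fixef(ref)),
               tolerance = 1e-4)
  vc <- as.data.frame(lme4::VarCorr(ref))
  expect_equal(fit$sigma_u2, vc$vcov[1], tolerance = 1e-3)
  expect_equal(fit$sigma_e2, vc$vcov[2], tolerance = 1e-3)
  expect_equal(fit$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-5)
})

test_that("LMM recovers simulated fixed effects and flags bad designs", {
  set.seed(44)
  beta <- c(2, 1, -0.5)
  hits <- 0L
  for (r in 1:100) {
    n <- 200
    g <- rep(1:10, each = 20)
    X <- data.frame(A = rbinom(n, 1, 0.5), B = rbinom(n, 1, 0.5))
    y <- beta[1] + beta[2] * X$A + beta[3] * X$B +
      rep(rnorm(10, sd = 0.7), each = 20) + rnorm(n, sd = 0.5)
    fit <- fit_random_intercept_lmm(y, X, g)
    co <- fit$coefficients
    ok <- all(abs(co$estimate - beta) <= 3 * co$se)
    hits <- hits + ok
  }
  expect_gte(hits, 95L)

  # constant predictors drop with a warning; duplicates are aliased errors
  X2 <- data.frame(A = rbinom(40, 1, 0.5), K = 1)
  expect_warning(fit_random_intercept_lmm(rnorm(40), X2, rep(1:4, 10)),
                 "constant predictor")
  X3 <- data.frame(A = rbinom(40, 1, 0.5))
  X3$B <- X3$A
  expect_error(suppressWarnings(
    fit_random_intercept_lmm(rnorm(40), X3, rep(1:4, 10))),
    "aliased")

  # profile optimum never falls below the theta = 0 (OLS) likelihood
  set.seed(45)
  A <- rbinom(40, 1, 0.5)
  yy <- rnorm(40) + rep(rnorm(4, sd = 1.5), each = 10)
  ff <- fit_random_intercept_lmm(yy, data.frame(A = A), rep(1:4, each = 10))
  expect_gte(ff$loglik, as.numeric(stats::logLik(lm(yy ~ A))) - 1e-8)
})

test_that("cfu_mixed_model applies the log10(CFU + 1) outcome scale", {
  set.seed(46)
  cfu <- 10^runif(40, 3, 8)
  X <- data.frame(ABC = rbinom(40, 1, 0.5))
  g <- rep(1:4, 10)
  fit_log <- cfu_mixed_model(cfu, X, g)
  fit_ref <- fit_random_intercept_lmm(log10(cfu + 1), X, g)
  expect_equal(fit_log$coefficients$estimate, fit_ref$coefficients$estimate)
  fit_raw <- cfu_mixed_model(cfu, X, g, scale = "raw")
  expect_false(isTRUE(all.equal(fit_raw$coefficients$estimate,
                                fit_log$coefficients$estimate)))
})
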