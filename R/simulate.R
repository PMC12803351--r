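# Synthetic-data generators: every pipeline input with known ground truth.

# Product templates that must match each transporter subtype rule, and decoy
# products that must never be counted: gate-term-missing, token-missing, and
# lowercase-"abc" traps.
.abc_templates <- c("sugar ABC transporter permease",
                    "sugar ABC transporter ATP-binding protein",
                    "ATP-binding cassette sugar transporter")
.pts_templates <- c("PTS sugar transporter subunit IIA",
                    "sugar transporter, phosphotransferase system IIB",
                    "PTS system sugar transporter subunit IIC")
.mfs_templates <- c("MFS sugar transporter",
                    "major facilitator superfamily sugar transporter")
.decoy_templates <- c(
  "glucose ABC transporter permease",        # gate term "sugar" missing
  "amino acid ABC transporter",              # gate term "sugar" missing
  "sugar porter family protein",             # gate term "transporter" missing
  "sugar-binding periplasmic protein",       # gate term "transporter" missing
  "sugar transporter",                       # gate passes, no subtype token
  "sugar transporter abcdef domain protein", # lowercase abc inside a word
  "MFS transporter",                         # gate term "sugar" missing
  "PTS system glucose-specific transporter", # gate term "sugar" missing
  "hypothetical protein",
  "DNA polymerase III subunit alpha",
  "phosphate ABC transporter ATP-binding protein",
  "drug efflux MFS transporter"
)

#' Generate annotation objects with planted transporter counts
#'
#' Per genome, emits exactly the planted number of products matching each
#' subtype rule plus decoy products that must not match (gate-term-missing,
#' token-missing, and lowercase-"abc" traps), so that
#' [census_transporters()] on the output equals the planted counts exactly.
#' Optionally plants glycolytic-enzyme products.
#'
#' @param plan Data frame with columns `genome_id`, `genus`, `abc`, `pts`,
#'   `mfs` (and optionally `species`, `phylum`). If `NULL`, a plan is drawn:
#'   `n_genera` genera with `genomes_per_genus` genomes each, per-genus mean
#'   counts drawn once and genome counts Poisson around them.
#' @param n_genera,genomes_per_genus Used only when `plan` is `NULL`.
#' @param n_decoys Decoy products per genome (default 20).
#' @param enzymes Optional character vector of enzyme symbols to plant in
#'   every genome (drawn from [default_enzyme_terms()]), or `NULL`.
#' @param seed Integer seed.
#' @return List with `annotations` (named list of [genome_annotation()]),
#'   `truth` (the plan data frame) and `seed`.
#' @export
gen_annotations <- function(plan = NULL, n_genera = 10L,
                            genomes_per_genus = 3L, n_decoys = 20L,
                            enzymes = NULL, seed = 1L) {
  if (is.null(plan)) {
    plan <- with_seed(derive_seed(seed, 101L), {
      genera <- sprintf("Genus%02d", seq_len(n_genera))
      lam_abc <- stats::runif(n_genera, 0, 25)
      lam_pts <- stats::runif(n_genera, 0, 15)
      lam_mfs <- stats::runif(n_genera, 0, 10)
      rows <- lapply(seq_len(n_genera), function(i) {
        data.frame(
          genome_id = sprintf("%s_g%02d", genera[i],
                              seq_len(genomes_per_genus)),
          genus = genera[i],
          abc = stats::rpois(genomes_per_genus, lam_abc[i]),
          pts = stats::rpois(genomes_per_genus, lam_pts[i]),
          mfs = stats::rpois(genomes_per_genus, lam_mfs[i]),
          stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    })
  }
  .assert(all(c("genome_id", "genus", "abc", "pts", "mfs") %in% names(plan)),
          "plan must have columns genome_id, genus, abc, pts, mfs")
  .assert(all(plan$abc >= 0 & plan$pts >= 0 & plan$mfs >= 0),
          "planted counts must be non-negative")
  enzyme_terms <- default_enzyme_terms()
  if (!is.null(enzymes)) {
    miss <- setdiff(enzymes, names(enzyme_terms))
    .assert(length(miss) == 0L, "unknown enzyme symbol(s): %s",
            paste(miss, collapse = ", "))
  }
  anns <- with_seed(derive_seed(seed, 102L), {
    lapply(seq_len(nrow(plan)), function(i) {
      rep_tmpl <- function(tmpl, k) {
        if (k == 0L) character() else
          tmpl[1L + (seq_len(k) - 1L) %% length(tmpl)]
      }
      products <- c(
        rep_tmpl(.abc_templates, plan$abc[i]),
        rep_tmpl(.pts_templates, plan$pts[i]),
        rep_tmpl(.mfs_templates, plan$mfs[i]),
        sample(.decoy_templates, n_decoys, replace = TRUE)
      )
      if (!is.null(enzymes)) {
        products <- c(products,
                      vapply(enzymes, function(e) enzyme_terms[[e]][1],
                             character(1)))
      }
      products <- sample(products)   # shuffle feature order
      feat <- data.frame(
        product = products,
        protein_id = sprintf("%s_p%05d", plan$genome_id[i],
                             seq_along(products)),
        stringsAsFactors = FALSE)
      genome_annotation(plan$genome_id[i], feat,
                        genus = plan$genus[i],
                        species = if ("species" %in% names(plan))
                          plan$species[i] else plan$genus[i],
                        phylum = if ("phylum" %in% names(plan))
                          plan$phylum[i] else NA_character_)
    })
  })
  names(anns) <- plan$genome_id
  list(annotations = anns, truth = plan, seed = seed)
}

#' Generate a qPCR Ct experiment with planted fold changes
#'
#' For chosen true fold changes F, emits reference/sample Ct record pairs
#' with `Ct_sample = Ct_ref - log2(F) + log2(w_sample / w_ref)` (plus
#' optional Gaussian Ct noise) so that the delta-Ct pipeline recovers F
#' exactly in the noise-free case. Strains named in `nd_strains` get `NA`
#' (not detected) sample Ct values.
#'
#' @param true_fc Named numeric vector of true fold changes per strain.
#' @param n_replicates Replicate pairs per strain (default 6).
#' @param ct_ref Reference-condition Ct (default 20 cycles).
#' @param noise_sd Gaussian noise sd in cycles added independently to each
#'   reference and sample Ct (default 0, exact round trip).
#' @param normalizer_kind `"volume"` or `"weight"`.
#' @param vary_weights Draw unequal normalizer values (the pipeline must
#'   correct for them)?
#' @param nd_strains Strains whose sample Ct is flagged ND.
#' @param condition Condition label for the table.
#' @param seed Integer seed.
#' @return List with `ct` (data frame in the [fold_change_table()] dialect,
#'   timepoints 0 and 72 h) and `truth` (strain, replicate, true
#'   fold change).
#' @export
gen_ct_experiment <- function(true_fc, n_replicates = 6L, ct_ref = 20,
                              noise_sd = 0,
                              normalizer_kind = c("volume", "weight"),
                              vary_weights = FALSE, nd_strains = character(),
                              condition = "GLU", seed = 1L) {
  normalizer_kind <- match.arg(normalizer_kind)
  .assert(is.numeric(true_fc) && all(true_fc > 0),
          "true fold changes must be positive")
  strains <- names(true_fc)
  if (is.null(strains)) strains <- sprintf("strain%02d", seq_along(true_fc))
  with_seed(derive_seed(seed, 201L), {
    rows <- list()
    truth <- list()
    for (s in seq_along(true_fc)) {
      for (r in seq_len(n_replicates)) {
        w_ref <- if (vary_weights) stats::runif(1, 0.05, 0.5) else 1
        w_smp <- if (vary_weights) stats::runif(1, 0.05, 0.5) else 1
        ct0 <- ct_ref + stats::rnorm(1, 0, noise_sd)
        ct1 <- ct_ref - log2(true_fc[s]) + log2(w_smp / w_ref) +
          stats::rnorm(1, 0, noise_sd)
        nd <- strains[s] %in% nd_strains
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_r%d_t0", strains[s], r),
          strain = strains[s], condition = condition, timepoint_h = 0,
          ct = ct0, normalizer_value = w_ref,
          normalizer_kind = normalizer_kind, replicate = r,
          stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_r%d_t72", strains[s], r),
          strain = strains[s], condition = condition, timepoint_h = 72,
          ct = if (nd) NA_real_ else ct1, normalizer_value = w_smp,
          normalizer_kind = normalizer_kind, replicate = r,
          stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <- data.frame(
          strain = strains[s], replicate = r, true_fold_change = true_fc[s],
          stringsAsFactors = FALSE)
      }
    }
    list(ct = do.call(rbind, rows), truth = do.call(rbind, truth))
  })
}

#' Generate data straight from the per-genus Bayesian model
#'
#' Draws `(alpha, beta, sigma)` from the model priors (unless supplied),
#' standardizes a Gaussian exposure, and simulates
#' `y = alpha + beta x + Normal(0, sigma)`. Used for calibration checks where
#' the fitted model must match the generating process exactly.
#'
#' @param n Sample size.
#' @param alpha,beta,sigma Optional fixed parameter values; `NULL` draws from
#'   the prior.
#' @param seed Integer seed.
#' @return List with `x`, `y`, and `truth` (alpha, beta, sigma).
#' @export
gen_genus_model_data <- function(n, alpha = NULL, beta = NULL, sigma = NULL,
                                 seed = 1L) {
  .assert(n >= 3L, "need n >= 3")
  with_seed(derive_seed(seed, 301L), {
    if (is.null(alpha)) alpha <- stats::rnorm(1)
    if (is.null(beta)) beta <- stats::rnorm(1)
    if (is.null(sigma)) sigma <- stats::rexp(1)
    x <- standardize(stats::rnorm(n))
    y <- alpha + beta * x + stats::rnorm(n, 0, sigma)
    list(x = x, y = y, truth = list(alpha = alpha, beta = beta,
                                    sigma = sigma))
  })
}

#' Generate a paired diet--abundance study with planted genus effects
#'
#' Emulates the structure of a longitudinal diet-microbiome cohort: meal
#' logs with 8-digit food codes and a nutrient lookup table, per-patient
#' daily sugar totals, microbiome samples whose exposure is the mean of the
#' two prior days, and an ASV count table whose genus-level CLR response to
#' standardized exposure follows `y_g = alpha_g + beta_g x + Normal(0,
#' sigma_noise)` with planted `beta_g`. Compositions are obtained by
#' inverse-CLR (softmax, overflow-guarded) with optional zero-inflation.
#'
#' Because the CLR centers each sample across genera, only effects relative
#' to the across-genus mean are identifiable; planted `true_beta` vectors
#' should therefore be (approximately) centered, as the default is.
#'
#' @param n_patients,n_samples,n_genera,n_days Study dimensions (defaults
#'   158 patients, 1009 samples, 91 genera, 40 study days, emulating the
#'   cohort scale).
#' @param true_beta Planted per-genus effects; default `rnorm(n_genera)`
#'   centered to mean zero.
#' @param alpha_g Per-genus intercepts; default `rnorm(n_genera)`.
#' @param sigma_noise Residual sd of the genus response (default 0.5).
#' @param zero_fraction Fraction of ASV counts zeroed before renormalization
#'   (default 0.05).
#' @param depth Sequencing depth per sample (default 1e5).
#' @param asvs_per_genus ASVs per genus (default 2) plus one unlabeled ASV.
#' @param seed Integer seed.
#' @return List with `meals`, `nutrients`, `samples` (sample_id, patient_id,
#'   sample_day), `counts` (samples x ASV matrix), `asv_genus` (labels, NA
#'   for the unlabeled ASV), `genera`, and `truth` (true_beta, alpha_g,
#'   exposure, x_std, clr_y).
#' @export
gen_diet_abundance <- function(n_patients = 158L, n_samples = 1009L,
                               n_genera = 91L, n_days = 40L,
                               true_beta = NULL, alpha_g = NULL,
                               sigma_noise = 0.5, zero_fraction = 0.05,
                               depth = 1e5, asvs_per_genus = 2L, seed = 1L) {
  .assert(sigma_noise > 0, "sigma_noise must be positive")
  .assert(zero_fraction >= 0 && zero_fraction < 1,
          "zero_fraction must lie in [0, 1)")
  with_seed(derive_seed(seed, 401L), {
    genera <- sprintf("Genus%03d", seq_len(n_genera))
    if (is.null(true_beta)) {
      true_beta <- stats::rnorm(n_genera)
      true_beta <- true_beta - mean(true_beta)
    }
    .assert(length(true_beta) == n_genera,
            "true_beta must have length n_genera")
    if (is.null(alpha_g)) alpha_g <- stats::rnorm(n_genera)

    # meal log: every patient eats 1-4 meals every study day
    codes <- sprintf("%08d", sample.int(99999999L, 40L))
    nutrients <- data.frame(food_code = codes,
                            sugar_g_per_100g = stats::runif(40L, 0, 60))
    meal_rows <- list()
    for (p in seq_len(n_patients)) {
      for (d in seq_len(n_days)) {
        k <- sample(1:4, 1)
        meal_rows[[length(meal_rows) + 1L]] <- data.frame(
          patient_id = sprintf("P%03d", p), day = d,
          food_code = sample(codes, k, replace = TRUE),
          grams = stats::runif(k, 20, 300),
          stringsAsFactors = FALSE)
      }
    }
    meals <- do.call(rbind, meal_rows)

    # the generator's own day sums and 2-day lagged exposures
    dens <- nutrients$sugar_g_per_100g[match(meals$food_code,
                                             nutrients$food_code)]
    sums <- tapply(meals$grams * dens / 100,
                   list(meals$patient_id, meals$day), sum)
    samples <- data.frame(
      sample_id = sprintf("S%04d", seq_len(n_samples)),
      patient_id = sprintf("P%03d", sample.int(n_patients, n_samples,
                                               replace = TRUE)),
      sample_day = sample(3:n_days, n_samples, replace = TRUE),
      stringsAsFactors = FALSE)
    exposure <- vapply(seq_len(n_samples), function(i) {
      mean(sums[samples$patient_id[i],
                as.character(samples$sample_day[i] - c(2L, 1L))])
    }, numeric(1))
    x_std <- standardize(exposure)

    # genus responses on the CLR scale, then inverse-CLR compositions
    clr_y <- vapply(seq_len(n_genera), function(g) {
      alpha_g[g] + true_beta[g] * x_std +
        stats::rnorm(n_samples, 0, sigma_noise)
    }, numeric(n_samples))
    colnames(clr_y) <- genera
    comp <- t(apply(clr_y, 1L, function(r) {
      e <- exp(r - max(r))
      e / sum(e)
    }))

    # split each genus across ASVs, add one unlabeled ASV, draw counts
    split_frac <- stats::runif(n_genera, 0.3, 0.7)
    asv_genus <- c(rep(genera, each = asvs_per_genus), NA_character_)
    n_asv <- length(asv_genus)
    counts <- matrix(0, n_samples, n_asv,
                     dimnames = list(samples$sample_id, sprintf(
                       "ASV%03d", seq_len(n_asv))))
    for (i in seq_len(n_samples)) {
      pr <- numeric(n_asv)
      for (g in seq_len(n_genera)) {
        j <- (g - 1L) * asvs_per_genus + 1L
        pr[j] <- comp[i, g] * split_frac[g]
        if (asvs_per_genus >= 2L) {
          pr[(j + 1L):(j + asvs_per_genus - 1L)] <-
            comp[i, g] * (1 - split_frac[g]) / (asvs_per_genus - 1L)
        }
      }
      pr[n_asv] <- 0.02                      # unlabeled ASV share
      pr <- pr / sum(pr)
      counts[i, ] <- stats::rmultinom(1, depth, pr)[, 1]
    }
    if (zero_fraction > 0) {
      drop_idx <- which(stats::runif(length(counts)) < zero_fraction)
      counts[drop_idx] <- 0
    }
    list(meals = meals, nutrients = nutrients, samples = samples,
         counts = counts, asv_genus = asv_genus, genera = genera,
         truth = list(true_beta = stats::setNames(true_beta, genera),
                      alpha_g = stats::setNames(alpha_g, genera),
                      exposure = stats::setNames(exposure,
                                                 samples$sample_id),
                      x_std = x_std, clr_y = clr_y))
  })
}

#' Generate a paired genus census / sugar-coefficient table
#'
#' Draws genus transporter counts from a Poisson distribution and plants
#' `beta_g = trait_effect * (count_g / max count) + Normal(0, sigma)`,
#' emitting both a genus census table and a coefficient table for testing
#' [trait_regression()] and [trait_spearman()].
#'
#' @param n_genera Number of genera (default 91).
#' @param trait_effect Slope linking the normalized count to the coefficient
#'   (default 1).
#' @param sigma Coefficient noise sd (default 0.05).
#' @param count_lambda Poisson mean of the transporter counts (default 20).
#' @param seed Integer seed.
#' @return List with `census` (genus, n_genomes_used, mean_abc, mean_pts,
#'   mean_mfs, mean_total), `betas` (genus, beta_mean) and `truth`.
#' @export
gen_trait_beta_pair <- function(n_genera = 91L, trait_effect = 1,
                                sigma = 0.05, count_lambda = 20, seed = 1L) {
  .assert(sigma > 0, "sigma must be positive")
  with_seed(derive_seed(seed, 501L), {
    genera <- sprintf("Genus%03d", seq_len(n_genera))
    counts <- stats::rpois(n_genera, count_lambda)
    if (max(counts) == 0) counts[1] <- 1L
    xn <- counts / max(counts)
    beta <- trait_effect * xn + stats::rnorm(n_genera, 0, sigma)
    census <- data.frame(genus = genera, n_genomes_used = 100L,
                         mean_abc = as.numeric(counts), mean_pts = 0,
                         mean_mfs = 0, mean_total = as.numeric(counts),
                         stringsAsFactors = FALSE)
    betas <- data.frame(genus = genera, beta_mean = beta,
                        stringsAsFactors = FALSE)
    list(census = census, betas = betas,
         truth = list(counts = counts, trait_effect = trait_effect,
                      sigma = sigma))
  })
}

#' Generate logistic growth curves with known AUC parameters
#'
#' OD600 follows `K / (1 + exp(-r (t - t0)))` sampled on a regular grid,
#' optionally with Gaussian noise. The ground truth records `(K, r, t0)` and
#' the closed-form integral of the logistic over the time span.
#'
#' @param n_curves Number of curves.
#' @param times Sampling times in hours (default every 30 min over 72 h).
#' @param noise_sd OD noise sd (default 0).
#' @param seed Integer seed.
#' @return List with `curves` (data frame strain, time_h, od600) and `truth`
#'   (strain, K, r, t0, auc_exact).
#' @export
gen_growth_curves <- function(n_curves = 5L, times = seq(0, 72, by = 0.5),
                              noise_sd = 0, seed = 1L) {
  with_seed(derive_seed(seed, 601L), {
    rows <- list()
    tr <- list()
    for (i in seq_len(n_curves)) {
      K <- stats::runif(1, 0.4, 1.5)
      r <- stats::runif(1, 0.1, 0.6)
      t0 <- stats::runif(1, 8, 30)
      od <- K / (1 + exp(-r * (times - t0)))
      if (noise_sd > 0) od <- pmax(od + stats::rnorm(length(od), 0,
                                                     noise_sd), 0)
      strain <- sprintf("strain%02d", i)
      rows[[i]] <- data.frame(strain = strain, time_h = times, od600 = od)
      auc_exact <- K / r * (log1p(exp(r * (max(times) - t0))) -
                              log1p(exp(r * (min(times) - t0))))
      tr[[i]] <- data.frame(strain = strain, K = K, r = r, t0 = t0,
                            auc_exact = auc_exact)
    }
    list(curves = do.call(rbind, rows), truth = do.call(rbind, tr))
  })
}
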