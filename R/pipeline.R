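# End-to-end synthetic study: simulate -> census -> clr -> fit -> associate.

#' Run the full pipeline on a synthetic study
#'
#' Generates a synthetic study in which per-genus sugar effects are planted
#' proportional to the genus mean sugar ABC transporter count (centered
#' across genera, since the CLR only identifies contrasts), then runs every
#' pipeline stage: annotation census and genus mean census, genus
#' aggregation, prevalence/abundance filtering, CLR transform, diet
#' aggregation and 2-day lagged exposure, per-genus Bayesian fits, and the
#' second-stage transporter-count regression with Spearman rank correlation
#' for each transporter type.
#'
#' @param seed Master seed for every source of randomness.
#' @param n_genera,n_samples,n_patients,n_days Study dimensions.
#' @param genomes_per_genus Genomes per genus for the annotation census.
#' @param trait_effect Planted slope linking the normalized ABC count to the
#'   genus sugar effect (default 1).
#' @param sigma_noise Residual sd of the genus CLR response (default 0.3).
#' @param zero_fraction ASV count zero-inflation (default 0.05).
#' @param chains,iter,warmup MCMC settings per genus model.
#' @param out_dir Optional directory; when given, census, summaries and
#'   association tables are written there as TSV.
#' @return List of class `sugartrait_pipeline`: `census`, `genus_census`,
#'   `summaries`, `trait` (per transporter type, each with `regression` and
#'   `spearman`), `truth`, `n_samples_fit`.
#' @export
run_sugar_pipeline <- function(seed = 1L, n_genera = 30L, n_samples = 200L,
                               n_patients = 25L, n_days = 30L,
                               genomes_per_genus = 3L, trait_effect = 1,
                               sigma_noise = 0.3, zero_fraction = 0.05,
                               chains = 2L, iter = 1000L, warmup = 500L,
                               out_dir = NULL) {
  # 1. genomes with genus-structured transporter counts
  ann <- gen_annotations(n_genera = n_genera,
                         genomes_per_genus = genomes_per_genus,
                         seed = derive_seed(seed, 1L))
  cen <- census_table(ann$annotations)
  gcen <- genus_mean_census(cen, cap = 100L, seed = derive_seed(seed, 2L))

  # 2. plant genus sugar effects proportional to the ABC census (centered)
  xn <- gcen$mean_abc / max(gcen$mean_abc)
  true_beta <- trait_effect * (xn - mean(xn))
  study <- gen_diet_abundance(
    n_patients = n_patients, n_samples = n_samples,
    n_genera = nrow(gcen), n_days = n_days,
    true_beta = true_beta, sigma_noise = sigma_noise,
    zero_fraction = zero_fraction, seed = derive_seed(seed, 3L))
  # align generated genus names with the census genera
  genus_map <- stats::setNames(gcen$genus, study$genera)

  # 3. compositional stage
  ab <- genus_aggregate(study$counts, study$asv_genus)
  keep <- genus_filter(ab)
  ab <- ab[, keep, drop = FALSE]
  clr <- clr_transform(ab)
  colnames(clr) <- unname(genus_map[colnames(clr)])

  # 4. diet stage
  totals <- daily_sugar_totals(study$meals, study$nutrients)
  expo <- lagged_exposure(totals, study$samples)
  expo <- expo[match(rownames(clr), expo$sample_id), , drop = FALSE]

  # 5. per-genus Bayesian fits
  summaries <- fit_all_genera(clr, expo, seed = derive_seed(seed, 4L),
                              chains = chains, iter = iter, warmup = warmup)

  # 6. second stage per transporter type
  merged <- merge(summaries, gcen, by = "genus")
  types <- c(ABC = "mean_abc", PTS = "mean_pts", MFS = "mean_mfs",
             total = "mean_total")
  trait <- list()
  for (k in seq_along(types)) {
    counts <- merged[[types[k]]]
    nm <- names(types)[k]
    sp <- trait_spearman(merged$beta_mean, counts, transporter_type = nm)
    reg <- if (max(counts) > 0) {
      trait_regression(merged$beta_mean, counts, transporter_type = nm,
                       seed = derive_seed(seed, 10L + k), chains = chains,
                       iter = iter, warmup = warmup)
    } else NULL
    trait[[nm]] <- list(regression = reg, spearman = sp)
  }

  out <- structure(
    list(census = cen, genus_census = gcen, summaries = summaries,
         trait = trait,
         truth = list(true_beta = stats::setNames(true_beta, gcen$genus),
                      trait_effect = trait_effect,
                      annotation_plan = ann$truth),
         n_samples_fit = attr(summaries, "n_samples")),
    class = "sugartrait_pipeline")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(x, f) utils::write.table(
      x, file.path(out_dir, f), sep = "\t", quote = FALSE,
      row.names = FALSE)
    wt(cen, "census.tsv")
    wt(gcen, "genus_census.tsv")
    wt(summaries, "genus_fits.tsv")
    assoc <- do.call(rbind, lapply(names(trait), function(nm) {
      s <- trait[[nm]]
      data.frame(transporter_type = nm,
                 spearman_rho = s$spearman$rho, spearman_p = s$spearman$p,
                 beta_mean = if (is.null(s$regression)) NA_real_ else
                   s$regression$summary$beta_mean,
                 ci95_lo = if (is.null(s$regression)) NA_real_ else
                   s$regression$summary$ci95_lo,
                 ci95_hi = if (is.null(s$regression)) NA_real_ else
                   s$regression$summary$ci95_hi)
    }))
    wt(assoc, "trait_associations.tsv")
  }
  out
}

#' @export
print.sugartrait_pipeline <- function(x, ...) {
  cat(sprintf(
    "Synthetic study: %d genera fitted on %d samples\n",
    nrow(x$summaries), x$n_samples_fit))
  cat(sprintf("HPD-excludes-zero genera: %d of %d\n",
              sum(x$summaries$excludes_zero), nrow(x$summaries)))
  for (nm in names(x$trait)) {
    s <- x$trait[[nm]]
    b <- if (is.null(s$regression)) NA_real_ else
      s$regression$summary$beta_mean
    cat(sprintf("  %-5s spearman rho %6.3f   regression beta %6.3f\n",
                nm, s$spearman$rho, b))
  }
  invisible(x)
}
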