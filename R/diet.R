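# Meal-level diet aggregation and lagged per-sample sugar exposure.

#' Daily sugar totals per patient
#'
#' Sums, per (patient, day), `grams * sugar_g_per_100g / 100` over all meals,
#' resolving each 8-digit food code in the nutrient table. Meals with
#' unresolvable food codes are skipped with a message; the skipped count is
#' attached as attribute `"n_unresolved"`. Days with no meals are absent from
#' the output.
#'
#' @param meals Data frame with columns `patient_id`, `day` (integer study
#'   day), `food_code`, `grams` (dry weight, >= 0).
#' @param nutrients Data frame with columns `food_code`,
#'   `sugar_g_per_100g` (>= 0).
#' @return Data frame `patient_id`, `day`, `sugar_g` (one row per
#'   patient-day with at least one resolvable meal).
#' @export
daily_sugar_totals <- function(meals, nutrients) {
  .assert(is.data.frame(meals) &&
            all(c("patient_id", "day", "food_code", "grams") %in% names(meals)),
          "meals must have columns patient_id, day, food_code, grams")
  .assert(is.data.frame(nutrients) &&
            all(c("food_code", "sugar_g_per_100g") %in% names(nutrients)),
          "nutrients must have columns food_code, sugar_g_per_100g")
  .assert(all(meals$grams >= 0), "grams must be non-negative")
  .assert(all(nutrients$sugar_g_per_100g >= 0),
          "sugar_g_per_100g must be non-negative")
  dens <- nutrients$sugar_g_per_100g[
    match(as.character(meals$food_code), as.character(nutrients$food_code))]
  unresolved <- is.na(dens)
  if (any(unresolved)) {
    message(sprintf("skipped %d meal(s) with unresolvable food codes",
                    sum(unresolved)))
  }
  ok <- meals[!unresolved, , drop = FALSE]
  sugar <- ok$grams * dens[!unresolved] / 100
  if (nrow(ok) == 0L) {
    out <- data.frame(patient_id = character(), day = integer(),
                      sugar_g = numeric())
  } else {
    agg <- stats::aggregate(sugar,
                            by = list(patient_id = ok$patient_id,
                                      day = ok$day),
                            FUN = sum)
    names(agg)[3] <- "sugar_g"
    out <- agg[order(agg$patient_id, agg$day), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "n_unresolved") <- sum(unresolved)
  out
}

#' Lagged sugar exposure for microbiome samples
#'
#' Attaches to each sample the mean of its patient's daily sugar totals over
#' the two days prior to collection (a sample on day d uses days d-2 and
#' d-1). By default the mean is taken over the prior days that have records
#' (`n_days_available` in 0..2, exposure `NA` when 0); with
#' `strict_two_days = TRUE` the exposure is defined only when both prior days
#' have records.
#'
#' @param day_totals Data frame from [daily_sugar_totals()].
#' @param samples Data frame with columns `patient_id`, `sample_day`
#'   (optionally `sample_id`).
#' @param strict_two_days Require both prior days?
#' @return `samples` with columns `sugar_exposure` and `n_days_available`
#'   appended.
#' @export
lagged_exposure <- function(day_totals, samples, strict_two_days = FALSE) {
  .assert(is.data.frame(samples) &&
            all(c("patient_id", "sample_day") %in% names(samples)),
          "samples must have columns patient_id, sample_day")
  key <- paste(day_totals$patient_id, day_totals$day, sep = "\r")
  lookup <- stats::setNames(day_totals$sugar_g, key)
  expo <- numeric(nrow(samples))
  avail <- integer(nrow(samples))
  for (i in seq_len(nrow(samples))) {
    days <- samples$sample_day[i] - c(2L, 1L)
    vals <- lookup[paste(samples$patient_id[i], days, sep = "\r")]
    vals <- vals[!is.na(vals)]
    avail[i] <- length(vals)
    expo[i] <- if (length(vals) == 0L) NA_real_ else mean(vals)
  }
  if (strict_two_days) expo[avail < 2L] <- NA_real_
  out <- samples
  out$sugar_exposure <- expo
  out$n_days_available <- avail
  out
}
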