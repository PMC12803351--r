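# qPCR delta-Ct fold changes and community growth calls.

#' Construct a qPCR Ct record
#'
#' @param sample_id Sample identifier.
#' @param strain Strain name.
#' @param ct Cycle-threshold value in (0, 40], or `NA` for "not detected"
#'   (ND).
#' @param normalizer_value Culture volume (mL) or fecal weight (g); must be
#'   positive.
#' @param normalizer_kind `"volume"` or `"weight"`.
#' @param condition,timepoint Optional labels (hours for `timepoint`).
#' @return A list of class `ct_record`.
#' @export
ct_record <- function(sample_id, strain, ct, normalizer_value,
                      normalizer_kind = c("volume", "weight"),
                      condition = NA_character_, timepoint = NA_real_) {
  normalizer_kind <- match.arg(normalizer_kind)
  if (!is.na(ct)) {
    .assert(is.numeric(ct) && ct > 0 && ct <= 40,
            "ct must lie in (0, 40] or be NA (not detected)")
  }
  .assert(is.numeric(normalizer_value) && normalizer_value > 0,
          "normalizer_value must be positive")
  structure(list(sample_id = sample_id, strain = strain,
                 condition = condition, timepoint = timepoint,
                 ct = ct, normalizer_value = normalizer_value,
                 normalizer_kind = normalizer_kind),
            class = "ct_record")
}

#' Fold change between two Ct records (delta-Ct method)
#'
#' Computes `delta_ct = (Ct_reference - Ct_sample) +
#' log2(normalizer_sample / normalizer_reference)` and
#' `fold_change = 2^delta_ct`. Lower Ct means more template, so a sample Ct
#' below the reference Ct gives a fold change above 1 (expansion). If either
#' Ct is ND (`NA`), the result is flagged `not_detected` and carries no
#' numeric fold change.
#'
#' @param reference [ct_record()] for the reference (e.g. t = 0) measurement.
#' @param sample [ct_record()] for the later/treated measurement.
#' @return A list of class `fold_change_result` with fields `strain`,
#'   `condition`, `delta_ct`, `fold_change`, `ct_reference`, `ct_sample`,
#'   `normalizer_reference`, `normalizer_sample`, `growth_call`.
#' @examples
#' r <- ct_record("s0", "Ec", 20, 1)
#' s <- ct_record("s1", "Ec", 18, 1)
#' fold_change_from_ct(r, s)$fold_change  # 4
#' @export
fold_change_from_ct <- function(reference, sample) {
  .assert(inherits(reference, "ct_record") && inherits(sample, "ct_record"),
          "both arguments must be ct_record objects")
  .assert(identical(reference$strain, sample$strain),
          "reference and sample must be the same strain")
  .assert(identical(reference$normalizer_kind, sample$normalizer_kind),
          "normalizer kinds differ (%s vs %s)",
          reference$normalizer_kind, sample$normalizer_kind)
  res <- list(strain = sample$strain, condition = sample$condition,
              ct_reference = reference$ct, ct_sample = sample$ct,
              normalizer_reference = reference$normalizer_value,
              normalizer_sample = sample$normalizer_value)
  if (is.na(reference$ct) || is.na(sample$ct)) {
    res$delta_ct <- NA_real_
    res$fold_change <- NA_real_
    res$growth_call <- "not_detected"
  } else {
    res$delta_ct <- (reference$ct - sample$ct) +
      log2(sample$normalizer_value / reference$normalizer_value)
    res$fold_change <- 2^res$delta_ct
    res$growth_call <- if (res$fold_change > 1) "expanded" else "not_expanded"
  }
  structure(res, class = "fold_change_result")
}

#' Classify community growth from a fold-change result
#'
#' A strain is called `expanded` iff its fold change over the horizon is
#' strictly greater than 1; not-detected results propagate.
#'
#' @param result A [fold_change_from_ct()] result.
#' @param horizon Hours between reference and sample (informational).
#' @return `"expanded"`, `"not_expanded"` or `"not_detected"`.
#' @export
classify_growth <- function(result, horizon = 72) {
  .assert(inherits(result, "fold_change_result"),
          "result must be a fold_change_result")
  if (is.na(result$fold_change)) return("not_detected")
  if (result$fold_change > 1) "expanded" else "not_expanded"
}

#' Fold changes for a Ct table
#'
#' Averages technical duplicates on the Ct scale per
#' (strain, condition, timepoint), then computes the delta-Ct fold change of
#' each strain/condition between `reference_time` and `horizon`. A group in
#' which any replicate is ND is treated as ND at that timepoint.
#'
#' @param ct Data frame with columns `sample_id`, `strain`, `condition`,
#'   `timepoint_h`, `ct`, `normalizer_value`, `normalizer_kind` (`ct` is `NA`
#'   for ND).
#' @param reference_time Reference timepoint in hours (default 0).
#' @param horizon Sample timepoint in hours (default 72).
#' @return Data frame with one row per (strain, condition): `delta_ct`,
#'   `fold_change`, `growth_call`.
#' @export
fold_change_table <- function(ct, reference_time = 0, horizon = 72) {
  need <- c("strain", "condition", "timepoint_h", "ct",
            "normalizer_value", "normalizer_kind")
  miss <- setdiff(need, names(ct))
  .assert(length(miss) == 0L, "ct table missing column(s): %s",
          paste(miss, collapse = ", "))
  agg <- function(sub) {
    if (anyNA(sub$ct)) return(list(ct = NA_real_,
                                   norm = sub$normalizer_value[1],
                                   kind = sub$normalizer_kind[1]))
    list(ct = mean(sub$ct), norm = mean(sub$normalizer_value),
         kind = sub$normalizer_kind[1])
  }
  keys <- unique(ct[, c("strain", "condition")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    st <- keys$strain[i]; cond <- keys$condition[i]
    sub <- ct[ct$strain == st & ct$condition == cond, , drop = FALSE]
    r0 <- sub[sub$timepoint_h == reference_time, , drop = FALSE]
    r1 <- sub[sub$timepoint_h == horizon, , drop = FALSE]
    .assert(nrow(r0) > 0L && nrow(r1) > 0L,
            "strain %s / condition %s lacks timepoint %g or %g",
            st, cond, reference_time, horizon)
    a0 <- agg(r0); a1 <- agg(r1)
    ref <- ct_record("ref", st, a0$ct, a0$norm, a0$kind, condition = cond,
                     timepoint = reference_time)
    smp <- ct_record("smp", st, a1$ct, a1$norm, a1$kind, condition = cond,
                     timepoint = horizon)
    fc <- fold_change_from_ct(ref, smp)
    data.frame(strain = st, condition = cond, delta_ct = fc$delta_ct,
               fold_change = fc$fold_change, growth_call = fc$growth_call,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-sample ratio t-test of fold changes against 1
#'
#' Two-tailed one-sample t-test of the log2 fold changes against mean 0
#' (equivalent to testing the geometric-mean ratio against 1).
#' Zero-variance input is handled by convention: if all log2 fold changes are
#' exactly 0 the statistic is 0 with p = 1; if they are constant and nonzero
#' the statistic is signed infinity with p = 0, flagged `degenerate`.
#'
#' @param fold_changes Numeric vector of positive fold changes, length >= 2.
#' @return List with `t`, `df`, `p`, `mean_log2`, `n`, `degenerate`.
#' @export
ratio_t_test <- function(fold_changes) {
  .assert(is.numeric(fold_changes) && length(fold_changes) >= 2L,
          "need at least 2 fold changes")
  .assert(all(is.finite(fold_changes)) && all(fold_changes > 0),
          "fold changes must be positive and finite")
  lg <- log2(fold_changes)
  n <- length(lg)
  m <- mean(lg)
  s <- stats::sd(lg)
  if (s == 0) {
    if (m == 0) {
      return(list(t = 0, df = n - 1L, p = 1, mean_log2 = 0, n = n,
                  degenerate = TRUE))
    }
    return(list(t = sign(m) * Inf, df = n - 1L, p = 0, mean_log2 = m, n = n,
                degenerate = TRUE))
  }
  tstat <- m / (s / sqrt(n))
  p <- 2 * stats::pt(-abs(tstat), df = n - 1L)
  list(t = tstat, df = n - 1L, p = p, mean_log2 = m, n = n,
       degenerate = FALSE)
}
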