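# Robustness machinery for the survival analysis: leave-one-out Cox refits,
# a permutation null for the Cox p-value, and the end-to-end cohort driver.

#' Leave-one-out Cox sensitivity analysis
#'
#' Refits the univariate Cox model n times, each time excluding one
#' patient, and collects the Wald p-value (and hazard ratio) of the
#' predictor from every reduced fit.
#'
#' @inheritParams cox_fit
#' @param predictor Numeric predictor vector.
#' @param ids Optional patient identifiers for labelling.
#' @return Object of class `loo_result`: `p_values` and `hrs` (one per
#'   left-out patient), `min_p`, `max_p`.
#' @export
leave_one_out <- function(time, event, predictor, ids = NULL,
                          tie_method = c("breslow", "efron")) {
  tie_method <- match.arg(tie_method)
  n <- length(time)
  if (n < 3L) stop("need at least 3 patients")
  if (is.null(ids)) ids <- paste0("obs", seq_len(n))
  ps <- hrs <- stats::setNames(numeric(n), ids)
  for (i in seq_len(n)) {
    fit <- tryCatch(
      cox_fit(time[-i], event[-i], predictor[-i], tie_method = tie_method),
      error = function(e) {
        stop("leave-one-out refit failed with patient ", ids[i],
             " excluded: ", conditionMessage(e))
      })
    ps[i] <- fit$p_value[1L]
    hrs[i] <- fit$hr[1L]
  }
  structure(list(p_values = ps, hrs = hrs, min_p = min(ps), max_p = max(ps)),
            class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf("Leave-one-out: %d refits, p in [%.4f, %.4f]\n",
              length(x$p_values), x$min_p, x$max_p))
  invisible(x)
}

#' Permutation null distribution for the Cox p-value
#'
#' Shuffles the predictor across patients `B` times with (time, event)
#' pairs fixed, refits the univariate Cox model per shuffle, and compares
#' the observed Wald p-value to the permuted ones. The empirical p-value
#' uses the add-one estimator
#' `(1 + #\{permuted p <= observed p\}) / (B + 1)`, which is never exactly
#' zero. A permutation whose fit fails to converge is redrawn and counted.
#'
#' @inheritParams leave_one_out
#' @param B Number of permutations (default 1000).
#' @param seed RNG seed, recorded in the output.
#' @return Object of class `permutation_null`: `observed_p`, `permuted_ps`,
#'   `empirical_p`, `B`, `seed`, `n_resampled`.
#' @export
permutation_null <- function(time, event, predictor, B = 1000L, seed = 1L,
                             tie_method = c("breslow", "efron")) {
  tie_method <- match.arg(tie_method)
  if (B < 1L) stop("B must be at least 1")
  obs <- cox_fit(time, event, predictor, tie_method = tie_method)$p_value[1L]
  set.seed(seed)
  perm_ps <- numeric(B)
  n_resampled <- 0L
  for (b in seq_len(B)) {
    repeat {
      xp <- sample(predictor)
      p <- tryCatch(
        cox_fit(time, event, xp, tie_method = tie_method)$p_value[1L],
        error = function(e) NA_real_)
      if (!is.na(p)) break
      n_resampled <- n_resampled + 1L
      if (n_resampled > 100L * B) stop("too many non-convergent permutations")
    }
    perm_ps[b] <- p
  }
  if (n_resampled > 0L) {
    message(n_resampled, " non-convergent permutation(s) were redrawn")
  }
  structure(
    list(observed_p = obs, permuted_ps = perm_ps,
         empirical_p = (1 + sum(perm_ps <= obs)) / (B + 1),
         B = as.integer(B), seed = as.integer(seed),
         n_resampled = n_resampled),
    class = "permutation_null"
  )
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf(
    "Permutation null (B = %d, seed = %d): observed p = %.4g, empirical p = %.4g\n",
    x$B, x$seed, x$observed_p, x$empirical_p))
  invisible(x)
}

#' Run the full cohort analysis
#'
#' Executes, on one patient table, every stage of the activity-to-survival
#' analysis: event count and median event time; the Kruskal-Wallis omnibus
#' and the three pairwise Mann-Whitney comparisons of global activity z
#' across NLGN3 tiers; the univariate Cox model of progression-free
#' survival on global z (Breslow ties); the same model excluding GBM
#' patients; the bivariate confounder models for every encodable covariate;
#' the median-split Kaplan-Meier curves; the leave-one-out refits; and the
#' permutation null.
#'
#' @param records Validated patient table (see [load_patient_table()]).
#' @param B Permutations for the null distribution.
#' @param seed Seed for the permutation analysis.
#' @param confounders Character vector of covariate encodings (columns of
#'   [encode_covariates()]) to use in bivariate models; `NULL` for the full
#'   set.
#' @return A list of results, one entry per analysis stage.
#' @export
cohort_analysis <- function(records, B = 1000L, seed = 7L,
                            confounders = NULL) {
  time <- records$time_weeks
  event <- records$event
  z <- records$oba_global_z

  res <- list()
  res$n <- nrow(records)
  res$n_events <- sum(event)
  res$median_pfs <- median_event_time(time, event)

  if (!is.null(records$nlgn3_tier)) {
    tiers <- records$nlgn3_tier
    by_tier <- split(z[tiers != "unavailable"],
                     tiers[tiers != "unavailable"])
    by_tier <- by_tier[c("low", "moderate", "high")]
    res$kruskal_wallis <- kruskal_wallis(by_tier)
    res$u_moderate_vs_low <- mann_whitney_u(by_tier$moderate, by_tier$low)
    res$u_high_vs_moderate <- mann_whitney_u(by_tier$high, by_tier$moderate)
    res$u_high_vs_low <- mann_whitney_u(by_tier$high, by_tier$low)
  }

  res$cox_global <- cox_fit(time, event, cbind(global_z = z),
                            tie_method = "breslow")
  non_gbm <- records$histology != "GBM"
  res$cox_global_no_gbm <- cox_fit(time[non_gbm], event[non_gbm],
                                   cbind(global_z = z[non_gbm]),
                                   tie_method = "breslow")

  enc <- encode_covariates(records)
  if (is.null(confounders)) {
    confounders <- setdiff(names(enc), "patient_id")
  }
  res$bivariate <- lapply(stats::setNames(confounders, confounders),
                          function(cv) {
    cox_fit_bivariate(time, event, z, enc[[cv]],
                      names = c("global_z", cv))
  })

  split_lab <- median_split(z)
  res$km <- lapply(split(seq_along(time), split_lab), function(idx) {
    km_estimate(time[idx], event[idx])
  })
  res$median_split_sizes <- table(split_lab)

  res$loo <- leave_one_out(time, event, z, ids = records$patient_id)
  res$permutation <- permutation_null(time, event, z, B = B, seed = seed)
  class(res) <- "cohort_analysis"
  res
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat(sprintf("Cohort analysis: n = %d, events = %d, median PFS %.0f weeks\n",
              x$n, x$n_events, x$median_pfs$median_weeks))
  if (!is.null(x$kruskal_wallis)) {
    cat("Global z by NLGN3 tier: "); print(x$kruskal_wallis)
  }
  cat("Cox (global z): "); print(x$cox_global)
  cat("Leave-one-out: "); print(x$loo)
  print(x$permutation)
  invisible(x)
}

#' Reference values for the packaged cohort
#'
#' The benchmark results originally reported for the packaged 24-patient
#' cohort, with the comparison tolerances used by [analysis_scorecard()].
#'
#' @return `data.frame` with columns `quantity`, `reference`, `tolerance`.
#' @export
benchmark_values <- function() {
  data.frame(
    quantity = c("n_events", "median_pfs_weeks", "kw_h_global",
                 "u_moderate_vs_low", "u_high_vs_moderate",
                 "p_high_vs_moderate", "hr_global", "hr_global_ci_low",
                 "hr_global_ci_high", "hr_global_no_gbm", "hr_biv_volume",
                 "hr_biv_age", "loo_min_p", "loo_max_p", "km_split_low",
                 "km_split_high"),
    reference = c(17, 87, 11.13, 2, 1, 0.048, 2.10, 1.22, 3.63, 2.12,
                  2.29, 2.33, 0.004, 0.036, 12, 12),
    tolerance = c(0, 0, 0.02, 0, 0, 0.002, 0.03, 0.03, 0.05, 0.03, 0.03,
                  0.03, 0.003, 0.003, 0, 0)
  )
}

#' Score a cohort analysis against reference values
#'
#' @param analysis Result of [cohort_analysis()].
#' @param reference A reference table as returned by [benchmark_values()].
#' @return `data.frame` with computed value, reference, tolerance and a
#'   pass flag per quantity.
#' @export
analysis_scorecard <- function(analysis, reference = benchmark_values()) {
  computed <- c(
    n_events = analysis$n_events,
    median_pfs_weeks = analysis$median_pfs$median_weeks,
    kw_h_global = analysis$kruskal_wallis$statistic,
    u_moderate_vs_low = analysis$u_moderate_vs_low$statistic,
    u_high_vs_moderate = analysis$u_high_vs_moderate$statistic,
    p_high_vs_moderate = analysis$u_high_vs_moderate$p_value,
    hr_global = analysis$cox_global$hr[[1]],
    hr_global_ci_low = analysis$cox_global$ci95[1, "lower"],
    hr_global_ci_high = analysis$cox_global$ci95[1, "upper"],
    hr_global_no_gbm = analysis$cox_global_no_gbm$hr[[1]],
    hr_biv_volume = analysis$bivariate$volume_cm3$hr[["global_z"]],
    hr_biv_age = analysis$bivariate$age_continuous$hr[["global_z"]],
    loo_min_p = analysis$loo$min_p,
    loo_max_p = analysis$loo$max_p,
    km_split_low = unname(analysis$median_split_sizes["low"]),
    km_split_high = unname(analysis$median_split_sizes["high"])
  )
  out <- reference
  out$computed <- unname(computed[out$quantity])
  out$pass <- abs(out$computed - out$reference) <= out$tolerance + 1e-9
  out[, c("quantity", "computed", "reference", "tolerance", "pass")]
}
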