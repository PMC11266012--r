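# Two-step mediation MR: exposure -> mediator (step 1) and mediator ->
# outcome (step 2), combined by the product of coefficients.

#' Two-step MR effect decomposition
#'
#' Given the total effect of the exposure on the outcome (`beta_all`), the
#' step-1 effect of the exposure on the mediator (`beta1`), and the step-2
#' effect of the mediator on the outcome (`beta2`), computes the mediated
#' (indirect) effect `beta12 = beta1 * beta2`, the direct effect
#' `beta_dir = beta_all - beta12`, and the proportion mediated
#' `beta_per = beta12 / beta_all`. All derived quantities are carried at
#' full precision; rounding happens only at serialization. When both step
#' SEs are supplied, the delta-method SE of the mediated effect,
#' `sqrt(beta1^2 se2^2 + beta2^2 se1^2)`, is included.
#'
#' @param beta_all Total exposure-on-outcome effect (IVW beta).
#' @param beta1 Step-1 exposure-on-mediator effect.
#' @param beta2 Step-2 mediator-on-outcome effect.
#' @param se1,se2 Optional step SEs for the delta-method `se12`.
#' @param exposure,mediator,outcome Optional trait labels.
#' @return An object of class `mediation_result` with fields `beta_all`,
#'   `beta1`, `beta2`, `beta12`, `beta_dir`, `beta_per` (`NA` with a flag
#'   when `beta_all = 0`), `se12`.
#' @export
two_step_mediation <- function(beta_all, beta1, beta2,
                               se1 = NULL, se2 = NULL,
                               exposure = NA_character_,
                               mediator = NA_character_,
                               outcome = NA_character_) {
  stopifnot(is.numeric(beta_all), is.numeric(beta1), is.numeric(beta2),
            length(beta_all) == 1L, length(beta1) == 1L, length(beta2) == 1L)
  beta12 <- beta1 * beta2
  beta_dir <- beta_all - beta12
  per_defined <- beta_all != 0
  beta_per <- if (per_defined) beta12 / beta_all else NA_real_
  se12 <- if (!is.null(se1) && !is.null(se2)) {
    sqrt(beta1^2 * se2^2 + beta2^2 * se1^2)
  } else NA_real_
  structure(
    list(exposure = exposure, mediator = mediator, outcome = outcome,
         beta_all = beta_all, beta1 = beta1, beta2 = beta2,
         beta12 = beta12, beta_dir = beta_dir, beta_per = beta_per,
         beta_per_defined = per_defined, se12 = se12),
    class = "mediation_result"
  )
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf(
    "<mediation_result> %s -> %s -> %s\n", x$exposure, x$mediator, x$outcome
  ))
  cat(sprintf(
    "  beta_all %.3f  beta1 %.3f  beta2 %.3f  beta12 %.3f  beta_dir %.3f  beta_per %s\n",
    x$beta_all, x$beta1, x$beta2, x$beta12, x$beta_dir,
    if (x$beta_per_defined) sprintf("%.3f", x$beta_per) else "undefined"
  ))
  invisible(x)
}

#' Serialize mediation results to a summary data frame
#'
#' One row per decomposition, with derived columns rounded to 3 decimals
#' for display (the objects themselves carry full precision).
#'
#' @param results A `mediation_result` or list of them.
#' @param digits Decimal places for display rounding (default 3).
#' @return A data frame with columns `exposure`, `mediator`, `outcome`,
#'   `beta_all`, `beta1`, `beta2`, `beta12`, `beta_dir`, `beta_per`.
#' @export
mediation_table <- function(results, digits = 3L) {
  if (inherits(results, "mediation_result")) results <- list(results)
  do.call(rbind, lapply(results, function(x) {
    data.frame(
      exposure = x$exposure, mediator = x$mediator, outcome = x$outcome,
      beta_all = round(x$beta_all, digits), beta1 = round(x$beta1, digits),
      beta2 = round(x$beta2, digits), beta12 = round(x$beta12, digits),
      beta_dir = round(x$beta_dir, digits),
      beta_per = round(x$beta_per, digits)
    )
  }))
}

#' Re-derive mediation decomposition columns from step estimates
#'
#' Given a data frame of published or computed `(beta_all, beta1, beta2)`
#' rows, recomputes `beta12`, `beta_dir`, and `beta_per` from the stated
#' formulas, carrying full precision and rounding only the emitted columns.
#'
#' @param df Data frame with columns `beta_all`, `beta1`, `beta2` and
#'   optionally `exposure`, `mediator`, `outcome`.
#' @param digits Decimal places for the derived columns (default 3).
#' @return `df` with derived columns `beta12`, `beta_dir`, `beta_per`
#'   replaced/added.
#' @export
rederive_mediation <- function(df, digits = 3L) {
  stopifnot(all(c("beta_all", "beta1", "beta2") %in% names(df)))
  beta12 <- df$beta1 * df$beta2
  df$beta12 <- round(beta12, digits)
  df$beta_dir <- round(df$beta_all - beta12, digits)
  df$beta_per <- round(ifelse(df$beta_all == 0, NA_real_,
                              beta12 / df$beta_all), digits)
  df
}

#' Run a full two-step mediation MR analysis
#'
#' Three univariable IVW analyses: exposure -> outcome (`beta_all`),
#' exposure -> mediator (`beta1`, step 1), and mediator -> outcome
#' (`beta2`, step 2). SNPs instrumenting the exposure in step 1 are deleted
#' from the mediator's instrument set before step 2, so the two steps use
#' disjoint instruments. A mediating effect is declared only when both step
#' IVW p-values are below 0.05; the decomposition itself is always
#' returned.
#'
#' @param exposure_table,mediator_table,outcome_table [sumstat_table()]s.
#' @param ladder,min_snps,ld,window_bp,r2_max Instrument selection settings
#'   (see [select_instruments()]).
#' @param palindrome_eaf_window Passed to [harmonize()].
#' @param effects_model Passed to [mr_ivw()].
#' @return A list: `decomposition` (a `mediation_result`),
#'   `mediation_declared`, `p_step1`, `p_step2`, and the three IVW fits
#'   (`fit_all`, `fit_step1`, `fit_step2`) plus `step2_excluded` (ids
#'   removed from step 2).
#' @export
run_mediation <- function(exposure_table, mediator_table, outcome_table,
                          ladder = c(5e-8, 5e-6, 5e-5), min_snps = 3L,
                          ld = NULL, window_bp = 1e7, r2_max = 0.001,
                          palindrome_eaf_window = 0.08,
                          effects_model = "multiplicative_random") {
  exp_iv <- select_instruments(exposure_table, ladder, min_snps, ld,
                               window_bp, r2_max)
  med_iv <- select_instruments(mediator_table, ladder, min_snps, ld,
                               window_bp, r2_max)

  h_all <- harmonize(exp_iv, outcome_table, palindrome_eaf_window)
  h_step1 <- harmonize(exp_iv, mediator_table, palindrome_eaf_window)
  h_step2 <- harmonize(med_iv, outcome_table, palindrome_eaf_window)
  shared <- intersect(h_step2$records$snp_id, exp_iv$records$snp_id)
  h_step2 <- exclude_snps(h_step2, shared, reason = "shared_with_step1")
  if (nrow(h_step2$records) == 0L) {
    stop("no step-2 instruments remain after removing SNPs shared with step 1")
  }

  fit_all <- mr_ivw(h_all, effects_model)
  fit_step1 <- mr_ivw(h_step1, effects_model)
  fit_step2 <- mr_ivw(h_step2, effects_model)

  dec <- two_step_mediation(
    fit_all$beta, fit_step1$beta, fit_step2$beta,
    se1 = fit_step1$se, se2 = fit_step2$se,
    exposure = exposure_table$trait_name,
    mediator = mediator_table$trait_name,
    outcome = outcome_table$trait_name
  )
  list(
    decomposition = dec,
    mediation_declared = fit_step1$pval < 0.05 && fit_step2$pval < 0.05,
    p_step1 = fit_step1$pval, p_step2 = fit_step2$pval,
    fit_all = fit_all, fit_step1 = fit_step1, fit_step2 = fit_step2,
    step2_excluded = shared
  )
}
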