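# Orchestration of a full summary-statistic MR study: forward and reverse
# screens across many exposure-outcome pairs, MVMR groups, and two-step
# mediation chains, with tabular reports and a reproducibility manifest.

#' Screen exposure-outcome pairs with the five-method MR panel
#'
#' For each exposure paired with the outcome: select and clump instruments,
#' harmonize, run the five univariable estimators, compute Cochran's Q (IVW
#' and Egger) and the Egger intercept test, classify the IVW result as
#' risk/protective/null, and run leave-one-out when the IVW p-value falls in
#' (0.04, 0.05). `direction = "reverse"` swaps roles: the outcome trait
#' becomes the exposure of every pair and a relaxed selection ladder applies
#' (with optional per-trait ladder overrides, e.g. a single trait needing
#' the most lenient threshold). Heterogeneity is reported but never used to
#' drop an analysis. Pairs that fail hard (e.g. no usable instruments) are
#' skipped and logged, not fatal to the batch.
#'
#' No multiple-testing correction is applied across exposures —
#' classification uses the raw IVW p-value — but an FDR-adjusted column
#' (`pval_fdr`, Benjamini-Hochberg across the screened pairs) is emitted in
#' the classification table for reference; it never gates classification.
#'
#' @param exposures Named list of [sumstat_table()]s.
#' @param outcome A [sumstat_table()].
#' @param direction `"forward"` (exposures -> outcome) or `"reverse"`
#'   (outcome -> each listed trait).
#' @param ladder P-value relaxation ladder for instrument selection.
#' @param ladder_overrides Optional named list mapping a trait name to its
#'   own ladder (used in reverse mode for traits needing extra relaxation).
#' @param min_snps,ld,window_bp,r2_max Instrument selection settings.
#' @param palindrome_eaf_window Passed to [harmonize()].
#' @param n_boot,seed Bootstrap settings for the median/mode estimators.
#' @return A list: `results` (per-pair, per-method data frame),
#'   `classification` (one row per pair: label, loo trigger, Q and
#'   intercept diagnostics, FDR column), `loo` (named list of leave-one-out
#'   tables for triggered pairs), `skipped` (data frame of skipped pairs
#'   with reasons).
#' @export
run_screen <- function(exposures, outcome,
                       direction = c("forward", "reverse"),
                       ladder = c(5e-8, 5e-6, 5e-5),
                       ladder_overrides = list(),
                       min_snps = 3L, ld = NULL, window_bp = 1e7,
                       r2_max = 0.001, palindrome_eaf_window = 0.08,
                       n_boot = 1000L, seed = 1L) {
  direction <- match.arg(direction)
  stopifnot(length(exposures) >= 1L, !is.null(names(exposures)),
            inherits(outcome, "sumstat_table"))
  res_rows <- list()
  cls_rows <- list()
  loo_list <- list()
  skipped <- list()
  for (nm in names(exposures)) {
    pair <- if (direction == "forward") {
      list(exp = exposures[[nm]], out = outcome)
    } else {
      list(exp = outcome, out = exposures[[nm]])
    }
    pair_ladder <- if (nm %in% names(ladder_overrides)) {
      ladder_overrides[[nm]]
    } else ladder
    step <- tryCatch({
      iv <- select_instruments(pair$exp, pair_ladder, min_snps, ld,
                               window_bp, r2_max)
      h <- harmonize(iv, pair$out, palindrome_eaf_window)
      if (nrow(h$records) == 0L) stop("no instruments survive harmonization")
      panel <- run_all_methods(h, seed = seed, n_boot = n_boot)
      ivw <- panel$results$ivw
      if (is.null(ivw)) stop("fewer than 2 usable instruments")
      cls <- classify_effect(ivw)
      q_ivw <- cochran_q(h, "ivw")
      q_egger <- if (nrow(h$records) >= 3L) cochran_q(h, "egger") else NULL
      itest <- if (nrow(h$records) >= 3L) egger_intercept_test(h) else NULL
      loo <- if (cls$loo_required) leave_one_out(h) else NULL
      list(h = h, panel = panel, cls = cls, q_ivw = q_ivw,
           q_egger = q_egger, itest = itest, loo = loo,
           threshold = iv$threshold_used)
    }, error = function(e) e)
    if (inherits(step, "error")) {
      skipped[[nm]] <- data.frame(pair = nm,
                                  reason = conditionMessage(step))
      next
    }
    exp_name <- step$h$exposure_name
    out_name <- step$h$outcome_name
    res_rows[[nm]] <- mr_result_table(step$panel$results, exp_name, out_name)
    cls_rows[[nm]] <- data.frame(
      exposure = exp_name, outcome = out_name,
      nsnp = nrow(step$h$records), threshold_used = step$threshold,
      beta = step$cls$basis$beta, or = step$cls$basis$or_,
      ci_low = step$cls$basis$ci_low, ci_high = step$cls$basis$ci_high,
      pval = step$cls$basis$pval, label = step$cls$label,
      loo_required = step$cls$loo_required,
      direction_consistent = step$panel$direction_consistent,
      q_ivw = step$q_ivw$Q, q_ivw_pval = step$q_ivw$pval,
      q_egger = if (is.null(step$q_egger)) NA else step$q_egger$Q,
      q_egger_pval = if (is.null(step$q_egger)) NA else step$q_egger$pval,
      egger_intercept = if (is.null(step$itest)) NA else step$itest$intercept,
      egger_intercept_pval = if (is.null(step$itest)) NA else step$itest$pval
    )
    if (!is.null(step$loo)) loo_list[[nm]] <- step$loo
  }
  classification <- do.call(rbind, cls_rows)
  if (!is.null(classification)) {
    classification$pval_fdr <- stats::p.adjust(classification$pval, "BH")
    rownames(classification) <- NULL
  }
  list(
    results = {
      r <- do.call(rbind, res_rows)
      if (!is.null(r)) rownames(r) <- NULL
      r
    },
    classification = classification,
    loo = loo_list,
    skipped = {
      s <- do.call(rbind, skipped)
      if (!is.null(s)) rownames(s) <- NULL
      s
    }
  )
}

#' Run a complete bidirectional MR study with MVMR and mediation
#'
#' Executes, in order: the forward screen (every exposure against the
#' outcome), the reverse screen (outcome against every exposure, relaxed
#' ladder), multivariable MR for each configured exposure group, and
#' two-step mediation for each configured (exposure, mediator) pair. A
#' mediation row enters the summary only when both step IVW p-values are
#' below 0.05 (the two-step gate); gated-out chains are listed with
#' reasons. When `out_dir` is given, every table is written as TSV along
#' with a plain-text manifest (package version, seed, settings) from which
#' each number is recomputable.
#'
#' @param exposures Named list of exposure [sumstat_table()]s.
#' @param outcome The outcome [sumstat_table()].
#' @param mvmr_groups Named list; each element a character vector of
#'   exposure names forming one MVMR group.
#' @param mediation_pairs List of `c(exposure, mediator)` name pairs.
#' @param reverse_ladder Relaxed ladder for the reverse screen (default
#'   starts at 5e-6).
#' @param reverse_ladder_overrides Per-trait reverse ladder overrides.
#' @param ladder,min_snps,ld,window_bp,r2_max,palindrome_eaf_window,n_boot,seed
#'   As [run_screen()].
#' @param out_dir Optional output directory for TSV reports.
#' @return A list: `forward`, `reverse` (screen results), `mvmr` (named
#'   list of `mvmr_result`), `mediation` (summary data frame),
#'   `mediation_detail` (full results per chain), `mediation_skipped`,
#'   `manifest`.
#' @export
run_full_study <- function(exposures, outcome, mvmr_groups = list(),
                           mediation_pairs = list(),
                           ladder = c(5e-8, 5e-6, 5e-5),
                           reverse_ladder = c(5e-6, 5e-5),
                           reverse_ladder_overrides = list(),
                           min_snps = 3L, ld = NULL, window_bp = 1e7,
                           r2_max = 0.001, palindrome_eaf_window = 0.08,
                           n_boot = 1000L, seed = 1L, out_dir = NULL) {
  forward <- run_screen(exposures, outcome, "forward", ladder,
                        list(), min_snps, ld, window_bp, r2_max,
                        palindrome_eaf_window, n_boot, seed)
  reverse <- run_screen(exposures, outcome, "reverse", reverse_ladder,
                        reverse_ladder_overrides, min_snps, ld, window_bp,
                        r2_max, palindrome_eaf_window, n_boot, seed + 1L)

  mvmr <- list()
  for (gname in names(mvmr_groups)) {
    members <- mvmr_groups[[gname]]
    sets <- lapply(members, function(m) {
      select_instruments(exposures[[m]], ladder, min_snps, ld, window_bp,
                         r2_max)
    })
    mvmr[[gname]] <- tryCatch({
      inp <- build_mvmr_input(sets, exposures[members], outcome, ld,
                              window_bp, r2_max, palindrome_eaf_window)
      mvmr_ivw(inp)
    }, error = function(e) e)
  }

  med_results <- list()
  med_skipped <- list()
  for (pair in mediation_pairs) {
    key <- paste(pair, collapse = " -> ")
    run <- tryCatch(
      run_mediation(exposures[[pair[1]]], exposures[[pair[2]]], outcome,
                    ladder, min_snps, ld, window_bp, r2_max,
                    palindrome_eaf_window),
      error = function(e) e
    )
    if (inherits(run, "error")) {
      med_skipped[[key]] <- data.frame(chain = key, reason = conditionMessage(run))
    } else if (!run$mediation_declared) {
      med_skipped[[key]] <- data.frame(chain = key, reason = sprintf(
        "two-step gate not met (p1 = %.3g, p2 = %.3g)",
        run$p_step1, run$p_step2
      ))
    } else {
      med_results[[key]] <- run
    }
  }
  mediation <- if (length(med_results)) {
    mediation_table(lapply(med_results, `[[`, "decomposition"))
  } else NULL

  manifest <- c(
    sprintf("package: mrtwosample %s",
            as.character(utils::packageVersion("mrtwosample"))),
    sprintf("seed: %d", seed),
    sprintf("ladder: %s", paste(ladder, collapse = ", ")),
    sprintf("reverse_ladder: %s", paste(reverse_ladder, collapse = ", ")),
    sprintf("clump: window %g bp, r2 <= %g", window_bp, r2_max),
    sprintf("palindrome_eaf_window: %g", palindrome_eaf_window),
    sprintf("n_boot: %d", n_boot),
    sprintf("exposures: %s", paste(names(exposures), collapse = ", ")),
    sprintf("outcome: %s", outcome$trait_name)
  )

  out <- list(forward = forward, reverse = reverse, mvmr = mvmr,
              mediation = mediation, mediation_detail = med_results,
              mediation_skipped = do.call(rbind, med_skipped),
              manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(df, f) {
      if (!is.null(df)) {
        utils::write.table(df, file.path(out_dir, f), sep = "\t",
                           quote = FALSE, row.names = FALSE)
      }
    }
    wt(forward$results, "forward_results.tsv")
    wt(forward$classification, "forward_classification.tsv")
    wt(reverse$results, "reverse_results.tsv")
    wt(reverse$classification, "reverse_classification.tsv")
    for (gname in names(mvmr)) {
      if (!inherits(mvmr[[gname]], "error")) {
        wt(mvmr[[gname]]$estimates,
           sprintf("mvmr_%s.tsv", gsub("[^A-Za-z0-9]+", "_", gname)))
      }
    }
    wt(out$mediation, "mediation_summary.tsv")
    writeLines(manifest, file.path(out_dir, "manifest.txt"))
  }
  out
}

#' Published two-step mediation estimates for obesity, lipids, and NSOM
#'
#' The reported IVW step estimates from a published two-step MR mediation
#' analysis of obesity/adiposity exposures, lipid mediators (HDL
#' cholesterol and apolipoprotein A1), and non-suppurative otitis media
#' (NSOM) as outcome: per chain, the total effect `beta_all`, the step-1
#' exposure-on-mediator effect `beta1`, and the step-2 mediator-on-outcome
#' effect `beta2`, all on the log-OR scale. Feed these rows to
#' [rederive_mediation()] to recompute the mediated effect, direct effect,
#' and proportion mediated from the stated formulas.
#'
#' @return A data frame with columns `exposure`, `mediator`, `outcome`,
#'   `beta_all`, `beta1`, `beta2`.
#' @export
nsom_mediation_estimates <- function() {
  path <- system.file("extdata", "nsom_mediation_estimates.tsv",
                      package = "mrtwosample", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
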