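# Multivariable MR: joint weighted regression of outcome effects on several
# exposures' effects, estimating each exposure's direct effect conditional
# on the others.

#' Assemble a multivariable MR input
#'
#' Takes the union of the per-exposure instruments, jointly clumps it (the
#' clumping priority of each SNP is its smallest p-value across exposures,
#' mirroring strongest-association practice), looks every surviving SNP up
#' in every exposure table and the outcome table, and aligns all studies to
#' the first exposure's effect allele per SNP. SNPs missing from any table,
#' or with irreconcilable or ambiguous-palindromic alleles in any table, are
#' dropped and audited.
#'
#' @param instrument_sets List of `instrument_set` objects, one per
#'   exposure (length m >= 2).
#' @param exposure_tables List of [sumstat_table()]s in the same order.
#' @param outcome_table The outcome [sumstat_table()].
#' @param ld,window_bp,r2_max Passed to [ld_clump()] for the joint clump.
#' @param palindrome_eaf_window Passed to the per-table alignment.
#' @return An object of class `mvmr_input`: `exposure_names`, `beta_exp`
#'   and `se_exp` (k x m matrices), `beta_out`, `se_out`, `snp_ids`, and a
#'   `dropped` audit data frame.
#' @export
build_mvmr_input <- function(instrument_sets, exposure_tables, outcome_table,
                             ld = NULL, window_bp = 1e7, r2_max = 0.001,
                             palindrome_eaf_window = 0.08) {
  m <- length(instrument_sets)
  stopifnot(m >= 2L, length(exposure_tables) == m,
            inherits(outcome_table, "sumstat_table"))
  names <- vapply(instrument_sets, function(s) s$exposure_name, character(1))

  # union of instruments, keyed by snp_id, priority = min p across exposures
  union_rec <- do.call(rbind, lapply(instrument_sets, function(s) s$records))
  ord <- order(union_rec$pval)
  union_rec <- union_rec[ord, , drop = FALSE]
  union_rec <- union_rec[!duplicated(union_rec$snp_id), , drop = FALSE]
  clumped <- ld_clump(union_rec, ld = ld, window_bp = window_bp,
                      r2_max = r2_max, exposure_name = "mvmr_union")

  snps <- clumped$records$snp_id
  ref <- clumped$records  # defines the reference effect allele per SNP
  tables <- c(exposure_tables, list(outcome_table))
  k0 <- length(snps)
  aligned <- matrix(NA_real_, k0, length(tables))
  ses <- matrix(NA_real_, k0, length(tables))
  drop_reason <- character(k0)

  ref_tab <- sumstat_table("mvmr_reference", ref)
  for (t in seq_along(tables)) {
    hs <- harmonize(ref_tab, tables[[t]],
                    palindrome_eaf_window = palindrome_eaf_window)
    idx <- match(snps, hs$records$snp_id)
    aligned[, t] <- hs$records$beta_out[idx]
    ses[, t] <- hs$records$se_out[idx]
    miss <- is.na(idx) & !nzchar(drop_reason)
    drop_reason[miss] <- sprintf("unusable_in:%s", tables[[t]]$trait_name)
  }
  keep <- !nzchar(drop_reason)
  if (sum(keep) <= m) {
    stop(sprintf(
      "only %d usable SNPs for %d exposures; need k > m", sum(keep), m
    ))
  }
  dropped <- data.frame(snp_id = snps[!keep], reason = drop_reason[!keep])
  structure(
    list(
      exposure_names = names,
      beta_exp = matrix(aligned[keep, seq_len(m)], ncol = m,
                        dimnames = list(NULL, names)),
      se_exp = matrix(ses[keep, seq_len(m)], ncol = m,
                      dimnames = list(NULL, names)),
      beta_out = aligned[keep, m + 1L],
      se_out = ses[keep, m + 1L],
      snp_ids = snps[keep],
      dropped = dropped
    ),
    class = "mvmr_input"
  )
}

#' Multivariable IVW estimator
#'
#' Weighted multiple regression of the outcome effects on the m exposure
#' effect columns, without intercept, with weights 1/se_out^2. Each
#' coefficient is the direct effect of that exposure conditional on the
#' others. Coefficient SEs are inflated by `max(1, sqrt(Q_mv / (k - m)))`
#' where Q_mv is the weighted residual sum of squares; p-values use
#' t(k - m). A rank-deficient exposure matrix (collinear exposures) is a
#' hard error naming the offending columns.
#'
#' @param input An `mvmr_input`, or a list with fields `exposure_names`,
#'   `beta_exp`, `se_exp`, `beta_out`, `se_out`.
#' @return An object of class `mvmr_result`: data frame `estimates` with
#'   one row per exposure (`exposure`, `nsnp`, `beta`, `se`, `pval`, `or`,
#'   `ci_low`, `ci_high`) plus fields `Q`, `df`.
#' @export
mvmr_ivw <- function(input) {
  X <- as.matrix(input$beta_exp)
  y <- input$beta_out
  sy <- input$se_out
  m <- ncol(X)
  k <- nrow(X)
  stopifnot(k > m, length(y) == k, length(sy) == k)
  qrX <- qr(X)
  if (qrX$rank < m) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1L):m]]
    stop("collinear exposures in MVMR input: ",
         paste(dep, collapse = ", "))
  }
  w <- 1 / sy^2
  fit <- stats::lm.wfit(X, y, w)
  beta <- fit$coefficients
  XtWX_inv <- chol2inv(chol(crossprod(X * sqrt(w))))
  Q <- sum(w * fit$residuals^2)
  df <- k - m
  scale <- max(1, sqrt(Q / df))
  se <- sqrt(diag(XtWX_inv)) * scale
  pval <- 2 * stats::pt(-abs(beta / se), df)
  est <- data.frame(
    exposure = input$exposure_names, nsnp = k, beta = unname(beta),
    se = unname(se), pval = unname(pval), or = exp(unname(beta)),
    ci_low = exp(unname(beta - 1.96 * se)),
    ci_high = exp(unname(beta + 1.96 * se))
  )
  structure(list(estimates = est, Q = Q, df = df), class = "mvmr_result")
}

#' @export
print.mvmr_result <- function(x, ...) {
  cat(sprintf("<mvmr_result> %d exposures, k = %d instruments\n",
              nrow(x$estimates), x$estimates$nsnp[1]))
  print(x$estimates, digits = 4)
  invisible(x)
}
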