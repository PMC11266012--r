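# Heterogeneity, pleiotropy, and leave-one-out diagnostics.

#' Cochran's Q heterogeneity test
#'
#' Measures heterogeneity of the per-SNP estimates around the pooled fit.
#' For IVW, Q is the weighted residual sum of squares about the
#' fixed-effects IVW slope (weights 1/se_out^2) on k - 1 degrees of freedom;
#' the fixed-effects slope is used even when random-effects IVW is reported,
#' because Q itself feeds the random-effects scale factor. For MR-Egger, Q
#' is the weighted residual sum of squares about the Egger fit on k - 2
#' degrees of freedom. The p-value is the upper chi-square tail.
#'
#' @param h A `harmonized_set`.
#' @param method `"ivw"` (k >= 2) or `"egger"` (k >= 3).
#' @return A list of class `q_result`: `method`, `Q`, `df`, `pval`.
#' @export
cochran_q <- function(h, method = c("ivw", "egger")) {
  method <- match.arg(method)
  v <- hset_vectors(h)
  if (method == "ivw") {
    if (v$k < 2L) stop("Cochran's Q (IVW) needs at least 2 instruments")
    w <- 1 / v$sy^2
    beta <- sum(w * v$bx * v$by) / sum(w * v$bx^2)
    Q <- sum(w * (v$by - beta * v$bx)^2)
    df <- v$k - 1L
  } else {
    if (v$k < 3L) stop("Cochran's Q (Egger) needs at least 3 instruments")
    fit <- egger_fit(v$bx, v$by, v$sy)
    Q <- fit$Q
    df <- v$k - 2L
  }
  structure(
    list(method = method, Q = Q, df = df,
         pval = stats::pchisq(Q, df, lower.tail = FALSE)),
    class = "q_result"
  )
}

#' @export
print.q_result <- function(x, ...) {
  cat(sprintf("<q_result> %s: Q = %.3f on %d df, p = %.3g\n",
              x$method, x$Q, x$df, x$pval))
  invisible(x)
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' Re-exports the intercept fields of [mr_egger()]: a non-zero intercept in
#' the Egger regression indicates that the instruments' average pleiotropic
#' effect on the outcome is directional, violating the exclusion
#' restriction. P-value from t(k - 2).
#'
#' @param h A `harmonized_set` with at least 3 instruments.
#' @return A list: `intercept`, `se`, `pval`.
#' @export
egger_intercept_test <- function(h) {
  fit <- mr_egger(h)
  list(intercept = fit$extra$intercept, se = fit$extra$intercept_se,
       pval = fit$extra$intercept_p)
}

#' Leave-one-out sensitivity analysis
#'
#' Refits the IVW estimate k times, each omitting one instrument, to detect
#' results driven by a single variant. Each refit is a fresh [mr_ivw()] call
#' on the reduced set.
#'
#' @param h A `harmonized_set` with at least 3 instruments.
#' @param effects_model Passed to [mr_ivw()].
#' @return A data frame with one row per omitted SNP (`omitted_snp`, `nsnp`,
#'   `beta`, `se`, `pval`), with attributes `sign_stable` (all leave-one-out
#'   betas share the full-set sign), `significance_stable` (all p-values on
#'   the same side of 0.05 as the full set), and `full` (the full-set IVW
#'   result).
#' @export
leave_one_out <- function(h, effects_model = "multiplicative_random") {
  v <- hset_vectors(h)
  if (v$k < 3L) stop("leave-one-out needs at least 3 instruments")
  full <- mr_ivw(h, effects_model)
  rows <- lapply(seq_len(v$k), function(i) {
    hi <- h
    hi$records <- h$records[-i, , drop = FALSE]
    fit <- mr_ivw(hi, effects_model)
    data.frame(omitted_snp = h$records$snp_id[i], nsnp = fit$k,
               beta = fit$beta, se = fit$se, pval = fit$pval)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "sign_stable") <- all(sign(out$beta) == sign(full$beta))
  attr(out, "significance_stable") <-
    all((out$pval < 0.05) == (full$pval < 0.05))
  attr(out, "full") <- full
  out
}
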