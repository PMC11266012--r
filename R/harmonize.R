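#' @keywords internal
allele_complement <- function(a) {
  c(A = "T", T = "A", C = "G", G = "C")[a]
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize exposure instruments against an outcome study
#'
#' Two-sample MR requires the exposure and outcome effect sizes at each
#' instrument to refer to the same effect allele. For each instrument found
#' in the outcome table:
#'
#' * same allele pair, same order: kept unchanged (`aligned`);
#' * same pair, swapped order: outcome beta negated and its effect-allele
#'   frequency reflected (`flipped`);
#' * pair matches after A<->T / C<->G complementation (a strand difference
#'   between studies): re-mapped and then aligned or flipped
#'   (`strand_corrected`);
#' * palindromic SNP (A/T or C/G, where strand cannot be resolved from the
#'   alleles): kept only when both effect-allele frequencies fall on the
#'   same side of 0.5 and both lie outside the ambiguity window
#'   `0.5 +/- palindrome_eaf_window`; kept SNPs with either frequency
#'   missing, or ambiguous frequencies, are dropped (`dropped_palindromic`);
#' * irreconcilable allele sets: dropped (`dropped_mismatch`);
#' * instruments absent from the outcome table: recorded in the dropped
#'   audit with reason `absent_from_outcome`.
#'
#' @param exposure An `instrument_set` or [sumstat_table()] of exposure
#'   associations.
#' @param outcome A [sumstat_table()] of outcome associations.
#' @param palindrome_eaf_window Half-width of the frequency ambiguity window
#'   around 0.5 for palindromic SNPs (default 0.08).
#'
#' @return An object of class `harmonized_set`: `exposure_name`,
#'   `outcome_name`, `records` (one row per retained instrument: `snp_id`,
#'   `beta_exp`, `se_exp`, `beta_out`, `se_out`, `eaf_exp`, `eaf_out`,
#'   `status`), and `dropped` (audit of removed instruments with reasons).
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_window = 0.08) {
  exp_rec <- if (inherits(exposure, "instrument_set")) exposure$records
             else if (inherits(exposure, "sumstat_table")) exposure$records
             else stop("exposure must be an instrument_set or sumstat_table")
  exp_name <- if (inherits(exposure, "instrument_set")) exposure$exposure_name
              else exposure$trait_name
  stopifnot(inherits(outcome, "sumstat_table"))
  out_rec <- outcome$records
  w <- palindrome_eaf_window

  rows <- vector("list", nrow(exp_rec))
  drops <- vector("list", nrow(exp_rec))
  for (i in seq_len(nrow(exp_rec))) {
    e <- exp_rec[i, ]
    j <- match(e$snp_id, out_rec$snp_id)
    if (is.na(j)) {
      drops[[i]] <- data.frame(snp_id = e$snp_id,
                               reason = "absent_from_outcome")
      next
    }
    o <- out_rec[j, ]
    ea1 <- e$effect_allele; oa1 <- e$other_allele
    ea2 <- o$effect_allele; oa2 <- o$other_allele
    beta_out <- o$beta; eaf_out <- o$eaf
    status <- NULL

    if (is_palindromic(ea1, oa1)) {
      # strand is unresolvable from alleles; orient by allele label, then
      # demand unambiguous, concordant frequencies
      if (ea2 == ea1 && oa2 == oa1) {
        status <- "aligned"
      } else if (ea2 == oa1 && oa2 == ea1) {
        status <- "flipped"
        beta_out <- -beta_out
        eaf_out <- 1 - eaf_out
      } else {
        status <- "dropped_mismatch"
      }
      if (!startsWith(status, "dropped")) {
        unambiguous <- !is.na(e$eaf) && !is.na(eaf_out) &&
          abs(e$eaf - 0.5) > w && abs(eaf_out - 0.5) > w &&
          sign(e$eaf - 0.5) == sign(eaf_out - 0.5)
        if (!unambiguous) status <- "dropped_palindromic"
      }
    } else {
      if (ea2 == ea1 && oa2 == oa1) {
        status <- "aligned"
      } else if (ea2 == oa1 && oa2 == ea1) {
        status <- "flipped"
        beta_out <- -beta_out
        eaf_out <- 1 - eaf_out
      } else {
        cea2 <- allele_complement(ea2); coa2 <- allele_complement(oa2)
        if (cea2 == ea1 && coa2 == oa1) {
          status <- "strand_corrected"
        } else if (cea2 == oa1 && coa2 == ea1) {
          status <- "strand_corrected"
          beta_out <- -beta_out
          eaf_out <- 1 - eaf_out
        } else {
          status <- "dropped_mismatch"
        }
      }
    }

    if (startsWith(status, "dropped")) {
      drops[[i]] <- data.frame(snp_id = e$snp_id, reason = status)
    } else {
      rows[[i]] <- data.frame(
        snp_id = e$snp_id, beta_exp = e$beta, se_exp = e$se,
        beta_out = unname(beta_out), se_out = o$se,
        eaf_exp = e$eaf, eaf_out = unname(eaf_out), status = status
      )
    }
  }
  records <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  dropped <- do.call(rbind, drops[!vapply(drops, is.null, logical(1))])
  if (is.null(records)) {
    records <- data.frame(
      snp_id = character(), beta_exp = numeric(), se_exp = numeric(),
      beta_out = numeric(), se_out = numeric(), eaf_exp = numeric(),
      eaf_out = numeric(), status = character()
    )
  }
  if (is.null(dropped)) {
    dropped <- data.frame(snp_id = character(), reason = character())
  }
  rownames(records) <- NULL
  rownames(dropped) <- NULL
  structure(
    list(exposure_name = exp_name, outcome_name = outcome$trait_name,
         records = records, dropped = dropped),
    class = "harmonized_set"
  )
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf(
    "<harmonized_set> %s -> %s: %d instruments retained, %d dropped\n",
    x$exposure_name, x$outcome_name, nrow(x$records), nrow(x$dropped)
  ))
  invisible(x)
}

#' Exclude SNPs from a harmonized set
#'
#' Removes the listed SNPs and audits the exclusions. Used by two-step
#' mediation MR, where SNPs instrumenting the exposure in step 1 are deleted
#' from the mediator's instrument set in step 2.
#'
#' @param set A `harmonized_set`.
#' @param snp_ids Character vector of SNP ids to remove; ids not present are
#'   ignored.
#' @param reason Audit label recorded for each exclusion.
#' @return A `harmonized_set` without the listed SNPs.
#' @export
exclude_snps <- function(set, snp_ids, reason = "excluded") {
  stopifnot(inherits(set, "harmonized_set"))
  hit <- set$records$snp_id %in% snp_ids
  if (any(hit)) {
    set$dropped <- rbind(
      set$dropped,
      data.frame(snp_id = set$records$snp_id[hit], reason = reason)
    )
    set$records <- set$records[!hit, , drop = FALSE]
    rownames(set$records) <- NULL
    rownames(set$dropped) <- NULL
  }
  set
}

#' Build a harmonized set directly from aligned effect vectors
#'
#' Constructor for already-aligned exposure/outcome effects; useful when
#' summary statistics arrive pre-harmonized or when building fixtures.
#'
#' @param beta_exp,se_exp,beta_out,se_out Numeric vectors of equal length.
#' @param snp_id SNP identifiers (default `snp0001`, ...).
#' @param exposure_name,outcome_name Trait labels.
#' @return A `harmonized_set`.
#' @export
harmonized_set <- function(beta_exp, se_exp, beta_out, se_out,
                           snp_id = sprintf("snp%04d", seq_along(beta_exp)),
                           exposure_name = "exposure",
                           outcome_name = "outcome") {
  stopifnot(all(se_exp > 0), all(se_out > 0))
  structure(
    list(
      exposure_name = exposure_name, outcome_name = outcome_name,
      records = data.frame(
        snp_id = snp_id, beta_exp = beta_exp, se_exp = se_exp,
        beta_out = beta_out, se_out = se_out,
        eaf_exp = rep(NA_real_, length(beta_exp)),
        eaf_out = rep(NA_real_, length(beta_exp)),
        status = rep("aligned", length(beta_exp))
      ),
      dropped = data.frame(snp_id = character(), reason = character())
    ),
    class = "harmonized_set"
  )
}
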