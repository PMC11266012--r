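#' Select candidate instruments by a p-value relaxation ladder
#'
#' Genetic instruments are normally taken at genome-wide significance
#' (p < 5e-8); when a trait yields too few SNPs at that threshold the
#' threshold is relaxed down an ordered ladder (5e-8, 5e-6, 5e-5 by default)
#' until at least `min_snps` candidates are found. If even the most lenient
#' rung yields fewer than `min_snps`, whatever exists is returned with a
#' warning flag.
#'
#' @param table A [sumstat_table()].
#' @param ladder Strictly increasing p-value thresholds to try in order.
#' @param min_snps Minimum candidate count required to stop descending the
#'   ladder. Defaults to 3, the smallest instrument count at which MR-Egger
#'   (k - 2 residual degrees of freedom) is estimable.
#'
#' @return A list with `records` (candidate rows), `threshold_used`, and
#'   `insufficient` (`TRUE` when even the last rung fell short).
#' @export
select_by_pvalue <- function(table, ladder = c(5e-8, 5e-6, 5e-5),
                             min_snps = 3L) {
  stopifnot(inherits(table, "sumstat_table"))
  if (nrow(table$records) == 0L) stop("empty summary-statistic table")
  stopifnot(length(ladder) >= 1L, min_snps >= 1L)
  if (is.unsorted(ladder, strictly = TRUE)) {
    stop("ladder thresholds must be strictly increasing")
  }
  rec <- table$records
  for (thr in ladder) {
    hits <- rec[rec$pval < thr, , drop = FALSE]
    if (nrow(hits) >= min_snps) {
      return(list(records = hits, threshold_used = thr, insufficient = FALSE))
    }
  }
  thr <- ladder[length(ladder)]
  hits <- rec[rec$pval < thr, , drop = FALSE]
  warning(sprintf(
    "only %d SNP(s) below the most lenient threshold %g (min_snps = %d)",
    nrow(hits), thr, min_snps
  ), call. = FALSE)
  list(records = hits, threshold_used = thr, insufficient = TRUE)
}

# Normalise an LD source to a lookup function r2(snp_a, snp_b).
#  - NULL        -> NULL (caller falls back to distance-only clumping)
#  - matrix      -> dense labeled lookup; absent label -> 0
#  - data.frame  -> sparse (snp_a, snp_b, r2); absent pair -> 0
#  - function    -> used as-is
ld_lookup <- function(ld) {
  if (is.null(ld)) return(NULL)
  if (is.function(ld)) return(ld)
  if (is.matrix(ld)) {
    if (is.null(rownames(ld)) || is.null(colnames(ld))) {
      stop("dense LD matrix must carry SNP ids as dimnames")
    }
    return(function(a, b) {
      if (a %in% rownames(ld) && b %in% colnames(ld)) ld[a, b] else 0
    })
  }
  if (is.data.frame(ld)) {
    need <- c("snp_a", "snp_b", "r2")
    if (!all(need %in% names(ld))) {
      stop("sparse LD table needs columns snp_a, snp_b, r2")
    }
    key <- c(paste(ld$snp_a, ld$snp_b), paste(ld$snp_b, ld$snp_a))
    val <- rep(ld$r2, 2L)
    env <- new.env(parent = emptyenv(), size = length(key))
    for (i in seq_along(key)) assign(key[i], val[i], envir = env)
    return(function(a, b) {
      v <- mget(paste(a, b), envir = env, ifnotfound = 0)[[1]]
      v
    })
  }
  stop("unsupported LD source; supply a matrix, data frame, or function")
}

#' Greedy LD clumping of candidate instruments
#'
#' Repeatedly takes the remaining SNP with the smallest p-value and discards
#' every other remaining SNP on the same chromosome within `window_bp` whose
#' r-squared with it exceeds `r2_max`. Ties in p-value are broken by
#' (chromosome, position, SNP id), so the result is invariant to input order.
#' Defaults follow the common instrument-pruning convention of a 10 Mb window
#' with r-squared cutoff 0.001.
#'
#' When no LD source is supplied, SNPs within the window are conservatively
#' treated as correlated (distance-only clumping). When a sparse LD source is
#' supplied, absent pairs are assumed unlinked (r-squared 0), matching sparse
#' LD exports that omit below-threshold pairs.
#'
#' @param candidates Data frame of candidate records (as from
#'   [select_by_pvalue()]).
#' @param ld LD source: `NULL`, a dense labeled r-squared matrix, a sparse
#'   data frame with columns `snp_a`/`snp_b`/`r2`, or a function
#'   `f(snp_a, snp_b)`.
#' @param window_bp Clumping window in base pairs (default 1e7, i.e. 10 Mb).
#' @param r2_max Maximum tolerated r-squared between retained SNPs within
#'   the window (default 0.001).
#' @param exposure_name Trait label carried on the result.
#' @param threshold_used Selection threshold carried on the result.
#'
#' @return An object of class `instrument_set`: list with `exposure_name`,
#'   `records`, `threshold_used`, `clump_window_bp`, `clump_r2`.
#' @export
ld_clump <- function(candidates, ld = NULL, window_bp = 1e7, r2_max = 0.001,
                     exposure_name = "exposure", threshold_used = NA_real_) {
  stopifnot(is.data.frame(candidates))
  if (nrow(candidates) > 0 &&
      (anyNA(candidates$chrom) || anyNA(candidates$pos))) {
    stop("candidates must carry chrom and pos for positional clumping")
  }
  r2 <- ld_lookup(ld)
  ord <- order(candidates$pval, candidates$chrom, candidates$pos,
               candidates$snp_id)
  rec <- candidates[ord, , drop = FALSE]
  keep <- logical(nrow(rec))
  alive <- rep(TRUE, nrow(rec))
  for (i in seq_len(nrow(rec))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    if (i == nrow(rec)) break
    later <- which(alive & seq_len(nrow(rec)) > i)
    if (!length(later)) next
    near <- later[rec$chrom[later] == rec$chrom[i] &
                  abs(rec$pos[later] - rec$pos[i]) <= window_bp]
    if (!length(near)) next
    if (is.null(r2)) {
      alive[near] <- FALSE
    } else {
      r2s <- vapply(near, function(j) r2(rec$snp_id[i], rec$snp_id[j]),
                    numeric(1))
      alive[near[r2s > r2_max]] <- FALSE
    }
  }
  out <- rec[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(
    list(exposure_name = exposure_name, records = out,
         threshold_used = threshold_used, clump_window_bp = window_bp,
         clump_r2 = r2_max),
    class = "instrument_set"
  )
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf(
    "<instrument_set> '%s': %d instruments (p < %g, window %g bp, r2 <= %g)\n",
    x$exposure_name, nrow(x$records), x$threshold_used, x$clump_window_bp,
    x$clump_r2
  ))
  invisible(x)
}

#' Select and clump instruments for one exposure
#'
#' Convenience wrapper: [select_by_pvalue()] then [ld_clump()].
#'
#' @inheritParams select_by_pvalue
#' @inheritParams ld_clump
#' @return An `instrument_set`; attribute `"insufficient"` flags a ladder
#'   that bottomed out short of `min_snps`.
#' @export
select_instruments <- function(table, ladder = c(5e-8, 5e-6, 5e-5),
                               min_snps = 3L, ld = NULL, window_bp = 1e7,
                               r2_max = 0.001) {
  sel <- select_by_pvalue(table, ladder, min_snps)
  out <- ld_clump(sel$records, ld = ld, window_bp = window_bp,
                  r2_max = r2_max, exposure_name = table$trait_name,
                  threshold_used = sel$threshold_used)
  attr(out, "insufficient") <- sel$insufficient
  out
}
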