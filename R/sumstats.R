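#' GWAS summary-statistic tables
#'
#' A `sumstat_table` holds per-SNP association results for one trait: one row
#' per biallelic SNP with alleles, effect size, standard error, effect-allele
#' frequency, p-value and sample size. It is the unit of input for instrument
#' selection, harmonization, and every MR estimator in this package.
#'
#' @param trait_name Trait label, e.g. `"HDL cholesterol"`.
#' @param records Data frame with columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#'   `eaf` and `n` may be `NA`.
#' @param metadata Named list of free-form dataset metadata (population,
#'   year, sample size, ...).
#'
#' @return An object of class `sumstat_table`.
#' @export
sumstat_table <- function(trait_name, records, metadata = list()) {
  stopifnot(is.character(trait_name), length(trait_name) == 1L)
  records <- validate_sumstat_records(records)
  if (anyDuplicated(records$snp_id)) {
    stop("duplicated snp_id in summary statistics for trait '", trait_name, "'")
  }
  structure(
    list(trait_name = trait_name, records = records, metadata = metadata),
    class = "sumstat_table"
  )
}

#' @export
print.sumstat_table <- function(x, ...) {
  cat(sprintf(
    "<sumstat_table> trait '%s': %d SNPs\n", x$trait_name, nrow(x$records)
  ))
  invisible(x)
}

SUMSTAT_COLS <- c(
  "snp_id", "chrom", "pos", "effect_allele", "other_allele",
  "eaf", "beta", "se", "pval", "n"
)
SUMSTAT_REQUIRED <- setdiff(SUMSTAT_COLS, c("eaf", "n"))

# Coerce column types and enforce per-record invariants; invalid rows are the
# caller's problem (use drop_invalid_records for tolerant parsing).
validate_sumstat_records <- function(records) {
  stopifnot(is.data.frame(records))
  missing <- setdiff(SUMSTAT_REQUIRED, names(records))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (!"eaf" %in% names(records)) records$eaf <- NA_real_
  if (!"n" %in% names(records)) records$n <- NA_real_
  records <- records[, SUMSTAT_COLS]
  records$snp_id <- as.character(records$snp_id)
  records$chrom <- as.character(records$chrom)
  records$pos <- as.integer(records$pos)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (col in c("eaf", "beta", "se", "pval", "n")) {
    records[[col]] <- as.numeric(records[[col]])
  }
  bad <- invalid_record_reasons(records)
  if (any(nzchar(bad))) {
    stop(
      "invalid summary-statistic record(s): ",
      paste(utils::head(unique(bad[nzchar(bad)]), 3), collapse = "; ")
    )
  }
  rownames(records) <- NULL
  records
}

# One reason string per row, "" when valid. Checked in order of severity so
# the drop tally is interpretable.
invalid_record_reasons <- function(records) {
  nucl <- c("A", "C", "G", "T")
  reason <- character(nrow(records))
  flag <- function(cond, msg) {
    cond[is.na(cond)] <- TRUE
    reason[cond & !nzchar(reason)] <<- msg
  }
  flag(is.na(records$snp_id) | !nzchar(records$snp_id), "missing snp_id")
  flag(!(records$effect_allele %in% nucl), "non-SNP effect allele")
  flag(!(records$other_allele %in% nucl), "non-SNP other allele")
  flag(records$effect_allele == records$other_allele, "identical alleles")
  flag(!(records$se > 0), "se not > 0")
  flag(!(records$pval > 0 & records$pval <= 1), "pval outside (0, 1]")
  ok_eaf <- is.na(records$eaf) | (records$eaf >= 0 & records$eaf <= 1)
  reason[!ok_eaf & !nzchar(reason)] <- "eaf outside [0, 1]"
  ok_n <- is.na(records$n) | records$n > 0
  reason[!ok_n & !nzchar(reason)] <- "n not > 0"
  flag(is.na(records$pos) | records$pos < 1, "invalid position")
  flag(is.na(records$beta), "missing beta")
  reason
}

#' Read GWAS summary statistics from a tab-separated file
#'
#' Parses the canonical dialect (tab-separated, header row, `NA` for missing
#' values). Rows that violate record invariants — indels or multi-allelic
#' alleles, non-positive standard errors, p-values outside `(0, 1]` — are
#' dropped, tallied by reason, and reported via a warning; the tally is
#' attached as attribute `"dropped"`.
#'
#' @param path Path to a TSV file with a header row.
#' @param trait_name Trait label; defaults to the file name.
#' @param column_map Optional named character vector mapping canonical column
#'   names (`snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pval`, `n`) to the file's column names. Unmapped
#'   canonical names are looked up verbatim.
#' @param metadata Named list stored on the table.
#'
#' @return A [sumstat_table()]; attribute `"dropped"` holds a named integer
#'   tally of dropped rows by reason (empty when nothing was dropped).
#' @export
read_sumstats <- function(path, trait_name = basename(path),
                          column_map = NULL, metadata = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(
    path, header = TRUE, sep = "\t", na.strings = "NA",
    colClasses = "character", check.names = FALSE,
    stringsAsFactors = FALSE
  )
  if (nrow(raw) == 0L) stop("empty summary-statistics file: ", path)
  lookup <- stats::setNames(SUMSTAT_COLS, SUMSTAT_COLS)
  if (!is.null(column_map)) {
    stopifnot(!is.null(names(column_map)))
    unknown <- setdiff(names(column_map), SUMSTAT_COLS)
    if (length(unknown)) {
      stop("column_map names not canonical columns: ",
           paste(unknown, collapse = ", "))
    }
    lookup[names(column_map)] <- column_map
  }
  missing <- setdiff(lookup[SUMSTAT_REQUIRED], names(raw))
  if (length(missing)) {
    stop("required column(s) absent from ", path, ": ",
         paste(missing, collapse = ", "))
  }
  records <- data.frame(row.names = seq_len(nrow(raw)))
  for (canon in SUMSTAT_COLS) {
    src <- lookup[[canon]]
    records[[canon]] <- if (src %in% names(raw)) raw[[src]] else NA_character_
  }
  records$effect_allele <- toupper(records$effect_allele)
  records$other_allele <- toupper(records$other_allele)
  suppressWarnings({
    records$pos <- as.integer(records$pos)
    for (col in c("eaf", "beta", "se", "pval", "n")) {
      records[[col]] <- as.numeric(records[[col]])
    }
  })
  reasons <- invalid_record_reasons(records)
  keep <- !nzchar(reasons)
  tally <- table(reasons[!keep])
  dropped <- stats::setNames(
    as.integer(tally),
    if (is.null(names(tally))) character(0) else names(tally)
  )
  if (length(dropped)) {
    warning(sprintf(
      "%s: dropped %d row(s): %s", basename(path), sum(dropped),
      paste(sprintf("%s (%d)", names(dropped), dropped), collapse = ", ")
    ), call. = FALSE)
  }
  out <- sumstat_table(trait_name, records[keep, , drop = FALSE], metadata)
  attr(out, "dropped") <- dropped
  out
}

#' Write a summary-statistic table to the canonical TSV dialect
#'
#' Tab-separated, header row, `"NA"` for missing values. Floating-point
#' columns are serialized with 17 significant digits so that
#' `read_sumstats(write_sumstats(t))` reproduces `t` exactly and repeated
#' writes are byte-identical.
#'
#' @param table A [sumstat_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(table, path) {
  stopifnot(inherits(table, "sumstat_table"))
  if (nrow(table$records) == 0L) stop("refusing to write an empty table")
  rec <- table$records
  fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  out <- data.frame(
    snp_id = rec$snp_id,
    chrom = rec$chrom,
    pos = as.character(rec$pos),
    effect_allele = rec$effect_allele,
    other_allele = rec$other_allele,
    eaf = fmt_num(rec$eaf),
    beta = fmt_num(rec$beta),
    se = fmt_num(rec$se),
    pval = fmt_num(rec$pval),
    n = fmt_num(rec$n),
    stringsAsFactors = FALSE
  )
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) {
    stop("cannot write to ", path, ": ", conditionMessage(e))
  })
  invisible(path)
}
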