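test_that("a well-formed TSV parses to an identical table and round-trips", {
  tab <- make_table(3, trait = "bmi")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(tab, path)
  back <- read_sumstats(path, trait_name = "bmi")
  expect_equal(back$records, tab$records)
  expect_identical(attr(back, "dropped"), setNames(integer(0), character(0)))
})

test_that("rows violating record invariants are dropped and tallied", {
  rec <- make_records(4)
  rec$se[2] <- 0              # non-positive SE
  rec$pval[3] <- 0            # p outside (0, 1]
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(tab <- read_sumstats(path), "dropped 2 row")
  expect_equal(nrow(tab$records), 2L)
  drops <- attr(tab, "dropped")
  expect_equal(sum(drops), 2L)
  expect_equal(unname(drops[["se not > 0"]]), 1L)
  expect_equal(unname(drops[["pval outside (0, 1]"]]), 1L)
})

test_that("indels and multi-allelic rows are dropped; alleles upper-cased", {
  rec <- make_records(3)
  rec$effect_allele <- c("a", "AT", "G")
  rec$other_allele <- c("g", "A", "G")   # row 3: identical alleles
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(tab <- read_sumstats(path), "dropped 2 row")
  expect_equal(tab$records$effect_allele, "A")
  expect_equal(tab$records$other_allele, "G")
})

test_that("parsing is independent of column order given a column_map", {
  tab <- make_table(6, trait = "t")
  canonical <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(tab, canonical)
  ref <- read_sumstats(canonical, trait_name = "t")

  shuffled <- read.delim(canonical, colClasses = "character",
                         check.names = FALSE)
  shuffled <- shuffled[, rev(names(shuffled))]
  names(shuffled) <- paste0("col_", names(shuffled))
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(shuffled, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  cmap <- setNames(paste0("col_", mrtwosample:::SUMSTAT_COLS),
                   mrtwosample:::SUMSTAT_COLS)
  got <- read_sumstats(path2, trait_name = "t", column_map = cmap)
  expect_equal(got$records, ref$records)
})

test_that("missing eaf serializes as NA and round-trips to missing", {
  tab <- make_table(3, eaf = c(0.2, NA, 0.4), n = rep(NA_real_, 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(tab, path)
  lines <- readLines(path)
  expect_true(any(grepl("\tNA\t", lines[-1], fixed = TRUE)))
  back <- read_sumstats(path)
  expect_identical(back$records$eaf, tab$records$eaf)
  expect_identical(back$records$n, tab$records$n)
})

test_that("writing a 1000-record synthetic table twice is byte-stable", {
  sim <- simulate_two_sample(sim_config(k = 1000, true_beta = 0.1, seed = 5))
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(sim$exposure, p1)
  write_sumstats(sim$exposure, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  back <- read_sumstats(p1)
  expect_equal(back$records, sim$exposure$records)
})

test_that("structural errors are hard: missing column, empty file, bad path", {
  tab <- make_table(3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(tab, path)
  raw <- read.delim(path, check.names = FALSE, colClasses = "character")
  raw$beta <- NULL
  write.table(raw, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_sumstats(path), "beta")

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(mrtwosample:::SUMSTAT_COLS, collapse = "\t"), empty)
  expect_error(read_sumstats(empty), "empty")

  expect_error(read_sumstats(file.path(tempdir(), "nope.tsv")), "not found")
  expect_error(
    suppressWarnings(write_sumstats(tab, file.path(tempdir(), "no_dir",
                                                   "x.tsv"))),
    "cannot write"
  )
  expect_error(sumstat_table("t", make_records(3, snp_id = rep("rs1", 3))),
               "duplicated")
})
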