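# Shared fixture builders. Everything is generated in code; no stored data.

# A valid records data frame; override any column by name.
make_records <- function(k = 5L, ...) {
  over <- list(...)
  rec <- data.frame(
    snp_id = sprintf("rs%04d", seq_len(k)),
    chrom = as.character(rep_len(1:22, k)),
    pos = seq_len(k) * 15000000L,
    effect_allele = rep_len(c("A", "C", "G", "T"), k),
    other_allele = rep_len(c("G", "T", "A", "C"), k),
    eaf = rep_len(c(0.2, 0.3, 0.4), k),
    beta = seq_len(k) / 100,
    se = rep(0.01, k),
    pval = rep(1e-9, k),
    n = rep(10000, k)
  )
  for (nm in names(over)) rec[[nm]] <- over[[nm]]
  rec
}

make_table <- function(k = 5L, trait = "trait", ...) {
  sumstat_table(trait, make_records(k, ...))
}

# Two-trait pair sharing SNP ids and alleles, with chosen effect vectors.
make_pair <- function(beta_exp, se_exp, beta_out, se_out,
                      pval_exp = rep(1e-12, length(beta_exp))) {
  k <- length(beta_exp)
  base <- make_records(k)
  exp_rec <- base
  exp_rec$beta <- beta_exp
  exp_rec$se <- se_exp
  exp_rec$pval <- pval_exp
  out_rec <- base
  out_rec$beta <- beta_out
  out_rec$se <- se_out
  out_rec$pval <- 2 * pnorm(-abs(beta_out / se_out))
  list(exposure = sumstat_table("exposure", exp_rec),
       outcome = sumstat_table("outcome", out_rec))
}

# Independent WLS-through-origin oracle for the IVW estimate.
ivw_oracle <- function(bx, by, sy) {
  fit <- lm(by ~ 0 + bx, weights = 1 / sy^2)
  s <- summary(fit)
  list(beta = unname(coef(fit)[1]),
       se_fixed = unname(s$coefficients[1, 2]) / s$sigma)
}

# Simulate one two-sample dataset and return the harmonized set.
sim_hset <- function(seed, k = 100L, true_beta = 0, pleiotropy = "none",
                     ...) {
  sim <- simulate_two_sample(sim_config(
    k = k, true_beta = true_beta, pleiotropy = pleiotropy, seed = seed, ...
  ))
  harmonize(sumstat_table_as_instruments(sim$exposure), sim$outcome)
}

sumstat_table_as_instruments <- function(tab) {
  ld_clump(tab$records, exposure_name = tab$trait_name)
}

# Hand-enumerated six-case fixture covering every harmonization status.
six_case_pair <- function() {
  exp_rec <- make_records(
    6,
    snp_id = sprintf("rs%d", 1:6),
    effect_allele = c("A", "A", "A", "A", "A", "A"),
    other_allele  = c("G", "G", "G", "T", "G", "G"),
    eaf = c(0.2, 0.2, 0.2, 0.2, 0.2, 0.2),
    beta = rep(0.1, 6)
  )
  out_rec <- make_records(
    6,
    snp_id = c(sprintf("rs%d", 1:5), "rs99"),
    effect_allele = c("A", "G", "T", "A", "A", "A"),
    other_allele  = c("G", "A", "C", "T", "C", "G"),
    eaf = c(0.25, 0.75, 0.25, 0.5, 0.25, 0.25),
    beta = rep(0.05, 6)
  )
  list(exposure = sumstat_table("exp", exp_rec),
       outcome = sumstat_table("out", out_rec))
}

# Build m exposure tables plus an outcome over a shared SNP panel with
# known per-exposure effects; instruments are disjoint across exposures.
make_mvmr_study <- function(k_per = 25L, m = 2L, coefs = c(0.5, 0),
                            seed = 1L, noise = NULL) {
  set.seed(seed)
  k <- k_per * m
  base <- make_records(k, snp_id = sprintf("rs%04d", seq_len(k)),
                       pos = as.integer(seq_len(k) * 15000000L))
  se <- rep(0.004, k)
  bx <- matrix(0, k, m)
  for (j in seq_len(m)) {
    idx <- ((j - 1) * k_per + 1):(j * k_per)
    bx[idx, j] <- rnorm(k_per, 0.08, 0.01)
  }
  bx_obs <- bx + rnorm(k * m, 0, se)
  dim(bx_obs) <- dim(bx)
  tables <- lapply(seq_len(m), function(j) {
    rec <- base
    rec$beta <- bx_obs[, j]
    rec$se <- se
    rec$pval <- 2 * pnorm(-abs(rec$beta / rec$se))
    sumstat_table(sprintf("exp%d", j), rec)
  })
  if (is.null(noise)) noise <- rnorm(k, 0, se)
  by <- as.vector(bx_obs %*% coefs) + noise
  out_rec <- base
  out_rec$beta <- by
  out_rec$se <- se
  out_rec$pval <- 2 * pnorm(-abs(by / se))
  list(exposures = tables, outcome = sumstat_table("outcome", out_rec),
       sets = lapply(tables, select_instruments))
}
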