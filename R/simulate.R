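# Seeded generator of synthetic two-sample GWAS summary statistics with
# known truth. Stands in for the real GWAS downloads the analysis design
# assumes: paired exposure/outcome tables with configurable causal effect,
# instrument-strength distribution, and pleiotropy regime, plus
# exposure-mediator-outcome chains with instrument overlap.

#' Simulation configuration for two-sample summary statistics
#'
#' Defaults emulate a well-powered European-ancestry GWAS pair: 100
#' independent instruments, 200,000 samples per study (the exposure GWAS in
#' the emulated study design range from ~14,000 to ~440,000), minor-allele
#' frequencies uniform on (0.05, 0.5), and per-allele exposure effects of
#' mean 0.08 SD with SD 0.02 — strong instruments whose marginal tests
#' clear genome-wide significance by a wide margin.
#'
#' @param k Number of instruments (independent SNPs).
#' @param n_exp,n_out GWAS sample sizes for the exposure and outcome study.
#' @param maf_range Minor-allele frequency range, a subinterval of (0, 0.5].
#' @param gamma_mean,gamma_sd Mean and SD of the per-SNP exposure effects.
#' @param true_beta Causal effect of the exposure on the outcome (log-odds
#'   scale when `binary_outcome`).
#' @param pleiotropy `"none"`, or `list(type = "balanced", sd = )`, or
#'   `list(type = "directional", mean = , sd = )` — the distribution of
#'   per-SNP direct (pleiotropic) effects on the outcome.
#' @param inside_violation When `TRUE`, the pleiotropic effect gains a
#'   component proportional to the instrument's strength, violating the
#'   InSIDE assumption.
#' @param binary_outcome Interpret outcome effects as log-odds. The SE
#'   model is unchanged (see [simulate_two_sample()]).
#' @param palindromic_frac Fraction of SNPs assigned palindromic (A/T or
#'   C/G) allele pairs.
#' @param seed Integer seed; regenerating with the same seed reproduces the
#'   tables bit-for-bit.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(k = 100L, n_exp = 2e5, n_out = 2e5,
                       maf_range = c(0.05, 0.5),
                       gamma_mean = 0.08, gamma_sd = 0.02,
                       true_beta = 0, pleiotropy = "none",
                       inside_violation = FALSE, binary_outcome = FALSE,
                       palindromic_frac = 0.2, seed = 1L) {
  if (is.character(pleiotropy)) {
    stopifnot(pleiotropy == "none")
    pleiotropy <- list(type = "none")
  }
  stopifnot(
    k >= 1L, n_exp > 0, n_out > 0,
    length(maf_range) == 2L, maf_range[1] > 0, maf_range[2] <= 0.5,
    maf_range[1] <= maf_range[2], gamma_sd >= 0,
    pleiotropy$type %in% c("none", "balanced", "directional"),
    palindromic_frac >= 0, palindromic_frac <= 1
  )
  if (pleiotropy$type != "none") stopifnot(pleiotropy$sd >= 0)
  structure(
    list(k = as.integer(k), n_exp = n_exp, n_out = n_out,
         maf_range = maf_range, gamma_mean = gamma_mean,
         gamma_sd = gamma_sd, true_beta = true_beta,
         pleiotropy = pleiotropy, inside_violation = inside_violation,
         binary_outcome = binary_outcome,
         palindromic_frac = palindromic_frac, seed = as.integer(seed)),
    class = "sim_config"
  )
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv())) {
            rm(".Random.seed", envir = globalenv())
          })
  set.seed(seed)
  force(expr)
}

draw_alleles <- function(k, palindromic_frac) {
  pal_pairs <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  npal_pairs <- list(c("A", "G"), c("G", "A"), c("A", "C"), c("C", "A"),
                     c("T", "G"), c("G", "T"), c("T", "C"), c("C", "T"))
  is_pal <- stats::runif(k) < palindromic_frac
  idx_pal <- sample.int(4L, k, replace = TRUE)
  idx_np <- sample.int(8L, k, replace = TRUE)
  ea <- character(k); oa <- character(k)
  for (j in seq_len(k)) {
    pair <- if (is_pal[j]) pal_pairs[[idx_pal[j]]] else npal_pairs[[idx_np[j]]]
    ea[j] <- pair[1]; oa[j] <- pair[2]
  }
  list(effect = ea, other = oa)
}

sumstat_se <- function(n, maf) 1 / sqrt(2 * n * maf * (1 - maf))

# Generated SNPs are statistically independent, so they are placed on a
# genomic grid whose same-chromosome spacing (11 Mb + <1 Mb jitter) always
# exceeds the default 10 Mb clumping window: distance-only clumping of
# simulated instruments is a no-op, consistent with identity LD.
draw_positions <- function(k) {
  slot <- seq_len(k) - 1L
  chrom <- as.character(slot %% 22L + 1L)
  base <- (slot %/% 22L) * 11000000L + 1000000L
  list(chrom = chrom, pos = base + sample.int(999999L, k, replace = TRUE))
}

build_table <- function(trait, snp_id, chrom, pos, ea, oa, eaf, beta, se, n) {
  pval <- 2 * stats::pnorm(-abs(beta / se))
  pval[pval == 0] <- .Machine$double.xmin
  sumstat_table(trait, data.frame(
    snp_id = snp_id, chrom = chrom, pos = pos, effect_allele = ea,
    other_allele = oa, eaf = eaf, beta = beta, se = se, pval = pval, n = n
  ))
}

#' Simulate paired exposure/outcome GWAS summary statistics
#'
#' Per SNP j: the minor-allele frequency is uniform on `maf_range`; the
#' true exposure effect gamma_j is normal(gamma_mean, gamma_sd); the direct
#' (pleiotropic) outcome effect alpha_j follows the configured regime (0,
#' normal(0, sd), or normal(mean, sd); with `inside_violation` it gains a
#' component `0.5 * gamma_j`); the true outcome effect is
#' `true_beta * gamma_j + alpha_j`. Observed betas are drawn around the
#' truth with standard errors `1 / sqrt(2 n maf (1 - maf))` — the SE of a
#' per-allele regression coefficient for a standardized continuous trait.
#' The same form is reused on the log-odds scale for binary outcomes as an
#' approximation (it is not a case-control power model). The two studies
#' are independent (no sample overlap) and SNPs are independent (identity
#' LD); alleles are drawn with a configurable palindromic fraction, and
#' both studies report the same alleles and frequencies.
#'
#' @param config A [sim_config()].
#' @return A list: `exposure` and `outcome` ([sumstat_table()]s) and
#'   `truth` (class `sim_truth`: the config plus realized `gamma`, `alpha`,
#'   per-SNP true outcome effects and the generating seed).
#' @export
simulate_two_sample <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    k <- config$k
    snp_id <- sprintf("rs%06d", seq_len(k))
    loc <- draw_positions(k)
    chrom <- loc$chrom
    pos <- loc$pos
    al <- draw_alleles(k, config$palindromic_frac)
    maf <- stats::runif(k, config$maf_range[1], config$maf_range[2])
    gamma <- stats::rnorm(k, config$gamma_mean, config$gamma_sd)
    pl <- config$pleiotropy
    alpha <- switch(pl$type,
      none = rep(0, k),
      balanced = stats::rnorm(k, 0, pl$sd),
      directional = stats::rnorm(k, pl$mean, pl$sd)
    )
    if (config$inside_violation) alpha <- alpha + 0.5 * gamma
    Gamma <- config$true_beta * gamma + alpha

    se_exp <- sumstat_se(config$n_exp, maf)
    se_out <- sumstat_se(config$n_out, maf)
    beta_exp <- stats::rnorm(k, gamma, se_exp)
    beta_out <- stats::rnorm(k, Gamma, se_out)

    exposure <- build_table("exposure", snp_id, chrom, pos, al$effect,
                            al$other, maf, beta_exp, se_exp, config$n_exp)
    outcome <- build_table("outcome", snp_id, chrom, pos, al$effect,
                           al$other, maf, beta_out, se_out, config$n_out)
    truth <- structure(
      list(config = config, gamma = gamma, alpha = alpha,
           outcome_effects = Gamma, seed = config$seed),
      class = "sim_truth"
    )
    list(exposure = exposure, outcome = outcome, truth = truth)
  })
}

#' Simulate an exposure-mediator-outcome summary-statistic chain
#'
#' Generates three GWAS tables with a known mediation structure. The SNP
#' panel is the union of `k_x` exposure instruments and `k_m - overlap`
#' mediator-only instruments. The first `overlap` exposure instruments are
#' drawn extra strong (per-SNP exposure effects uniform on 0.2-0.24 instead
#' of the `gamma_mean` baseline), so their inherited `beta1 * gamma_j`
#' association with the mediator itself reaches genome-wide significance:
#' these are the "duplicated" SNPs that a two-step analysis must delete in
#' step 2, because their mediator association is wholly downstream of the
#' exposure and instruments the wrong trait. The baseline instrument
#' strength (mean 0.05, SD 0.005) is deliberately more moderate than in
#' [sim_config()]: it keeps every designated instrument safely genome-wide
#' significant for its own trait while the `beta1 * gamma_j` leakage of
#' ordinary exposure SNPs onto the mediator stays well short of
#' significance, so instrument sets selected from the generated tables
#' match the designated ones. True effects: exposure SNPs affect X with
#' effect gamma_j; the mediator is `M = beta1 * X` plus its own genetics
#' (`delta_j` for mediator-only SNPs); the outcome is
#' `Y = direct_effect * X + beta2 * M`, so the total exposure-on-outcome
#' effect is `direct_effect + beta1 * beta2`.
#'
#' @param k_x,k_m Instrument counts for the exposure and mediator.
#' @param overlap Number of mediator instruments shared with the exposure
#'   (0 <= overlap <= min(k_x, k_m)).
#' @param beta1 True exposure-on-mediator effect.
#' @param beta2 True mediator-on-outcome effect.
#' @param direct_effect True direct exposure-on-outcome effect.
#' @param n GWAS sample size used for all three studies.
#' @param maf_range,gamma_mean,gamma_sd,palindromic_frac As [sim_config()].
#' @param seed Integer seed.
#' @return A list: `exposure`, `mediator`, `outcome` ([sumstat_table()]s)
#'   and `truth` (`beta1`, `beta2`, `direct_effect`,
#'   `total = direct_effect + beta1 * beta2`, shared SNP ids, seed).
#' @export
simulate_mediation_chain <- function(k_x = 30L, k_m = 30L, overlap = 0L,
                                     beta1 = -0.2, beta2 = -0.25,
                                     direct_effect = 0.1, n = 2e5,
                                     maf_range = c(0.15, 0.45),
                                     gamma_mean = 0.05, gamma_sd = 0.005,
                                     palindromic_frac = 0, seed = 1L) {
  stopifnot(overlap >= 0L, overlap <= min(k_x, k_m))
  with_seed(seed, {
    k_m_only <- k_m - overlap
    k <- k_x + k_m_only
    snp_id <- sprintf("rs%06d", seq_len(k))
    loc <- draw_positions(k)
    chrom <- loc$chrom
    pos <- loc$pos
    al <- draw_alleles(k, palindromic_frac)
    maf <- stats::runif(k, maf_range[1], maf_range[2])

    is_x <- seq_len(k) <= k_x
    is_shared <- seq_len(k) <= overlap
    gamma <- ifelse(is_x, stats::rnorm(k, gamma_mean, gamma_sd), 0)
    delta_own <- ifelse(!is_x, stats::rnorm(k, gamma_mean, gamma_sd), 0)
    if (overlap > 0L) {
      # shared SNPs: strong exposure loci whose inherited beta1 * gamma
      # effect on the mediator clears genome-wide significance by itself
      gamma[is_shared] <- stats::runif(overlap, 0.2, 0.24)
    }
    eff_x <- gamma
    eff_m <- beta1 * gamma + delta_own
    eff_y <- direct_effect * gamma + beta2 * eff_m

    se <- sumstat_se(n, maf)
    bx <- stats::rnorm(k, eff_x, se)
    bm <- stats::rnorm(k, eff_m, se)
    by <- stats::rnorm(k, eff_y, se)

    shared <- snp_id[is_shared]
    truth <- structure(
      list(beta1 = beta1, beta2 = beta2, direct_effect = direct_effect,
           total = direct_effect + beta1 * beta2, shared_snps = shared,
           exposure_snps = snp_id[is_x], mediator_snps = snp_id[!is_x],
           seed = seed),
      class = "sim_truth"
    )
    list(
      exposure = build_table("exposure", snp_id, chrom, pos, al$effect,
                             al$other, maf, bx, se, n),
      mediator = build_table("mediator", snp_id, chrom, pos, al$effect,
                             al$other, maf, bm, se, n),
      outcome = build_table("outcome", snp_id, chrom, pos, al$effect,
                            al$other, maf, by, se, n),
      truth = truth
    )
  })
}
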