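#!/usr/bin/env Rscript
# Step 4: two-step mediation MR on the synthetic chains.
#
# For each exposure -> mediator -> outcome chain: total effect by
# exposure -> outcome IVW, step 1 by exposure -> mediator IVW, step 2 by
# mediator -> outcome IVW after deleting SNPs shared with step 1, then the
# product-of-coefficients decomposition (beta12 = beta1 * beta2,
# beta_dir = beta_all - beta12, beta_per = beta12 / beta_all). A chain
# counts as mediating only when both step IVW p-values are below 0.05.

library(mrtwosample)

in_dir <- "scratch/synthetic_study"
if (!dir.exists(in_dir)) stop("run analysis/01_simulate_study.R first")
dir.create("results", showWarnings = FALSE)

chains <- c("chain_obesity_hdl", "chain_bmi_apoa1")
runs <- lapply(chains, function(cn) {
  rd <- function(part) {
    read_sumstats(file.path(in_dir, sprintf("%s_%s.tsv", cn, part)),
                  trait_name = sprintf("%s_%s", cn, part))
  }
  run_mediation(rd("exposure"), rd("mediator"), rd("outcome"))
})
names(runs) <- chains

summary <- mediation_table(lapply(runs, `[[`, "decomposition"))
summary$declared <- vapply(runs, `[[`, logical(1), "mediation_declared")
summary$step2_excluded <- vapply(runs, function(r) length(r$step2_excluded),
                                 integer(1))
write.table(summary, "results/mediation_chains.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("two-step mediation decomposition (display-rounded to 3 dp):\n")
print(summary, digits = 3)
for (cn in chains) {
  r <- runs[[cn]]
  cat(sprintf(
    "%s: step-1 p = %.2g, step-2 p = %.2g, %d shared SNP(s) deleted before step 2\n",
    cn, r$p_step1, r$p_step2, length(r$step2_excluded)
  ))
}
cat("\nnote: with both step effects negative the mediated contribution\n")
cat("beta12 is positive — an exposure that lowers a protective mediator\n")
cat("raises outcome risk through it.\n")
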