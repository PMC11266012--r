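#!/usr/bin/env Rscript
# Step 1: build the synthetic study.
#
# Generates a miniature stand-in for the real study design: a panel of
# obesity- and lipid-metabolism-like exposure GWAS (risk factors, protective
# factors, and nulls) screened against one shared binary outcome, plus two
# exposure -> mediator -> outcome chains with known truth. All tables are
# written as canonical sumstats TSVs under scratch/synthetic_study/ for the
# downstream scripts; the generative truth is written alongside.

library(mrtwosample)

out_dir <- "scratch/synthetic_study"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
seed <- 20240601L

# exposure panel: name -> true causal effect on the outcome (log-odds)
panel <- c(
  obesity_like    =  0.30,   # risk factor, OR ~ 1.35
  bmi_like        =  0.32,
  hdl_like        = -0.25,   # protective, OR ~ 0.78
  apoa1_like      = -0.22,
  resistin_like   =  0.15,
  ldl_like        =  0.00,   # nulls
  triglyceride_like = 0.00,
  adiponectin_like  = 0.00
)

sims <- lapply(seq_along(panel), function(i) {
  simulate_two_sample(sim_config(
    k = 60, true_beta = panel[[i]], binary_outcome = TRUE,
    seed = seed + i
  ))
})
names(sims) <- names(panel)

# each exposure gets its own SNP namespace; the outcome study pools the
# per-panel outcome rows into one shared table, re-spaced on the clumping
# grid so the pooled panel stays mutually independent
for (nm in names(sims)) {
  for (tb in c("exposure", "outcome")) {
    sims[[nm]][[tb]]$records$snp_id <-
      paste0(nm, "_", sims[[nm]][[tb]]$records$snp_id)
  }
}
out_rec <- do.call(rbind, lapply(sims, function(s) s$outcome$records))
slot <- seq_len(nrow(out_rec)) - 1L
out_rec$chrom <- as.character(slot %% 22L + 1L)
out_rec$pos <- (slot %/% 22L) * 11000000L + 1000000L
for (nm in names(sims)) {
  idx <- match(sims[[nm]]$exposure$records$snp_id, out_rec$snp_id)
  sims[[nm]]$exposure$records$pos <- out_rec$pos[idx]
  sims[[nm]]$exposure$records$chrom <- out_rec$chrom[idx]
  sims[[nm]]$exposure$trait_name <- nm
  write_sumstats(sims[[nm]]$exposure, file.path(out_dir, paste0(nm, ".tsv")))
}
outcome <- sumstat_table("nsom_like", out_rec)
write_sumstats(outcome, file.path(out_dir, "nsom_like.tsv"))

# mediation chains mirroring the obesity -> HDL-C / BMI -> apoA1 structure:
# negative step effects, positive direct effect, 4 shared instruments
chains <- list(
  chain_obesity_hdl = simulate_mediation_chain(
    k_x = 30, k_m = 30, overlap = 4, beta1 = -0.20, beta2 = -0.25,
    direct_effect = 0.10, seed = seed + 101L
  ),
  chain_bmi_apoa1 = simulate_mediation_chain(
    k_x = 30, k_m = 30, overlap = 4, beta1 = -0.18, beta2 = -0.22,
    direct_effect = 0.12, seed = seed + 102L
  )
)
for (cn in names(chains)) {
  ch <- chains[[cn]]
  for (tb in c("exposure", "mediator", "outcome")) {
    ch[[tb]]$trait_name <- paste0(cn, "_", tb)
    write_sumstats(ch[[tb]], file.path(out_dir, paste0(cn, "_", tb, ".tsv")))
  }
}

truth <- data.frame(
  dataset = c(names(panel), names(chains)),
  true_beta = c(unname(panel),
                sapply(chains, function(c) c$truth$total)),
  note = c(rep("exposure -> outcome causal effect", length(panel)),
           sprintf("total effect; beta1 %.2f, beta2 %.2f, direct %.2f",
                   sapply(chains, function(c) c$truth$beta1),
                   sapply(chains, function(c) c$truth$beta2),
                   sapply(chains, function(c) c$truth$direct_effect)))
)
write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf(
  "wrote %d exposure tables, 1 pooled outcome (%d SNPs), 2 mediation chains to %s\n",
  length(panel), nrow(out_rec), out_dir
))
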