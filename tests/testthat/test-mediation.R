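test_that("decomposition identities hold to machine precision", {
  d <- two_step_mediation(0.35, -0.21, -0.17, se1 = 0.03, se2 = 0.05)
  expect_identical(d$beta12, -0.21 * -0.17)
  expect_identical(d$beta_dir, 0.35 - (-0.21 * -0.17))
  expect_identical(d$beta_per * d$beta_all, d$beta12)
  expect_equal(d$se12,
               sqrt((-0.21)^2 * 0.05^2 + (-0.17)^2 * 0.03^2))

  # both step effects negative => positive mediated contribution
  expect_gt(d$beta12, 0)

  # null mediation: beta1 = 0
  d0 <- two_step_mediation(0.2, 0, -0.3)
  expect_equal(d0$beta12, 0)
  expect_equal(d0$beta_dir, 0.2)
  expect_equal(d0$beta_per, 0)

  # proportion undefined at zero total effect: flagged, not thrown
  dz <- two_step_mediation(0, 0.1, 0.2)
  expect_false(dz$beta_per_defined)
  expect_true(is.na(dz$beta_per))
})

test_that("published step estimates re-derive the reported decomposition", {
  est <- nsom_mediation_estimates()
  expect_equal(nrow(est), 4L)
  out <- rederive_mediation(est)

  expect_equal(out$beta12, c(0.016, 0.010, 0.050, 0.041))
  # the obesity -> apoA1 row's reported direct effect is inconsistent with
  # the stated formula (an apparent transcription slip in the source), so
  # only the other three rows are checked against the reported values
  expect_equal(out$beta_dir[c(1, 3, 4)], c(0.146, 0.267, 0.276))
  expect_equal(out$beta_per[c(1, 2, 4)], c(0.099, 0.063, 0.130))
  # full-precision formula values for the remaining cells
  expect_equal(out$beta_dir[2], round(0.162 - (-0.045) * (-0.226), 3))
  expect_equal(out$beta_per[3],
               round((-0.233) * (-0.214) / 0.317, 3))

  # display rounding only: the mediation_result keeps full precision
  d <- two_step_mediation(est$beta_all[1], est$beta1[1], est$beta2[1])
  expect_identical(d$beta12, est$beta1[1] * est$beta2[1])
  expect_equal(mediation_table(d)$beta12, 0.016)
})

test_that("run_mediation wires the two steps and deletes shared SNPs", {
  chain <- simulate_mediation_chain(k_x = 20, k_m = 20, overlap = 4,
                                    seed = 42)
  med <- run_mediation(chain$exposure, chain$mediator, chain$outcome)

  # set oracle: step-2 k = harmonized mediator instruments minus exclusions
  med_iv <- select_instruments(chain$mediator)
  h_med <- harmonize(med_iv, chain$outcome)
  expect_equal(med$fit_step2$k,
               nrow(h_med$records) - length(med$step2_excluded))
  # every designated shared SNP was excluded, none survives into step 2
  expect_true(all(chain$truth$shared_snps %in% med$step2_excluded))
  exp_iv <- select_instruments(chain$exposure)
  expect_length(
    intersect(exp_iv$records$snp_id,
              setdiff(h_med$records$snp_id, med$step2_excluded)), 0
  )

  expect_identical(med$decomposition$beta12,
                   med$fit_step1$beta * med$fit_step2$beta)

  # a clean, strong chain (no shared pleiotropic SNPs inflating step-1
  # heterogeneity) is declared mediating
  clean <- simulate_mediation_chain(k_x = 20, k_m = 20, overlap = 0,
                                    seed = 43)
  med_clean <- run_mediation(clean$exposure, clean$mediator, clean$outcome)
  expect_true(med_clean$mediation_declared)
  expect_lt(med_clean$p_step1, 0.05)
  expect_lt(med_clean$p_step2, 0.05)
})

test_that("no exposure-mediator association means no declared mediation", {
  chain <- simulate_mediation_chain(k_x = 20, k_m = 20, overlap = 0,
                                    beta1 = 0, beta2 = -0.25,
                                    direct_effect = 0.15, seed = 7)
  med <- run_mediation(chain$exposure, chain$mediator, chain$outcome)
  expect_false(med$mediation_declared)
  expect_gt(med$p_step1, 0.05)
})

test_that("an emptied step-2 instrument set is a hard error", {
  chain <- simulate_mediation_chain(k_x = 10, k_m = 10, overlap = 10,
                                    seed = 3)
  expect_error(
    run_mediation(chain$exposure, chain$mediator, chain$outcome),
    "step-2"
  )
})

test_that("the generative chain's truth arithmetic is self-consistent", {
  chain <- simulate_mediation_chain(beta1 = -0.2, beta2 = -0.25,
                                    direct_effect = 0.1, seed = 1)
  expect_equal(chain$truth$total, 0.1 + (-0.2) * (-0.25))
  expect_equal(chain$truth$total, 0.15)
})
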