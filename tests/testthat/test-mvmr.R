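test_that("MVMR input assembly: union, joint clump, completeness audit", {
  st <- make_mvmr_study(k_per = 10, seed = 3)
  inp <- build_mvmr_input(st$sets, st$exposures, st$outcome)
  expect_s3_class(inp, "mvmr_input")
  # disjoint instruments, all present everywhere: k = union size
  union_ids <- unique(unlist(lapply(st$sets, function(s) s$records$snp_id)))
  expect_setequal(inp$snp_ids, union_ids)
  expect_equal(dim(inp$beta_exp), c(length(union_ids), 2L))

  # hand-assembled oracle: each matrix cell is that table's beta for the SNP
  for (j in 1:2) {
    tab <- st$exposures[[j]]$records
    expect_equal(inp$beta_exp[, j],
                 tab$beta[match(inp$snp_ids, tab$snp_id)])
    expect_equal(inp$se_exp[, j],
                 tab$se[match(inp$snp_ids, tab$snp_id)])
  }
  out_tab <- st$outcome$records
  expect_equal(inp$beta_out, out_tab$beta[match(inp$snp_ids, out_tab$snp_id)])

  # a SNP missing from one exposure table is dropped and audited
  st2 <- make_mvmr_study(k_per = 10, seed = 3)
  victim <- st2$sets[[1]]$records$snp_id[1]
  st2$exposures[[2]]$records <-
    st2$exposures[[2]]$records[st2$exposures[[2]]$records$snp_id != victim, ]
  inp2 <- build_mvmr_input(st2$sets, st2$exposures, st2$outcome)
  expect_false(victim %in% inp2$snp_ids)
  expect_true(victim %in% inp2$dropped$snp_id)
  expect_match(inp2$dropped$reason[inp2$dropped$snp_id == victim], "exp2")
})

test_that("three-exposure assembly matches a hand-built oracle", {
  st <- make_mvmr_study(k_per = 8, m = 3, coefs = c(0.4, 0.2, 0), seed = 9)
  inp <- build_mvmr_input(st$sets, st$exposures, st$outcome)
  expect_equal(ncol(inp$beta_exp), 3L)
  for (j in 1:3) {
    tab <- st$exposures[[j]]$records
    expect_equal(inp$beta_exp[, j], tab$beta[match(inp$snp_ids, tab$snp_id)])
  }
})

test_that("with m = 1 the MVMR estimate reduces to univariable IVW", {
  st <- make_mvmr_study(k_per = 30, m = 1, coefs = 0.5, seed = 4)
  tab <- st$exposures[[1]]$records
  inp <- list(exposure_names = "exp1",
              beta_exp = matrix(tab$beta, ncol = 1,
                                dimnames = list(NULL, "exp1")),
              se_exp = matrix(tab$se, ncol = 1),
              beta_out = st$outcome$records$beta,
              se_out = st$outcome$records$se)
  mv <- mvmr_ivw(inp)
  h <- harmonized_set(tab$beta, tab$se, st$outcome$records$beta,
                      st$outcome$records$se)
  uv <- mr_ivw(h)
  expect_equal(mv$estimates$beta, uv$beta, tolerance = 1e-12)
  expect_equal(mv$estimates$se, uv$se, tolerance = 1e-12)
})

test_that("MVMR recovers (0.5, 0) and respects column permutation", {
  est <- t(sapply(1:20, function(seed) {
    st <- make_mvmr_study(k_per = 50, coefs = c(0.5, 0), seed = seed)
    inp <- build_mvmr_input(st$sets, st$exposures, st$outcome)
    mvmr_ivw(inp)$estimates$beta
  }))
  mc_se <- apply(est, 2, sd) / sqrt(nrow(est))
  expect_lt(abs(mean(est[, 1]) - 0.5), 3 * mc_se[1] + 1e-3)
  expect_lt(abs(mean(est[, 2]) - 0), 3 * mc_se[2] + 1e-3)

  # permuting exposure columns permutes coefficients identically
  st <- make_mvmr_study(k_per = 40, coefs = c(0.5, 0), seed = 31)
  inp <- build_mvmr_input(st$sets, st$exposures, st$outcome)
  perm <- list(exposure_names = rev(inp$exposure_names),
               beta_exp = inp$beta_exp[, 2:1],
               se_exp = inp$se_exp[, 2:1],
               beta_out = inp$beta_out, se_out = inp$se_out)
  f1 <- mvmr_ivw(inp)$estimates
  f2 <- mvmr_ivw(perm)$estimates
  expect_equal(f2$beta, rev(f1$beta))
  expect_equal(f2$se, rev(f1$se))
})

test_that("collinear exposures raise a hard error naming the columns", {
  st <- make_mvmr_study(k_per = 20, seed = 6)
  inp <- build_mvmr_input(st$sets, st$exposures, st$outcome)
  dup <- inp
  dup$beta_exp <- cbind(inp$beta_exp, dup2 = inp$beta_exp[, 1])
  dup$se_exp <- cbind(inp$se_exp, dup2 = inp$se_exp[, 1])
  dup$exposure_names <- c(inp$exposure_names, "dup2")
  expect_error(mvmr_ivw(dup), "collinear")

  tiny <- list(exposure_names = c("a", "b"),
               beta_exp = matrix(rnorm(4), 2, 2,
                                 dimnames = list(NULL, c("a", "b"))),
               se_exp = matrix(0.01, 2, 2),
               beta_out = rnorm(2), se_out = rep(0.01, 2))
  expect_error(mvmr_ivw(tiny))
})
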