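test_that("Wald ratio arithmetic and boundary behaviour", {
  w <- wald_ratio(0.1, 0.01, 0.05, 0.01)
  expect_equal(w$beta, 0.5)
  expect_equal(w$se, 0.1)
  expect_equal(w$or_, exp(0.5))

  w0 <- wald_ratio(0.1, 0.01, 0, 0.01)
  expect_equal(w0$beta, 0)
  expect_equal(w0$pval, 1)

  expect_error(wald_ratio(0, 0.01, 0.05, 0.01), "beta_exp = 0")

  # brute-force oracle over random records
  set.seed(42)
  for (i in 1:10) {
    bx <- runif(1, 0.05, 0.3); sx <- runif(1, 0.005, 0.02)
    by <- rnorm(1, 0, 0.1); sy <- runif(1, 0.005, 0.02)
    w <- wald_ratio(bx, sx, by, sy)
    expect_equal(w$beta, by / bx)
    expect_equal(w$se, sy / abs(bx))
    expect_equal(w$pval, 2 * pnorm(-abs((by / bx) / (sy / abs(bx)))))
    w2 <- wald_ratio(bx, sx, by, sy, second_order = TRUE)
    expect_equal(w2$se, sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4))
  }
})

test_that("IVW matches a WLS-through-origin oracle to 1e-10", {
  set.seed(9)
  k <- 30
  bx <- rnorm(k, 0.1, 0.03)
  sy <- runif(k, 0.005, 0.03)
  by <- 0.4 * bx + rnorm(k, 0, sy)
  h <- harmonized_set(bx, rep(0.01, k), by, sy)
  fit <- mr_ivw(h)
  oracle <- ivw_oracle(bx, by, sy)
  expect_equal(fit$beta, oracle$beta, tolerance = 1e-10)
  expect_equal(fit$extra$se_fixed, oracle$se_fixed, tolerance = 1e-10)
  # multiplicative random effects never shrinks below fixed
  expect_gte(fit$se, fit$extra$se_fixed)
  expect_equal(mr_ivw(h, "fixed")$se, fit$extra$se_fixed)
})

test_that("IVW limits: k = 2 with identical records, and noiseless data", {
  h2 <- harmonized_set(c(0.1, 0.1), c(0.01, 0.01), c(0.05, 0.05),
                       c(0.01, 0.01))
  expect_equal(mr_ivw(h2)$beta, 0.5)
  expect_error(mr_ivw(harmonized_set(0.1, 0.01, 0.05, 0.01)), "wald_ratio")

  bx <- seq(0.05, 0.3, length.out = 10)
  h <- harmonized_set(bx, rep(0.01, 10), 0.7 * bx, rep(0.02, 10))
  fit <- mr_ivw(h)
  expect_equal(fit$beta, 0.7)
  expect_equal(fit$extra$Q, 0)
  expect_equal(fit$se, fit$extra$se_fixed)
})

test_that("MR-Egger: intercept translation and no-pleiotropy limit", {
  set.seed(21)
  k <- 20
  bx <- runif(k, 0.05, 0.3)  # all positive: no re-orientation
  sy <- runif(k, 0.01, 0.03)
  by <- 0.3 * bx + rnorm(k, 0, sy)
  h0 <- harmonized_set(bx, rep(0.01, k), by, sy)
  f0 <- mr_egger(h0)
  h1 <- harmonized_set(bx, rep(0.01, k), by + 0.1, sy)
  f1 <- mr_egger(h1)
  expect_equal(f1$extra$intercept, f0$extra$intercept + 0.1,
               tolerance = 1e-10)
  expect_equal(f1$beta, f0$beta, tolerance = 1e-10)

  # with no pleiotropy the intercept is near 0 and the slope near IVW
  expect_lt(abs(f0$extra$intercept), 2 * f0$extra$intercept_se)
  expect_lt(abs(f0$beta - mr_ivw(h0)$beta), 3 * f0$se)

  expect_error(mr_egger(harmonized_set(c(1, 1), c(1, 1), c(1, 1), c(1, 1))),
               "at least 3")
})

test_that("MR-Egger detects directional pleiotropy at k = 200", {
  hits <- 0L
  n_rep <- 200L
  for (seed in seq_len(n_rep)) {
    h <- sim_hset(seed, k = 200, true_beta = 0.1,
                  pleiotropy = list(type = "directional",
                                    mean = 0.05, sd = 0.01),
                  palindromic_frac = 0)
    if (egger_intercept_test(h)$pval < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.8)
})

test_that("weighted median reduces to the plain median and resists outliers", {
  # equal weights (equal bx, equal sy), odd k: plain median of ratios
  k <- 11
  by <- c(0.31, 0.28, 0.35, 0.30, 0.29, 0.33, 0.27, 0.32, 0.30, 0.26, 0.34)
  h <- harmonized_set(rep(0.1, k), rep(0.01, k), by * 0.1, rep(0.02, k))
  fit <- mr_weighted_median(h, n_boot = 200, seed = 4)
  expect_equal(fit$beta, median(by))

  # one wild outlier barely moves the estimate
  by_out <- by; by_out[1] <- 5
  h_out <- harmonized_set(rep(0.1, k), rep(0.01, k), by_out * 0.1,
                          rep(0.02, k))
  fit_out <- mr_weighted_median(h_out, n_boot = 200, seed = 4)
  expect_lt(abs(fit_out$beta - fit$beta), fit$se)

  expect_error(mr_weighted_median(harmonized_set(1, 1, 1, 1)), "at least 3")
})

test_that("mode estimators: degenerate density, bimodal sets, symmetry", {
  # all ratios identical: estimate is the common ratio
  bx <- c(0.1, 0.2, 0.3, 0.15)
  h <- harmonized_set(bx, rep(0.01, 4), 0.7 * bx, rep(0.02, 4))
  expect_equal(mr_mode(h, weighted = TRUE, n_boot = 0)$beta, 0.7)

  # bimodal ratios: 10 SNPs near 0.2, 3 near 0.9 -> mode in the 0.2 cluster
  set.seed(8)
  r <- c(rnorm(10, 0.2, 0.01), rnorm(3, 0.9, 0.01))
  k <- length(r)
  h_bi <- harmonized_set(rep(0.1, k), rep(0.01, k), r * 0.1, rep(0.02, k))
  fit_bi <- mr_mode(h_bi, weighted = FALSE, n_boot = 0)
  expect_lt(abs(fit_bi$beta - 0.2), 0.05)
  # independent KDE argmax oracle on a fine grid
  hband <- 0.9 * min(sd(r), IQR(r) / 1.349) * k^(-1 / 5)
  fine <- seq(min(r) - 1, max(r) + 1, length.out = 20001)
  dens <- sapply(fine, function(g) mean(dnorm(g, r, hband)))
  expect_lt(abs(fit_bi$beta - fine[which.max(dens)]), 0.01)

  # simple and weighted mode coincide under equal weights
  fit_s <- mr_mode(h_bi, weighted = FALSE, n_boot = 0)
  fit_w <- mr_mode(h_bi, weighted = TRUE, n_boot = 0)
  expect_equal(fit_s$beta, fit_w$beta)
})

test_that("scale equivariance and outcome sign flip hold for all methods", {
  set.seed(14)
  k <- 25
  bx <- runif(k, 0.05, 0.3)
  sy <- runif(k, 0.01, 0.03)
  by <- 0.25 * bx + rnorm(k, 0, sy)
  h <- harmonized_set(bx, rep(0.01, k), by, sy)
  betas <- function(h, seed = 5) {
    c(ivw = mr_ivw(h)$beta,
      egger = mr_egger(h)$beta,
      wm = mr_weighted_median(h, n_boot = 0)$beta,
      sm = mr_mode(h, weighted = FALSE, n_boot = 0)$beta,
      wmode = mr_mode(h, weighted = TRUE, n_boot = 0)$beta)
  }
  b0 <- betas(h)

  # multiplying all exposure betas by c divides every estimate by c
  h_sc <- harmonized_set(2 * bx, rep(0.01, k), by, sy)
  expect_equal(betas(h_sc), b0 / 2, tolerance = 1e-8)

  # negating the outcome negates every estimate
  h_ng <- harmonized_set(bx, rep(0.01, k), -by, sy)
  expect_equal(betas(h_ng), -b0, tolerance = 1e-8)
  expect_equal(mr_ivw(h_ng)$pval, mr_ivw(h)$pval)
  expect_equal(mr_egger(h_ng)$pval, mr_egger(h)$pval)
})

test_that("the five-method panel degrades gracefully and flags direction", {
  bx <- seq(0.05, 0.3, length.out = 12)
  h <- harmonized_set(bx, rep(0.01, 12), 0.6 * bx, rep(0.02, 12))
  panel <- run_all_methods(h, seed = 2, n_boot = 50)
  expect_named(panel$results, c("ivw", "egger", "weighted_median",
                                "simple_mode", "weighted_mode"))
  for (r in panel$results) expect_equal(r$beta, 0.6, tolerance = 1e-8)
  expect_true(panel$direction_consistent)
  expect_false(panel$degraded)

  h2 <- harmonized_set(c(0.1, 0.2), c(0.01, 0.01), c(0.05, 0.1),
                       c(0.02, 0.02))
  p2 <- run_all_methods(h2)
  expect_named(p2$results, "ivw")
  expect_true(p2$degraded)

  h1 <- harmonized_set(0.1, 0.01, 0.05, 0.02)
  p1 <- run_all_methods(h1)
  expect_named(p1$results, "wald")
  expect_true(p1$degraded)

  empty <- harmonized_set(numeric(0), numeric(0), numeric(0), numeric(0))
  expect_error(run_all_methods(empty), "empty")
})

test_that("IVW classification follows the risk/protective/null rules", {
  mk <- function(p, or) {
    mrtwosample:::mr_result("ivw", 10L, log(or),
                            abs(log(or)) / qnorm(1 - p / 2), p)
  }
  risk <- classify_effect(mk(0.02, 1.4))
  expect_equal(risk$label, "risk_factor")
  expect_false(risk$loo_required)

  prot <- classify_effect(mk(0.045, 0.8))
  expect_equal(prot$label, "protective_factor")
  expect_true(prot$loo_required)

  null <- classify_effect(mk(0.2, 1.1))
  expect_equal(null$label, "null")

  expect_error(classify_effect(mr_egger(harmonized_set(
    c(0.1, 0.2, 0.3), rep(0.01, 3), c(0.05, 0.1, 0.15), rep(0.02, 3)
  ))), "IVW")
})
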