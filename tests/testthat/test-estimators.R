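test_that("Wald ratio follows the delta-method formula", {
  ins <- make_insts(0.5, 1.0, se_out = 0.25)
  est <- wald_ratio(ins[1, ])
  expect_equal(est$beta, 2.0)
  expect_equal(est$se, 0.5)

  null_out <- make_insts(0.3, 0)
  expect_equal(wald_ratio(null_out[1, ])$or, 1)

  expect_error(wald_ratio(make_insts(0, 0.1)[1, ]), "beta_exp = 0")

  # the fixture's single significant instrument: p equals the outcome p
  tnk <- tnk_instruments()
  est74 <- wald_ratio(tnk[tnk$snp_id == "rs1738074", ])
  expect_equal(est74$or, 6.52, tolerance = 0.01)
  expect_equal(est74$pval, 2.33e-2, tolerance = 1e-3)
})

test_that("IVW equals the weighted regression through the origin", {
  # independent oracle: explicit weighted sums
  ins <- make_insts(c(0.1, 0.2, -0.3), c(0.05, 0.11, -0.14),
                    se_out = c(0.1, 0.2, 0.15))
  w <- 1 / ins$se_out^2
  slope_oracle <- sum(w * ins$beta_exp * ins$beta_out) / sum(w * ins$beta_exp^2)
  expect_equal(ivw(ins)$beta, slope_oracle)

  # single instrument degenerates to the Wald ratio
  one <- ins[1, ]
  expect_equal(ivw(one)$beta, wald_ratio(one)$beta)
  expect_equal(ivw(one)$se, wald_ratio(one)$se)
  expect_equal(ivw(one)$pval, wald_ratio(one)$pval)

  # exact linear data: slope recovered exactly, RE scale floored at 1
  exact <- make_insts(c(0.1, 0.2, 0.3), 0.7 * c(0.1, 0.2, 0.3))
  fit <- ivw(exact)
  expect_equal(fit$beta, 0.7, tolerance = 1e-12)
  expect_equal(fit$se, ivw(exact, "fixed")$se)  # sigma floored, not shrunk

  expect_error(ivw(make_insts(numeric(), numeric())), "at least one")
})

test_that("Egger regression recovers intercept and slope on exact data", {
  # exact-fit oracle: y = 0.2 + 0.5 x with all positive exposure betas
  x <- c(0.1, 0.15, 0.25, 0.3)
  ins <- make_insts(x, 0.2 + 0.5 * x)
  fit <- egger(ins)
  expect_equal(fit$slope$beta, 0.5, tolerance = 1e-10)
  expect_equal(fit$intercept$estimate, 0.2, tolerance = 1e-10)

  # line through the origin: zero intercept
  ins0 <- make_insts(x, 0.9 * x)
  fit0 <- egger(ins0)
  expect_equal(fit0$intercept$estimate, 0, tolerance = 1e-10)
  expect_equal(fit0$slope$beta, 0.9, tolerance = 1e-10)

  expect_error(egger(make_insts(c(0.1, 0.2), c(0.1, 0.1))), "at least 3")
})

test_that("Egger matches a weighted lm oracle on noisy data", {
  d <- generate_two_sample(synthetic_truth(theta = 0.4, seed = 7,
                                           pleiotropy_mean = 0.03,
                                           pleiotropy_sd = 0.02))
  ins <- d$instruments
  s <- sign(ins$beta_exp)
  ref <- stats::lm(I(ins$beta_out * s) ~ I(ins$beta_exp * s),
                   weights = 1 / ins$se_out^2)
  fit <- egger(ins)
  expect_equal(fit$slope$beta, unname(stats::coef(ref)[2]), tolerance = 1e-10)
  expect_equal(fit$intercept$estimate, unname(stats::coef(ref)[1]),
               tolerance = 1e-10)
  # residual scale here exceeds 1, so SEs match lm's t-based summary
  sm <- summary(ref)
  if (sm$sigma > 1) {
    expect_equal(fit$slope$se, unname(sm$coefficients[2, 2]), tolerance = 1e-10)
    expect_equal(fit$intercept$pval, unname(sm$coefficients[1, 4]),
                 tolerance = 1e-10)
  }
})

test_that("weighted median interpolates the cumulative standardized weights", {
  # equal weights, odd count: plain median
  expect_equal(mrceliac:::weighted_median_point(c(1, 2, 3), c(1, 1, 1)), 2)
  # hand-computed interpolation: s = (0.125, 0.625), 0 + (0.5-0.125)/0.5
  expect_equal(mrceliac:::weighted_median_point(c(0, 1), c(1, 3)), 0.75)
  expect_error(mrceliac:::weighted_median_point(c(0, 1), c(0, 0)), "zero")

  d <- generate_two_sample(synthetic_truth(theta = 0.3, seed = 5, n_snps = 7))
  a <- weighted_median(d$instruments, n_boot = 200, seed = 9)
  b <- weighted_median(d$instruments, n_boot = 200, seed = 9)
  expect_identical(a, b)  # deterministic given seed
  expect_error(weighted_median(d$instruments, n_boot = 200), "seed")
})

test_that("Cochran's Q measures dispersion around the pooled estimate", {
  # identical ratios: zero heterogeneity
  ins <- make_insts(c(0.1, 0.2, 0.4), 0.5 * c(0.1, 0.2, 0.4))
  q0 <- cochran_q(ins, 0.5)
  expect_equal(q0$q_stat, 0)
  expect_equal(q0$pval, 1)

  # hand evaluation: ratios {0, 2}, unit weights, theta 1 -> Q = 2, df = 1
  ins2 <- make_insts(c(1, 1), c(0, 2), se_out = c(1, 1))
  q2 <- cochran_q(ins2, 1)
  expect_equal(q2$q_stat, 2)
  expect_equal(q2$df, 1L)

  expect_error(cochran_q(make_insts(0.1, 0.1), 1), "at least 2")

  # Q is minimized at the fixed-effect IVW estimate
  for (seed in 1:20) {
    d <- generate_two_sample(synthetic_truth(theta = 0.4, seed = seed,
                                             pleiotropy_sd = 0.05))
    th <- ivw(d$instruments)$beta
    q_at <- cochran_q(d$instruments, th)$q_stat
    for (delta in c(-0.05, 0.05)) {
      expect_gte(cochran_q(d$instruments, th + delta)$q_stat, q_at)
    }
  }
})

test_that("instrument strength sums per-SNP squared z-scores", {
  ins <- make_insts(0.02, 0.1, se_exp = 0.02)
  expect_equal(instrument_strength(ins)$combined_f, 1)  # beta = se -> F = 1

  # rs13151961: z ~ 8.615 -> F ~ 74.2
  se <- se_from_pval(-0.3239, 6.31e-18)
  one <- make_insts(-0.3239, 0.1, se_exp = se)
  expect_equal(unname(instrument_strength(one)$per_snp_f), 74.2, tolerance = 0.01)

  s <- instrument_strength(tnk_instruments())
  expect_equal(s$combined_f, sum(s$per_snp_f))
  expect_gt(s$combined_f, 500)
})

test_that("BH adjustment matches the step-up rule and p.adjust", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(c(1, 1)), c(1, 1))
  expect_error(bh_fdr(c(0.1, 0)), "0, 1")

  set.seed(3)
  for (i in 1:10) {
    p <- stats::runif(sample(2:30, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, stats::p.adjust(p, "BH"))  # independent implementation
    expect_true(all(adj >= p) && all(adj <= 1))
  }
})

test_that("MR power calculation behaves like a test size/consistency curve", {
  expect_equal(mr_power_binary(1e4, 0.3, 0.02, or_alt = 1, alpha = 0.05), 0.05)
  # monotone in n and |log OR|
  ns <- c(1e3, 1e4, 1e5, 1e6)
  pw <- vapply(ns, function(n) mr_power_binary(n, 0.3, 0.02, 1.5), numeric(1))
  expect_true(all(diff(pw) >= 0))
  ors <- c(1.1, 1.3, 1.7, 2.5)
  pw2 <- vapply(ors, function(o) mr_power_binary(1e4, 0.3, 0.02, o), numeric(1))
  expect_true(all(diff(pw2) >= 0))
  expect_equal(mr_power_binary(1e9, 0.3, 0.02, 1.2), 1, tolerance = 1e-6)
  expect_error(mr_power_binary(-1, 0.3, 0.02, 1.5))
})

test_that("estimators are invariant to allele re-orientation", {
  d <- generate_two_sample(synthetic_truth(theta = 0.5, seed = 21,
                                           pleiotropy_sd = 0.03))
  ins <- d$instruments
  flip <- ins
  idx <- c(2, 5, 9)
  flip$beta_exp[idx] <- -flip$beta_exp[idx]
  flip$beta_out[idx] <- -flip$beta_out[idx]
  expect_equal(ivw(flip), ivw(ins))
  expect_equal(egger(flip)$slope$beta, egger(ins)$slope$beta)
  expect_equal(egger(flip)$intercept$estimate, egger(ins)$intercept$estimate)
  expect_equal(weighted_median(flip, n_boot = 100, seed = 2)$beta,
               weighted_median(ins, n_boot = 100, seed = 2)$beta)
  th <- ivw(ins)$beta
  expect_equal(cochran_q(flip, th), cochran_q(ins, th))
})

test_that("every estimate keeps OR = exp(beta) inside its CI", {
  tnk <- tnk_instruments()
  ests <- dplyr::bind_rows(ivw(tnk), egger(tnk)$slope,
                           weighted_median(tnk, seed = 4),
                           run_presso(tnk, seed = 4)$estimate)
  expect_equal(ests$or, exp(ests$beta))
  expect_true(all(ests$ci_low <= ests$or & ests$or <= ests$ci_high))
})
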