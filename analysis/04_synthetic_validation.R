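#!/usr/bin/env Rscript
# Validate the estimator machinery on synthetic two-sample data with known
# causal truth: IVW calibration, MR-PRESSO outlier detection, weighted-
# median robustness, Egger pleiotropy recovery, MVMR effect recovery and
# directional (bidirectional-MR) discrimination.
#
# Finding: under the fixture-like signal-to-noise regime the IVW test is
# calibrated (type-I ~0.04, 95% CI coverage ~0.95), MR-PRESSO detects a
# 10-sigma planted outlier essentially always while holding its null size,
# the weighted median stays near-unbiased with 40% invalid instruments,
# and MVMR recovers three simultaneous effects at the 91-instrument design
# scale used for the celiac + smoking + waist-circumference model.

library(mrceliac)

dir.create("results", showWarnings = FALSE)
rows <- list()
note <- function(metric, value, n) {
  rows[[length(rows) + 1]] <<- tibble::tibble(metric = metric, value = value,
                                              n_replicates = n)
  cat(sprintf("%-45s %8.4f  (n = %d)\n", metric, value, n))
}

# IVW calibration at the study scale (theta = ln 1.72)
n <- 1000
rej <- cover <- logical(n)
for (i in seq_len(n)) {
  d0 <- generate_two_sample(synthetic_truth(theta = 0, seed = 20000 + i))
  rej[i] <- ivw(d0$instruments)$pval < 0.05
  d1 <- generate_two_sample(synthetic_truth(theta = log(1.72), seed = 40000 + i))
  e <- ivw(d1$instruments)
  cover[i] <- e$ci_low <= 1.72 && 1.72 <= e$ci_high
}
note("IVW type-I error at alpha 0.05", mean(rej), n)
note("IVW 95% CI coverage", mean(cover), n)

# MR-PRESSO: planted 10-sigma outlier detection and null size
hit <- vapply(1:100, function(i) {
  d <- generate_two_sample(synthetic_truth(theta = 0.3, n_snps = 10,
                                           outlier_frac = 0.1,
                                           outlier_shift = 10, seed = 1000 + i))
  pr <- run_presso(d$instruments, n_sim = 1000, seed = 1000 + i)
  all(d$instruments$snp_id[d$truth$outlier_idx] %in% pr$outliers)
}, logical(1))
note("MR-PRESSO planted-outlier detection rate", mean(hit), 100)
null_rej <- vapply(1:500, function(i) {
  d <- generate_two_sample(synthetic_truth(theta = 0, n_snps = 10,
                                           seed = 5000 + i))
  run_presso(d$instruments, n_sim = 500, seed = 5000 + i)$global_pval < 0.05
}, logical(1))
note("MR-PRESSO null global-test size", mean(null_rej), 500)

# Weighted median vs IVW with 40% invalid instruments
wm_b <- ivw_b <- numeric(500)
for (i in 1:500) {
  d <- generate_two_sample(synthetic_truth(theta = 0.3, n_snps = 10,
                                           outlier_frac = 0.4,
                                           outlier_shift = 5, seed = 70000 + i))
  ins <- d$instruments
  wm_b[i] <- weighted_median(ins, n_boot = 1, seed = 1)$beta - 0.3
  ivw_b[i] <- ivw(ins)$beta - 0.3
}
note("weighted-median median bias (40% invalid)", median(wm_b), 500)
note("IVW median bias (40% invalid)", median(ivw_b), 500)

# Egger intercept under directional pleiotropy (mean 0.05)
inter <- vapply(1:500, function(i) {
  d <- generate_two_sample(synthetic_truth(theta = 0.3, pleiotropy_mean = 0.05,
                                           pleiotropy_sd = 0.01,
                                           gamma_sign = "positive",
                                           seed = 60000 + i))
  egger(d$instruments)$intercept$estimate
}, numeric(1))
note("Egger intercept mean (true pleiotropy 0.05)", mean(inter), 500)

# MVMR recovery at the 91-instrument, 3-exposure design
ok <- vapply(1:200, function(i) {
  g <- generate_multivariable(91, 3, c(0.4, 1.6, 1.7), seed = 80000 + i)
  est <- mvmr_ivw(g$input)
  all(abs(est$beta - c(0.4, 1.6, 1.7)) <= 3 * est$se)
}, logical(1))
note("MVMR recovery within 3 SEs (k=91, m=3)", mean(ok), 200)

# Directional discrimination: forward effect only
dir_ok <- vapply(1:200, function(i) {
  fwd <- generate_two_sample(synthetic_truth(theta = 0.5, seed = 81000 + i,
                                             se_out_range = c(0.08, 0.12)))
  rev <- generate_two_sample(synthetic_truth(theta = 0, seed = 82000 + i,
                                             se_out_range = c(0.08, 0.12)))
  ivw(fwd$instruments)$pval < 0.05 && ivw(rev$instruments)$pval >= 0.05
}, logical(1))
note("bidirectional: forward-only significance rate", mean(dir_ok), 200)

readr::write_csv(dplyr::bind_rows(rows), "results/synthetic_validation.csv")
cat("\n-> results/synthetic_validation.csv\n")
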