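#!/usr/bin/env Rscript
# Sensitivity analyses for the mature T/NK-cell lymphoma signal: per-SNP
# Wald ratios (forest-plot data), leave-one-out, and removal of the
# potential confounder instrument rs653178 (associated with obesity and
# smoking traits).
#
# Finding: the risk effect is not driven by any single variant (all
# leave-one-out IVW ORs stay above 1 and the rs653178-omitted model stays
# significant: IVW p 1.7e-2, MR-PRESSO p 4.0e-2). The only individually
# significant instrument is rs1738074 in the TAGAP locus (Wald OR 6.5,
# p 2.3e-2).

library(mrceliac)

dir.create("results", showWarnings = FALSE)

tnk <- fixture_instruments("Mature T/NK-cell lymphomas")

forest <- single_snp_estimates(tnk)
readr::write_csv(forest, "results/single_snp_wald.csv")
cat("Per-SNP Wald ratios -> results/single_snp_wald.csv\n")
cat("Individually significant instruments (p < 0.05):\n")
print(as.data.frame(forest[forest$pval < 0.05,
                           c("snp_id", "or", "ci_low", "ci_high", "pval")]),
      digits = 3)

loo <- leave_one_out(tnk, "ivw")
readr::write_csv(loo, "results/leave_one_out_ivw.csv")
cat("\nLeave-one-out IVW OR range: [",
    round(min(loo$or), 3), ",", round(max(loo$or), 3),
    "]; max p =", signif(max(loo$pval), 3), "\n")

conf <- remove_snps_rerun(tnk, "rs653178",
                          study_config(methods = c("ivw", "presso"), seed = 1))
readr::write_csv(conf, "results/confounder_removed.csv")
cat("\nAfter removing rs653178 (10 instruments):\n")
print(as.data.frame(conf[, c("method", "nsnp", "pval", "or", "ci_low",
                             "ci_high")]), digits = 3)
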