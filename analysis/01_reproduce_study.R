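#!/usr/bin/env Rscript
# Reproduce the full 8-outcome x 4-method causal-estimate grid for celiac
# disease against lymphoma subtypes and small bowel cancer, from the
# packaged instrument-level fixture, and diff it against the published
# estimates.
#
# Finding: only mature T/NK-cell lymphoma shows a causal risk effect
# (IVW OR 1.72, p 5.3e-3, FDR-significant across the 8-outcome family);
# every computed OR sits within 0.04 of the published value, and the IVW
# ORs match the published two decimals for 7 of 8 outcomes (the published
# non-follicular block is not reproducible from the published per-SNP
# inputs; see the methods vignette).

library(mrceliac)
suppressMessages(library(dplyr))

dir.create("results", showWarnings = FALSE)

fx <- celiac_lymphoma_fixture()
grid <- run_study(fx$exposure, fx$outcomes, study_config(seed = 1))
readr::write_csv(grid, "results/study_grid.csv")

pub <- published_estimates()
cmp <- inner_join(grid, pub, by = c("outcome_id" = "outcome", "method"),
                  suffix = c("_computed", "_published")) |>
  transmute(outcome_id, method,
            or_computed = round(or_computed, 4), or_published,
            or_diff = round(or_computed - or_published, 4),
            pval_computed = signif(pval_computed, 3), pval_published)
readr::write_csv(cmp, "results/published_comparison.csv")

cat("Estimate grid:", nrow(grid), "rows ->  results/study_grid.csv\n")
sig <- grid |> filter(pval_fdr < 0.05)
cat("FDR-significant rows (alpha 0.05, per-method family):\n")
print(as.data.frame(sig[, c("outcome_id", "method", "nsnp", "pval",
                            "pval_fdr", "or", "ci_low", "ci_high")]),
      digits = 3)
cat("\nLargest |OR difference| vs published:",
    max(abs(cmp$or_diff)), "\n")
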