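#!/usr/bin/env Rscript

# Step 3 — paired statistics and agreement analysis.
#
# Reads the per-patient-state table of step 2, runs the distribution-gated
# paired test (Shapiro-gated paired t / Wilcoxon signed-rank) for every
# index and WSS summary, and the Bland-Altman agreement of model FFR
# against the synthetic invasive channel. Writes the results tables under
# results/.

library(coroflow)

tab <- read.csv("results/cohort_table.csv")
validation <- if (file.exists("results/validation_ffr.csv"))
  read.csv("results/validation_ffr.csv") else NULL

cohort <- structure(list(table = tab, validation = validation,
                         cfg = run_config(n = 26, seed = 0)),
                    class = "cohort_result")
st <- cohort_stats(cohort)

write.csv(st$paired, "results/paired_tests.csv", row.names = FALSE)
print(st$paired[, c("variable", "mean_pre", "mean_post", "delta_mean",
                    "test_used", "p_value")], digits = 3)

if (!is.null(st$bland_altman)) {
  ba <- st$bland_altman
  jsonlite::write_json(
    list(bias = ba$bias, sd = ba$sd, loa_low = ba$loa_low,
         loa_high = ba$loa_high, pct_within_loa = ba$pct_within_loa, n = ba$n),
    "results/bland_altman.json", auto_unbox = TRUE, digits = NA)
  cat(sprintf("\nBland-Altman (model vs synthetic invasive FFR, %% diff):\n"))
  cat(sprintf("  bias %.3f%%, SD %.3f%%, LOA [%.3f, %.3f], %.0f%% within LOA\n",
              ba$bias, ba$sd, ba$loa_low, ba$loa_high, 100 * ba$pct_within_loa))
}
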