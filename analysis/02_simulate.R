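#!/usr/bin/env Rscript

# Step 2 — tune and simulate every patient-state.
#
# For each patient and each state (pre/post AVR): tune the aortic RCR to
# the state's pressure targets, tune the coronary outlets to the resting
# (4% of CO) and hyperemic (10-12%) flow targets with the 3:1 L:R velocity
# ratio, run the 7-cycle rest and hyperemia simulations, and collect the
# coronary indices (FFR, iFR, Pd/Pa, CFR, flows) and the peri-lesion WSS
# summaries (TAWSS, OSI, high-WSS exposure). Writes the per-patient-state
# table and the synthetic invasive-FFR validation pairs under results/.

library(coroflow)

cfg <- run_config(n = 26, seed = 0)
patients <- if (dir.exists("results/cohort")) {
  lapply(list.files("results/cohort", pattern = "^patient_.*json$",
                    full.names = TRUE), read_patient_json)
} else NULL

t0 <- Sys.time()
res <- run_cohort(cfg, patients = patients, progress = TRUE)
cat(sprintf("cohort run: %.0f s, %d/%d patients completed\n",
            as.numeric(Sys.time() - t0, units = "secs"),
            res$completed, res$attempted))

dir.create("results", showWarnings = FALSE)
write.csv(res$table, "results/cohort_table.csv", row.names = FALSE)
if (!is.null(res$validation))
  write.csv(res$validation, "results/validation_ffr.csv", row.names = FALSE)

pre <- res$table[res$table$state == "pre", ]
cat(sprintf("pre-AVR:  FFR %.3f (%.3f), iFR %.3f, CFR %.2f, OSI %.3f\n",
            mean(pre$ffr), sd(pre$ffr), mean(pre$ifr), mean(pre$cfr),
            mean(pre$osi_mean)))
post <- res$table[res$table$state == "post", ]
cat(sprintf("post-AVR: FFR %.3f (%.3f), iFR %.3f, CFR %.2f, OSI %.3f\n",
            mean(post$ffr), sd(post$ffr), mean(post$ifr), mean(post$cfr),
            mean(post$osi_mean)))
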