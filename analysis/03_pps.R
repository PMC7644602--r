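#!/usr/bin/env Rscript
# Peripersonal space analysis: check the expectancy drift, build the
# time-matched approach-minus-receding delta curve per subject, fit the
# bounded sigmoid (central point xc = PPS size, b = gradient), retain fits
# with R2 > 0.5, and contrast nearest-distance facilitation against the
# tactile-only baseline.

suppressMessages(library(ppsmap))

ds <- read_trials("results/data/trials.csv", "results/data/subjects.csv")
pps_trials <- ds$trials[ds$trials$task == "PPS", ]

ed <- expectancy_diagnostic(pps_trials)
cat(sprintf("expectancy drift: %.1f ms of RT per s of onset delay (CI %.1f..%.1f)\n",
            1000 * ed$slope, 1000 * ed$ci[1], 1000 * ed$ci[2]))

out <- pps_results(ds)
dir.create("results/pps", recursive = TRUE, showWarnings = FALSE)
write.csv(out$curves, "results/pps/delta_curves.csv", row.names = FALSE, na = "")
write.csv(out$fits, "results/pps/sigmoid_fits.csv", row.names = FALSE, na = "")
write.csv(out$retention_log, "results/pps/retention.csv", row.names = FALSE)
write.csv(out$catch, "results/pps/catch_false_alarms.csv", row.names = FALSE)

for (i in seq_len(nrow(out$retention_log)))
  cat(sprintf("group %s: kept %d/%d sigmoid fits\n",
              out$retention_log$group[i], out$retention_log$kept[i],
              out$retention_log$attempted[i]))
fc <- baseline_contrast(filter_trials_pps(pps_trials)$trials)
cat(sprintf("nearest-distance facilitation: %.1f ms, t = %.2f, p = %.2g\n",
            1000 * fc$mean_difference, fc$statistic, fc$p))
cat(sprintf("catch false alarms: %.2f%% of catch trials\n",
            100 * mean(out$catch$fa_rate)))
cat("wrote results/pps/\n")
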