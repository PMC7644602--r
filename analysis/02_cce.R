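#!/usr/bin/env Rscript
# Crossmodal congruency analysis: clean trials (drop non-responses and RTs
# over 2 s), exclude subjects with fewer than 10 trials in any of the six
# condition cells, compute per-subject congruency metrics, and contrast them
# against zero.

suppressMessages(library(ppsmap))

ds <- read_trials("results/data/trials.csv", "results/data/subjects.csv")
out <- cce_results(ds)

dir.create("results/cce", recursive = TRUE, showWarnings = FALSE)
write.csv(out$results, "results/cce/cce_results.csv", row.names = FALSE, na = "")
write.csv(out$rejections, "results/cce/rejections.csv", row.names = FALSE)

ok <- out$results[!out$results$excluded, ]
rt_c <- contrast_vs_zero(ok$cce_rt)
ac_c <- contrast_vs_zero(ok$cce_acc)
cat(sprintf("analysed %d subjects (%d excluded)\n", nrow(ok), out$n_excluded))
cat(sprintf("congruency effect, RT: mean %.1f ms, t = %.2f, p = %.2g\n",
            1000 * rt_c$mean, rt_c$statistic, rt_c$p))
cat(sprintf("congruency effect, accuracy: mean %.1f pp, t = %.2f, p = %.2g\n",
            ac_c$mean, ac_c$statistic, ac_c$p))
cat("wrote results/cce/\n")
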