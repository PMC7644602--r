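#!/usr/bin/env Rscript
# Simulate the study cohort: TD n = 36, ASD n = 26, SZ n = 22, both tasks per
# subject (90 CCE + 462 PPS trials), covariate missingness as in the sample
# (one SZ gender, five full-scale IQs). Writes trials/subjects/truth CSVs.

suppressMessages(library(ppsmap))

seed <- 20201023
cfg <- run_config(seed = seed, out_dir = "results/data", cohort = cohort_spec())
ds <- run_simulate(cfg)

cat(sprintf("subjects: %d (%s)\n", nrow(ds$subjects),
            paste(sprintf("%s=%d", names(table(ds$subjects$group)),
                          table(ds$subjects$group)), collapse = ", ")))
cat(sprintf("trials: %d; missing gender: %d, missing FSIQ: %d\n",
            nrow(ds$trials), sum(is.na(ds$subjects$gender)),
            sum(is.na(ds$subjects$fsiq))))
cat("wrote results/data/{trials,subjects,truth}.csv\n")
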