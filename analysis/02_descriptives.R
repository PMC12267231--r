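#!/usr/bin/env Rscript
# Baseline characteristics by lactate quartile (Table-1 style) and the
# pooled 28-day mortality rate with its normal-approximation CI.

library(lacthresh)
tab <- read_cohort("results/analysis/cohort.csv")

qb <- quartile_bin(tab)
cat(sprintf("quartile cutpoints: %.2f / %.2f / %.2f mmol/L; group sizes %s\n",
            qb$cutpoints[1], qb$cutpoints[2], qb$cutpoints[3],
            paste(qb$group_n, collapse = "/")))

t1 <- baseline_table(tab, qb$bin)
utils::write.table(t1, "results/analysis/table1.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)

deaths <- sum(tab$mortality_28d)
p <- proportion_ci(deaths, nrow(tab))
cat(sprintf("28-day mortality %.1f%% (%d/%d), 95%% CI %.2f-%.2f%%\n",
            100 * p$proportion, deaths, nrow(tab),
            100 * p$ci_low, 100 * p$ci_high))
mort <- t1[t1$variable == "mortality_28d", ]
cat("mortality row group test:", mort$p_display[1], "\n")
cat("wrote results/analysis/table1.tsv\n")
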