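#!/usr/bin/env Rscript
# Forest-style subgroup analysis: adjusted per-unit lactate ORs within
# prespecified clinical strata (continuous stratifiers split at the
# in-sample median) and one interaction LRT p-value per stratifier.

library(lacthresh)
tab <- read_cohort("results/analysis/cohort.csv")

stratifiers <- c("hr", "temperature", "potassium", "wbc", "bicarbonate",
                 "rdw", "bun", "apache_iv", "sofa")
sg <- subgroup_effects(tab, stratifiers, covariates = model_ii_covariates())
sg$or_ci <- ifelse(is.na(sg$odds_ratio), "-",
                   sprintf("%.2f (%.2f, %.2f)", sg$odds_ratio, sg$ci_low,
                           sg$ci_high))
sg$interaction_p_display <- format_p(sg$interaction_p)
utils::write.table(sg, "results/analysis/subgroups.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)

for (s in unique(sg$stratifier)) {
  rows <- sg[sg$stratifier == s, ]
  cat(sprintf("%-12s %s | interaction p %s\n", s,
              paste(sprintf("%s: %s", rows$stratum, rows$or_ci),
                    collapse = "  "),
              rows$interaction_p_display[1]))
}
n_mod <- sum(tapply(sg$interaction_p, sg$stratifier, min) < 0.05)
cat(sprintf("%d of %d stratifiers show nominal effect modification\n",
            n_mod, length(stratifiers)))
cat("wrote results/analysis/subgroups.tsv\n")
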