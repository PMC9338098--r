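#!/usr/bin/env Rscript
# Stage 5: DNA methylation around ACRs.
#
# Weighted (count-pooled) methylation levels of the ACRs by context, with
# the coverage-below-3 missing-data rule, and context-specific profiles
# around ACR summits.

source(file.path("analysis", "00_common.R"))

state <- run_stage("methylation")

print(state$methylation$acr_levels, row.names = FALSE)
pr <- state$methylation$profiles
ctr <- pr[pr$bin_rel == 0 & pr$context == "CG", ]
fl <- pr[pr$bin_rel == -1000L & pr$context == "CG", ]
cat(sprintf("CG level at ACR center vs -1 kb flank: %.3f vs %.3f\n",
            mean(ctr$level, na.rm = TRUE), mean(fl$level, na.rm = TRUE)))
cat("tables written: methylation_acr_levels.tsv, methylation_profiles.tsv\n")
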