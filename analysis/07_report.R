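#!/usr/bin/env Rscript
# Stage 7: consolidated subgenome asymmetry report.
#
# Wilcoxon rank-sum / chi-square comparisons of ACR pileup and counts and
# gene expression between subgenomes, homeologs vs subgenome-unique genes,
# and duplicate classes, per genotype. No planted subgenome asymmetry
# exists in the default design, so significant rows reflect the nominal
# false-positive rate.

source(file.path("analysis", "00_common.R"))

state <- run_stage("report")

rep <- state$report
cat(sprintf("%d comparisons; %d significant at p < 0.05\n", nrow(rep),
            sum(rep$p < 0.05)))
print(head(rep[order(rep$p), ], 8), row.names = FALSE)
cat("table written: asymmetry_report.tsv\n")
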