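#!/usr/bin/env Rscript
# Stage 2: build the in silico 'hybrid' (A_C) by mixing the progenitors.
#
# ATAC/ChIP/RNA are mixed 1:1 (each parent's contribution equalized by
# depth rescaling); DNA methylation coverage is split in proportion to the
# parental genome sizes.

source(file.path("analysis", "00_common.R"))

state <- run_stage("hybrid")
hyb <- state$hybrid

cat(sprintf("hybrid ACR set: %d peaks (union of parental calls)\n",
            nrow(hyb$peaks)))
cat("per-replicate parental scale factors (ATAC):\n")
print(round(hyb$scale, 3))
cat("tables written: peaks_A_C.narrowPeak, hybrid_scale_factors.tsv\n")
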