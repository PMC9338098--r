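#!/usr/bin/env Rscript
# Stage 3: ACR taxonomy and comparisons.
#
# Filters peaks at fold enrichment > 3.4, splits genic/intergenic ACRs,
# annotates genomic features by midpoint, classifies three-way
# common/shared/genotype-specific overlap, tests differential enrichment
# (|log2FC| >= 1, p < 0.05) on the common ACRs of each genotype pair, ranks
# pileup deciles and assigns the six histone-association clusters.

source(file.path("analysis", "00_common.R"))

state <- run_stage("acr")

cat("three-way overlap classes per genotype:\n")
print(state$acr$venn)
for (nm in names(state$acr$deas)) {
  d <- state$acr$deas[[nm]]
  cat(sprintf("%s: %d common regions tested, %d differentially enriched\n",
              nm, nrow(d),
              sum(d$status %in% c("enriched_in_x", "enriched_in_y"))))
}
a <- state$acr$acrs$NAC
cat(sprintf("NAC: %.1f%% genic ACRs; histone clusters populated: %s\n",
            100 * mean(a$genic_flag == "gACR"),
            paste(sort(unique(na.omit(a$histone_cluster))),
                  collapse = " ")))
cat("tables written: acr_*.tsv, acr_venn_counts.tsv, dea_*.tsv\n")
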