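#!/usr/bin/env Rscript
# Stage 1: generate the synthetic multi-genotype, multi-omic dataset.
#
# Emulates the study design: two diploid progenitors mapped to disjoint
# subgenomes of the allopolyploid coordinate system, a resynthesized (RAC)
# and a natural (NAC) allopolyploid, with planted ACR loci (common /
# genotype-specific / differentially enriched), histone-mark combinations,
# ACR-depleted methylomes, and NB expression with planted DEGs and
# homeolog expression bias.

source(file.path("analysis", "00_common.R"))

state <- run_stage("simulate")
sim <- state$simulate

cat(sprintf("genome: %d chromosomes, %d genes (%d homeolog pairs)\n",
            nrow(sim$genome$layout), nrow(sim$genome$genes),
            sum(sim$genome$genes$origin_class == "homeolog") / 2))
tb <- table(sim$accessibility$truth$kind)
cat("planted ACR loci by kind:\n")
print(tb)
cat(sprintf("methylome sites per genotype/replicate: %d\n",
            nrow(sim$methylome$RAC[[1]])))
cat("tables written: genome_layout.tsv, genes.tsv, peaks_*.narrowPeak,",
    "truth_*.tsv\n")
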