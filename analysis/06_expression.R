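#!/usr/bin/env Rscript
# Stage 6: expression integration.
#
# TPM normalization and expression classes, NB differential expression
# (|log2FC| >= 1, padj <= 0.001) for the three genotype comparisons,
# homeolog expression-bias (BEG) classes, and the overlap between
# genotype-enriched ACR-associated genes and genotype-enriched DEGs.

source(file.path("analysis", "00_common.R"))

state <- run_stage("expression")

cls <- state$expression$classes
cat("expression classes (NAC):\n")
print(table(cls$class[cls$genotype == "NAC"]))
for (nm in names(state$expression$degs)) {
  d <- state$expression$degs[[nm]]
  cat(sprintf("%s: %d DEGs of %d genes\n", nm, sum(d$status != "ns"),
              nrow(d)))
}
for (g in names(state$expression$begs)) {
  b <- state$expression$begs[[g]]
  cat(sprintf("%s: %d A-biased, %d C-biased of %d homeolog pairs\n", g,
              sum(b$beg_class == "A_BEG"), sum(b$beg_class == "C_BEG"),
              nrow(b)))
}
cat("ACR x DEG overlap:\n")
print(state$expression$acr_deg, row.names = FALSE)
cat("tables written: expression_classes.tsv, deg_*.tsv, beg_*.tsv,",
    "acr_deg_overlap.tsv\n")
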