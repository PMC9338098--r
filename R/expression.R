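# Expression normalization (TPM), expression classes, a negative-binomial
# differential-expression caller (median-of-ratios size factors,
# method-of-moments dispersion, Wald-type test, Benjamini-Hochberg
# adjustment), ACR x DEG overlap statistics, and homeolog expression-bias
# (BEG) classification.

#' Transcripts per million
#'
#' `tpm_g = (count_g / length_kb_g) / sum_g(count / length_kb) * 1e6` per
#' sample; every column sums to 1e6.
#'
#' @param counts genes x samples matrix of non-negative counts.
#' @param gene_length vector of gene lengths in bp (> 0), recycled by name
#'   when named.
#' @return TPM matrix of the same shape.
#' @export
compute_tpm <- function(counts, gene_length) {
  counts <- as.matrix(counts)
  if (!is.null(names(gene_length)) && !is.null(rownames(counts)))
    gene_length <- gene_length[rownames(counts)]
  if (length(gene_length) != nrow(counts))
    stop("gene_length does not match the count matrix rows")
  if (any(gene_length <= 0)) stop("gene lengths must be > 0")
  rate <- counts / (gene_length / 1000)
  tot <- colSums(rate)
  if (any(tot == 0)) stop("a sample has zero total expression")
  sweep(rate, 2L, tot, "/") * 1e6
}

#' Expression classes from mean TPM
#'
#' high: TPM > 10; med: 1 <= TPM <= 10; low: 0 < TPM < 1; none: TPM = 0.
#'
#' @param tpm_mean per-gene mean TPM within a genotype.
#' @return factor with levels high/med/low/none.
#' @export
classify_expression <- function(tpm_mean) {
  if (any(tpm_mean < 0)) stop("TPM must be non-negative")
  cls <- ifelse(tpm_mean > 10, "high",
         ifelse(tpm_mean >= 1, "med",
         ifelse(tpm_mean > 0, "low", "none")))
  factor(cls, levels = c("high", "med", "low", "none"))
}

#' Median-of-ratios size factors
#'
#' DESeq-style: per sample, the median ratio of counts to the per-gene
#' geometric mean, computed over genes expressed in every sample.
#'
#' @param counts genes x samples matrix.
#' @return Numeric vector of size factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  lg <- log(counts)
  gm <- rowMeans(lg)
  use <- is.finite(gm)
  if (!any(use)) stop("no gene is expressed in every sample")
  sf <- apply(counts[use, , drop = FALSE], 2L, function(col)
    exp(median(log(col) - gm[use], na.rm = TRUE)))
  sf
}

#' Negative-binomial differential expression between two genotypes
#'
#' Counts are normalized with joint median-of-ratios size factors; per gene,
#' an NB dispersion is estimated by method of moments from the within-group
#' variances and moderated by flooring it at the genome-wide median of the
#' expressed genes' estimates (raw per-gene dispersion at n = 3 is too noisy
#' for a Wald test: genes with underestimated variance would dominate the
#' tail). The log fold change is tested with a Wald statistic (delta-method
#' standard error of the log mean ratio, standard normal reference), and
#' p-values are BH-adjusted. A gene is differential iff
#' `|log2FC| >= lfc_cut` and `padj <= padj_cut`.
#'
#' @param counts_x,counts_y genes x replicates count matrices (same genes in
#'   the same order; >= 2 replicates each).
#' @param lfc_cut,padj_cut thresholds (defaults 1 and 0.001).
#' @return data.frame `gene_id`, `base_mean`, `log2fc`, `p`, `padj`,
#'   `status` (`up_in_x`/`up_in_y`/`ns`).
#' @export
call_degs <- function(counts_x, counts_y, lfc_cut = 1, padj_cut = 0.001) {
  counts_x <- as.matrix(counts_x); counts_y <- as.matrix(counts_y)
  if (ncol(counts_x) < 2L || ncol(counts_y) < 2L)
    stop("at least 2 replicates per genotype are required")
  stopifnot(nrow(counts_x) == nrow(counts_y))
  nx <- ncol(counts_x); ny <- ncol(counts_y)
  all <- cbind(counts_x, counts_y)
  sf <- size_factors(all)
  k <- sweep(all, 2L, sf, "/")
  kx <- k[, seq_len(nx), drop = FALSE]
  ky <- k[, nx + seq_len(ny), drop = FALSE]
  mx <- rowMeans(kx); my <- rowMeans(ky)
  vx <- apply(kx, 1L, var); vy <- apply(ky, 1L, var)
  # pooled within-group method-of-moments dispersion, floored at the
  # genome-wide median over expressed genes (moderation)
  mu_bar <- (nx * mx + ny * my) / (nx + ny)
  v_bar <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
  disp <- pmax(0, (v_bar - mu_bar) / mu_bar^2)
  disp[!is.finite(disp)] <- 0
  expressed <- mu_bar > 5
  disp_prior <- if (any(expressed)) median(disp[expressed]) else 0
  disp <- pmax(disp, disp_prior)
  # Wald on the natural-log mean ratio; +0.5 pseudocount stabilizes zeros
  lmx <- log(mx + 0.5); lmy <- log(my + 0.5)
  se <- sqrt((1 / (mx + 0.5) + disp) / nx + (1 / (my + 0.5) + disp) / ny)
  z <- (lmx - lmy) / se
  p <- 2 * pnorm(-abs(z))
  # degenerate zero-variance, nonzero-difference genes: perfect separation
  sep <- v_bar == 0 & mx != my
  p[sep] <- 0
  p[v_bar == 0 & mx == my] <- 1
  padj <- p.adjust(p, method = "BH")
  log2fc <- (lmx - lmy) / log(2)
  status <- ifelse(abs(log2fc) >= lfc_cut & padj <= padj_cut,
                   ifelse(log2fc > 0, "up_in_x", "up_in_y"), "ns")
  ids <- rownames(counts_x)
  if (is.null(ids)) ids <- sprintf("gene_%d", seq_len(nrow(counts_x)))
  data.frame(gene_id = ids, base_mean = mu_bar, log2fc = log2fc, p = p,
             padj = padj, status = status, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Overlap of genotype-enriched ACR-associated genes with enriched DEGs
#'
#' For one side of a comparison: how many of the genotype-enriched DEGs are
#' associated with that genotype's enriched ACRs (genotype-specific ACRs or
#' ACRs with enriched differential accessibility), as a count and a
#' percentage of the enriched DEGs.
#'
#' @param acr_genes character vector of ACR-associated gene ids for the
#'   genotype.
#' @param enriched_degs character vector of the genotype-enriched DEG ids.
#' @return list with `n_overlap`, `n_degs`, `percent`.
#' @export
acr_deg_overlap <- function(acr_genes, enriched_degs) {
  ov <- length(intersect(unique(acr_genes), unique(enriched_degs)))
  n <- length(unique(enriched_degs))
  list(n_overlap = ov, n_degs = n,
       percent = if (n == 0) 0 else 100 * ov / n)
}

#' Classify homeolog pairs by expression bias
#'
#' Within one genotype, each homeolog pair is tested with a paired test
#' across replicates on the per-replicate log2 ratio of the A copy to the C
#' copy (0.5 pseudocount). As in [call_degs()], the per-pair standard
#' deviation of the ratios is moderated by flooring it at the median across
#' pairs (a raw per-pair sd over 3 replicates leaves a paired t with 2 df
#' and little power), and the moderated z is referenced against the normal.
#' A-biased (`A_BEG`) iff `log2FC >= lfc_cut` and BH-adjusted
#' p <= `padj_cut`; `C_BEG` symmetric; otherwise `no_BEG`.
#'
#' @param counts genes x replicates matrix for the genotype.
#' @param pairs data.frame with `a_gene`, `c_gene` (row names of `counts`).
#' @param lfc_cut,padj_cut thresholds (defaults 1 and 0.05).
#' @return data.frame `a_gene`, `c_gene`, `log2fc`, `p`, `padj`,
#'   `beg_class`. Pairs with a missing copy are dropped with a warning.
#' @export
classify_begs <- function(counts, pairs, lfc_cut = 1, padj_cut = 0.05) {
  counts <- as.matrix(counts)
  ok <- pairs$a_gene %in% rownames(counts) &
        pairs$c_gene %in% rownames(counts)
  if (any(!ok)) {
    warning(sum(!ok), " homeolog pair(s) skipped: copy missing from the ",
            "count matrix")
    pairs <- pairs[ok, , drop = FALSE]
  }
  n <- nrow(pairs)
  d <- log2((counts[pairs$a_gene, , drop = FALSE] + 0.5) /
            (counts[pairs$c_gene, , drop = FALSE] + 0.5))
  log2fc <- rowMeans(d)
  sds <- apply(d, 1L, sd)
  sd_floor <- median(sds)
  sds <- pmax(sds, sd_floor)
  p <- ifelse(sds == 0, ifelse(log2fc == 0, 1, 0),
              2 * pnorm(-abs(log2fc) / (sds / sqrt(ncol(d)))))
  padj <- p.adjust(p, method = "BH")
  beg <- ifelse(padj <= padj_cut & log2fc >= lfc_cut, "A_BEG",
         ifelse(padj <= padj_cut & log2fc <= -lfc_cut, "C_BEG", "no_BEG"))
  data.frame(a_gene = pairs$a_gene, c_gene = pairs$c_gene, log2fc = log2fc,
             p = p, padj = padj, beg_class = beg, stringsAsFactors = FALSE)
}
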