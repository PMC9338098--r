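# synthetic-data generator: determinism, planted structure, calibration of
# the emitted noise models

test_that("genome generation is deterministic and respects the design", {
  cfg <- tiny_config()
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1, g2)
  genes <- g1$genes
  expect_equal(sum(genes$subgenome == "A"), 15L)
  expect_equal(sum(genes$origin_class == "homeolog"), 20L)
  expect_silent(validate_genes(genes, g1$layout))
  # duplicate-class counts follow the configured proportions within rounding
  tb <- table(genes$dup_class)
  want <- cfg$dup_class_proportions * nrow(genes)
  for (cl in names(want))
    expect_lte(abs(tb[[cl]] - want[[cl]]), 1)
})

test_that("gene placement fails gracefully when the genome is too small", {
  cfg <- tiny_config(chrom_length = 2e4)
  expect_error(generate_genome(cfg), "chrom_length")
})

test_that("accessibility truth matches the planted fractions", {
  cfg <- tiny_config()
  genome <- generate_genome(cfg)
  acc <- generate_accessibility(cfg, genome)
  truth <- acc$truth
  expect_equal(sum(truth$kind == "common"), 12L)   # 0.3 * 40
  expect_equal(sum(truth$kind == "dea"), 8L)       # 0.2 * 40
  expect_equal(sum(truth$kind == "specific"), 60L) # 0.5 * 40 per genotype
  # every genotype carries exactly n_acrs + decoys
  for (g in c("RAC", "NAC")) {
    pk <- acc$peaks[[g]]
    expect_equal(sum(!is.na(pk$locus_id)), 40L)
    expect_equal(sum(is.na(pk$locus_id)), 4L)  # 10% sub-threshold decoys
    expect_true(all(pk$fold_enrichment[is.na(pk$locus_id)] <= 3.4))
  }
  # parents carry the hybrid's loci restricted to their subgenome
  expect_true(all(startsWith(acc$peaks$rapa$chrom, "A")))
  expect_true(all(startsWith(acc$peaks$oleracea$chrom, "C")))
  # all six histone combinations present among common loci
  expect_setequal(unique(na.omit(truth$cluster)), 1:6)
})

test_that("same seed reproduces the full dataset", {
  cfg <- tiny_config()
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$accessibility$truth, s2$accessibility$truth)
  expect_identical(s1$expression$counts, s2$expression$counts)
  expect_identical(s1$methylome$RAC[[1]], s2$methylome$RAC[[1]])
})

test_that("track enrichment over planted peaks matches the configured rate", {
  cfg <- tiny_config(n_acrs_per_genotype = 100L, frac_common = 1,
                     frac_specific = 0, frac_dea = 0, frac_low_fe = 0)
  genome <- generate_genome(cfg)
  acc <- generate_accessibility(cfg, genome)
  tr <- acc$tracks[["RAC.ATAC.1"]]
  pk <- acc$peaks$RAC
  per_peak <- vapply(seq_len(nrow(pk)), function(i)
    acrpoly:::.track_sum(tr, pk$chrom[i], pk$start[i], pk$end[i]) /
      (pk$end[i] - pk$start[i]), 0)
  # pileup-proportional amplitudes average out to background * enrichment
  want <- cfg$background_rate * cfg$peak_enrichment
  se <- sd(per_peak) / sqrt(length(per_peak))
  expect_lt(abs(mean(per_peak) - want), 3 * se + 0.05 * want)
})

test_that("methylome respects binomial support and planted depletion", {
  cfg <- tiny_config()
  genome <- generate_genome(cfg)
  acc <- generate_accessibility(cfg, genome)
  meth <- generate_methylome(cfg, genome, acc$peaks)
  tab <- meth$RAC[[1]]
  expect_true(all(tab$meth_reads <= tab$total_reads))
  expect_true(any(tab$total_reads < 3))  # exercises the missing-data rule
  # recovered in/out-of-ACR ratio close to the configured depletion
  acr <- merge_intervals(acc$peaks$RAC[, c("chrom", "start", "end")])
  lv_in <- region_level(tab, acr, context = "CG")
  genomewide <- data.frame(chrom = genome$layout$chrom, start = 0L,
                           end = genome$layout$length)
  lv_all <- region_level(tab, genomewide, context = "CG")
  out_rate <- cfg$meth_base_rate[["CG"]]
  ratio <- mean(lv_in, na.rm = TRUE) / out_rate
  expect_lt(abs(ratio - cfg$acr_meth_depletion), 0.08)
  expect_lt(abs(mean(lv_all, na.rm = TRUE) - out_rate), 0.02)
})

test_that("null depletion leaves ACR methylation at the base rate", {
  cfg <- tiny_config(acr_meth_depletion = 1)
  genome <- generate_genome(cfg)
  acc <- generate_accessibility(cfg, genome)
  tab <- generate_methylome(cfg, genome, acc$peaks)$RAC[[1]]
  acr <- merge_intervals(acc$peaks$RAC[, c("chrom", "start", "end")])
  lv <- region_level(tab, acr, context = "CG")
  expect_lt(abs(mean(lv, na.rm = TRUE) - cfg$meth_base_rate[["CG"]]), 0.05)
})

test_that("expression counts follow the configured NB model", {
  cfg <- tiny_config(n_homeolog_pairs = 500L,
                     n_unique_genes_per_subgenome = 500L,
                     chrom_length = 6e6, deg_fraction = 0, beg_fraction = 0)
  genome <- generate_genome(cfg)
  expr <- generate_expression(cfg, genome)
  cnt <- expr$counts$RAC
  # per-gene means are lognormal around nb_mean; the planted silent slice
  # aside, the median log2 mean should sit near log2(nb_mean)
  mu <- rowMeans(cnt)
  expect_lt(abs(median(log2(mu[mu > 0])) - log2(cfg$nb_mean)), 0.2)
  expect_equal(unname(colSums(expr$tpm$RAC)), rep(1e6, 3), tolerance = 1e-9)
  expect_true(all(is.na(expr$truth$deg_up_in)))
})

test_that("zero-noise mode emits expected values exactly", {
  cfg <- tiny_config(noise = "none")
  sim <- simulate_dataset(cfg)
  cnt <- sim$expression$counts$RAC
  expect_identical(cnt[, 1], cnt[, 2])
  tr1 <- sim$accessibility$tracks[["RAC.ATAC.1"]]
  tr2 <- sim$accessibility$tracks[["RAC.ATAC.2"]]
  expect_identical(tr1$steps, tr2$steps)
})
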